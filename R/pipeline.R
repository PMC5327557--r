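# Pipeline orchestration: generate/load -> extract -> classify -> report.

#' Build a validation run configuration
#'
#' @param cohort A [cohort()], or `NULL` to simulate one from
#'   `generator_config`.
#' @param generator_config A [cohort_config()] used when `cohort` is `NULL`
#'   (its seed is overridden by `seed`).
#' @param cancer_types Character vector of cancer types to evaluate
#'   (default: the generator's configured cancers).
#' @param indicators Named list per cancer type of
#'   `list(indicators = ..., composites = ...)` as returned by
#'   [default_indicators()]; default builds the standard battery.
#' @param eval_window `c(start, end)` `"YYYY-MM"` comparison period.
#' @param windows Integer vector of matching half-widths to evaluate
#'   (default `c(3, 12)`).
#' @param primary_window Half-width used for optimal-algorithm selection,
#'   lag profiling and mismatch reporting (default `max(windows)`).
#' @param ppv_floor Minimum PPV an indicator must reach to be eligible as
#'   the optimal algorithm (default 0.8).
#' @param min_age Baseline age floor for eligibility (default 45).
#' @param outdir Output directory for report files, or `NULL` to skip
#'   writing.
#' @param seed Integer seed for simulation.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(cohort = NULL, generator_config = cohort_config(),
                       cancer_types = NULL, indicators = NULL,
                       eval_window = NULL, windows = c(3L, 12L),
                       primary_window = NULL, ppv_floor = 0.8,
                       min_age = 45, outdir = NULL, seed = 1L) {
  if (any(windows <= 0)) stop("windows must be positive", call. = FALSE)
  if (is.null(cancer_types)) {
    cancer_types <- if (!is.null(cohort))
      sort(unique(cohort$registry$cancer_type))
    else names(generator_config$cancers)
  }
  if (!length(cancer_types))
    stop("at least one cancer type required", call. = FALSE)
  if (is.null(eval_window)) {
    eval_window <- if (is.null(cohort)) generator_config$eval_window
    else stop("eval_window required when supplying a cohort",
              call. = FALSE)
  }
  if (is.null(indicators)) {
    indicators <- stats::setNames(
      lapply(cancer_types, default_indicators), cancer_types)
  }
  for (ct in cancer_types) {
    if (is.null(indicators[[ct]]) || !length(indicators[[ct]]$indicators))
      stop("at least one indicator required for ", ct, call. = FALSE)
  }
  structure(list(cohort = cohort, generator_config = generator_config,
                 cancer_types = cancer_types, indicators = indicators,
                 eval_window = eval_window,
                 windows = sort(unique(as.integer(windows))),
                 primary_window = primary_window %||%
                   max(as.integer(windows)),
                 ppv_floor = ppv_floor, min_age = min_age,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

# stable content hash (polynomial rolling hash mod a Mersenne prime) for
# manifests
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full ascertainment-validation pipeline
#'
#' Generates (or takes) a linked cohort, applies eligibility exclusions,
#' extracts every configured indicator and composite for every cancer
#' type, classifies persons against the registry at each matching window,
#' and assembles a report bundle: a metrics table (one row per indicator x
#' cancer type x window), lag profiles and a mismatch report for the
#' optimal algorithm, a death-record discordance triage when a death
#' indicator is configured, and an incremental-case report when the
#' surrogate source extends past the registry.  The optimal algorithm per
#' cancer type maximises sensitivity subject to `PPV >= ppv_floor`
#' (ties broken by higher PPV) at the primary window.
#'
#' Re-running with the same configuration and seed reproduces identical
#' report files; timestamps live only in the manifest.
#'
#' @param rc A [run_config()].
#' @return A `"report_bundle"`: list with `metrics` (data.frame),
#'   `optimal` (named list per cancer type), `lag_profiles`, `mismatch`,
#'   `triage`, `incremental`, `exclusions`, `cohort`, `truth` (when
#'   simulated) and `manifest`.
#' @export
run_validation <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  truth <- NULL
  if (is.null(rc$cohort)) {
    gcfg <- rc$generator_config
    gcfg$seed <- rc$seed
    gen <- generate_cohort(gcfg)
    ch <- gen$cohort
    truth <- gen$truth
  } else {
    ch <- rc$cohort
  }
  excl <- apply_exclusions(ch, min_age = rc$min_age)
  ch <- excl$cohort

  metrics <- list()
  sets_by_ct <- list()
  for (ct in rc$cancer_types) {
    defs <- rc$indicators[[ct]]
    sets <- lapply(defs$indicators, function(ind)
      extract_indicator(ch$events, ind, rc$eval_window, ch$coverage))
    for (nm in names(defs$composites)) {
      sets[[nm]] <- evaluate_composite(ch$events, defs$composites[[nm]],
                                       rc$eval_window, defs$indicators,
                                       ch$coverage)
    }
    sets_by_ct[[ct]] <- sets
    for (nm in names(sets)) {
      for (W in rc$windows) {
        mc <- classify_cases(sets[[nm]], ch$registry, ct, rc$eval_window,
                             W, ch$persons)
        metrics[[length(metrics) + 1L]] <- metrics_row(compute_metrics(mc))
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  ## optimal algorithm per cancer type -------------------------------------
  optimal <- list()
  prim <- metrics[metrics$window_months == rc$primary_window, , drop = FALSE]
  for (ct in rc$cancer_types) {
    rows <- prim[prim$cancer_type == ct, , drop = FALSE]
    elig <- rows[!is.na(rows$ppv) & rows$ppv >= rc$ppv_floor, , drop = FALSE]
    pick <- if (nrow(elig)) {
      elig[order(-elig$sensitivity, -elig$ppv), , drop = FALSE][1L, ]
    } else {
      rows[order(-rows$sensitivity, -rows$ppv), , drop = FALSE][1L, ]
    }
    optimal[[ct]] <- list(indicator = pick$indicator,
                          sensitivity = pick$sensitivity,
                          ppv = pick$ppv,
                          met_floor = nrow(elig) > 0)
  }
  metrics$optimal <- mapply(function(ct, nm, W) {
    W == rc$primary_window && identical(optimal[[ct]]$indicator, nm)
  }, metrics$cancer_type, metrics$indicator, metrics$window_months)

  ## lag profile + mismatch for the optimal algorithm ----------------------
  lag_profiles <- list(); mismatch <- list(); triage <- list()
  incremental <- list()
  for (ct in rc$cancer_types) {
    opt_set <- sets_by_ct[[ct]][[optimal[[ct]]$indicator]]
    mc <- classify_cases(opt_set, ch$registry, ct, rc$eval_window,
                         rc$primary_window, ch$persons)
    lag_profiles[[ct]] <- lag_profile(mc)
    mismatch[[ct]] <- stratify_mismatches(mc, ch$persons, ch$registry)

    death_sets <- Filter(function(ind) {
      inherits(ind, "indicator") && ind$source == "death"
    }, rc$indicators[[ct]]$indicators)
    if (length(death_sets)) {
      dnm <- names(death_sets)[1L]
      dmc <- classify_cases(sets_by_ct[[ct]][[dnm]], ch$registry, ct,
                            rc$eval_window, rc$primary_window, ch$persons)
      triage[[ct]] <- triage_death_fps(dmc, ch$events, ch$registry, ct)
    }

    ## incremental cases beyond registry coverage --------------------------
    reg_cov <- ch$coverage[ch$coverage$source == "registry", , drop = FALSE]
    if (nrow(reg_cov)) {
      reg_end <- reg_cov$end[1L]
      defs_ct <- rc$indicators[[ct]]
      opt_ind <- defs_ct$indicators[[optimal[[ct]]$indicator]]
      if (is.null(opt_ind)) {
        # composite algorithms extend past the registry through their
        # anchor leaf (its single source avoids differing data availability
        # across the composite's sources)
        opt_comp <- defs_ct$composites[[optimal[[ct]]$indicator]]
        if (!is.null(opt_comp))
          opt_ind <- defs_ct$indicators[[opt_comp$anchor]]
      }
      if (inherits(opt_ind, "indicator")) {
        src_cov <- ch$coverage[ch$coverage$source == opt_ind$source, ,
                               drop = FALSE]
        if (nrow(src_cov) &&
            month_index(src_cov$end[1L]) > month_index(reg_end)) {
          ext_set <- extract_indicator(
            ch$events, opt_ind, c(rc$eval_window[1], src_cov$end[1L]),
            ch$coverage)
          incremental[[ct]] <- count_incremental_cases(
            ext_set, ch$registry, ct, reg_end, ch$persons)
        }
      }
    }
  }

  manifest <- list(package = "caseval",
                   version = as.character(utils::packageVersion("caseval")),
                   seed = rc$seed,
                   config_hash = config_hash(
                     rc[setdiff(names(rc), "cohort")]),
                   n_evaluated = nrow(ch$persons),
                   cancer_types = rc$cancer_types,
                   windows = rc$windows,
                   timestamp = format(Sys.time(), tz = "UTC"))

  bundle <- structure(list(metrics = metrics, optimal = optimal,
                           lag_profiles = lag_profiles,
                           mismatch = mismatch, triage = triage,
                           incremental = incremental,
                           exclusions = excl$report, cohort = ch,
                           truth = truth, manifest = manifest),
                      class = "report_bundle")
  if (!is.null(rc$outdir)) write_report_bundle(bundle, rc$outdir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Validation report bundle: %d metric row(s), %d person(s)\n",
              nrow(x$metrics), x$manifest$n_evaluated))
  for (ct in names(x$optimal)) {
    o <- x$optimal[[ct]]
    cat(sprintf("  optimal for %-12s %s (sensitivity %.1f%%, PPV %.1f%%)\n",
                paste0(ct, ":"), o$indicator, 100 * o$sensitivity,
                100 * o$ppv))
  }
  invisible(x)
}

write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$metrics, file.path(outdir, "metrics.csv"),
                   row.names = FALSE, na = "")
  lp <- do.call(rbind, lapply(names(bundle$lag_profiles), function(ct) {
    d <- as.data.frame(bundle$lag_profiles[[ct]])
    d$cancer_type <- ct
    d$negative_lag_fraction <-
      attr(bundle$lag_profiles[[ct]], "negative_lag_fraction")
    d
  }))
  if (!is.null(lp))
    utils::write.csv(lp, file.path(outdir, "lag_profile.csv"),
                     row.names = FALSE, na = "")
  if (nrow(bundle$exclusions))
    utils::write.csv(bundle$exclusions,
                     file.path(outdir, "exclusions.csv"),
                     row.names = FALSE, na = "")
  yaml::write_yaml(bundle$manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' Read a validation run configuration from YAML
#'
#' The file may declare generator overrides (`n_persons`, `seed`,
#' `border_fraction`, `border_penalty`, per-cancer parameter blocks),
#' evaluation settings (`cancer_types`, `windows`, `primary_window`,
#' `ppv_floor`, `outdir`) and indicator definitions
#' (`indicators:` a list of `{name, source, slot_role, code_system, codes,
#' prefix, cause_position}`, `composites:` a list of `{name, expression,
#' anchor}`); omitted sections fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator %||% list()
  if (!is.null(gen_args$cancers)) {
    gen_args$cancers <- lapply(gen_args$cancers, function(a) {
      if (!is.null(a$lag_pmf)) a$lag_pmf <- unlist(a$lag_pmf)
      do.call(cancer_sim_params, a)
    })
  }
  gcfg <- do.call(cohort_config, gen_args)
  cancer_types <- y$cancer_types %||% names(gcfg$cancers)
  indicators <- NULL
  if (!is.null(y$indicators)) {
    ind <- list()
    for (a in y$indicators) {
      ind[[a$name]] <- indicator(a$name, a$source, a$slot_role,
                                 a$code_system, unlist(a$codes),
                                 prefix = a$prefix %||% TRUE,
                                 cause_position = a$cause_position %||%
                                   "underlying_or_contributing")
    }
    cmp <- list()
    for (a in y$composites %||% list()) {
      cmp[[a$name]] <- composite(a$name, a$expression, a$anchor)
    }
    indicators <- stats::setNames(
      rep(list(list(indicators = ind, composites = cmp)),
          length(cancer_types)),
      cancer_types)
  }
  run_config(generator_config = gcfg, cancer_types = cancer_types,
             indicators = indicators,
             eval_window = y$eval_window %||% gcfg$eval_window,
             windows = y$windows %||% c(3L, 12L),
             primary_window = y$primary_window,
             ppv_floor = y$ppv_floor %||% 0.8,
             outdir = y$outdir, seed = y$seed %||% gcfg$seed)
}
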