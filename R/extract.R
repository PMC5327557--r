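# Indicator extraction over event streams and OR/AND combination.
#
# An ascertainment set maps each flagged person to the first date the
# indicator fired for them.  The first occurrence is the earliest event by
# month; within a month, dated events precede undated ones, then earlier
# day, then slot order — a deterministic total order.

new_ascertainment <- function(person_id, first_date, name, eval_window) {
  df <- data.frame(person_id = as.character(person_id),
                   first_date = as.character(first_date),
                   stringsAsFactors = FALSE)
  df <- df[order(df$person_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ascertainment", "data.frame"),
            indicator = name, eval_window = eval_window)
}

#' @export
print.ascertainment <- function(x, ...) {
  cat(sprintf("Ascertainment set '%s': %d person(s), window %s to %s\n",
              attr(x, "indicator"), nrow(x),
              attr(x, "eval_window")[1], attr(x, "eval_window")[2]))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

check_eval_window <- function(eval_window, coverage, source) {
  if (length(eval_window) != 2L)
    stop("eval_window must be c(start, end)", call. = FALSE)
  ws <- month_index(eval_window[1]); we <- month_index(eval_window[2])
  if (ws > we) stop("eval_window start after end", call. = FALSE)
  if (!is.null(coverage) && nrow(coverage)) {
    i <- match(source, coverage$source)
    if (!is.na(i)) {
      if (ws < month_index(coverage$start[i]) ||
          we > month_index(coverage$end[i]))
        stop(sprintf(
          "configuration error: eval_window %s..%s outside %s coverage %s..%s",
          eval_window[1], eval_window[2], source, coverage$start[i],
          coverage$end[i]), call. = FALSE)
    }
  }
  c(ws, we)
}

#' Extract an indicator's ascertainment set from an event table
#'
#' A person is ascertained when at least one event from the indicator's
#' source within the evaluation window carries a slot of the indicator's
#' role whose code matches its code set (same coding system only).  The
#' ascertainment date is the first such event's date: admission date for
#' inpatient records, presentation date for emergency records,
#' service/supply date for claims, date of death for death records.  For a
#' death-source indicator with `cause_position = "underlying_only"` only
#' the underlying-cause slot (slot 1) is searched.
#'
#' @param events Long-layout event table (see [cohort()]).
#' @param ind An [indicator()].
#' @param eval_window Character `c(start, end)` in `"YYYY-MM"`; must lie
#'   within the source's coverage when `coverage` is given.
#' @param coverage Optional coverage table for window checking.
#' @return An `"ascertainment"` data.frame with columns `person_id`,
#'   `first_date`.
#' @export
extract_indicator <- function(events, ind, eval_window, coverage = NULL) {
  stopifnot(inherits(ind, "indicator"))
  check_eval_window(eval_window, coverage, ind$source)
  ws <- month_index(eval_window[1]); we <- month_index(eval_window[2])

  e <- events[events$source == ind$source &
              events$slot_role == ind$slot_role &
              events$code_system == ind$code_system, , drop = FALSE]
  if (ind$source == "death" && ind$cause_position == "underlying_only")
    e <- e[e$slot == 1L, , drop = FALSE]
  if (nrow(e)) {
    em <- month_index(e$event_date)
    e <- e[em >= ws & em <= we, , drop = FALSE]
  }
  if (nrow(e)) {
    e <- e[code_matches(e$code, ind$code_set, ind$prefix), , drop = FALSE]
  }
  if (!nrow(e)) {
    return(new_ascertainment(character(0), character(0), ind$name,
                             eval_window))
  }
  p <- parse_study_date(e$event_date)
  mi <- 12L * p$year + (p$month - 1L)
  has_day <- !is.na(p$day)
  day <- ifelse(has_day, p$day, 99L)
  ord <- order(e$person_id, mi, !has_day, day, e$slot)
  e <- e[ord, , drop = FALSE]
  first <- e[!duplicated(e$person_id), , drop = FALSE]
  new_ascertainment(first$person_id, first$event_date, ind$name, eval_window)
}

#' Combine ascertainment sets by OR (union)
#'
#' The union of flagged persons; each person's date is the earliest first
#' date across the contributing sets, with intra-month ties resolved in
#' favour of the earlier-listed set.
#'
#' @param ... Two or more `"ascertainment"` sets (or a single list of them).
#' @param name Name for the combined set.
#' @return An `"ascertainment"` set.
#' @export
combine_or <- function(..., name = "or_composite") {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "ascertainment"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  rows <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    data.frame(person_id = s$person_id, first_date = s$first_date,
               input = rep(i, nrow(s)), stringsAsFactors = FALSE)
  }))
  ew <- attr(sets[[1]], "eval_window")
  if (is.null(rows) || !nrow(rows))
    return(new_ascertainment(character(0), character(0), name, ew))
  mi <- month_index(rows$first_date)
  ord <- order(rows$person_id, mi, rows$input)
  rows <- rows[ord, , drop = FALSE]
  first <- rows[!duplicated(rows$person_id), , drop = FALSE]
  new_ascertainment(first$person_id, first$first_date, name, ew)
}

#' Combine ascertainment sets by AND (intersection)
#'
#' The intersection of flagged persons, dated by the anchor set's first
#' date (conventionally the cancer-diagnosis component: the composite reads
#' as "diagnosis cases who also had the other component").
#'
#' @param ... Two or more `"ascertainment"` sets (or a single list).
#' @param anchor Name of the set whose dates date the composite (an
#'   `indicator` attribute of one of the inputs).
#' @param name Name for the combined set.
#' @return An `"ascertainment"` set.
#' @export
combine_and <- function(..., anchor, name = "and_composite") {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "ascertainment"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  labels <- vapply(sets, function(s) attr(s, "indicator"), character(1))
  ai <- match(anchor, labels)
  if (is.na(ai))
    stop("configuration error: anchor '", anchor,
         "' is not among the combined sets (", paste(labels, collapse = ", "),
         ")", call. = FALSE)
  ids <- Reduce(intersect, lapply(sets, function(s) s$person_id))
  a <- sets[[ai]]
  keep <- a$person_id %in% ids
  new_ascertainment(a$person_id[keep], a$first_date[keep], name,
                    attr(sets[[1]], "eval_window"))
}

#' Evaluate a composite indicator over an event table
#'
#' Recursively extracts each leaf indicator and folds the expression tree
#' with [combine_or()] / [combine_and()].  AND nodes whose subtree contains
#' the composite's anchor leaf are dated by it; AND nodes that do not
#' contain the anchor are dated by their own first leaf.
#'
#' @param events Long-layout event table.
#' @param comp A [composite()].
#' @param eval_window Character `c(start, end)` in `"YYYY-MM"`.
#' @param indicators Named list of [indicator()] definitions covering every
#'   leaf name in the expression.
#' @param coverage Optional coverage table for window checking.
#' @return An `"ascertainment"` set named after the composite.
#' @export
evaluate_composite <- function(events, comp, eval_window, indicators,
                               coverage = NULL) {
  stopifnot(inherits(comp, "composite_indicator"))
  eval_node <- function(node) {
    if (!is.null(node$leaf)) {
      ind <- indicators[[node$leaf]]
      if (is.null(ind))
        stop("no indicator definition for leaf '", node$leaf, "'",
             call. = FALSE)
      s <- extract_indicator(events, ind, eval_window, coverage)
      attr(s, "indicator") <- node$leaf
      return(s)
    }
    parts <- lapply(node$args, eval_node)
    if (node$op == "OR") {
      out <- combine_or(parts, name = "OR")
    } else {
      leaves <- expression_leaves(node)
      anch <- if (comp$anchor %in% leaves) comp$anchor else leaves[1L]
      part_labels <- vapply(parts, function(s) attr(s, "indicator"),
                            character(1))
      # date each non-leaf part by itself; anchor match is on direct parts,
      # falling back to the part containing the anchor leaf
      target <- which(part_labels == anch)
      if (!length(target)) {
        contains <- vapply(node$args, function(a) {
          anch %in% expression_leaves(a)
        }, logical(1))
        target <- which(contains)[1]
        if (is.na(target)) target <- 1L
      } else target <- target[1L]
      attr(parts[[target]], "indicator") <- "..anchor.."
      out <- combine_and(parts, anchor = "..anchor..", name = "AND")
    }
    attr(out, "indicator") <- paste0("(", node$op, ")")
    out
  }
  res <- eval_node(comp$tree)
  attr(res, "indicator") <- comp$name
  res
}
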