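# Declarative surrogate indicators and their boolean combination algebra.
#
# An indicator is a code-list rule over one event source ("an inpatient
# admission carrying a C18-C20 diagnosis code"); a composite combines
# indicators with OR/AND, mirroring how ascertainment algorithms are built
# ("hospital cancer diagnosis OR death record with the primary cancer as a
# cause").

#' Define a code-list indicator
#'
#' @param name Indicator name (used in composite expressions).
#' @param source Event source: one of `"inpatient"`, `"emergency"`,
#'   `"claims_medical"`, `"claims_pharma"`, `"death"`.
#' @param slot_role Which coded slot to search: `"diagnosis"`,
#'   `"procedure"`, `"item"` or `"cause_of_death"`.
#' @param code_system Coding system of the code set (codes in other systems
#'   never match; cross-system matching needs an explicit recode of the
#'   events upstream).
#' @param code_set Character vector of codes; see [code_matches()].
#' @param prefix Logical (recycled over `code_set`): prefix-pattern entries.
#' @param cause_position For `source = "death"` only:
#'   `"underlying_or_contributing"` (default; any cause slot) or
#'   `"underlying_only"` (slot 1 only).
#' @return An object of class `"indicator"`.
#' @export
indicator <- function(name, source, slot_role, code_system, code_set,
                      prefix = TRUE,
                      cause_position = c("underlying_or_contributing",
                                         "underlying_only")) {
  cause_position <- match.arg(cause_position)
  if (!source %in% EVENT_SOURCES) stop("unknown source: ", source,
                                       call. = FALSE)
  if (!slot_role %in% SLOT_ROLES) stop("unknown slot_role: ", slot_role,
                                       call. = FALSE)
  if (!code_system %in% CODE_SYSTEMS) stop("unknown code_system: ",
                                           code_system, call. = FALSE)
  if (length(code_set) == 0L) stop("code_set must be non-empty",
                                   call. = FALSE)
  bad <- !grepl("^[A-Z0-9.]+$", toupper(code_set))
  if (any(bad)) stop("code pattern(s) not alphanumeric-with-dot: ",
                     paste(code_set[bad], collapse = ", "), call. = FALSE)
  structure(list(name = name, source = source, slot_role = slot_role,
                 code_system = code_system, code_set = code_set,
                 prefix = rep_len(prefix, length(code_set)),
                 cause_position = cause_position),
            class = "indicator")
}

#' @export
print.indicator <- function(x, ...) {
  cat(sprintf("Indicator '%s': %s/%s [%s] codes {%s}%s\n", x$name, x$source,
              x$slot_role, x$code_system,
              paste(x$code_set, collapse = ", "),
              if (x$source == "death" && x$cause_position == "underlying_only")
                " (underlying cause only)" else ""))
  invisible(x)
}

#' Define a composite indicator
#'
#' The expression combines indicator names with `OR` and `AND` (AND binds
#' tighter) and parentheses, e.g. `"hospital_dx OR death_cause"` or
#' `"hospital_dx AND (surgery OR chemo)"`.  An AND-composite is dated by
#' its anchor leaf (by default the first leaf in the expression, which
#' conventionally is the cancer-diagnosis indicator): the composite reads
#' as "diagnosis cases who also had the other component", and the diagnosis
#' admission is the clinically meaningful ascertainment date.
#'
#' @param name Composite name.
#' @param expression Expression string over indicator names.
#' @param anchor Name of the leaf whose date dates the composite; default
#'   the expression's first leaf.
#' @return An object of class `"composite_indicator"`.
#' @export
composite <- function(name, expression, anchor = NULL) {
  tree <- parse_indicator_expression(expression)
  leaves <- expression_leaves(tree)
  if (is.null(anchor)) anchor <- leaves[1L]
  if (!anchor %in% leaves)
    stop("anchor '", anchor, "' is not a leaf of the expression",
         call. = FALSE)
  structure(list(name = name, expression = expression, tree = tree,
                 anchor = anchor),
            class = "composite_indicator")
}

#' @export
print.composite_indicator <- function(x, ...) {
  cat(sprintf("Composite '%s': %s (anchor: %s)\n", x$name, x$expression,
              x$anchor))
  invisible(x)
}

# Recursive-descent parser for the composite grammar:
#   expr := term (OR term)* ; term := factor (AND factor)* ;
#   factor := NAME | "(" expr ")"
# OR/AND are case-insensitive keywords; names are [A-Za-z0-9_.]+.
parse_indicator_expression <- function(text) {
  toks <- regmatches(text,
                     gregexpr("\\(|\\)|[A-Za-z0-9_.]+", text))[[1]]
  if (!length(toks)) stop("empty indicator expression", call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos - 1L] }
  is_kw <- function(t, kw) !is.na(t) && toupper(t) == kw

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), "OR")) {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "OR", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "AND")) {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "AND", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of indicator expression",
                       call. = FALSE)
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")"))
        stop("unbalanced parentheses in indicator expression", call. = FALSE)
      advance()
      return(e)
    }
    if (t == ")" || is_kw(t, "OR") || is_kw(t, "AND"))
      stop("unexpected token '", t, "' in indicator expression",
           call. = FALSE)
    advance()
    list(leaf = t)
  }
  out <- parse_expr()
  if (pos <= length(toks))
    stop("trailing token '", peek(), "' in indicator expression",
         call. = FALSE)
  out
}

expression_leaves <- function(tree) {
  if (!is.null(tree$leaf)) return(tree$leaf)
  unlist(lapply(tree$args, expression_leaves))
}

#' Default indicator and composite definitions
#'
#' The indicator battery evaluated per cancer type: hospital (inpatient)
#' diagnosis of the primary cancer, hospital history-of-cancer code,
#' hospital surgical resection, emergency-department diagnosis, medical
#' claims treatment items, pharmaceutical chemotherapy items, and a death
#' record carrying the primary cancer as any cause; plus the usual OR/AND
#' combinations.  Diagnosis and history code sets are the shipped ICD-10
#' defaults; procedure and claims item code sets here are the synthetic
#' generator's own item vocabularies and should be replaced with
#' jurisdiction-specific lists for real extracts.
#'
#' @param cancer_type `"colorectal"` or `"lung"` (or any key present in
#'   `code_sets$diagnosis`).
#' @param code_sets Code-set dictionary, by default [default_code_sets()].
#' @return List with elements `indicators` (named list of [indicator()])
#'   and `composites` (named list of [composite()]).
#' @export
default_indicators <- function(cancer_type, code_sets = default_code_sets()) {
  dx <- code_sets$diagnosis[[cancer_type]]
  if (is.null(dx)) stop("unknown cancer_type: ", cancer_type, call. = FALSE)
  hist <- code_sets$history[[cancer_type]]
  proc <- synthetic_item_codes(cancer_type)
  ind <- list(
    hospital_dx = indicator("hospital_dx", "inpatient", "diagnosis",
                            "ICD10", dx),
    hospital_history = indicator("hospital_history", "inpatient",
                                 "diagnosis", "ICD10", hist),
    hospital_surgery = indicator("hospital_surgery", "inpatient",
                                 "procedure", "ACHI", proc$surgery_achi),
    ed_dx = indicator("ed_dx", "emergency", "diagnosis", "ICD10", dx),
    mbs_surgery = indicator("mbs_surgery", "claims_medical", "item",
                            "MBS_ITEM", proc$surgery_mbs, prefix = FALSE),
    mbs_chemo = indicator("mbs_chemo", "claims_medical", "item",
                          "MBS_ITEM", proc$chemo_mbs, prefix = FALSE),
    pbs_chemo = indicator("pbs_chemo", "claims_pharma", "item",
                          "PBS_ITEM", proc$chemo_pbs, prefix = FALSE),
    death_cause = indicator("death_cause", "death", "cause_of_death",
                            "ICD10", dx)
  )
  comp <- list(
    dx_or_death = composite("dx_or_death", "hospital_dx OR death_cause"),
    dx_or_history = composite("dx_or_history",
                              "hospital_dx OR hospital_history"),
    dx_and_surgery = composite("dx_and_surgery",
                               "hospital_dx AND hospital_surgery"),
    dx_or_ed = composite("dx_or_ed", "hospital_dx OR ed_dx")
  )
  list(indicators = ind, composites = comp)
}

# Item/procedure vocabularies used by the synthetic generator; stand-ins for
# jurisdiction-specific surgical/chemotherapy code lists, which are always
# user-configurable.
synthetic_item_codes <- function(cancer_type) {
  if (cancer_type == "colorectal") {
    list(surgery_achi = c("32000", "32003", "32006", "32024"),
         surgery_mbs = c("32024", "32025", "32026"),
         chemo_mbs = c("13950", "13915"),
         chemo_pbs = c("FLUOROURACIL", "OXALIPLATIN"))
  } else if (cancer_type == "lung") {
    list(surgery_achi = c("38438", "38441", "38444"),
         surgery_mbs = c("38438", "38440"),
         chemo_mbs = c("13950", "13918"),
         chemo_pbs = c("CARBOPLATIN", "CISPLATIN", "DOCETAXEL"))
  } else {
    list(surgery_achi = "90000", surgery_mbs = "90000",
         chemo_mbs = "13950", chemo_pbs = "GENERIC_CYTOTOXIC")
  }
}
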