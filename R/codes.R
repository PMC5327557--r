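# Code-list matching.
#
# Entries in a code set are either exact codes or prefix patterns.  Matching
# is performed on dot-stripped uppercase codes, the usual normalisation for
# ICD-10 phenotyping code lists, so the three-character category "C18"
# covers C18.0-C18.9 while a secondary-site code such as C78.5 never matches
# a primary-site set.

normalize_code <- function(code) gsub(".", "", toupper(trimws(code)), fixed = TRUE)

#' Match codes against a code set
#'
#' @param codes Character vector of observed codes (e.g. `"C18.2"`).
#' @param code_set Character vector of set entries (e.g. `c("C18", "C19",
#'   "C20")`).  Entries flagged as prefixes match any code beginning with
#'   them; exact entries match after dot-stripping and case-folding only.
#' @param prefix Logical vector (recycled) marking which entries are prefix
#'   patterns.  Default `TRUE`: ICD-10 category-range semantics.
#' @return Logical vector, one element per observed code.
#' @examples
#' code_matches(c("C18.2", "C78.5"), c("C18", "C19", "C20"))
#' @export
code_matches <- function(codes, code_set, prefix = TRUE) {
  if (length(code_set) == 0L) stop("empty code set", call. = FALSE)
  prefix <- rep_len(prefix, length(code_set))
  nc <- normalize_code(codes)
  ns <- normalize_code(code_set)
  hit <- rep(FALSE, length(nc))
  for (i in seq_along(ns)) {
    hit <- hit | (if (prefix[i]) startsWith(nc, ns[i]) else nc == ns[i])
  }
  hit & !is.na(codes)
}

#' Default primary-site diagnosis code sets
#'
#' ICD-10 category sets for the two cancer types the validation study was
#' designed around: colorectal (C18-C20) and lung (C34).  Companion sets give
#' the personal-history ("history of malignant neoplasm") codes and the
#' secondary/metastatic-site categories used when triaging discordant
#' death-record cases.
#'
#' @return Named list with elements `diagnosis` (per cancer type),
#'   `history` (per cancer type) and `secondary` (site-independent C77-C79).
#' @export
default_code_sets <- function() {
  list(
    diagnosis = list(colorectal = c("C18", "C19", "C20"), lung = "C34"),
    history = list(colorectal = "Z85.0", lung = "Z85.1"),
    secondary = c("C77", "C78", "C79")
  )
}
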