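#' Normalize a clinical code
#'
#' Codes are matched on a canonical form: upper case, surrounding whitespace
#' trimmed, and dots removed (`"M01.2"` becomes `"M012"`). ICD-10 and OPCS-4
#' are prefix-structured vocabularies, so hierarchy filters (chapter `"K"`,
#' category `"M01"`) reduce to prefix tests on the normalized form.
#'
#' @param code character vector of raw codes.
#' @return character vector of normalized codes.
#' @examples
#' normalize_code(c("m01.2", " j90 "))
#' @export
normalize_code <- function(code) {
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

#' Prefix match between normalized codes
#'
#' @param code character vector of normalized codes.
#' @param prefix one or more normalized prefixes; a code matches if it starts
#'   with any of them.
#' @return logical vector, one element per `code`.
#' @examples
#' code_matches("K11", "K")
#' code_matches("M012", "M01")
#' code_matches("KM1", "K1")
#' @export
code_matches <- function(code, prefix) {
  if (length(prefix) == 0L) return(rep(FALSE, length(code)))
  out <- rep(FALSE, length(code))
  for (p in prefix) out <- out | startsWith(code, p)
  out
}
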