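#' Normalise a chemical name for matching
#'
#' Registry lookups are insensitive to case, whitespace, hyphenation and
#' typographic dash/apostrophe variants, so that names such as
#' `"Hexachloro-butadiene"`, `"hexachlorobutadiene"` and
#' `"Hexachloro butadiene"` all resolve to the same record. Printed tables of
#' permitted doses are typographically inconsistent; matching on a normalised
#' key avoids silent misses.
#'
#' @param x Character vector of chemical names.
#' @return Character vector of normalised keys.
#' @examples
#' normalize_chemical(c("p,p'-DDE", "P,P'-DDE ", "Hexachloro-butadiene"))
#' @export
normalize_chemical <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[‐‑‒–—―−]", "-", x)
  x <- gsub("[‘’]", "'", x)
  x <- gsub("\\*", "", x)
  x <- gsub("\\s+", "", x)
  gsub("-", "", x)
}

abort_domain <- function(message, ...) {
  abort(message, class = "mcrscreen_domain_error", ...)
}

abort_format <- function(message, ...) {
  abort(message, class = "mcrscreen_format_error", ...)
}

abort_validation <- function(message, ...) {
  abort(message, class = "mcrscreen_validation_error", ...)
}

check_number <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_domain(sprintf("`%s` must be numeric and non-missing.", name))
  }
  bad <- if (allow_zero) x < lower else x <= lower
  if (any(bad)) {
    abort_domain(sprintf(
      "`%s` must be %s %s.", name,
      if (allow_zero) ">=" else ">", format(lower)
    ))
  }
  invisible(x)
}

match_nd_case <- function(nd_case) {
  if (!is.character(nd_case) || !all(nd_case %in% c("case1", "case2"))) {
    abort_domain('`nd_case` must be "case1" (ND = 0) or "case2" (ND = DL/sqrt(2)).')
  }
  nd_case
}
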