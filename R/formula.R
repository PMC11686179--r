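#' Parse an elemental formula in Hill notation
#'
#' Tokenizes a chemical formula into element counts. Pseudo-elements such as
#' `R` (generic acyl rest) or `X` (unspecified biomass matter) are treated like
#' ordinary element symbols, which is the standard convention for generic
#' groups in genome-scale reconstructions.
#'
#' @param formula A single non-empty character string, e.g. `"C6H12O6"`.
#'   Tokens are one capital letter plus optional lowercase letters, followed by
#'   an optional integer count (default 1).
#' @return A named integer vector of element counts. Repeated symbols are
#'   summed.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("C11H19NO9")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  pos <- 1L
  n <- nchar(formula)
  counts <- integer(0)
  while (pos <= n) {
    rest <- substr(formula, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]*)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) {
      stop(sprintf("malformed formula '%s': unexpected token at position %d",
                   formula, pos), call. = FALSE)
    }
    elem <- m[2]
    cnt <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[elem] <- if (elem %in% names(counts)) counts[[elem]] + cnt else cnt
    pos <- pos + nchar(m[1])
  }
  counts
}

# Multiply element counts by a coefficient and accumulate into a running sum.
# Used by check_balance(); kept separate so synthetic chemistry can reuse it.
add_element_counts <- function(acc, counts, coeff) {
  for (el in names(counts)) {
    acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) + coeff * counts[[el]]
  }
  acc
}

#' Compose a formula string from element counts (Hill order: C, H, then
#' alphabetical).
#' @param counts Named numeric vector of element counts.
#' @return A single formula string.
#' @keywords internal
format_formula <- function(counts) {
  counts <- counts[counts != 0]
  els <- names(counts)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(hill, function(e) {
    k <- counts[[e]]
    if (k == 1) e else paste0(e, format(k, scientific = FALSE))
  }, character(1)), collapse = "")
}
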