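## Chemical formula bookkeeping (CHONPS-level; metals such as Mg in
## chlorophyll are deliberately not tracked, see the methods vignette).

#' Parse a chemical formula string
#'
#' Turns `"C6H12O6"` (fractional counts such as `"CH1.59O0.57"` are allowed)
#' into a named numeric vector of element counts. An empty string or `NA`
#' yields an empty vector (used for massless pseudo-species such as photons).
#'
#' @param x formula string.
#' @return named numeric vector element -> count.
#' @export
#' @examples
#' parse_formula("C6H12O6")
parse_formula <- function(x) {
  if (is.na(x) || !nzchar(x)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x)[[1]]
  parts <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x))[[1]]
  if (sum(nchar(parts)) != nchar(x)) {
    stop("cannot parse chemical formula: ", x, call. = FALSE)
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  tapply(ct, factor(el, levels = unique(el)), sum)[unique(el)]
}

#' Format element counts as a formula string
#'
#' @param counts named numeric vector element -> count.
#' @param digits rounding for non-integer counts.
#' @return character scalar, elements in Hill-ish order (C, H, then others
#'   alphabetically).
#' @export
format_formula <- function(counts, digits = 3) {
  counts <- counts[counts != 0]
  if (!length(counts)) return("")
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  counts <- counts[ord]
  fmt1 <- function(el, n) {
    if (isTRUE(all.equal(n, round(n), tolerance = 1e-9))) {
      n <- round(n)
      if (n == 1) el else paste0(el, n)
    } else {
      paste0(el, format(round(n, digits), trim = TRUE, scientific = FALSE))
    }
  }
  paste0(mapply(fmt1, ord, counts), collapse = "")
}

## sum of scaled formulas: Reduce over named vectors
sum_formulas <- function(formula_strings, weights) {
  tot <- c(C = 0)
  for (i in seq_along(formula_strings)) {
    f <- parse_formula(formula_strings[[i]])
    for (el in names(f)) {
      tot[el] <- (if (el %in% names(tot)) tot[[el]] else 0) + weights[[i]] * f[[el]]
    }
  }
  tot[tot != 0 | names(tot) == "C"]
}
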