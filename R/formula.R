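#' @keywords internal
"_PACKAGE"

# Elements tracked for balance checks. Every metabolite formula is reduced to
# counts over this set; elements outside it are rejected at parse time.
RF_ELEMENTS <- c("C", "H", "N", "O", "P", "S")

RF_ATOMIC_MASS <- c(
  C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974, S = 32.06
)

#' Parse a chemical formula string
#'
#' Converts a Hill-style formula such as `"C26H48O9"` into a named numeric
#' vector of element counts over C, H, N, O, P, S. Counts may be fractional
#' (useful for lumped pseudo-species); absent elements are zero.
#'
#' @param x Formula string, or an already-named numeric vector (returned
#'   normalised), or `NULL`/`""` for an empty formula.
#' @return Named numeric vector with one entry per tracked element.
#' @examples
#' parse_formula("C2H6O")        # ethanol
#' parse_formula("C26H48O9")[["C"]]  # mono-rhamnolipid carbon count
#' @export
parse_formula <- function(x) {
  out <- stats::setNames(numeric(length(RF_ELEMENTS)), RF_ELEMENTS)
  if (is.null(x) || (is.character(x) && !nzchar(x))) return(out)
  if (is.numeric(x)) {
    bad <- setdiff(names(x), RF_ELEMENTS)
    if (length(bad) > 0) {
      stop("unsupported element(s) in formula: ", paste(bad, collapse = ", "))
    }
    if (any(x < 0)) stop("element counts must be >= 0")
    out[names(x)] <- as.numeric(x)
    return(out)
  }
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x)[[1]]
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x))[[1]]
  if (sum(nchar(toks)) != nchar(x)) {
    stop("cannot parse formula: '", x, "'")
  }
  for (tok in toks) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    n <- sub("^[A-Z][a-z]?", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    if (!el %in% RF_ELEMENTS) {
      stop("unsupported element '", el, "' in formula '", x, "'")
    }
    out[el] <- out[el] + n
  }
  out
}

#' Render element counts back to a formula string
#' @param counts Named numeric vector as returned by [parse_formula()].
#' @return A formula string in C, H, N, O, P, S order (empty if all zero).
#' @export
formula_string <- function(counts) {
  counts <- parse_formula(counts)
  nz <- counts[counts != 0]
  if (length(nz) == 0) return("")
  paste0(
    vapply(names(nz), function(el) {
      n <- nz[[el]]
      num <- if (isTRUE(all.equal(n, 1))) "" else
        sub("0+$", "", sub("\\.$", "", format(n, scientific = FALSE)))
      # keep integers clean
      if (isTRUE(all.equal(n, round(n)))) num <- if (round(n) == 1) "" else
        as.character(round(n))
      paste0(el, num)
    }, character(1)),
    collapse = ""
  )
}

#' Molecular weight from a formula
#' @param x Formula string or element-count vector.
#' @return Molecular mass in g/mol.
#' @examples
#' molecular_weight("C2H6O")  # ethanol, 46.07
#' @export
molecular_weight <- function(x) {
  counts <- parse_formula(x)
  sum(counts * RF_ATOMIC_MASS[names(counts)])
}
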