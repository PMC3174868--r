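#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Standard valences for neutral atoms. CASE generation only ever places the
# elements NMR natural-product work encounters; anything else is rejected at
# parse time.
.VALENCE <- c(
  C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
  F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L
)

# Periodic-table symbols (through element 103) used only to validate tokens so
# that a typo like "Cx" is reported as an unknown element, not silently kept.
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr"
)

valence_of <- function(element) {
  v <- .VALENCE[element]
  if (anyNA(v)) {
    abort(paste0(
      "no valence configured for element(s): ",
      paste(unique(element[is.na(v)]), collapse = ", ")
    ), class = "nmrcase_valence_error")
  }
  unname(v)
}

#' Parse a molecular formula in Hill notation
#'
#' Turns a formula string such as `"C17H12O6"` into a named integer vector of
#' element counts. Bare element symbols count as 1. Isotopes, charges and
#' parentheses are not supported.
#'
#' @param text A single formula string (Hill notation).
#' @return A named integer vector of class `mol_formula`; names are element
#'   symbols, values are counts.
#' @examples
#' parse_formula("C2H6O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text)) {
    abort(paste0("cannot parse formula: '", text, "'"),
          class = "nmrcase_parse_error")
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  elems <- sub("[0-9]+$", "", tokens)
  counts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  counts[is.na(counts)] <- 1L
  bad <- setdiff(elems, .ELEMENTS)
  if (length(bad) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")),
          class = "nmrcase_parse_error")
  }
  out <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  out <- stats::setNames(as.integer(out), names(out))
  if (sum(out[setdiff(names(out), "H")]) < 1L) {
    abort("formula must contain at least one heavy atom",
          class = "nmrcase_parse_error")
  }
  structure(out, class = "mol_formula")
}

#' Format element counts as a Hill-notation formula string
#'
#' @param counts Named integer vector of element counts (or a `mol_formula`).
#' @return A single string: carbon first, then hydrogen, then the remaining
#'   elements alphabetically.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  el <- names(counts)
  ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}

#' Degree of unsaturation (double-bond equivalents)
#'
#' Computes `DBE = 1 + sum_i n_i (v_i - 2) / 2` over all atoms with configured
#' valence `v_i`, the standard ring-plus-multiple-bond count implied by a
#' molecular formula. For CHNO formulas this reduces to
#' `C + 1 - H/2 - X/2 + N/2`.
#'
#' @param formula A `mol_formula` or named count vector.
#' @return A non-negative integer.
#' @examples
#' dbe(parse_formula("C6H6")) # 4
#' @export
dbe <- function(formula) {
  counts <- as.integer(formula)
  names(counts) <- names(formula)
  v <- valence_of(names(counts))
  val <- 1 + sum(counts * (v - 2)) / 2
  if (val < 0 || val != round(val)) {
    abort(paste0(
      "formula inconsistent: degree of unsaturation is ", val,
      " for ", format_formula(counts)
    ), class = "nmrcase_formula_error")
  }
  as.integer(round(val))
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}
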