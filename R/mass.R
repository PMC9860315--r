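# Monoisotopic masses of the most abundant isotope (Da), CODATA/IUPAC 2021.
MONOISOTOPIC_MASS <- c(
  H = 1.00782503223, C = 12.0, N = 14.0030740044, O = 15.9949146196,
  S = 31.9720711744, P = 30.97376199842, Na = 22.9897692820,
  K = 38.9637064864, Cl = 34.968852682, F = 18.99840316273,
  Br = 78.9183376, I = 126.9044719, Si = 27.97692653465,
  Se = 79.9165218, Ca = 39.962590863, Mg = 23.985041697,
  Fe = 55.9349375, Zn = 63.9291420, Cu = 62.9295977,
  B = 11.00930536, Li = 7.0160034366
)

ELECTRON_MASS_DA <- 0.000548579909

#' Parse an elemental formula string
#'
#' Accepts Hill-style formulas such as `"C5H12NO2"`; element symbols must
#' come from the built-in monoisotopic mass table.
#'
#' @param formula Formula string, or an already-parsed named count vector.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    if (!is.character(formula) || length(formula) != 1L || !nzchar(formula)) {
      stop_input("`formula` must be a non-empty string")
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
    toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1L]]
    if (sum(attr(m, "match.length")) != nchar(formula)) {
      stop_input("cannot parse formula: ", formula)
    }
    sym <- sub("[0-9]*$", "", toks)
    num <- sub("^[A-Za-z]+", "", toks)
    counts <- setNames(ifelse(num == "", 1L, as.integer(num)), sym)
    counts <- tapply(counts, names(counts), sum)
  }
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop_input("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 1)) stop_input("element counts must be >= 1")
  counts
}

#' Monoisotopic m/z of an ion
#'
#' Sums the monoisotopic atomic masses of the formula, subtracts
#' `charge` electron masses, and divides by `|charge|` (for neutral species
#' the plain monoisotopic mass is returned). Rounded to 4 decimals, the
#' convention of high-resolution MS reporting. For a protonated molecule pass
#' the `[M + H]+` formula with `charge = 1`.
#'
#' @param formula Formula string or named count vector (see
#'   [parse_formula()]).
#' @param charge Integer charge of the ion (default +1).
#' @return m/z in Da, rounded to 4 decimal places.
#' @examples
#' monoisotopic_mz("C5H12NO2", charge = 1)  # protonated betaine, 118.0863
#' @export
monoisotopic_mz <- function(formula, charge = 1L) {
  counts <- parse_formula(formula)
  if (charge != round(charge)) stop_input("`charge` must be an integer")
  m <- sum(MONOISOTOPIC_MASS[names(counts)] * counts) -
    charge * ELECTRON_MASS_DA
  mz <- if (charge == 0) m else m / abs(charge)
  round(mz, 4L)
}
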