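# Elemental-formula arithmetic over CHNOPS.
#
# A formula is an integer count vector over the fixed element order
# C, H, N, O, P, S. All tree-building arithmetic (sub-formula tests,
# neutral losses, monoisotopic masses) happens on these vectors.

#' Elements supported by the package, in canonical (Hill-like) order
#' @keywords internal
.ELEMENTS <- c("C", "H", "N", "O", "P", "S")

# Monoisotopic atomic masses (Da), CODATA/IUPAC values.
.ATOMIC_MASS <- c(
  C = 12,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

# Electron rest mass (Da); subtracted per positive charge in ion m/z.
.ELECTRON_MASS <- 0.00054857990946

#' Construct an elemental formula
#'
#' An `elemental_formula` is a named integer vector of atom counts over the
#' CHNOPS elements. Counts default to zero; elements outside CHNOPS are
#' rejected. The empty formula (all counts zero) is valid and represents,
#' e.g., the neutral loss of a compound from itself.
#'
#' @param ... named integer counts, e.g. `elemental_formula(C = 10, H = 18,
#'   N = 3, O = 6, S = 1)`. Alternatively a single named vector.
#' @return an object of class `elemental_formula`.
#' @examples
#' gsh <- elemental_formula(C = 10, H = 18, N = 3, O = 6, S = 1)
#' monoisotopic_mass(gsh)
#' @export
elemental_formula <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    args <- as.list(args[[1]])
  }
  counts <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  if (length(args)) {
    nm <- names(args)
    if (is.null(nm) || any(nm == "")) {
      stop("elemental_formula() requires named element counts", call. = FALSE)
    }
    bad <- setdiff(nm, .ELEMENTS)
    if (length(bad)) {
      stop("unsupported element(s): ", paste(bad, collapse = ", "),
           " (only CHNOPS allowed)", call. = FALSE)
    }
    v <- unlist(args, use.names = TRUE)
    if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      stop("element counts must be non-negative integers", call. = FALSE)
    }
    counts[nm] <- as.integer(v)
  }
  structure(counts, class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  s <- serialize_formula(x, "display")
  cat("<elemental_formula> ", if (nzchar(s)) s else "(empty)", "\n", sep = "")
  invisible(x)
}

#' @export
`==.elemental_formula` <- function(e1, e2) {
  all(unclass(e1) == unclass(e2))
}

is_ef <- function(x) inherits(x, "elemental_formula")

as_ef <- function(x) {
  if (is_ef(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) return(elemental_formula(x))
  stop("cannot interpret object as an elemental formula", call. = FALSE)
}

#' Monoisotopic mass of a formula
#'
#' Sum of per-element monoisotopic atomic masses times counts.
#'
#' @param formula an [elemental_formula] (or formula string).
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_ef(formula)
  sum(unclass(f) * .ATOMIC_MASS)
}

#' Theoretical m/z of an ion
#'
#' The formula is the composition of the ion itself (protonation included,
#' e.g. `C10H18N3O6S` for protonated glutathione). The electron deficit is
#' subtracted for cations and added for anions:
#' `(M - polarity * charge * m_e) / charge`.
#'
#' @param formula ion composition, an [elemental_formula] or string.
#' @param polarity `+1` (cation) or `-1` (anion).
#' @param charge positive integer, default 1 (singly charged ions are the
#'   only charge state used in the MSn workflows here).
#' @return theoretical m/z.
#' @export
ion_mz <- function(formula, polarity = 1L, charge = 1L) {
  if (!charge || charge < 1) stop("charge must be a positive integer", call. = FALSE)
  if (!polarity %in% c(-1L, 1L)) stop("polarity must be +1 or -1", call. = FALSE)
  (monoisotopic_mass(formula) - polarity * charge * .ELECTRON_MASS) / charge
}

#' Ring and double bond equivalents (RDBE)
#'
#' `RDBE = C + 1 - H/2 + (N + P)/2` with O and S contributing zero and P
#' treated trivalent. Even-electron CHNOPS ions give half-integer values,
#' which is what the non-integer RDBE plausibility filter keys on.
#'
#' @inheritParams monoisotopic_mass
#' @return a value on the 0.5 grid.
#' @export
rdbe <- function(formula) {
  f <- unclass(as_ef(formula))
  f[["C"]] + 1 - f[["H"]] / 2 + (f[["N"]] + f[["P"]]) / 2
}

#' Signed relative mass error in ppm
#'
#' `(observed - theoretical) / theoretical * 1e6`; negative when the observed
#' mass is below the theoretical one.
#'
#' @param observed_mz,theoretical_mz m/z values; `theoretical_mz` must be > 0.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical m/z must be positive", call. = FALSE)
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Sub-formula test
#'
#' `TRUE` iff `a` contains no more atoms of any element than `b` — the
#' precursor-product constraint: a fragment ion cannot contain more atoms of
#' an element than its precursor.
#'
#' @param a,b elemental formulas (or strings).
#' @export
is_subformula <- function(a, b) {
  all(unclass(as_ef(a)) <= unclass(as_ef(b)))
}

#' Neutral-loss formula
#'
#' Element-wise difference `precursor - fragment`; errors if any count would
#' go negative (hierarchy violation). Fragment plus neutral loss add up to
#' the precursor exactly.
#'
#' @param precursor,fragment elemental formulas (or strings).
#' @return the neutral loss as an [elemental_formula].
#' @export
subtract_formula <- function(precursor, fragment) {
  p <- unclass(as_ef(precursor))
  f <- unclass(as_ef(fragment))
  d <- p - f
  if (any(d < 0)) {
    stop("fragment exceeds precursor for element(s): ",
         paste(.ELEMENTS[d < 0], collapse = ", "), call. = FALSE)
  }
  elemental_formula(d)
}

#' Serialize a formula
#'
#' Two dialects are used throughout:
#' * `display` — element order C, H, N, O, P, S with count 1 omitted
#'   (`"C5H8NO3S"`), as in human-readable output;
#' * `efp_token` — same order with every nonzero count explicit
#'   (`"C5H8N1O3S1"`), the token dialect used inside EFP strings.
#'
#' The empty formula serializes to `""` in both dialects.
#'
#' @inheritParams monoisotopic_mass
#' @param dialect `"display"` or `"efp_token"`.
#' @export
serialize_formula <- function(formula, dialect = c("display", "efp_token")) {
  dialect <- match.arg(dialect)
  f <- unclass(as_ef(formula))
  keep <- f > 0
  if (!any(keep)) return("")
  n <- f[keep]
  cnt <- if (dialect == "display") ifelse(n == 1L, "", as.character(n)) else as.character(n)
  paste0(.ELEMENTS[keep], cnt, collapse = "")
}

#' Parse a formula string
#'
#' Left inverse of [serialize_formula()] for both dialects: accepts
#' `"C5H8NO3S"` as well as `"C5H8N1O3S1"`. Repeated element symbols are
#' summed. Unknown symbols or malformed text raise an error.
#'
#' @param text a formula string; `""` parses to the empty formula.
#' @return an [elemental_formula].
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) return(elemental_formula())
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  pieces <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula string: ", text, call. = FALSE)
  }
  counts <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  for (p in pieces) {
    el <- gsub("[0-9]", "", p)
    if (!el %in% .ELEMENTS) stop("unknown element symbol '", el, "' in: ", text, call. = FALSE)
    num <- gsub("[^0-9]", "", p)
    counts[el] <- counts[el] + if (nzchar(num)) as.integer(num) else 1L
  }
  elemental_formula(counts)
}
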