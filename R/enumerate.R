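# Candidate-formula enumeration under mass tolerance, element-ratio
# plausibility rules (Kind-Fiehn style), RDBE filtering and an optional
# precursor cap. This is the engine behind both precursor assignment and
# the hierarchy-constrained assignment of fragment peaks.

#' Constraint set for formula assignment
#'
#' Bundles every tunable of the formula generator. Defaults follow the
#' MSn workflow conventions: 6 ppm mass tolerance, CHNOPS elements with
#' per-element maxima for the < 500 Da window (C 39, H 72, N 20, O 20,
#' P 9, S 10), extended-range element-ratio rules (0.1 <= H/C <= 6,
#' N/C <= 4, O/C <= 3, P/C <= 2, S/C <= 3), and the requirement that the
#' ion RDBE be non-integer (fractional part 0.5, >= -0.5), which holds for
#' even-electron CHNOPS cations and anions.
#'
#' @param tol_ppm mass tolerance in ppm (> 0), default 6.
#' @param element_max named integer vector of per-element maximum counts.
#' @param ratio_rules_enabled logical; apply the element-ratio checks.
#' @param rdbe_rule `"non_integer_required"` or `"none"`.
#' @param precursor_cap optional [elemental_formula] acting as an
#'   element-wise upper bound (the precursor ion's composition).
#' @return a list of class `formula_constraints`.
#' @export
formula_constraints <- function(tol_ppm = 6,
                                element_max = c(C = 39L, H = 72L, N = 20L,
                                                O = 20L, P = 9L, S = 10L),
                                ratio_rules_enabled = TRUE,
                                rdbe_rule = c("non_integer_required", "none"),
                                precursor_cap = NULL) {
  stopifnot(tol_ppm > 0)
  rdbe_rule <- match.arg(rdbe_rule)
  em <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  bad <- setdiff(names(element_max), .ELEMENTS)
  if (length(bad)) stop("element_max has non-CHNOPS element(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  em[names(element_max)] <- as.integer(element_max)
  if (any(em < 0)) stop("element_max must be non-negative", call. = FALSE)
  if (!is.null(precursor_cap)) precursor_cap <- as_ef(precursor_cap)
  structure(
    list(tol_ppm = tol_ppm, element_max = em,
         ratio_rules_enabled = isTRUE(ratio_rules_enabled),
         rdbe_rule = rdbe_rule, precursor_cap = precursor_cap),
    class = "formula_constraints"
  )
}

# Vectorised ratio-rule predicate on a count matrix (columns C,H,N,O,P,S).
.ratio_ok <- function(m) {
  C <- m[, "C"]
  ok <- rep(TRUE, nrow(m))
  hasC <- C > 0
  # carbon-free formulas: ratio checks vacuous, maxima are checked elsewhere
  ok[hasC] <-
    m[hasC, "H"] / C[hasC] >= 0.1 & m[hasC, "H"] / C[hasC] <= 6 &
    m[hasC, "N"] / C[hasC] <= 4 &
    m[hasC, "O"] / C[hasC] <= 3 &
    m[hasC, "P"] / C[hasC] <= 2 &
    m[hasC, "S"] / C[hasC] <= 3
  ok
}

#' Element-ratio plausibility check
#'
#' Heuristic filter restricting the hydrogen/heteroatom content relative to
#' carbon (extended ranges: 0.1 <= H/C <= 6, N/C <= 4, O/C <= 3, P/C <= 2,
#' S/C <= 3) together with the per-element maxima of `constraints`. For a
#' carbon-free formula only the maxima are evaluated (documented behaviour,
#' not an error).
#'
#' @inheritParams monoisotopic_mass
#' @param constraints a [formula_constraints] object.
#' @return logical.
#' @export
passes_ratio_rules <- function(formula, constraints = formula_constraints()) {
  f <- unclass(as_ef(formula))
  if (any(f > constraints$element_max)) return(FALSE)
  m <- matrix(f, nrow = 1, dimnames = list(NULL, .ELEMENTS))
  .ratio_ok(m)
}

# Count matrix of all candidate compositions, before predicate filtering.
# Capped: full grid bounded element-wise by the cap (and element_max).
# Uncapped: grid over C,N,O,P,S bounded by the mass window, with the H count
# solved per row from the window (at ppm-scale tolerances at most one value).
.candidate_grid <- function(target_mz, polarity, constraints) {
  tol <- constraints$tol_ppm * 1e-6 * target_mz
  # mass window for the ion *composition* (ion m/z plus polarity electrons)
  lo <- target_mz - tol + polarity * .ELECTRON_MASS
  hi <- target_mz + tol + polarity * .ELECTRON_MASS
  cap <- constraints$precursor_cap
  if (!is.null(cap)) {
    lim <- pmin(unclass(cap), constraints$element_max)
    g <- as.matrix(expand.grid(lapply(lim, function(n) 0:n),
                               KEEP.OUT.ATTRS = FALSE))
    colnames(g) <- .ELEMENTS
    mass <- g %*% .ATOMIC_MASS
    g <- g[mass >= lo & mass <= hi, , drop = FALSE]
    return(g)
  }
  heavy <- setdiff(.ELEMENTS, "H")
  lim <- pmin(constraints$element_max[heavy], floor(hi / .ATOMIC_MASS[heavy]))
  g <- as.matrix(expand.grid(lapply(lim, function(n) 0:n),
                             KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- heavy
  rest <- g %*% .ATOMIC_MASS[heavy]
  keep <- rest <= hi
  g <- g[keep, , drop = FALSE]
  rest <- rest[keep]
  h_lo <- pmax(0, ceiling((lo - rest) / .ATOMIC_MASS[["H"]]))
  h_hi <- pmin(constraints$element_max[["H"]], floor((hi - rest) / .ATOMIC_MASS[["H"]]))
  # expand rows that admit several H counts (only at very wide tolerances)
  reps <- pmax(0L, as.integer(h_hi - h_lo + 1L))
  idx <- rep.int(seq_len(nrow(g)), reps)
  H <- unlist(lapply(seq_len(nrow(g)), function(i)
    if (reps[i] > 0L) seq.int(h_lo[i], h_hi[i]) else integer(0)), use.names = FALSE)
  out <- cbind(C = g[idx, "C"], H = H, g[idx, c("N", "O", "P", "S"), drop = FALSE])
  out
}

#' Enumerate candidate elemental formulas for an observed m/z
#'
#' Returns every CHNOPS ion composition whose theoretical m/z lies within
#' `tol_ppm` of `target_mz` and that survives the enabled plausibility
#' filters: the element-wise precursor cap (if set), the per-element maxima,
#' the element-ratio rules and the non-integer RDBE rule. The list is sorted
#' by absolute ppm error, ties broken by the lexicographic `efp_token`
#' serialization. An empty result is valid and marks the peak as a candidate
#' artifact.
#'
#' @param target_mz observed m/z (> 0).
#' @param polarity `+1` or `-1`.
#' @param constraints a [formula_constraints] object.
#' @return a data.frame with columns `token`, `display`, `theoretical_mz`,
#'   `ppm_error`, ordered best-first.
#' @examples
#' cons <- formula_constraints(precursor_cap = parse_formula("C10H18N3O6S"))
#' enumerate_candidates(179.0485, 1L, cons)
#' @export
enumerate_candidates <- function(target_mz, polarity = 1L,
                                 constraints = formula_constraints()) {
  stopifnot(target_mz > 0, polarity %in% c(-1L, 1L))
  g <- .candidate_grid(target_mz, polarity, constraints)
  empty <- data.frame(token = character(), display = character(),
                      theoretical_mz = numeric(), ppm_error = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(g)) return(empty)
  keep <- !colSums(t(g) > constraints$element_max)
  if (constraints$rdbe_rule == "non_integer_required") {
    r <- g[, "C"] + 1 - g[, "H"] / 2 + (g[, "N"] + g[, "P"]) / 2
    keep <- keep & (r %% 1 == 0.5) & (r >= -0.5)
  }
  if (constraints$ratio_rules_enabled) keep <- keep & .ratio_ok(g)
  g <- g[keep, , drop = FALSE]
  if (!nrow(g)) return(empty)
  theo <- as.numeric(g %*% .ATOMIC_MASS - polarity * .ELECTRON_MASS)
  ppm <- ppm_error(target_mz, theo)
  keep <- abs(ppm) <= constraints$tol_ppm
  g <- g[keep, , drop = FALSE]
  theo <- theo[keep]
  ppm <- ppm[keep]
  if (!nrow(g)) return(empty)
  token <- vapply(seq_len(nrow(g)), function(i)
    serialize_formula(elemental_formula(g[i, ]), "efp_token"), character(1))
  display <- vapply(seq_len(nrow(g)), function(i)
    serialize_formula(elemental_formula(g[i, ]), "display"), character(1))
  ord <- order(abs(ppm), token, method = "radix")
  data.frame(token = token[ord], display = display[ord],
             theoretical_mz = theo[ord], ppm_error = ppm[ord],
             stringsAsFactors = FALSE)
}
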