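# Hierarchy-constrained elemental formula assignment: every peak receives
# candidate formulas capped element-wise by its precursor ion's formula;
# peaks with no surviving candidate are artifacts and are dropped. The
# output is a fragmentation tree represented as elemental formula paths
# (EFPs), root-to-ion lists of ion compositions joined by "||".

#' Assign a formula to the precursor (root) ion
#'
#' If `known_formula` is given it is validated against the observed root m/z
#' at the configured tolerance; otherwise the best-ranked candidate from
#' [enumerate_candidates()] (no cap) is taken. MS1 isotope-pattern
#' information is not used.
#'
#' @param tree a `spectrum_tree` with `root_mz` set.
#' @param known_formula optional ion composition ([elemental_formula] or
#'   string).
#' @param constraints a [formula_constraints] object.
#' @return a list with `formula` ([elemental_formula]), `token`, `ppm_error`,
#'   `theoretical_mz`.
#' @export
assign_root <- function(tree, known_formula = NULL,
                        constraints = formula_constraints()) {
  if (is.null(tree$root_mz) || is.na(tree$root_mz)) {
    stop("spectrum tree has no root m/z", call. = FALSE)
  }
  polarity <- tree$scans[[tree$root_id]]$polarity
  if (!is.null(known_formula)) {
    f <- as_ef(known_formula)
    theo <- ion_mz(f, polarity)
    ppm <- ppm_error(tree$root_mz, theo)
    if (abs(ppm) > constraints$tol_ppm) {
      stop(sprintf("unassignable precursor: %s is %.1f ppm from observed %.4f",
                   serialize_formula(f), ppm, tree$root_mz), call. = FALSE)
    }
    return(list(formula = f, token = serialize_formula(f, "efp_token"),
                ppm_error = ppm, theoretical_mz = theo))
  }
  cons <- constraints
  cons$precursor_cap <- NULL
  cand <- enumerate_candidates(tree$root_mz, polarity, cons)
  if (!nrow(cand)) {
    stop(sprintf("unassignable precursor: no candidate within %.1f ppm of %.4f",
                 constraints$tol_ppm, tree$root_mz), call. = FALSE)
  }
  list(formula = parse_formula(cand$token[1]), token = cand$token[1],
       ppm_error = cand$ppm_error[1], theoretical_mz = cand$theoretical_mz[1])
}

#' Build a fragmentation tree from a linked spectrum tree
#'
#' Walks the scan hierarchy top-down. Every peak of an MSn scan receives
#' candidate formulas from [enumerate_candidates()] with the parent ion's
#' formula as element-wise cap, which simultaneously enforces the
#' sub-formula constraint and a non-negative neutral loss. Peaks with no
#' surviving candidate are dropped as artifacts; peaks with several
#' candidates keep the best (minimum absolute ppm error, ties by
#' lexicographic token) and are flagged ambiguous. A fragmented peak whose
#' formula was dropped takes its whole subtree with it.
#'
#' @param tree a linked `spectrum_tree` (see [link_precursors()]).
#' @param root_formula optional known ion composition of the precursor;
#'   when `NULL` the root is assigned by enumeration.
#' @param constraints a [formula_constraints] object.
#' @param compound_id free-text identifier stored on the tree.
#' @return an object of class `fragmentation_tree`: list with `nodes` (a
#'   data.frame with one row per retained ion: `efp`, `parent_efp`, `token`,
#'   `display`, `ms_level`, `observed_mz`, `theoretical_mz`, `rel_intensity`,
#'   `ppm_error`, `ambiguous`), `root_token`, `polarity`, `compound_id`,
#'   `constraints` and a character `log` of per-peak drop reasons.
#' @export
assign_tree <- function(tree, root_formula = NULL,
                        constraints = formula_constraints(),
                        compound_id = "") {
  root <- assign_root(tree, root_formula, constraints)
  polarity <- tree$scans[[tree$root_id]]$polarity
  log <- character()

  # per-scan table of assigned nodes, keyed "<scan_id>#<peak_row>"
  node_key <- function(scan_id, peak_idx) paste0(scan_id, "#", peak_idx)
  assigned <- new.env(parent = emptyenv())

  root_scan <- tree$scans[[tree$root_id]]
  root_peak_idx <- if (nrow(root_scan$peaks)) {
    which.min(abs(root_scan$peaks$mz - tree$root_mz))
  } else NA_integer_
  nodes <- data.frame(
    efp = root$token, parent_efp = NA_character_, token = root$token,
    display = serialize_formula(root$formula), ms_level = 1L,
    observed_mz = tree$root_mz, theoretical_mz = root$theoretical_mz,
    rel_intensity = 100, ppm_error = root$ppm_error, ambiguous = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.na(root_peak_idx)) {
    assign(node_key(tree$root_id, root_peak_idx),
           list(efp = root$token, formula = root$formula), envir = assigned)
  }

  # scans in level order so parents are processed before children
  ids <- names(tree$scans)
  ids <- ids[order(vapply(tree$scans, function(s) s$ms_level, integer(1)))]
  for (id in ids) {
    s <- tree$scans[[id]]
    if (s$ms_level == 1L) next
    pid <- tree$parent[[id]]
    pidx <- tree$parent_peak[[id]]
    pnode <- if (!is.null(pid)) mget(node_key(pid, pidx), envir = assigned,
                                     ifnotfound = list(NULL))[[1]] else NULL
    if (is.null(pnode)) {
      log <- c(log, sprintf("scan %s dropped: precursor peak carries no formula", id))
      next
    }
    if (all(s$peaks$intensity == 0) || !nrow(s$peaks)) next
    s <- normalize_intensities(s)
    cons <- constraints
    cons$precursor_cap <- pnode$formula
    scan_rows <- list()
    for (i in seq_len(nrow(s$peaks))) {
      cand <- enumerate_candidates(s$peaks$mz[i], polarity, cons)
      if (!nrow(cand)) {
        log <- c(log, sprintf("scan %s peak %.4f dropped: no formula under cap %s",
                              id, s$peaks$mz[i], serialize_formula(pnode$formula)))
        next
      }
      scan_rows[[length(scan_rows) + 1L]] <- data.frame(
        efp = paste(pnode$efp, cand$token[1], sep = "||"),
        parent_efp = pnode$efp, token = cand$token[1], display = cand$display[1],
        ms_level = s$ms_level, observed_mz = s$peaks$mz[i],
        theoretical_mz = cand$theoretical_mz[1],
        rel_intensity = s$peaks$rel_intensity[i],
        ppm_error = cand$ppm_error[1], ambiguous = nrow(cand) > 1L,
        peak_idx = i, stringsAsFactors = FALSE
      )
    }
    if (!length(scan_rows)) next
    new <- do.call(rbind, scan_rows)
    # EFP strings must be unique: on a within-scan collision keep min |ppm|
    if (anyDuplicated(new$efp)) {
      new <- new[order(new$efp, abs(new$ppm_error)), , drop = FALSE]
      dup <- duplicated(new$efp)
      log <- c(log, sprintf("scan %s: %d duplicate EFP peak(s) merged", id, sum(dup)))
      new <- new[!dup, , drop = FALSE]
    }
    for (j in seq_len(nrow(new))) {
      assign(node_key(id, new$peak_idx[j]),
             list(efp = new$efp[j], formula = parse_formula(new$token[j])),
             envir = assigned)
    }
    nodes <- rbind(nodes, new[setdiff(names(new), "peak_idx")])
  }
  rownames(nodes) <- NULL
  out <- structure(
    list(nodes = nodes, root_token = root$token, polarity = polarity,
         compound_id = compound_id, constraints = constraints, log = log),
    class = "fragmentation_tree"
  )
  validate_fragmentation_tree(out)
  out
}

#' Validate a fragmentation tree
#'
#' Asserts hierarchy soundness on every node: the formula is a sub-formula
#' of its parent's (equivalently the neutral loss is non-negative), the EFP
#' length equals the MS level, and EFP strings are unique.
#'
#' @param ft a `fragmentation_tree`.
#' @return the tree, invisibly; errors on violation.
#' @export
validate_fragmentation_tree <- function(ft) {
  n <- ft$nodes
  if (anyDuplicated(n$efp)) stop("duplicate EFP strings in tree", call. = FALSE)
  for (i in seq_len(nrow(n))) {
    parts <- strsplit(n$efp[i], "||", fixed = TRUE)[[1]]
    if (length(parts) != n$ms_level[i]) {
      stop("EFP length does not match MS level at ", n$efp[i], call. = FALSE)
    }
    if (length(parts) > 1L) {
      child <- parse_formula(parts[length(parts)])
      parent <- parse_formula(parts[length(parts) - 1L])
      if (!is_subformula(child, parent)) {
        stop("hierarchy violation at ", n$efp[i], call. = FALSE)
      }
    }
  }
  invisible(ft)
}

#' @export
print.fragmentation_tree <- function(x, ...) {
  cat(sprintf("<fragmentation_tree> root %s, %d EFP(s), %d message(s) logged\n",
              x$root_token, nrow(x$nodes), length(x$log)))
  invisible(x)
}

#' EFP strings of a fragmentation tree
#'
#' One string per node: the `efp_token` serializations of the ion
#' compositions from the precursor down to the node, joined by `"||"`.
#' The root's single-element path is included.
#'
#' @param tree a `fragmentation_tree`.
#' @return character vector of distinct EFP strings.
#' @export
efp_strings <- function(tree) {
  tree$nodes$efp
}

#' Consensus tree over repeated acquisitions
#'
#' Aggregates fragmentation trees of the same precursor across repetitions.
#' An EFP is retained iff it is present in at least `min_fraction` of the
#' trees (inclusive; the default 0.4 retains a 2-of-5 EFP). Per retained
#' EFP the mean and sample (n-1) standard deviation of the relative
#' intensity, and the mean ppm error, are computed over the trees where the
#' EFP is present.
#'
#' @param trees list of `fragmentation_tree` objects with identical root
#'   formula.
#' @param min_fraction minimum presence fraction in `[0, 1]`, default 0.4.
#' @return an object of class `consensus_tree`: list with `entries` (a
#'   data.frame `efp`, `ms_level`, `presence_fraction`, `mean_rel_intensity`,
#'   `sd_rel_intensity`, `mean_ppm_error`), `n_repetitions`, `root_token`
#'   and `min_fraction`.
#' @export
consensus <- function(trees, min_fraction = 0.4) {
  stopifnot(length(trees) >= 1L, min_fraction >= 0, min_fraction <= 1)
  roots <- unique(vapply(trees, function(t) t$root_token, character(1)))
  if (length(roots) != 1L) {
    stop("consensus requires identical root formulas, got: ",
         paste(roots, collapse = ", "), call. = FALSE)
  }
  n <- length(trees)
  all_nodes <- do.call(rbind, lapply(seq_along(trees), function(i) {
    cbind(trees[[i]]$nodes[c("efp", "ms_level", "rel_intensity", "ppm_error")],
          rep_id = i)
  }))
  sp <- split(all_nodes, all_nodes$efp)
  entries <- do.call(rbind, lapply(sp, function(d) {
    data.frame(
      efp = d$efp[1], ms_level = d$ms_level[1],
      presence_fraction = length(unique(d$rep_id)) / n,
      mean_rel_intensity = mean(d$rel_intensity),
      sd_rel_intensity = if (nrow(d) > 1L) stats::sd(d$rel_intensity) else 0,
      mean_ppm_error = mean(d$ppm_error),
      stringsAsFactors = FALSE
    )
  }))
  entries <- entries[entries$presence_fraction >= min_fraction, , drop = FALSE]
  entries <- entries[order(entries$efp), , drop = FALSE]
  rownames(entries) <- NULL
  structure(
    list(entries = entries, n_repetitions = n, root_token = roots,
         min_fraction = min_fraction),
    class = "consensus_tree"
  )
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("<consensus_tree> root %s, %d EFP(s) over %d repetition(s)\n",
              x$root_token, nrow(x$entries), x$n_repetitions))
  invisible(x)
}
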