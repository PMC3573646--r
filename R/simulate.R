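# Data-dependent MSn acquisition simulator. Ground-truth fragmentation
# trees (ion formulas with per-spectrum relative intensities) are turned
# into scan sequences following a top-N DDA scheme, with ppm-scale mass
# noise, multiplicative intensity noise and injected artifact peaks, so the
# whole pipeline is testable end-to-end without instrument data.

#' Data-dependent acquisition scheme
#'
#' @param top_n_by_level named integer vector mapping an MS level to the
#'   number of its highest peaks that are fragmented into the next level;
#'   default `c("2" = 5, "3" = 5, "4" = 3)` (the MS1 survey scan always
#'   selects exactly one precursor).
#' @param max_level deepest MS level acquired, default 5.
#' @param precursor_threshold minimum absolute intensity (ion counts) for a
#'   peak to be selected for fragmentation, default 4500.
#' @param isolation_width precursor isolation window in m/z, default 2.
#' @return a list of class `acquisition_scheme`.
#' @export
acquisition_scheme <- function(top_n_by_level = c("2" = 5L, "3" = 5L, "4" = 3L),
                               max_level = 5L, precursor_threshold = 4500,
                               isolation_width = 2) {
  stopifnot(max_level >= 2L, all(top_n_by_level >= 0L), precursor_threshold >= 0)
  structure(list(top_n_by_level = top_n_by_level,
                 max_level = as.integer(max_level),
                 precursor_threshold = precursor_threshold,
                 isolation_width = isolation_width),
            class = "acquisition_scheme")
}

#' Noise model for simulated acquisitions
#'
#' @param mass_sigma_ppm standard deviation of the relative mass error in
#'   ppm (Normal, mean 0).
#' @param intensity_cv coefficient of variation of the multiplicative
#'   (log-normal) intensity noise.
#' @param artifact_rate expected number of injected artifact peaks per
#'   fragmentation scan (Poisson). Artifact m/z values are rejection-sampled
#'   to lie at least two mass tolerances away from every valid sub-formula
#'   ion mass of the scan's precursor, so they admit no formula; their
#'   absolute intensities are drawn below the precursor threshold, so they
#'   are never selected for fragmentation.
#' @param seed master seed; one fixed child seed is derived per repetition,
#'   making output fully deterministic.
#' @return a list of class `noise_model`.
#' @export
noise_model <- function(mass_sigma_ppm = 0, intensity_cv = 0,
                        artifact_rate = 0, seed = 1L) {
  stopifnot(mass_sigma_ppm >= 0, intensity_cv >= 0, artifact_rate >= 0,
            is.finite(seed))
  structure(list(mass_sigma_ppm = mass_sigma_ppm, intensity_cv = intensity_cv,
                 artifact_rate = artifact_rate, seed = as.integer(seed)),
            class = "noise_model")
}

#' Number of scan events a DDA scheme can generate
#'
#' Assuming every spectrum yields enough peaks to saturate the scheme:
#' one full scan, one MS2 of the selected precursor, then at each level the
#' product of the top-N values so far. The default 5/5/3 scheme to MS5
#' gives `1 + 1 + 5 + 25 + 75 = 107`.
#'
#' @param scheme an [acquisition_scheme()].
#' @param assume_full_trees logical; the saturated count (the only mode,
#'   kept as an explicit argument for clarity).
#' @return integer scan-event count.
#' @export
count_scan_events <- function(scheme = acquisition_scheme(),
                              assume_full_trees = TRUE) {
  stopifnot(isTRUE(assume_full_trees))
  total <- 2L  # full scan + MS2 of the selected precursor
  prod_n <- 1
  if (scheme$max_level >= 3L) {
    for (lvl in 2L:(scheme$max_level - 1L)) {
      n <- scheme$top_n_by_level[[as.character(lvl)]]
      if (is.null(n)) n <- 0L
      prod_n <- prod_n * n
      total <- total + prod_n
    }
  }
  as.integer(total)
}

# ---- ground-truth trees --------------------------------------------------

#' Build a ground-truth tree from EFP strings
#'
#' Reconstructs the nested node structure from a set of EFP strings whose
#' prefixes are closed (every prefix of a path is itself a path). Optional
#' per-node relative intensities and fixed mass shifts (ppm) ride along;
#' shifts are applied deterministically on top of any random mass noise
#' during simulation.
#'
#' @param efps character vector of EFP strings (root = single token).
#' @param rel_intensity numeric vector aligned with `efps` (percent of the
#'   spectrum base peak); defaults to 100 everywhere.
#' @param mass_shift_ppm numeric vector aligned with `efps`; default 0.
#' @param polarity `+1` or `-1`.
#' @return an object of class `truth_tree` with fields `root` (nested nodes
#'   `formula`, `rel_intensity`, `mass_shift_ppm`, `efp`, `children`) and
#'   `polarity`.
#' @export
truth_from_paths <- function(efps, rel_intensity = NULL, mass_shift_ppm = NULL,
                             polarity = 1L) {
  stopifnot(length(efps) >= 1L, !anyDuplicated(efps))
  if (is.null(rel_intensity)) rel_intensity <- rep(100, length(efps))
  if (is.null(mass_shift_ppm)) mass_shift_ppm <- rep(0, length(efps))
  depth <- lengths(strsplit(efps, "||", fixed = TRUE))
  if (sum(depth == 1L) != 1L) stop("exactly one root path required", call. = FALSE)
  make_node <- function(efp, i) {
    parts <- strsplit(efp, "||", fixed = TRUE)[[1]]
    kid_idx <- which(startsWith(efps, paste0(efp, "||")) &
                       depth == length(parts) + 1L)
    f <- parse_formula(parts[length(parts)])
    if (length(parts) > 1L &&
        !is_subformula(f, parse_formula(parts[length(parts) - 1L]))) {
      stop("truth tree violates the sub-formula relation at ", efp, call. = FALSE)
    }
    list(formula = f, efp = efp, rel_intensity = rel_intensity[i],
         mass_shift_ppm = mass_shift_ppm[i],
         children = lapply(kid_idx, function(k) make_node(efps[k], k)))
  }
  root_i <- which(depth == 1L)
  structure(list(root = make_node(efps[root_i], root_i),
                 polarity = as.integer(polarity)),
            class = "truth_tree")
}

#' EFP strings of a ground-truth tree
#' @param truth a `truth_tree`.
#' @return character vector.
#' @export
truth_efps <- function(truth) {
  walk <- function(node) c(node$efp, unlist(lapply(node$children, walk)))
  walk(truth$root)
}

#' @export
print.truth_tree <- function(x, ...) {
  cat(sprintf("<truth_tree> root %s, %d node(s)\n",
              serialize_formula(x$root$formula), length(truth_efps(x))))
  invisible(x)
}

#' The glutathione MSn worked example
#'
#' The packaged 21-path fragmentation tree of protonated glutathione
#' (root ion C10H18N3O6S), with each node's per-spectrum relative intensity,
#' its reported mass error in ppm (used as a fixed mass shift when the tree
#' is simulated), and the reported standard deviation of the relative
#' intensity. This is the canonical fixture for the whole pipeline.
#'
#' @return list with `truth` (a [truth_from_paths()] tree, positive mode),
#'   `table` (one row per path: `efp`, `ms_level`, `display`, `printed_mz`,
#'   `rel_intensity`, `ppm_error`, `sd_rel_intensity`), and `efp` (the 21
#'   expected EFP strings).
#' @export
glutathione_fixture <- function() {
  tab <- .GLUTATHIONE_TABLE
  truth <- truth_from_paths(tab$efp, tab$rel_intensity, tab$ppm_error,
                            polarity = 1L)
  list(truth = truth, table = tab, efp = tab$efp)
}

.GLUTATHIONE_TABLE <- local({
  raw <- c(
    "C10H18N3O6S1;1;C10H18N3O6S;308.091;100;-0.5;0",
    "C10H18N3O6S1||C5H11N2O3S1;2;C5H11N2O3S;179.049;100;1.3;0",
    "C10H18N3O6S1||C5H11N2O3S1||C5H8N1O3S1;3;C5H8NO3S;162.022;100;0.2;0",
    "C10H18N3O6S1||C5H11N2O3S1||C5H8N1O3S1||C4H6N1O1S1;4;C4H6NOS;116.016;27;-0.3;1.4",
    "C10H18N3O6S1||C5H11N2O3S1||C5H8N1O3S1||C5H6N1O2S1;4;C5H6NO2S;144.011;100;0.1;0",
    "C10H18N3O6S1||C5H11N2O3S1||C5H8N1O3S1||C5H6N1O2S1||C4H6N1O1S1;5;C4H6NOS;116.016;100;-0.4;0",
    "C10H18N3O6S1||C5H8N1O3S1;2;C5H8NO3S;162.022;33;1.3;1.8",
    "C10H18N3O6S1||C5H8N1O3S1||C4H6N1O1S1;3;C4H6NOS;116.016;27;-0.4;1.4",
    "C10H18N3O6S1||C5H8N1O3S1||C5H6N1O2S1;3;C5H6NO2S;144.011;100;0.1;0",
    "C10H18N3O6S1||C5H8N1O3S1||C5H6N1O2S1||C4H6N1O1S1;4;C4H6NOS;116.016;100;-0.5;0",
    "C10H18N3O6S1||C8H13N2O4S1;2;C8H13N2O4S;233.059;25;1.7;1.4",
    "C10H18N3O6S1||C8H13N2O4S1||C7H11N2O2S1;3;C7H11N2O2S;187.054;100;0.8;0",
    "C10H18N3O6S1||C8H13N2O4S1||C7H11N2O2S1||C7H8N1O2S1;4;C7H8NO2S;170.027;100;0.5;0",
    "C10H18N3O6S1||C8H13N2O4S1||C7H11N2O2S1||C7H8N1O2S1||C6H6N1S1;5;C6H6NS;124.022;100;-0.4;0",
    "C10H18N3O6S1||C8H13N2O4S1||C8H11N2O3S1;3;C8H11N2O3S;215.049;32;0.9;3.5",
    "C10H18N3O6S1||C8H13N2O4S1||C8H11N2O3S1||C7H11N2O2S1;4;C7H11N2O2S;187.054;100;0.8;0",
    "C10H18N3O6S1||C8H13N2O4S1||C8H11N2O3S1||C7H11N2O2S1||C6H9N2S1;5;C6H9N2S;141.048;100;-0.1;0",
    "C10H18N3O6S1||C8H13N2O4S1||C8H11N2O3S1||C7H11N2O2S1||C7H8N1O2S1;5;C7H8NO2S;170.027;82;0.3;8.7",
    "C10H18N3O6S1||C5H11N2O3S1||C5H8N1O3S1||C4H6N1O1S1||C3H6N1S1;5;C3H6NS;88.021;100;-1.0;0",
    "C10H18N3O6S1||C5H8N1O3S1||C4H6N1O1S1||C3H6N1S1;4;C3H6NS;88.021;100;-1.0;0",
    "C10H18N3O6S1||C5H8N1O3S1||C5H6N1O2S1||C4H6N1O1S1||C3H6N1S1;5;C3H6NS;88.021;100;-1.0;0"
  )
  f <- strsplit(raw, ";", fixed = TRUE)
  data.frame(
    efp = vapply(f, `[`, character(1), 1),
    ms_level = as.integer(vapply(f, `[`, character(1), 2)),
    display = vapply(f, `[`, character(1), 3),
    printed_mz = as.numeric(vapply(f, `[`, character(1), 4)),
    rel_intensity = as.numeric(vapply(f, `[`, character(1), 5)),
    ppm_error = as.numeric(vapply(f, `[`, character(1), 6)),
    sd_rel_intensity = as.numeric(vapply(f, `[`, character(1), 7)),
    stringsAsFactors = FALSE
  )
})

# ---- acquisition ---------------------------------------------------------

#' Simulate a data-dependent MSn acquisition
#'
#' Per repetition: an MS1 survey scan carrying the root ion, then a
#' depth-first DDA walk. Each fragmented peak (top-N of its spectrum by
#' noisy intensity, absolute intensity above the precursor threshold)
#' yields a child scan whose peaks are the corresponding truth node's
#' children with `m/z = ion_mz * (1 + shift_ppm*1e-6 + eps)`,
#' `eps ~ Normal(0, mass_sigma_ppm * 1e-6)`, multiplicative log-normal
#' intensity noise at the given CV, plus Poisson-many artifact peaks (see
#' [noise_model()]). Fully deterministic given the master seed.
#'
#' @param truth a `truth_tree` (see [truth_from_paths()]); must not be
#'   deeper than `scheme$max_level`.
#' @param scheme an [acquisition_scheme()].
#' @param noise a [noise_model()].
#' @param repetitions number of repeats of the MSn sequence, default 1.
#' @param root_intensity absolute ion count of the precursor in the survey
#'   scan, default 1e6.
#' @param transfer per-stage ion transfer efficiency: a fragment spectrum's
#'   base peak carries `transfer` times its precursor peak's absolute
#'   intensity, default 0.5.
#' @param tol_ppm tolerance used when rejection-sampling artifact m/z away
#'   from valid sub-formula masses, default 6.
#' @return a list of [scan()] objects in acquisition order (all
#'   repetitions concatenated).
#' @export
simulate_acquisition <- function(truth, scheme = acquisition_scheme(),
                                 noise = noise_model(), repetitions = 1L,
                                 root_intensity = 1e6, transfer = 0.5,
                                 tol_ppm = 6) {
  depth <- max(lengths(strsplit(truth_efps(truth), "||", fixed = TRUE)))
  if (depth > scheme$max_level) {
    stop("truth tree deeper than the acquisition scheme's max_level", call. = FALSE)
  }
  scans <- list()
  scan_no <- 0L
  pol <- truth$polarity

  noisy_mz <- function(node) {
    eps <- if (noise$mass_sigma_ppm > 0) stats::rnorm(1, 0, noise$mass_sigma_ppm) else 0
    ion_mz(node$formula, pol) * (1 + (node$mass_shift_ppm + eps) * 1e-6)
  }
  noisy_int <- function(x) {
    if (noise$intensity_cv == 0) return(x)
    sl <- sqrt(log(1 + noise$intensity_cv^2))
    x * exp(stats::rnorm(length(x), -sl^2 / 2, sl))
  }
  emit <- function(s) {
    scans[[length(scans) + 1L]] <<- s
  }

  # all valid sub-formula ion masses of a cap, for artifact rejection
  subformula_masses <- function(cap) {
    g <- as.matrix(expand.grid(lapply(unclass(cap), function(n) 0:n),
                               KEEP.OUT.ATTRS = FALSE))
    as.numeric(g %*% .ATOMIC_MASS - pol * .ELECTRON_MASS)
  }
  draw_artifacts <- function(cap, precursor_mz) {
    k <- stats::rpois(1, noise$artifact_rate)
    if (!k) return(data.frame(mz = numeric(), intensity = numeric()))
    masses <- subformula_masses(cap)
    mz <- numeric(0)
    while (length(mz) < k) {
      cand <- stats::runif(1, 50, precursor_mz + 5)
      rel_d <- min(abs(cand - masses) / cand) * 1e6
      if (rel_d > 2 * tol_ppm) mz <- c(mz, cand)
    }
    data.frame(mz = mz,
               intensity = stats::runif(k, 0.05, 0.8) * scheme$precursor_threshold)
  }

  fragment <- function(node, node_abs, node_obs_mz, parent_scan_id, level) {
    # emits the fragmentation scan of `node` and recurses by DDA selection
    if (!length(node$children) || level + 1L > scheme$max_level) return(invisible())
    if (node_abs < scheme$precursor_threshold) return(invisible())
    child_level <- level + 1L
    base <- node_abs * transfer
    kid_abs <- noisy_int(vapply(node$children, function(k) k$rel_intensity, numeric(1)) / 100 * base)
    kid_mz <- vapply(node$children, noisy_mz, numeric(1))
    art <- draw_artifacts(node$formula, node_obs_mz)
    peaks <- data.frame(mz = c(kid_mz, art$mz),
                        intensity = c(kid_abs, art$intensity))
    scan_no <<- scan_no + 1L
    sid <- as.character(scan_no)
    emit(scan(sid, child_level, peaks, polarity = pol,
              precursor_mz = node_obs_mz, precursor_scan_id = parent_scan_id,
              precursor_intensity = node_abs))
    if (child_level >= scheme$max_level) return(invisible())
    n_frag <- scheme$top_n_by_level[[as.character(child_level)]]
    if (is.null(n_frag) || n_frag < 1L) return(invisible())
    eligible <- which(peaks$intensity >= scheme$precursor_threshold)
    sel <- eligible[order(-peaks$intensity[eligible])]
    sel <- utils::head(sel, n_frag)
    for (i in sel) {
      if (i > length(node$children)) next  # artifact peak: no true subtree
      fragment(node$children[[i]], peaks$intensity[i], peaks$mz[i], sid, child_level)
    }
    invisible()
  }

  for (rep_i in seq_len(repetitions)) {
    set.seed((noise$seed + 97L * (rep_i - 1L)) %% .Machine$integer.max)
    root_abs <- noisy_int(root_intensity)
    root_mz <- noisy_mz(truth$root)
    scan_no <- scan_no + 1L
    root_sid <- as.character(scan_no)
    emit(scan(root_sid, 1L, data.frame(mz = root_mz, intensity = root_abs),
              polarity = pol))
    fragment(truth$root, root_abs, root_mz, root_sid, 1L)
  }
  scans
}

#' Write scans to a minimal valid mzXML file
#'
#' Serialization goes through `mzR::writeMSData()` (mzXML output), so the
#' files are readable by any standards-compliant tool as well as by
#' [read_mzxml()].
#'
#' @param scans list of [scan()] objects in acquisition order.
#' @param path output path (conventionally `.mzXML`).
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(scans, path) {
  stopifnot(length(scans) >= 1L)
  n <- length(scans)
  na <- rep(NA_real_, n)
  num <- function(f) vapply(scans, f, numeric(1))
  int <- function(f) vapply(scans, f, integer(1))
  h <- data.frame(
    seqNum = seq_len(n),
    acquisitionNum = int(function(s) as.integer(s$scan_id)),
    msLevel = int(function(s) s$ms_level),
    polarity = int(function(s) if (s$polarity > 0) 1L else 0L),
    peaksCount = int(function(s) nrow(s$peaks)),
    totIonCurrent = num(function(s) sum(s$peaks$intensity)),
    retentionTime = seq_len(n),
    basePeakMZ = num(function(s)
      if (nrow(s$peaks)) s$peaks$mz[which.max(s$peaks$intensity)] else 0),
    basePeakIntensity = num(function(s)
      if (nrow(s$peaks)) max(s$peaks$intensity) else 0),
    collisionEnergy = num(function(s) if (s$ms_level > 1) 35 else 0),
    ionisationEnergy = rep(0, n),
    lowMZ = num(function(s) if (nrow(s$peaks)) min(s$peaks$mz) else 0),
    highMZ = num(function(s) if (nrow(s$peaks)) max(s$peaks$mz) else 0),
    precursorScanNum = int(function(s)
      if (is.null(s$precursor_scan_id)) 0L else as.integer(s$precursor_scan_id)),
    precursorMZ = num(function(s)
      if (is.null(s$precursor_mz)) 0 else s$precursor_mz),
    precursorCharge = int(function(s) if (s$ms_level > 1) 1L else 0L),
    precursorIntensity = num(function(s)
      if (is.null(s$precursor_intensity)) 0 else s$precursor_intensity),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n),
    filterString = rep(NA_character_, n),
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = rep(TRUE, n),
    ionMobilityDriftTime = na,
    isolationWindowTargetMZ = num(function(s)
      if (is.null(s$precursor_mz)) NA_real_ else s$precursor_mz),
    isolationWindowLowerOffset = ifelse(int(function(s) s$ms_level) > 1, 1, NA),
    isolationWindowUpperOffset = ifelse(int(function(s) s$ms_level) > 1, 1, NA),
    scanWindowLowerLimit = na, scanWindowUpperLimit = na,
    stringsAsFactors = FALSE
  )
  pk <- lapply(scans, function(s) {
    m <- as.matrix(s$peaks[order(s$peaks$mz), c("mz", "intensity"), drop = FALSE])
    dimnames(m) <- NULL
    m
  })
  mzR::writeMSData(pk, file = path, header = h, outformat = "mzxml")
  invisible(path)
}

# ---- isomer-pair fixture -------------------------------------------------

# neutral-loss pool used when growing synthetic trees
.LOSS_POOL <- c("H2O", "CO", "CO2", "CH2O", "C2H4", "C2H2O", "C3H6", "CH2",
                "H2", "C2H4O2", "C4H8", "C2H6", "C3H4O", "H2O2", "C4H6",
                "C2H4O", "C3H4", "C5H8", "CH4O", "C2H2")

# grow `n_new` EFPs under existing nodes, never producing a path in `avoid`
.grow_paths <- function(nodes, n_new, avoid, max_depth = 5L) {
  # nodes: data.frame(efp, token, depth); grows in place and returns it
  added <- 0L
  tries <- 0L
  while (added < n_new) {
    tries <- tries + 1L
    if (tries > 5000L) {
      stop("infeasible EFP counts: could not grow a distinct path", call. = FALSE)
    }
    i <- sample.int(nrow(nodes), 1)
    if (nodes$depth[i] >= max_depth) next
    parent <- parse_formula(nodes$token[i])
    loss <- parse_formula(sample(.LOSS_POOL, 1))
    if (!is_subformula(loss, parent)) next
    child <- subtract_formula(parent, loss)
    if (sum(unclass(child)) == 0L || unclass(child)[["C"]] < 1L ||
        unclass(child)[["H"]] < 1L) next
    tok <- serialize_formula(child, "efp_token")
    efp <- paste(nodes$efp[i], tok, sep = "||")
    if (efp %in% nodes$efp || efp %in% avoid) next
    nodes <- rbind(nodes, data.frame(efp = efp, token = tok,
                                     depth = nodes$depth[i] + 1L,
                                     stringsAsFactors = FALSE))
    added <- added + 1L
  }
  nodes
}

# per-spectrum relative intensities: the first child of every parent is the
# base peak (100), siblings get reproducible values in [30, 95]
.assign_rel_intensities <- function(efps) {
  depth <- lengths(strsplit(efps, "||", fixed = TRUE))
  parent <- vapply(strsplit(efps, "||", fixed = TRUE), function(p) {
    if (length(p) == 1L) "" else paste(p[-length(p)], collapse = "||")
  }, character(1))
  rel <- rep(100, length(efps))
  for (pp in unique(parent[parent != ""])) {
    kids <- which(parent == pp)
    if (length(kids) > 1L) {
      rel[kids[-1L]] <- round(stats::runif(length(kids) - 1L, 30, 95))
    }
  }
  rel[depth == 1L] <- 100
  rel
}

#' Synthetic isomer pair with controlled EFP overlap
#'
#' Builds two ground-truth trees with the same root ion whose EFP sets have
#' sizes `n_a` and `n_b` and intersect in exactly `n_shared` paths
#' (the shared paths form a common subtree including the root). Mirrors the
#' structure of an isomeric compound pair measured under the same method:
#' a common fragmentation core plus compound-characteristic branches.
#'
#' @param n_a,n_b EFP set sizes of the two trees.
#' @param n_shared size of the intersection; must satisfy
#'   `1 <= n_shared <= min(n_a, n_b)` (the root path is always shared).
#' @param seed integer seed; the construction is deterministic given it.
#' @param root root ion composition, default `"C20H31O5"` (a deprotonated
#'   prostaglandin-like ion); polarity is negative.
#' @return list with `truth_a`, `truth_b` (class `truth_tree`) and `efp_a`,
#'   `efp_b` (their EFP sets).
#' @export
make_isomer_pair_fixture <- function(n_a, n_b, n_shared, seed = 1L,
                                     root = "C20H31O5") {
  if (n_shared < 1L) {
    stop("n_shared must be >= 1: the root path is common to both trees", call. = FALSE)
  }
  if (n_shared > min(n_a, n_b)) {
    stop("n_shared cannot exceed min(n_a, n_b)", call. = FALSE)
  }
  set.seed(seed)
  root_tok <- serialize_formula(parse_formula(root), "efp_token")
  base <- data.frame(efp = root_tok, token = root_tok, depth = 1L,
                     stringsAsFactors = FALSE)
  shared <- .grow_paths(base, n_shared - 1L, avoid = character())
  a <- .grow_paths(shared, n_a - n_shared, avoid = character())
  b <- .grow_paths(shared, n_b - n_shared, avoid = a$efp)
  truth_a <- truth_from_paths(a$efp, .assign_rel_intensities(a$efp), polarity = -1L)
  truth_b <- truth_from_paths(b$efp, .assign_rel_intensities(b$efp), polarity = -1L)
  list(truth_a = truth_a, truth_b = truth_b, efp_a = a$efp, efp_b = b$efp)
}
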