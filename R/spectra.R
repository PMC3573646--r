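# Scan and spectrum-tree containers, mzXML reading (via mzR), precursor
# linking, intensity normalization and the internal peak-tree JSON format.

#' Construct a scan
#'
#' A centroided peak list at one MSn level. MS1 scans carry no precursor
#' fields; an MSn (n >= 2) scan records the m/z that was isolated and,
#' when known, the identifier of the scan it came from.
#'
#' @param scan_id unique scan identifier (coerced to character).
#' @param ms_level integer >= 1.
#' @param peaks data.frame with numeric columns `mz` (> 0) and `intensity`
#'   (>= 0); a `rel_intensity` column is added by [normalize_intensities()].
#' @param polarity `+1` or `-1`.
#' @param precursor_mz,precursor_scan_id,precursor_intensity precursor
#'   attributes; must be absent for MS1 scans.
#' @return an object of class `msn_scan`.
#' @export
scan <- function(scan_id, ms_level, peaks, polarity = 1L,
                 precursor_mz = NULL, precursor_scan_id = NULL,
                 precursor_intensity = NULL) {
  ms_level <- as.integer(ms_level)
  stopifnot(ms_level >= 1L, polarity %in% c(-1L, 1L))
  if (ms_level == 1L && !is.null(precursor_mz)) {
    stop("MS1 scans cannot carry precursor attributes", call. = FALSE)
  }
  if (ms_level > 1L && is.null(precursor_mz)) {
    stop("MSn (n >= 2) scans require precursor_mz", call. = FALSE)
  }
  peaks <- as.data.frame(peaks)
  if (!nrow(peaks)) {
    peaks <- data.frame(mz = numeric(), intensity = numeric())
  }
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$mz <= 0) || any(peaks$intensity < 0)) {
    stop("peaks require mz > 0 and intensity >= 0", call. = FALSE)
  }
  if (is.null(peaks$rel_intensity)) peaks$rel_intensity <- rep(NA_real_, nrow(peaks))
  structure(
    list(scan_id = as.character(scan_id), ms_level = ms_level,
         polarity = as.integer(polarity),
         precursor_mz = precursor_mz,
         precursor_scan_id = if (is.null(precursor_scan_id)) NULL else as.character(precursor_scan_id),
         precursor_intensity = precursor_intensity,
         peaks = peaks[c("mz", "intensity", "rel_intensity")]),
    class = "msn_scan"
  )
}

#' @export
print.msn_scan <- function(x, ...) {
  cat(sprintf("<msn_scan %s> MS%d, %d peak(s)%s\n", x$scan_id, x$ms_level,
              nrow(x$peaks),
              if (!is.null(x$precursor_mz))
                sprintf(", precursor %.4f", x$precursor_mz) else ""))
  invisible(x)
}

#' Read an mzXML file into scans
#'
#' Backed by `mzR`: scan headers supply `msLevel`, `precursorMZ`,
#' `precursorScanNum` and polarity; peak arrays are decoded by the library.
#' `precursor_scan_id` is taken from `precursorScanNum` when present,
#' otherwise left unset for [link_precursors()] to infer. Profile-mode data
#' triggers a warning and is passed through unchanged (peak picking is out
#' of scope; inputs are assumed centroided).
#'
#' @param path path to an mzXML file.
#' @return a list of [scan()] objects in acquisition order.
#' @export
read_mzxml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f), add = TRUE)
  h <- mzR::header(f)
  if (!nrow(h)) return(list())
  if (any(is.na(h$msLevel)) || any(h$msLevel < 1)) {
    stop("mzXML scan without a valid msLevel attribute", call. = FALSE)
  }
  if (!is.null(h$centroided) && any(!is.na(h$centroided) & !h$centroided)) {
    warning("profile-mode scans detected; passing peaks through unchanged")
  }
  pk <- mzR::peaks(f)
  if (is.matrix(pk)) pk <- list(pk)
  lapply(seq_len(nrow(h)), function(i) {
    p <- pk[[i]]
    peaks <- data.frame(mz = p[, 1], intensity = p[, 2])
    lvl <- h$msLevel[i]
    pol <- if (!is.null(h$polarity) && !is.na(h$polarity[i]) && h$polarity[i] == 0) -1L else 1L
    pnum <- h$precursorScanNum[i]
    scan(
      scan_id = h$acquisitionNum[i], ms_level = lvl, peaks = peaks,
      polarity = pol,
      precursor_mz = if (lvl > 1) h$precursorMZ[i] else NULL,
      precursor_scan_id = if (lvl > 1 && !is.na(pnum) && pnum > 0) pnum else NULL,
      precursor_intensity = if (lvl > 1) h$precursorIntensity[i] else NULL
    )
  })
}

#' Link scans into spectrum trees via precursor relations
#'
#' Each MSn (n >= 2) scan is attached to the most recent preceding scan of
#' level n-1 that contains a peak within `link_tol_mz` of the scan's
#' precursor m/z (when the file records an explicit precursor scan id, that
#' scan is tried first). Scans with no candidate parent are dropped with a
#' warning. When `repetition_split` is on, every new MS1 scan opens a new
#' repetition of the MSn sequence, yielding one tree per repetition.
#'
#' @param scans list of [scan()] objects in acquisition order.
#' @param link_tol_mz absolute m/z window for matching a precursor to a
#'   parent-scan peak; default 0.5 (half a typical isolation width).
#' @param repetition_split logical, default `TRUE`.
#' @return a list of `spectrum_tree` objects. Each has fields `scans`
#'   (named list), `parent` and `parent_peak` (named vectors keyed by scan
#'   id), `root_id`, `root_mz` and `repetition`.
#' @export
link_precursors <- function(scans, link_tol_mz = 0.5, repetition_split = TRUE) {
  stopifnot(link_tol_mz > 0)
  trees <- list()
  cur <- NULL
  orphans <- 0L
  flush <- function() {
    if (!is.null(cur)) trees[[length(trees) + 1L]] <<- .finalize_tree(cur)
  }
  for (s in scans) {
    if (s$ms_level == 1L) {
      if (is.null(cur) || repetition_split) {
        flush()
        cur <- list(scans = list(), parent = character(), parent_peak = integer(),
                    root_id = s$scan_id, repetition = length(trees) + 1L)
      }
      cur$scans[[s$scan_id]] <- s
      next
    }
    if (is.null(cur)) { orphans <- orphans + 1L; next }
    hit <- .find_parent(cur, s, link_tol_mz)
    if (is.null(hit)) { orphans <- orphans + 1L; next }
    cur$scans[[s$scan_id]] <- s
    cur$parent[s$scan_id] <- hit$id
    cur$parent_peak[s$scan_id] <- hit$peak
    # parents must already carry a formula-bearing level chain
  }
  flush()
  if (orphans > 0L) {
    warning(sprintf("%d orphan scan(s) dropped (no matching parent peak)", orphans))
  }
  trees
}

.find_parent <- function(cur, s, tol) {
  ids <- names(cur$scans)
  cand_ids <- character()
  if (!is.null(s$precursor_scan_id) && s$precursor_scan_id %in% ids) {
    cand_ids <- s$precursor_scan_id
  }
  # most-recent-first fallback over preceding scans one level up
  lv <- vapply(cur$scans, function(x) x$ms_level, integer(1))
  cand_ids <- c(cand_ids, rev(ids[lv == s$ms_level - 1L]))
  for (id in cand_ids) {
    p <- cur$scans[[id]]
    if (p$ms_level != s$ms_level - 1L) next
    d <- abs(p$peaks$mz - s$precursor_mz)
    if (length(d) && min(d) <= tol) {
      return(list(id = id, peak = which.min(d)))
    }
  }
  NULL
}

.finalize_tree <- function(cur) {
  # root m/z: precursor of the first MS2 scan; for an MS1-only tree the
  # base peak of the survey scan
  ms2 <- Filter(function(s) s$ms_level == 2L, cur$scans)
  root_scan <- cur$scans[[cur$root_id]]
  root_mz <- if (length(ms2)) {
    ms2[[1]]$precursor_mz
  } else if (nrow(root_scan$peaks)) {
    root_scan$peaks$mz[which.max(root_scan$peaks$intensity)]
  } else NA_real_
  tree <- structure(
    list(scans = cur$scans, parent = cur$parent, parent_peak = cur$parent_peak,
         root_id = cur$root_id, root_mz = root_mz, repetition = cur$repetition),
    class = "spectrum_tree"
  )
  validate_spectrum_tree(tree)
  tree
}

#' Validate a spectrum tree
#'
#' Asserts the structural invariants: acyclic parent links and level
#' consistency (each child scan's level is its parent's plus one).
#'
#' @param tree a `spectrum_tree`.
#' @return the tree, invisibly; errors on violation.
#' @export
validate_spectrum_tree <- function(tree) {
  ids <- names(tree$scans)
  for (id in names(tree$parent)) {
    pid <- tree$parent[[id]]
    if (!pid %in% ids) stop("parent scan '", pid, "' missing", call. = FALSE)
    if (tree$scans[[id]]$ms_level != tree$scans[[pid]]$ms_level + 1L) {
      stop("level inconsistency at scan '", id, "'", call. = FALSE)
    }
    # cycle check by walking up; parent chain must terminate at the root
    seen <- id
    cur <- pid
    while (!is.null(cur)) {
      if (cur %in% seen) stop("cyclic precursor links at scan '", id, "'", call. = FALSE)
      seen <- c(seen, cur)
      cur <- if (cur %in% names(tree$parent)) tree$parent[[cur]] else NULL
    }
  }
  invisible(tree)
}

#' @export
print.spectrum_tree <- function(x, ...) {
  cat(sprintf("<spectrum_tree> root m/z %.4f, %d scan(s), repetition %d\n",
              x$root_mz, length(x$scans), x$repetition))
  invisible(x)
}

#' Normalize peak intensities to the base peak
#'
#' Sets `rel_intensity = 100 * intensity / max(intensity)` so the base peak
#' of each scan is exactly 100. Idempotent. Errors on an all-zero scan.
#'
#' @param scan an [scan()] object with at least one peak of intensity > 0.
#' @export
normalize_intensities <- function(scan) {
  if (!nrow(scan$peaks) || all(scan$peaks$intensity == 0)) {
    stop("cannot normalize a scan with no positive intensity", call. = FALSE)
  }
  scan$peaks$rel_intensity <- 100 * scan$peaks$intensity / max(scan$peaks$intensity)
  scan
}

#' Simple intensity threshold filter
#'
#' Removes peaks below `min_intensity` counts or below `min_snr` times the
#' median intensity of the scan — a deliberately simple surrogate for
#' upstream peak picking, which is assumed done.
#'
#' @param scan an [scan()] object.
#' @param min_intensity absolute floor in ion counts (default 0).
#' @param min_snr multiple of the scan's median intensity (default 0).
#' @export
threshold_filter <- function(scan, min_intensity = 0, min_snr = 0) {
  if (!nrow(scan$peaks)) return(scan)
  floor_ <- max(min_intensity, min_snr * stats::median(scan$peaks$intensity))
  scan$peaks <- scan$peaks[scan$peaks$intensity >= floor_, , drop = FALSE]
  rownames(scan$peaks) <- NULL
  scan
}

#' Composite spectrum of a whole MSn experiment
#'
#' Merges the peaks of every scan in the tree into one spectrum: peaks
#' within `bin_tol_mz` of each other are coalesced into a single peak at
#' the intensity-weighted mean m/z with summed intensity, then intensities
#' are renormalized to base peak 100. Output is independent of scan order.
#'
#' @param tree a `spectrum_tree`.
#' @param bin_tol_mz coalescing window in m/z units, default 0.01.
#' @return a data.frame with columns `mz`, `intensity`, `rel_intensity`.
#' @export
composite_spectrum <- function(tree, bin_tol_mz = 0.01) {
  all_pk <- do.call(rbind, lapply(tree$scans, function(s) s$peaks[c("mz", "intensity")]))
  if (is.null(all_pk) || !nrow(all_pk)) {
    return(data.frame(mz = numeric(), intensity = numeric(), rel_intensity = numeric()))
  }
  all_pk <- all_pk[order(all_pk$mz), , drop = FALSE]
  grp <- cumsum(c(1, diff(all_pk$mz) > bin_tol_mz))
  mz <- as.numeric(tapply(all_pk$mz * all_pk$intensity, grp, sum) /
                     tapply(all_pk$intensity, grp, sum))
  # all-zero bins fall back to the plain mean m/z
  zero <- is.na(mz)
  if (any(zero)) mz[zero] <- as.numeric(tapply(all_pk$mz, grp, mean))[zero]
  intensity <- as.numeric(tapply(all_pk$intensity, grp, sum))
  out <- data.frame(mz = mz, intensity = intensity)
  out$rel_intensity <- if (max(out$intensity) > 0) 100 * out$intensity / max(out$intensity) else 0
  out[order(out$mz), , drop = FALSE]
}

# ---- internal peak-tree JSON format --------------------------------------

#' Write spectrum trees to the internal peak-tree JSON format
#'
#' Schema: `{run: {polarity, trees: [{repetition, scans: [{id, level,
#' precursor_mz, precursor_id, peaks: [[mz, intensity], ...]}]}]}}`.
#' The round trip through [read_peaktree_json()] is lossless for scan
#' fields and hierarchy.
#'
#' @param trees list of `spectrum_tree` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peaktree_json <- function(trees, path) {
  pol <- if (length(trees)) trees[[1]]$scans[[1]]$polarity else 1L
  doc <- list(run = list(
    polarity = pol,
    trees = lapply(trees, function(tr) {
      list(
        repetition = tr$repetition,
        scans = lapply(names(tr$scans), function(id) {
          s <- tr$scans[[id]]
          rec <- list(id = s$scan_id, level = s$ms_level)
          if (!is.null(s$precursor_mz)) rec$precursor_mz <- s$precursor_mz
          pid <- if (id %in% names(tr$parent)) tr$parent[[id]] else s$precursor_scan_id
          if (!is.null(pid)) rec$precursor_id <- pid
          rec$peaks <- unname(apply(s$peaks[c("mz", "intensity")], 1, as.numeric, simplify = FALSE))
          rec
        })
      )
    })
  ))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read the internal peak-tree JSON format
#'
#' Validates the schema and the hierarchy invariants (acyclic links, level
#' consistency) on read.
#'
#' @param path file written by [write_peaktree_json()].
#' @return a list of `spectrum_tree` objects.
#' @export
read_peaktree_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$run) || is.null(doc$run$trees)) {
    stop("peak-tree JSON: missing $run$trees", call. = FALSE)
  }
  pol <- if (!is.null(doc$run$polarity)) as.integer(doc$run$polarity) else 1L
  lapply(seq_along(doc$run$trees), function(ti) {
    tr <- doc$run$trees[[ti]]
    cur <- list(scans = list(), parent = character(), parent_peak = integer(),
                root_id = NULL,
                repetition = if (!is.null(tr$repetition)) as.integer(tr$repetition) else ti)
    for (sc in tr$scans) {
      for (fld in c("id", "level", "peaks")) {
        if (is.null(sc[[fld]])) {
          stop("peak-tree JSON: scan record missing $", fld, call. = FALSE)
        }
      }
      pk <- if (length(sc$peaks)) {
        m <- do.call(rbind, lapply(sc$peaks, function(p) as.numeric(unlist(p))))
        data.frame(mz = m[, 1], intensity = m[, 2])
      } else data.frame(mz = numeric(), intensity = numeric())
      lvl <- as.integer(sc$level)
      s <- scan(sc$id, lvl, pk, polarity = pol,
                precursor_mz = if (lvl > 1) sc$precursor_mz else NULL,
                precursor_scan_id = if (lvl > 1) sc$precursor_id else NULL)
      cur$scans[[s$scan_id]] <- s
      if (lvl == 1L && is.null(cur$root_id)) cur$root_id <- s$scan_id
      if (lvl > 1L) {
        if (is.null(sc$precursor_id)) {
          stop("peak-tree JSON: MSn scan '", s$scan_id, "' lacks precursor_id", call. = FALSE)
        }
        cur$parent[s$scan_id] <- as.character(sc$precursor_id)
      }
    }
    if (is.null(cur$root_id)) stop("peak-tree JSON: tree without an MS1 scan", call. = FALSE)
    # recover parent_peak indices from precursor m/z
    for (id in names(cur$parent)) {
      p <- cur$scans[[cur$parent[[id]]]]
      if (is.null(p)) stop("peak-tree JSON: unknown precursor_id '", cur$parent[[id]], "'", call. = FALSE)
      d <- abs(p$peaks$mz - cur$scans[[id]]$precursor_mz)
      if (!length(d) || min(d) > 0.5) {
        stop("peak-tree JSON: precursor of scan '", id, "' matches no parent peak", call. = FALSE)
      }
      cur$parent_peak[id] <- which.min(d)
    }
    .finalize_tree(cur)
  })
}
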