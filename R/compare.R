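# Comparison of fragmentation trees: Tanimoto similarity over EFP presence
# sets, occurrence matrices, hierarchical clustering of tree collections,
# and a composite-spectrum dot product as the conventional baseline.

#' Tanimoto coefficient of two EFP sets
#'
#' `|a & b| / (|a| + |b| - |a & b|)`, i.e. intersection over union of the
#' presence sets (intensities are not used). Defined as 0 when both sets
#' are empty.
#'
#' @param a,b character vectors of EFP strings (duplicates ignored).
#' @return a coefficient in `[0, 1]`.
#' @examples
#' tanimoto(c("r", "r||x"), c("r", "r||y")) # 1/3
#' @export
tanimoto <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (!length(a) && !length(b)) return(0)
  ni <- length(intersect(a, b))
  ni / (length(a) + length(b) - ni)
}

#' Partition two EFP sets into characteristic and shared paths
#'
#' @param a,b character vectors of EFP strings.
#' @return list with `only_a`, `only_b`, `shared`; the three parts cover
#'   the union exactly.
#' @export
characteristic_efps <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  list(only_a = setdiff(a, b), only_b = setdiff(b, a), shared = intersect(a, b))
}

#' Binary occurrence matrix over a collection of trees
#'
#' Rows are trees, columns are the union of all EFP strings (lexicographic
#' order), cells are presence 0/1. The column set is the exact union, so no
#' all-zero column exists.
#'
#' @param efp_sets named list of character vectors (names are unique tree
#'   identifiers); `fragmentation_tree` objects are accepted and converted
#'   via [efp_strings()].
#' @return an integer matrix with rownames = tree ids.
#' @export
occurrence_matrix <- function(efp_sets) {
  efp_sets <- lapply(efp_sets, function(x) {
    if (inherits(x, "fragmentation_tree")) efp_strings(x) else unique(as.character(x))
  })
  ids <- names(efp_sets)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("occurrence_matrix() requires a named list of EFP sets", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate tree identifiers", call. = FALSE)
  cols <- sort(unique(unlist(efp_sets, use.names = FALSE)), method = "radix")
  m <- matrix(0L, nrow = length(efp_sets), ncol = length(cols),
              dimnames = list(ids, cols))
  for (i in seq_along(efp_sets)) m[i, efp_sets[[i]]] <- 1L
  m
}

#' Pairwise similarity matrix over EFP sets
#'
#' @inheritParams occurrence_matrix
#' @param metric `"tanimoto"` (the only set metric; see [dot_product()] for
#'   the spectral baseline).
#' @return a symmetric matrix in `[0, 1]` with unit diagonal for non-empty
#'   trees; carries the metric name as attribute `metric`.
#' @export
similarity_matrix <- function(efp_sets, metric = "tanimoto") {
  metric <- match.arg(metric)
  efp_sets <- lapply(efp_sets, function(x) {
    if (inherits(x, "fragmentation_tree")) efp_strings(x) else unique(as.character(x))
  })
  n <- length(efp_sets)
  m <- matrix(0, n, n, dimnames = list(names(efp_sets), names(efp_sets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- tanimoto(efp_sets[[i]], efp_sets[[j]])
    }
  }
  attr(m, "metric") <- metric
  m
}

#' Cluster trees by their EFP occurrence vectors
#'
#' Agglomerative clustering of the presence/absence rows of an occurrence
#' matrix under Euclidean distance. The default linkage is complete
#' (bottom-up, merge height = maximum pairwise distance); `"average"`
#' linkage is available as the alternative. Rows are sorted by label before
#' clustering so that ties break deterministically by label order.
#'
#' @param matrix an [occurrence_matrix()] (or any numeric matrix with row
#'   labels); at least 2 rows.
#' @param linkage `"complete"` (default) or `"average"`.
#' @return an object of class `hclust` (merge history and heights).
#' @export
cluster_trees <- function(matrix, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  if (nrow(matrix) < 2L) stop("clustering requires at least 2 trees", call. = FALSE)
  matrix <- matrix[order(rownames(matrix), method = "radix"), , drop = FALSE]
  stats::hclust(stats::dist(matrix, method = "euclidean"), method = linkage)
}

#' Newick serialization of a dendrogram
#'
#' @param hc an `hclust` object as returned by [cluster_trees()].
#' @return a single Newick string (with branch lengths).
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Dot-product (cosine) similarity of two composite spectra
#'
#' Peaks are aligned greedily by m/z: walking both spectra in m/z order,
#' the closest cross-spectrum pair within `bin_tol_mz` is matched first and
#' each peak is used at most once; unmatched peaks pair with zero. The
#' score is the cosine of the aligned relative-intensity vectors, hence
#' invariant to uniform intensity scaling.
#'
#' @param a,b composite spectra as returned by [composite_spectrum()]
#'   (data.frames with `mz` and `rel_intensity`); non-empty.
#' @param bin_tol_mz alignment window in m/z units, default 0.01.
#' @return a score in `[0, 1]`.
#' @export
dot_product <- function(a, b, bin_tol_mz = 0.01) {
  if (!nrow(a) || !nrow(b)) stop("dot_product() requires non-empty spectra", call. = FALSE)
  ia <- a$rel_intensity
  ib <- b$rel_intensity
  # candidate cross pairs within tolerance, closest first, greedy one-to-one
  d <- abs(outer(a$mz, b$mz, "-"))
  pairs <- which(d <= bin_tol_mz, arr.ind = TRUE)
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  num <- 0
  if (nrow(pairs)) {
    pairs <- pairs[order(d[pairs]), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]
      j <- pairs[k, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- used_b[j] <- TRUE
      num <- num + ia[i] * ib[j]
    }
  }
  num / sqrt(sum(ia^2) * sum(ib^2))
}
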