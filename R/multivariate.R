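# Feature matrices, PCA and hierarchical clustering of digest samples.

#' Residue-level feature matrix (samples x residue positions)
#'
#' Rows are (substrate, time) samples; columns are every mature residue
#' position of every protein supplied, in protein order. Each cell is the
#' summed intensity of all peptides overlapping that residue in that sample,
#' i.e. the matrix is the horizontal concatenation of [profile_matrix()]
#' outputs and the input to the substrate-discriminating PCA.
#'
#' @param observations Mapped observation data frame.
#' @param proteins List of [protein_record()] objects.
#' @param mode Profile mode passed to [profile_matrix()].
#' @return Numeric matrix, rownames `substrate@time`, colnames
#'   `protein_id:position`.
#' @export
residue_feature_matrix <- function(observations, proteins,
                                   mode = "intensity_sum") {
  do.call(cbind, lapply(proteins, function(p) {
    profile_matrix(observations, p, mode = mode)
  }))
}

#' Peptide-level feature matrix with a presence filter
#'
#' Rows are (substrate, time) samples, columns are peptide sequences, cells
#' are summed intensities (0 when absent). A peptide is kept only if present
#' (intensity > 0) in at least `min_presence` distinct time points --
#' counted within each substrate by default (`scope = "substrate"`: the
#' peptide is kept if it passes in either substrate) or over the whole
#' experiment (`scope = "overall"`).
#'
#' @param observations Observation data frame (sequence-resolved; mapping not
#'   required).
#' @param min_presence Minimum number of distinct time points (default 2).
#' @param scope Presence-counting scope, `"substrate"` or `"overall"`.
#' @return Numeric matrix, rownames `substrate@time`, colnames peptide
#'   sequences (sorted).
#' @export
peptide_feature_matrix <- function(observations, min_presence = 2L,
                                   scope = c("substrate", "overall")) {
  scope <- match.arg(scope)
  min_presence <- as.integer(min_presence)
  if (is.na(min_presence) || min_presence < 1L) stop("min_presence must be >= 1")

  if (scope == "overall") {
    pres <- unique(observations[, c("sequence", "time_min")])
    n_times <- table(pres$sequence)
    keep_seq <- names(n_times)[n_times >= min_presence]
  } else {
    pres <- unique(observations[, c("sequence", "substrate", "time_min")])
    n_times <- table(paste(pres$sequence, pres$substrate, sep = "\r"))
    ok <- names(n_times)[n_times >= min_presence]
    keep_seq <- unique(vapply(strsplit(ok, "\r", fixed = TRUE), `[`, "", 1L))
  }
  keep_seq <- sort(keep_seq)
  keys <- sample_row_keys(observations)
  m <- matrix(0, nrow = nrow(keys), ncol = length(keep_seq),
              dimnames = list(paste0(keys$substrate, "@", keys$time_min),
                              keep_seq))
  obs <- observations[observations$sequence %in% keep_seq, , drop = FALSE]
  if (nrow(obs)) {
    rk <- match(paste0(obs$substrate, "@", obs$time_min), rownames(m))
    ck <- match(obs$sequence, keep_seq)
    for (i in seq_len(nrow(obs))) m[rk[i], ck[i]] <- m[rk[i], ck[i]] + obs$intensity[i]
  }
  m
}

#' Principal component analysis of a sample x feature matrix
#'
#' Thin wrapper around a singular value decomposition of the (optionally
#' centered and scaled) matrix, with a fixed sign convention: each loading
#' vector is flipped so its largest-magnitude entry is positive. Defaults are
#' column mean-centering on and unit-variance scaling off, since MS
#' intensities share one meaningful scale across features. Zero-variance
#' columns are dropped with a message when scaling.
#'
#' @param x Numeric matrix (samples in rows) such as
#'   [residue_feature_matrix()] output.
#' @param center Mean-center columns (default `TRUE`).
#' @param scale. Scale columns to unit variance (default `FALSE`).
#' @return A `peptidome_pca`: list with `scores` (samples x components),
#'   `loadings` (features x components), `explained_ratio`, `center`,
#'   `scale`.
#' @export
peptidome_pca <- function(x, center = TRUE, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples (rows)")
  if (scale.) {
    v <- apply(x, 2, stats::var)
    drop <- v == 0
    if (any(drop)) {
      message(sum(drop), " zero-variance column(s) dropped before scaling")
      x <- x[, !drop, drop = FALSE]
    }
  }
  p <- stats::prcomp(x, center = center, scale. = scale.)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  ev <- p$sdev^2
  structure(list(scores = scores, loadings = loadings,
                 explained_ratio = ev / sum(ev),
                 center = center, scale = scale.),
            class = "peptidome_pca")
}

#' @export
print.peptidome_pca <- function(x, ...) {
  k <- min(5L, length(x$explained_ratio))
  cat("<peptidome_pca>", nrow(x$scores), "samples,", nrow(x$loadings),
      "features\n  explained variance:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k),
                     100 * x$explained_ratio[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Agglomerative clustering of digest samples
#'
#' Hierarchically clusters matrix rows. Intensities are log10(1 + x)
#' transformed by default because MS intensities span decades and would
#' otherwise let a handful of abundant features dominate the distances.
#' Defaults (Euclidean distance, Ward linkage) are chosen for robustness;
#' correlation distance and average/complete/single linkage are available.
#' With the correlation metric a zero-variance row would give an undefined
#' correlation; such rows are assigned the maximal distance 2 to every other
#' row.
#'
#' @param x Numeric samples x features matrix.
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage `"ward"` (Ward.D2 on the chosen distance), `"average"`,
#'   `"complete"` or `"single"`.
#' @param log_transform Apply log10(1 + x) first (default `TRUE`).
#' @return A `sample_cluster`: list with the `hclust` object (`merge_tree`),
#'   `leaf_order`, `labels`, `distance_metric`, `linkage_method`.
#' @export
cluster_samples <- function(x, distance = c("euclidean", "correlation"),
                            linkage = c("ward", "average", "complete", "single"),
                            log_transform = TRUE) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("clustering needs at least 2 samples (rows)")
  if (log_transform) x <- log10(1 + x)
  if (distance == "euclidean") {
    d <- stats::dist(x)
  } else {
    cc <- suppressWarnings(stats::cor(t(x)))
    cc[is.na(cc)] <- -1  # zero-variance rows: maximal distance to everything
    diag(cc) <- 1
    d <- stats::as.dist(1 - cc)
  }
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete", single = "single")[[linkage]]
  hc <- stats::hclust(d, method = method)
  structure(list(merge_tree = hc, leaf_order = hc$order,
                 labels = rownames(x), distance_metric = distance,
                 linkage_method = linkage),
            class = "sample_cluster")
}

#' @export
print.sample_cluster <- function(x, ...) {
  cat(sprintf("<sample_cluster> %d samples, %s distance, %s linkage\n",
              length(x$labels), x$distance_metric, x$linkage_method))
  cat("  leaf order:", paste(x$labels[x$leaf_order], collapse = " "), "\n")
  invisible(x)
}

#' Cut a sample dendrogram into k clusters
#' @param x A `sample_cluster` from [cluster_samples()].
#' @param k Number of clusters.
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(x, k) stats::cutree(x$merge_tree, k = k)

#' Export a sample dendrogram as Newick
#'
#' @param x A `sample_cluster`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
as_newick <- function(x, path = NULL) {
  phy <- ape::as.phylo(x$merge_tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
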