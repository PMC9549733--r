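#' Build the motility state space: PCA + Ward clustering + silhouette
#'
#' Features are median-imputed (missing values replaced by the column
#' median, with the imputation count logged), z-scored, and decomposed by
#' PCA. The number of retained components is the smaller of `max_components`
#' and the smallest count whose cumulative explained variance reaches
#' `var_target`. Tracks are clustered by Ward-linkage agglomerative
#' clustering (Euclidean distance on the retained PC scores) cut at `k`
#' clusters. Cluster labels are relabelled so that cluster `k` has the
#' highest mean `total_distance` — i.e. the last cluster is always the
#' motile one, making labels reproducible across seeds and track orders.
#' The silhouette width is computed in the same retained-PC space.
#'
#' @param fm A [feature_table()] data frame (or any data frame with numeric
#'   feature columns plus `track_id` and `condition`).
#' @param var_target Cumulative explained-variance target, default 0.95.
#' @param max_components Cap on retained components, default 30.
#' @param k Number of clusters, default 2.
#' @return An object of class `"statespace_result"`: list with
#'   `kept_components`, `explained_variance` (all PCs), `pc_scores`
#'   (retained), `cluster_labels`, `silhouette` (mean width),
#'   `silhouette_widths`, `track_id`, `condition`, `n_imputed`,
#'   `dropped_constant` (names of zero-variance features).
#' @export
reduce_and_cluster <- function(fm, var_target = 0.95, max_components = 30L,
                               k = 2L) {
  X <- as.matrix(fm[, feature_columns(fm), drop = FALSE])
  n <- nrow(X)
  if (n < k + 1L) stop("need at least k+1 tracks")
  n_imputed <- sum(is.na(X))
  X <- apply(X, 2L, function(col) {
    col[is.na(col)] <- stats::median(col, na.rm = TRUE)
    col
  })
  sds <- apply(X, 2L, stats::sd)
  constant <- colnames(X)[sds == 0 | is.na(sds)]
  X <- X[, !(colnames(X) %in% constant), drop = FALSE]
  if (ncol(X) < 2L) stop("fewer than 2 features with nonzero variance")
  Z <- scale(X)
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  cum <- cumsum(ev)
  kept <- min(as.integer(max_components),
              which(cum >= var_target)[1L],
              length(ev), na.rm = TRUE)
  scores <- pca$x[, seq_len(kept), drop = FALSE]
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  labels <- relabel_by_total_distance(labels, fm$total_distance, k)
  sil <- cluster::silhouette(labels, stats::dist(scores))
  structure(list(kept_components = kept, explained_variance = ev,
                 pc_scores = scores, cluster_labels = labels,
                 silhouette = mean(sil[, "sil_width"]),
                 silhouette_widths = sil[, "sil_width"],
                 track_id = fm$track_id, condition = fm$condition,
                 n_imputed = n_imputed, dropped_constant = constant),
            class = "statespace_result")
}

# Relabel clusters by ascending mean total_distance, so cluster k is the
# most motile. Falls back to first-appearance order without total_distance.
relabel_by_total_distance <- function(labels, total_distance, k) {
  if (is.null(total_distance)) return(labels)
  means <- tapply(total_distance, labels, mean, na.rm = TRUE)
  ord <- order(means)
  remap <- stats::setNames(seq_len(k), names(means)[ord])
  unname(remap[as.character(labels)])
}

#' @export
print.statespace_result <- function(x, ...) {
  cat(sprintf(
    "<statespace_result> %d tracks, %d PCs kept (%.1f%% var), k = %d, silhouette %.3f\n",
    length(x$cluster_labels), x$kept_components,
    100 * sum(x$explained_variance[seq_len(x$kept_components)]),
    length(unique(x$cluster_labels)), x$silhouette))
  invisible(x)
}

#' t-SNE embedding of the retained PC scores
#'
#' Two-dimensional t-SNE for visualisation only; clustering never uses the
#' embedding. Deterministic given `seed`.
#'
#' @param scores Numeric matrix of PC scores (tracks x components).
#' @param perplexity t-SNE perplexity; must satisfy
#'   `perplexity < (n - 1) / 3`. Default 35.
#' @param seed Integer seed.
#' @return n x 2 embedding matrix.
#' @export
tsne_embed <- function(scores, perplexity = 35, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity ", perplexity, " too large for n = ", n,
         " (needs perplexity < (n-1)/3)")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  emb <- Rtsne::Rtsne(scores, dims = 2L, perplexity = perplexity,
                      pca = FALSE, check_duplicates = FALSE)$Y
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  colnames(emb) <- c("tsne1", "tsne2")
  emb
}

#' Chi-squared test of condition-by-cluster proportions
#'
#' Pearson chi-squared test (no continuity correction) on the condition x
#' cluster contingency table, with `df = (r - 1)(c - 1)`. Per-condition
#' cluster proportions are reported alongside.
#'
#' @param labels Cluster labels per track.
#' @param conditions Condition labels per track.
#' @return List with `contingency`, `chi2`, `df`, `p`, `proportions`
#'   (per-condition row proportions).
#' @export
condition_cluster_test <- function(labels, conditions) {
  if (length(labels) != length(conditions))
    stop("labels and conditions differ in length")
  tab <- table(condition = conditions, cluster = labels)
  if (nrow(tab) < 2L) stop("need at least 2 conditions")
  if (ncol(tab) < 2L) stop("need at least 2 clusters")
  if (any(rowSums(tab) == 0))
    stop("condition '", rownames(tab)[rowSums(tab) == 0][1L],
         "' has zero tracks (empty margin)")
  if (any(colSums(tab) == 0))
    stop("cluster '", colnames(tab)[colSums(tab) == 0][1L],
         "' is empty (empty margin)")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(contingency = tab, chi2 = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value,
       proportions = prop.table(tab, margin = 1L))
}

#' Min-max normalised feature means per group
#'
#' Each feature is min-max scaled to \[0, 1\] across all tracks, then
#' averaged within each group (condition or cluster), with the standard
#' error of the mean. A constant feature scales to 0 everywhere and is
#' recorded in the `constant_features` attribute.
#'
#' @param fm A [feature_table()] data frame.
#' @param groups Group label per track.
#' @return Long data frame `feature, group, mean, sem, n`.
#' @export
normalized_feature_means <- function(fm, groups) {
  if (!length(groups)) stop("need at least 1 group label")
  if (length(groups) != nrow(fm))
    stop("groups must have one label per track")
  feats <- feature_columns(fm)
  constant <- character(0)
  out <- list()
  for (f in feats) {
    v <- fm[[f]]
    rng <- range(v, na.rm = TRUE)
    if (!all(is.finite(rng))) next
    if (diff(rng) == 0) {
      scaled <- rep(0, length(v))
      constant <- c(constant, f)
    } else {
      scaled <- (v - rng[1L]) / diff(rng)
    }
    agg <- tapply(scaled, groups, function(x) {
      x <- x[!is.na(x)]
      c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
        n = length(x))
    })
    out[[f]] <- data.frame(feature = f, group = names(agg),
                           mean = vapply(agg, `[[`, numeric(1), "mean"),
                           sem = vapply(agg, `[[`, numeric(1), "sem"),
                           n = vapply(agg, `[[`, numeric(1), "n"),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(constant))
    message("constant feature(s) scaled to 0: ",
            paste(constant, collapse = ", "))
  attr(res, "constant_features") <- constant
  res
}

#' One-dimensional Ward clustering of a single feature
#'
#' Hierarchical (Ward) clustering of tracks on one standardised feature —
#' used for total distance travelled in 3D tissue scenes, where the full
#' battery is not computed. Clusters are ordered by ascending mean, so
#' cluster `k` is the most motile.
#'
#' @param values Numeric vector (one value per track), not all identical.
#' @param k Number of clusters, default 2.
#' @return List with `labels`, `means` (per-cluster means of the original
#'   values) and `silhouette`.
#' @export
cluster_1d <- function(values, k = 2L) {
  if (length(values) < k) stop("need at least k values")
  if (anyNA(values)) stop("values contain NA")
  if (stats::sd(values) == 0) stop("all values identical; nothing to cluster")
  z <- as.matrix(scale(values))
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  labels <- relabel_by_total_distance(labels, values, k)
  # all-singleton partitions have silhouette 0 by convention
  sil <- if (length(values) > k)
    mean(cluster::silhouette(labels, stats::dist(z))[, "sil_width"])
  else 0
  list(labels = labels,
       means = tapply(values, labels, mean),
       silhouette = sil)
}
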