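#' Cluster cells on a feature matrix
#'
#' Runs a standard clustering backend on the columns (cells) of a
#' features-by-cells matrix. Backends: k-means (`stats::kmeans`,
#' `nstart = 10`), hierarchical (Ward linkage on Euclidean distances,
#' `ward.D2`, cut at `k`), spectral (`kernlab::specc`, requires the
#' kernlab package). All are deterministic under a fixed `seed`.
#'
#' @param x Numeric features-by-cells matrix, or a `delta_rank_matrix`
#'   (normalized layer).
#' @param method `"kmeans"`, `"hierarchical"` or `"spectral"`.
#' @param k Number of clusters (<= number of cells).
#' @param seed Integer seed (default 1).
#' @return Named integer vector of cluster labels in 1..k, named by cell
#'   ID.
#' @export
cluster_cells <- function(x, method = c("kmeans", "hierarchical", "spectral"),
                          k, seed = 1) {
  method <- match.arg(method)
  if (inherits(x, "delta_rank_matrix")) x <- drm_layer(x, "normalized")
  if (any(!is.finite(x))) stop_validation("feature matrix must be finite")
  n <- ncol(x)
  if (k > n) stop_validation(sprintf("k = %d exceeds the %d cells", k, n))
  if (k < 1L) stop_validation("k must be >= 1")
  obs <- t(x)
  labels <- switch(method,
    kmeans = with_seed(seed, kmeans(obs, centers = k, nstart = 10L,
                                    iter.max = 100L)$cluster),
    hierarchical = cutree(hclust(dist(obs), method = "ward.D2"), k = k),
    spectral = {
      if (!requireNamespace("kernlab", quietly = TRUE))
        stop_validation("the spectral backend requires the 'kernlab' package")
      with_seed(seed, as.integer(kernlab::specc(obs, centers = k)))
    }
  )
  labels <- as.integer(labels)
  names(labels) <- colnames(x)
  labels
}

check_partitions <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop_validation("partitions cover different numbers of cells")
  if (!is.null(names(truth)) && !is.null(names(pred))) {
    if (!setequal(names(truth), names(pred)))
      stop_validation("partitions cover different cell sets")
    pred <- pred[names(truth)]
  }
  list(truth = as.character(truth), pred = as.character(pred))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions of the same cells,
#' corrected for chance; 1 for identical partitions, approximately 0 for
#' independent ones, negative for worse-than-chance agreement.
#'
#' @param truth,pred Label vectors over the same cells (aligned by name
#'   when both are named).
#' @return A number in \[-1, 1\].
#' @export
ari <- function(truth, pred) {
  z <- check_partitions(truth, pred)
  ct <- table(z$truth, z$pred)
  sum_ij <- sum(choose(ct, 2))
  a <- sum(choose(rowSums(ct), 2))
  b <- sum(choose(colSums(ct), 2))
  n <- length(z$truth)
  expected <- a * b / choose(n, 2)
  maximum <- (a + b) / 2
  if (maximum == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

#' Normalized mutual information
#'
#' Mutual information between two partitions normalized by the
#' arithmetic mean of their label entropies, NMI = 2 I(T;P) /
#' (H(T) + H(P)). When both partitions are trivial (single cluster),
#' both entropies are zero and NMI is defined as 1.
#'
#' @inheritParams ari
#' @return A number in \[0, 1\].
#' @export
nmi <- function(truth, pred) {
  z <- check_partitions(truth, pred)
  n <- length(z$truth)
  joint <- table(z$truth, z$pred) / n
  pt_ <- rowSums(joint); pp <- colSums(joint)
  ht <- -sum(ifelse(pt_ > 0, pt_ * log(pt_), 0))
  hp <- -sum(ifelse(pp > 0, pp * log(pp), 0))
  if (ht + hp == 0) return(1)
  outer_p <- outer(pt_, pp)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer_p[nz]))
  max(0, min(1, 2 * mi / (ht + hp)))
}

#' Cluster purity
#'
#' Fraction of cells assigned to the majority true class of their
#' predicted cluster. Inflated by fine partitions (all singletons give
#' purity 1), so it is reported alongside ARI and NMI, never alone.
#'
#' @inheritParams ari
#' @return A number in \[0, 1\].
#' @export
purity <- function(truth, pred) {
  z <- check_partitions(truth, pred)
  ct <- table(z$pred, z$truth)
  sum(apply(ct, 1L, max)) / length(z$truth)
}

#' Score a predicted partition against the truth
#'
#' @inheritParams ari
#' @return List with elements `ari`, `nmi`, `purity`.
#' @export
score_partition <- function(truth, pred) {
  list(ari = ari(truth, pred), nmi = nmi(truth, pred),
       purity = purity(truth, pred))
}
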