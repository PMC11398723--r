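# Eta-squared similarity of limbic whole-brain connectivity profiles and
# Ward agglomerative clustering (error-sum-of-squares merges) with explicit
# dendrogram cuts and height-gap diagnostics.

#' Eta-squared similarity of two connectivity profiles
#'
#' `eta2 = 1 - sum[(a_p - m_p)^2 + (b_p - m_p)^2] /
#'             sum[(a_p - M)^2 + (b_p - M)^2]`,
#' with `m_p` the pointwise mean of the two profiles and `M` their grand
#' mean: the fraction of total variance about the grand mean that the two
#' profiles share. 1 for identical profiles; 0 when all shared variance is
#' pointwise-opposed.
#'
#' @param map_a,map_b Equal-length numeric profiles (length >= 2).
#' @return Scalar in `[0, 1]`.
#' @examples
#' eta_squared(c(1, 2, 3), c(3, 2, 1))  # 0
#' @export
eta_squared <- function(map_a, map_b) {
  if (length(map_a) != length(map_b)) stop("profiles differ in length")
  if (length(map_a) < 2) stop("profiles must have length >= 2")
  M <- mean(c(map_a, map_b))
  denom <- sum((map_a - M)^2 + (map_b - M)^2)
  if (denom == 0) stop("both profiles constant: eta-squared undefined")
  m <- (map_a + map_b) / 2
  1 - sum((map_a - m)^2 + (map_b - m)^2) / denom
}

#' Eta-squared similarity matrix over a parcel subset
#'
#' Pairwise eta-squared between the whole-brain connectivity rows of the
#' selected (limbic) parcels. Self-connection columns are retained in the
#' profiles (stored as zero by the diagonal convention). Given a list of
#' subject matrices, per-subject similarity matrices are averaged into the
#' group matrix.
#'
#' @param rsfc An `rsfc_matrix` or a list of them.
#' @param subset_parcels Indices of the parcels (rows) to compare; nonempty.
#' @return A `similarity_matrix`: `eta2` (L x L, symmetric, unit diagonal),
#'   `subset_parcels`, `subject_id`.
#' @export
similarity_matrix <- function(rsfc, subset_parcels) {
  if (!length(subset_parcels)) stop("subset is empty")
  if (is.list(rsfc) && !inherits(rsfc, "rsfc_matrix")) {
    mats <- lapply(rsfc, similarity_matrix, subset_parcels = subset_parcels)
    eta <- Reduce(`+`, lapply(mats, `[[`, "eta2")) / length(mats)
    return(structure(list(eta2 = eta, subset_parcels = subset_parcels,
                          subject_id = "group"),
                     class = "similarity_matrix"))
  }
  stopifnot(inherits(rsfc, "rsfc_matrix"))
  if (any(subset_parcels > nrow(rsfc$z)) || any(subset_parcels < 1)) {
    stop("subset parcel missing from matrix")
  }
  rows <- rsfc$z[subset_parcels, , drop = FALSE]
  L <- nrow(rows)
  eta <- diag(1, L)
  if (L > 1) {
    for (i in seq_len(L - 1)) {
      for (j in seq(i + 1, L)) {
        eta[i, j] <- eta[j, i] <- eta_squared(rows[i, ], rows[j, ])
      }
    }
  }
  structure(list(eta2 = eta, subset_parcels = subset_parcels,
                 subject_id = rsfc$subject_id),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Eta-squared similarity (", x$subject_id, "): ",
      nrow(x$eta2), " x ", ncol(x$eta2), " parcels\n", sep = "")
  invisible(x)
}

#' Ward agglomerative clustering of similarity profiles
#'
#' The feature vector of each parcel is its row of the similarity matrix
#' (its similarity to every other parcel in the subset). Merges follow
#' Ward's error-sum-of-squares criterion via Lance-Williams updates
#' (`stats::hclust`, method `ward.D`, on squared Euclidean distances);
#' reported merge heights are the ESS increase of each merge (half the
#' Lance-Williams height) and are nondecreasing.
#'
#' @param sim A `similarity_matrix`, or a plain numeric matrix whose rows are
#'   feature vectors.
#' @return A `cluster_solution`: `merges` (data frame `child_a`, `child_b`,
#'   `height`; negative ids are singletons, positive ids earlier merges),
#'   `hclust`, `n`.
#' @export
ward_cluster <- function(sim) {
  feats <- if (inherits(sim, "similarity_matrix")) sim$eta2 else as.matrix(sim)
  if (anyNA(feats)) stop("NaN in similarity matrix")
  if (nrow(feats) < 2) stop("need at least 2 parcels to cluster")
  hc <- stats::hclust(stats::dist(feats)^2, method = "ward.D")
  hc$height <- hc$height / 2   # ESS increase per merge
  merges <- data.frame(child_a = hc$merge[, 1], child_b = hc$merge[, 2],
                       height = hc$height)
  structure(list(merges = merges, hclust = hc, n = nrow(feats)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("Ward cluster solution over", x$n, "parcels;",
      nrow(x$merges), "merges, total ESS =",
      round(sum(x$merges$height), 4), "\n")
  invisible(x)
}

#' @export
plot.cluster_solution <- function(x, ...) {
  plot(x$hclust, xlab = "parcel", sub = "",
       main = "Ward dendrogram (heights = ESS increase)", ...)
  invisible(x)
}

#' Cut the Ward dendrogram at k clusters
#'
#' Returns the cluster labels at `k` clusters, plus the merge-height gap at
#' every candidate k (attribute `height_gaps`) to support choosing k
#' explicitly: `gap(k)` is the height of the first merge undone by the
#' k-cluster cut minus the height of the last merge kept. A large gap at k
#' marks k well-separated clusters.
#'
#' @param solution A [ward_cluster()] solution.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer labels (1..k), with a `height_gaps` data frame attribute.
#' @export
cut_dendrogram <- function(solution, k) {
  stopifnot(inherits(solution, "cluster_solution"))
  n <- solution$n
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  labels <- if (k == n) seq_len(n) else
    as.integer(stats::cutree(solution$hclust, k = k))
  h <- c(0, solution$merges$height)    # h[1] = 0 floor for k = n
  ks <- seq(2, n)
  gaps <- data.frame(
    k = ks,
    gap = h[n - ks + 2] - h[n - ks + 1]
  )
  attr(labels, "height_gaps") <- gaps
  labels
}

#' Per-cluster mean connectivity maps
#'
#' For each subject and cluster, the mean whole-brain z row over the
#' cluster's member parcels; the inputs to mass-univariate map statistics.
#'
#' @param rsfc List of subject `rsfc_matrix` objects.
#' @param labels Cluster labels over `subset_parcels`.
#' @param subset_parcels Parcel indices the labels refer to.
#' @return Named list, one subject x parcel matrix per cluster.
#' @export
cluster_mean_maps <- function(rsfc, labels, subset_parcels) {
  if (length(labels) != length(subset_parcels)) {
    stop("labels must cover the parcel subset")
  }
  if (!all(table(labels) >= 1) || length(unique(labels)) < 1) {
    stop("empty cluster")
  }
  clusters <- sort(unique(labels))
  out <- lapply(clusters, function(cl) {
    members <- subset_parcels[labels == cl]
    rows <- t(vapply(rsfc, function(m) {
      colMeans(m$z[members, , drop = FALSE])
    }, numeric(ncol(rsfc[[1]]$z))))
    rownames(rows) <- vapply(rsfc, `[[`, character(1), "subject_id")
    rows
  })
  names(out) <- paste0("cluster", clusters)
  out
}
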