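# Mass-univariate one-sample and paired t maps on RSFC rows, Bonferroni and
# absolute-top-fraction thresholding, and network-wise / subcortical profiles.

#' Mass-univariate one-sample t map
#'
#' Per parcel: `t = mean / (sd / sqrt(n))`, two-sided p from the t
#' distribution with `n - 1` df. Zero-variance parcels are flagged undefined
#' and excluded from the masks (their t is 0 when the mean is also 0, NA
#' otherwise). Bonferroni and absolute-top-fraction masks are attached using
#' the supplied constants.
#'
#' @param rows Subject x parcel matrix of z values (>= 3 subjects, no NaN).
#' @param mu Null value (default 0).
#' @param alpha Significance level for the Bonferroni mask.
#' @param n_comparisons Correction denominator; defaults to the parcel count
#'   (set 1032 to match a full-scale parcellation).
#' @param top_fraction Fraction for the absolute-top mask.
#' @param contrast Description string carried along.
#' @return A `stat_map` data frame: `parcel`, `t`, `p`, `undefined`,
#'   `mask_bonf`, `mask_top`, with `df_t` and `contrast` attributes.
#' @export
one_sample_map <- function(rows, mu = 0, alpha = 0.01,
                           n_comparisons = ncol(rows), top_fraction = 0.10,
                           contrast = "one-sample") {
  rows <- as.matrix(rows)
  n <- nrow(rows)
  if (n < 3) stop("need at least 3 subjects")
  if (anyNA(rows)) stop("NaN in input rows")
  mean_p <- colMeans(rows) - mu
  sd_p <- apply(rows, 2, stats::sd)
  undefined <- sd_p == 0
  t_val <- ifelse(undefined, ifelse(mean_p == 0, 0, NA_real_),
                  mean_p / (sd_p / sqrt(n)))
  p_val <- ifelse(is.na(t_val) | undefined, NA_real_,
                  2 * stats::pt(-abs(t_val), df = n - 1))
  mask_bonf <- bonferroni_mask(p_val, alpha, n_comparisons)
  mask_top <- top_fraction_mask(ifelse(undefined, NA, t_val), top_fraction)
  out <- data.frame(parcel = seq_len(ncol(rows)), t = t_val, p = p_val,
                    undefined = undefined, mask_bonf = mask_bonf,
                    mask_top = mask_top)
  attr(out, "df_t") <- n - 1
  attr(out, "contrast") <- contrast
  class(out) <- c("stat_map", "data.frame")
  out
}

#' Mass-univariate paired-sample t map
#'
#' One-sample t map on per-subject differences `rows_a - rows_b`; subjects
#' must match in number and order. Identical inputs yield t = 0 everywhere
#' (flagged undefined, hence excluded from masks).
#'
#' @param rows_a,rows_b Subject x parcel matrices, same subjects in the same
#'   order.
#' @inheritParams one_sample_map
#' @return A `stat_map` (see [one_sample_map()]).
#' @export
paired_contrast_map <- function(rows_a, rows_b, alpha = 0.01,
                                n_comparisons = ncol(rows_a),
                                top_fraction = 0.10,
                                contrast = "paired") {
  rows_a <- as.matrix(rows_a); rows_b <- as.matrix(rows_b)
  if (!all(dim(rows_a) == dim(rows_b))) stop("subject/parcel mismatch")
  if (!is.null(rownames(rows_a)) && !is.null(rownames(rows_b)) &&
      !identical(rownames(rows_a), rownames(rows_b))) {
    stop("subject order mismatch")
  }
  one_sample_map(rows_a - rows_b, mu = 0, alpha = alpha,
                 n_comparisons = n_comparisons, top_fraction = top_fraction,
                 contrast = contrast)
}

#' Bonferroni mask
#'
#' `mask = { p < alpha / n_comparisons }`; exactly the brute-force set
#' comprehension. NA p values (undefined parcels) are never selected.
#'
#' @param p Per-parcel two-sided p values in `[0, 1]` (NA allowed).
#' @param alpha Family-wise level, in (0, 1).
#' @param n_comparisons Correction denominator (e.g. 1032 at full scale).
#' @return Logical mask.
#' @export
bonferroni_mask <- function(p, alpha = 0.01, n_comparisons = length(p)) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  mask <- rep(FALSE, length(p))
  mask[ok] <- p[ok] < alpha / n_comparisons
  mask
}

#' Absolute top-fraction mask
#'
#' Retains the `round_half_away(fraction * n)` parcels with largest absolute
#' value; ties at the cutoff are broken by parcel id (lower id wins), so the
#' mask is deterministic. NA values are never selected and do not count
#' toward n.
#'
#' @param values Per-parcel values (NA allowed).
#' @param fraction Fraction to retain, in (0, 1].
#' @return Logical mask with exactly `round_half_away(fraction * n_non_NA)`
#'   TRUE entries.
#' @export
top_fraction_mask <- function(values, fraction = 0.10) {
  if (!length(values)) stop("empty input")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ok <- which(!is.na(values))
  m <- round_half_away(fraction * length(ok))
  mask <- rep(FALSE, length(values))
  if (m > 0) {
    ord <- ok[order(-abs(values[ok]), ok)]
    mask[ord[seq_len(min(m, length(ord)))]] <- TRUE
  }
  mask
}

# round half away from zero (round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Network-wise and subcortical profile of a connectivity row
#'
#' Mean z per 17-network label and per subcortical structure; every parcel
#' contributes to exactly one entry.
#'
#' @param row Per-parcel z values (one connectivity map).
#' @param atlas A [make_atlas()] atlas covering the parcels.
#' @return Named numeric vector over the 17 + 7 labels present in the atlas.
#' @export
network_profile <- function(row, atlas) {
  stopifnot(inherits(atlas, "toy_atlas"))
  if (length(row) != nrow(atlas)) stop("row length must equal parcel count")
  labels <- c(CORTICAL_NETWORKS, SUBCORTICAL_STRUCTURES)
  present <- labels[labels %in% atlas$network_label]
  if (!setequal(present, labels)) {
    stop("network(s) with zero parcels: ",
         paste(setdiff(labels, present), collapse = ", "))
  }
  vapply(labels, function(lab) {
    mean(row[atlas$network_label == lab])
  }, numeric(1))
}

#' Network-wise paired contrast between two sets of subject maps
#'
#' Collapses each subject's map to its network profile, then runs a paired t
#' test per network label (spider-plot style contrasts).
#'
#' @param rows_a,rows_b Subject x parcel matrices (same subjects, same
#'   order).
#' @param atlas A [make_atlas()] atlas.
#' @param alpha Significance level (Bonferroni over the label count).
#' @return Data frame: `label`, `mean_a`, `mean_b`, `t`, `p`, `significant`.
#' @export
profile_contrast <- function(rows_a, rows_b, atlas, alpha = 0.01) {
  prof_a <- t(apply(rows_a, 1, network_profile, atlas = atlas))
  prof_b <- t(apply(rows_b, 1, network_profile, atlas = atlas))
  d <- prof_a - prof_b
  n <- nrow(d)
  t_val <- colMeans(d) / (apply(d, 2, stats::sd) / sqrt(n))
  p_val <- 2 * stats::pt(-abs(t_val), df = n - 1)
  data.frame(label = colnames(prof_a),
             mean_a = colMeans(prof_a), mean_b = colMeans(prof_b),
             t = t_val, p = p_val,
             significant = p_val < alpha / ncol(prof_a),
             row.names = NULL)
}
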