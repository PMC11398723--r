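# Parcel-wise MEFC connectivity: product-moment correlation of BOLD
# component coefficients across parcels, df-adjusted Fisher z, group mean.

#' Fisher z adjusted for MEFC degrees of freedom
#'
#' `Z = arctanh(R) * sqrt(df - 3)`: the r-to-z transform scaled by the
#' variance-stabilising factor, so subjects with more retained BOLD
#' components (larger df) contribute proportionally larger z for the same R.
#'
#' @param R Correlation value(s), in `[-1, 1]`.
#' @param df Degrees of freedom (number of BOLD components), `> 3`.
#' @return Numeric z value(s).
#' @examples
#' fisher_z(0.5, 103)  # atanh(0.5) * 10
#' @export
fisher_z <- function(R, df) {
  if (any(df <= 3)) stop("df must exceed 3 (z needs df - 3 > 0)")
  R <- pmin(pmax(R, -(1 - 1e-12)), 1 - 1e-12)
  atanh(R) * sqrt(df - 3)
}

#' Average region-level coefficients into parcels
#'
#' Mean coefficient over the regions belonging to each atlas parcel; the
#' identity when the data are already parcel-level (one region per parcel).
#' No smoothing is applied.
#'
#' @param mefc An [build_mefc()] object (or a plain region x component
#'   matrix).
#' @param atlas A [make_atlas()] atlas.
#' @param region_parcel Integer vector mapping each coefficient row to a
#'   parcel id; default `atlas$parcel_id` (parcel-level data).
#' @return Parcel x component matrix, rows ordered by `atlas$parcel_id`.
#' @export
parcellate_coefficients <- function(mefc, atlas,
                                    region_parcel = atlas$parcel_id) {
  coeffs <- if (inherits(mefc, "mefc")) mefc$coeffs else as.matrix(mefc)
  if (length(region_parcel) != nrow(coeffs)) {
    stop("region_parcel must map every coefficient row")
  }
  empty <- setdiff(atlas$parcel_id, region_parcel)
  if (length(empty)) {
    stop("empty parcel(s): ", paste(empty, collapse = ", "))
  }
  out <- rowsum(coeffs, group = region_parcel, reorder = TRUE) /
    as.vector(table(factor(region_parcel, levels = sort(unique(region_parcel)))))
  out[match(atlas$parcel_id, sort(unique(region_parcel))), , drop = FALSE]
}

#' RSFC matrix from MEFC coefficients
#'
#' Product-moment correlation over the component dimension for every parcel
#' pair, then the df-adjusted Fisher z. The diagonal (self-connection) is
#' excluded by convention: stored as 0 and flagged, and ignored by all
#' downstream statistics.
#'
#' @param coeffs Parcel x component coefficient matrix.
#' @param df Number of BOLD components; must be at least 4.
#' @param subject_id Subject identifier.
#' @return An `rsfc_matrix`: `z` (parcel x parcel, symmetric, zero diagonal),
#'   `r` (raw correlations), `df`, `subject_id`.
#' @export
rsfc_from_mefc <- function(coeffs, df = ncol(coeffs),
                           subject_id = NA_character_) {
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) < 2) stop("need at least 2 parcels")
  if (df <= 3) stop("df must exceed 3 (z needs df - 3 > 0)")
  sds <- apply(coeffs, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance parcel row(s): ",
         paste(which(sds == 0), collapse = ", "))
  }
  R <- stats::cor(t(coeffs))
  Z <- fisher_z(R, df)
  diag(Z) <- 0
  diag(R) <- 1
  structure(list(z = Z, r = R, df = df, subject_id = subject_id,
                 diag_excluded = TRUE),
            class = "rsfc_matrix")
}

#' @export
print.rsfc_matrix <- function(x, ...) {
  cat("RSFC matrix (", x$subject_id, "): ", nrow(x$z), " x ", ncol(x$z),
      if (!is.null(x$df) && !is.na(x$df)) paste0(", df = ", x$df), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.rsfc_matrix <- function(x, ...) {
  z <- x$z
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z[, rev(seq_len(ncol(z)))],
                  xlab = "parcel", ylab = "parcel",
                  main = paste("RSFC z,", x$subject_id), ...)
  invisible(x)
}

#' Group-mean RSFC matrix
#'
#' Elementwise mean of the subject z matrices; parcel order must agree.
#'
#' @param matrices List of `rsfc_matrix` objects (>= 2 subjects).
#' @return An `rsfc_matrix` with `subject_id = "group"` and `df = NA`.
#' @export
group_mean_matrix <- function(matrices) {
  if (length(matrices) < 2) stop("need at least 2 subjects")
  dims <- vapply(matrices, function(m) nrow(m$z), integer(1))
  if (length(unique(dims)) != 1) stop("parcel-order (dimension) mismatch")
  zs <- lapply(matrices, `[[`, "z")
  Z <- Reduce(`+`, zs) / length(zs)
  structure(list(z = Z, r = NULL, df = NA_integer_, subject_id = "group",
                 diag_excluded = TRUE),
            class = "rsfc_matrix")
}
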