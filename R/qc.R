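# Subject-level quality metrics (framewise displacement, DVARS, TSNR,
# retained-component count) and the four exclusion rules.

#' Framewise displacement (Power convention)
#'
#' `FD_t = sum |delta translation| + 50 mm * sum |delta rotation|`, the
#' rotational terms converted to displacement on a 50 mm sphere. Rotations
#' must be in radians.
#'
#' @param motion Time x 6 matrix: 3 translations (mm), 3 rotations (rad).
#' @param radius Sphere radius, mm.
#' @return Numeric FD series of length `nrow(motion) - 1`.
#' @export
framewise_displacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns (3 trans, 3 rot)")
  if (nrow(motion) < 2) stop("need at least 2 frames")
  d <- abs(diff(motion))
  rowSums(d[, 1:3, drop = FALSE]) + radius * rowSums(d[, 4:6, drop = FALSE])
}

#' Median-standardised DVARS
#'
#' Root-mean-square over regions of the frame-to-frame signal difference,
#' divided by its own run median, so a typical frame has DVARS near 1 and
#' the value is invariant to the overall signal scale.
#'
#' @param series Region x time matrix.
#' @return Numeric DVARS series of length `ncol(series) - 1`.
#' @export
dvars <- function(series) {
  series <- as.matrix(series)
  if (ncol(series) < 2) stop("need at least 2 frames")
  d <- sqrt(colMeans((series[, -1, drop = FALSE] -
                        series[, -ncol(series), drop = FALSE])^2))
  md <- stats::median(d)
  if (md == 0) stop("zero-variance run: DVARS undefined")
  d / md
}

#' Assemble a subject QC record
#'
#' Computes FD from the motion parameters and DVARS plus median TSNR from the
#' denoised (BOLD back-projected) series, per the convention that quality
#' assessments are performed on the reconstructed time series.
#'
#' @param run A `multi_echo_run`.
#' @param denoised Region x time denoised series (see
#'   [reconstruct_denoised()]).
#' @param n_bold_components Retained BOLD component count.
#' @param coreg_fail Externally supplied coregistration-failure flag.
#' @return A `qc_record` list.
#' @export
qc_record <- function(run, denoised, n_bold_components, coreg_fail = FALSE) {
  stopifnot(inherits(run, "multi_echo_run"))
  fd <- framewise_displacement(run$motion)
  dv <- dvars(denoised)
  tsnr <- compute_tsnr(denoised)
  structure(list(
    subject_id = run$subject_id,
    fd_series = fd, max_fd = max(fd),
    dvars_series = dv,
    median_tsnr = stats::median(tsnr$tsnr, na.rm = TRUE),
    n_bold_components = as.integer(n_bold_components),
    coreg_fail = isTRUE(coreg_fail)
  ), class = "qc_record")
}

#' @export
print.qc_record <- function(x, ...) {
  cat(sprintf("QC %s: max FD %.3f mm, median TSNR %.1f, %d BOLD components\n",
              x$subject_id, x$max_fd, x$median_tsnr, x$n_bold_components))
  invisible(x)
}

#' Apply the subject exclusion rules
#'
#' A subject is excluded iff any frame shows framewise displacement above
#' `fd_thresh` AND (conjunctively) DVARS above `dvars_thresh` at the same
#' frame, OR median TSNR is below `tsnr_thresh`, OR fewer than
#' `min_components` BOLD components were retained, OR coregistration failed.
#' The FD/DVARS conjunction can alternatively be evaluated run-wise
#' (`conjunction = "run"`: any high-FD frame and any high-DVARS frame,
#' not necessarily the same one).
#'
#' @param records List of [qc_record()] objects.
#' @param fd_thresh,dvars_thresh,tsnr_thresh,min_components Rule thresholds;
#'   defaults 0.50 mm, 1, 50, 10.
#' @param conjunction `"frame"` (default) or `"run"`.
#' @return A data frame with one row per subject: `subject_id`, metric
#'   summaries, `excluded`, and comma-separated `reasons`.
#' @export
apply_exclusions <- function(records, fd_thresh = 0.50, dvars_thresh = 1,
                             tsnr_thresh = 50, min_components = 10L,
                             conjunction = c("frame", "run")) {
  conjunction <- match.arg(conjunction)
  rows <- lapply(records, function(r) {
    if (!inherits(r, "qc_record")) stop("records must be qc_record objects")
    need <- c("fd_series", "dvars_series", "median_tsnr", "n_bold_components")
    miss <- need[vapply(need, function(f) is.null(r[[f]]) || anyNA(r[[f]]),
                        logical(1))]
    if (length(miss)) {
      stop("subject ", r$subject_id, ": missing metric(s) ",
           paste(miss, collapse = ", "))
    }
    if (length(r$fd_series) != length(r$dvars_series)) {
      stop("subject ", r$subject_id, ": FD and DVARS series lengths differ")
    }
    fd_dvars <- if (conjunction == "frame") {
      any(r$fd_series > fd_thresh & r$dvars_series > dvars_thresh)
    } else {
      any(r$fd_series > fd_thresh) && any(r$dvars_series > dvars_thresh)
    }
    reasons <- c(
      if (fd_dvars) "fd_dvars",
      if (r$median_tsnr < tsnr_thresh) "low_tsnr",
      if (r$n_bold_components < min_components) "few_components",
      if (isTRUE(r$coreg_fail)) "coreg_fail"
    )
    data.frame(subject_id = r$subject_id,
               max_fd = max(r$fd_series),
               max_dvars = max(r$dvars_series),
               median_tsnr = r$median_tsnr,
               n_bold_components = r$n_bold_components,
               excluded = length(reasons) > 0,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
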