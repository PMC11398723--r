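# Temporal SNR, mono-exponential decay fitting, TSNR-optimal echo
# combination, and multi-vs-single-echo TSNR difference maps.

#' Temporal signal-to-noise ratio per region
#'
#' TSNR is the mean of a region's time series divided by its standard
#' deviation. Zero-variance regions are flagged undefined rather than
#' returned as infinite.
#'
#' @param series Region x time numeric matrix (>= 2 time points).
#' @param source One of `"multi_echo"`, `"single_echo_TE2"`, `"difference"`.
#' @return A `tsnr_map` data frame: `region`, `tsnr`, `undefined`, `source`.
#' @export
compute_tsnr <- function(series, source = "multi_echo") {
  series <- as.matrix(series)
  if (ncol(series) < 2) stop("TSNR needs at least 2 time points")
  m <- rowMeans(series)
  s <- apply(series, 1, stats::sd)
  undef <- s == 0
  tsnr <- ifelse(undef, NA_real_, m / s)
  structure(data.frame(region = seq_len(nrow(series)), tsnr = tsnr,
                       undefined = undef, source = source,
                       stringsAsFactors = FALSE),
            class = c("tsnr_map", "data.frame"))
}

#' Log-linear mono-exponential decay fit
#'
#' Fits `S(TE) = S0 * exp(-TE / T2*)` per region by least squares on
#' `log S(TE)`; exact on noiseless mono-exponential input. Regions with a
#' non-positive mean at any echo are flagged as failures rather than fitted.
#' T2* estimates are clipped to `t2s_limits` (default 5-150 ms) for
#' robustness to noise at long TE.
#'
#' @param mean_per_echo Numeric matrix (region x echo) or vector (one region)
#'   of time-averaged signal per echo; all echoes share `TEs`.
#' @param TEs Echo times, ms, length >= 2, strictly increasing.
#' @param t2s_limits Length-2 clip range for T2*, ms.
#' @return A `decay_fit` list: `S0`, `T2star` (ms), `fit_residual`, `failed`.
#' @examples
#' fit_monoexponential(100 * exp(-c(13.7, 30, 47) / 30), c(13.7, 30, 47))
#' @export
fit_monoexponential <- function(mean_per_echo, TEs, t2s_limits = c(5, 150)) {
  if (is.null(dim(mean_per_echo))) {
    mean_per_echo <- matrix(mean_per_echo, nrow = 1)
  }
  E <- length(TEs)
  if (E < 2) stop("need at least 2 echoes")
  if (ncol(mean_per_echo) != E) stop("mean_per_echo/TEs length mismatch")
  P <- nrow(mean_per_echo)

  failed <- apply(mean_per_echo <= 0, 1, any)
  S0 <- T2s <- resid <- rep(NA_real_, P)
  ok <- which(!failed)
  if (length(ok)) {
    y <- log(mean_per_echo[ok, , drop = FALSE])
    x <- TEs - mean(TEs)
    # slope = -1/T2*, intercept at mean TE
    slope <- (y %*% x) / sum(x^2)
    inter <- rowMeans(y)
    T2fit <- ifelse(slope < 0, -1 / slope, Inf)
    T2s[ok] <- pmin(pmax(T2fit, t2s_limits[1]), t2s_limits[2])
    S0[ok] <- exp(inter + mean(TEs) / T2s[ok])
    pred <- outer(1 / T2s[ok], -TEs) + log(S0[ok])
    resid[ok] <- rowSums((y - pred)^2)
  }
  structure(list(S0 = S0, T2star = T2s, fit_residual = resid,
                 failed = failed),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Decay fit:", length(x$S0), "regions,", sum(x$failed), "failed;",
      "median T2* =", round(stats::median(x$T2star, na.rm = TRUE), 1), "ms\n")
  invisible(x)
}

#' TSNR-optimal combination of echoes
#'
#' Weighted sum across echoes with the classical T2*-weighted rule:
#' per-region weights `w_e` proportional to `TE_e * exp(-TE_e / T2*_r)`,
#' normalised to sum to 1. Regions whose decay fit failed fall back to a
#' simple average (logged via attribute `fallback_regions`).
#'
#' @param run A `multi_echo_run`.
#' @param fit A [fit_monoexponential()] fit covering all regions; computed
#'   from the time-averaged echo images when omitted.
#' @return Region x time matrix of optimally combined signal, with the
#'   per-region weight matrix in attribute `weights`.
#' @export
optimal_combine <- function(run, fit = NULL) {
  stopifnot(inherits(run, "multi_echo_run"))
  E <- dim(run$data)[1]; P <- dim(run$data)[2]; Tn <- dim(run$data)[3]
  if (is.null(fit)) {
    means <- t(apply(run$data, 2, rowMeans))  # P x E
    fit <- fit_monoexponential(means, run$TEs)
  }
  if (length(fit$T2star) != P) stop("fit does not cover all regions")
  if (all(fit$failed)) stop("decay fit failed for every region")

  w <- combination_weights(fit$T2star, run$TEs)
  fallback <- which(fit$failed)
  if (length(fallback)) w[fallback, ] <- 1 / E
  out <- matrix(0, P, Tn)
  for (e in seq_len(E)) out <- out + w[, e] * run$data[e, , ]
  attr(out, "weights") <- w
  attr(out, "fallback_regions") <- fallback
  out
}

#' Per-region echo combination weights
#'
#' @param T2star Per-region T2*, ms.
#' @param TEs Echo times, ms.
#' @return Region x echo weight matrix, rows nonnegative and summing to 1.
#' @examples
#' combination_weights(30, c(13.7, 30, 47))  # ~ (0.294, 0.374, 0.332)
#' @export
combination_weights <- function(T2star, TEs) {
  w <- outer(T2star, TEs, function(t2, te) te * exp(-te / t2))
  w[is.na(w)] <- 1  # failed fits handled by caller; keep rows valid
  w / rowSums(w)
}

#' Multi-echo minus single-echo TSNR difference map
#'
#' Elementwise difference of two TSNR maps over the same regions; by
#' convention the subtrahend is the second-echo (single-echo proxy) map.
#'
#' @param multi,single_TE2 `tsnr_map` objects over identical regions.
#' @return A `tsnr_map` with `source = "difference"`; regions undefined in
#'   either operand stay undefined.
#' @export
tsnr_difference_map <- function(multi, single_TE2) {
  if (nrow(multi) != nrow(single_TE2) ||
      any(multi$region != single_TE2$region)) {
    stop("TSNR maps cover different regions")
  }
  undef <- multi$undefined | single_TE2$undefined
  structure(data.frame(
    region = multi$region,
    tsnr = ifelse(undef, NA_real_, multi$tsnr - single_TE2$tsnr),
    undefined = undef, source = "difference", stringsAsFactors = FALSE
  ), class = c("tsnr_map", "data.frame"))
}
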