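# Simplified ME-ICA: seeded FastICA decomposition of the optimally combined
# series, per-component TE-dependence scoring against Delta-R2* and Delta-S0
# models (kappa / rho), binary BOLD vs non-BOLD classification, MEFC
# coefficient extraction, and BOLD-only back-projection.

#' Seeded ICA decomposition of a region x time signal
#'
#' PCA whitening followed by symmetric fixed-point FastICA (logcosh
#' nonlinearity). Returns temporal sources ("mixing", time x K, unit
#' variance) and spatial coefficients (region x K) such that
#' `coeffs %*% t(mixing)` reconstructs the row-centred input up to the
#' residual outside the retained subspace. Components are ordered by
#' descending variance explained; each component's sign is fixed so its
#' largest-magnitude spatial coefficient is positive. Deterministic given
#' `seed`.
#'
#' @param combined Region x time matrix (e.g. from [optimal_combine()]).
#' @param K Number of components; default: smallest K retaining
#'   `var_target` of the variance by PCA. Must satisfy
#'   `K < min(regions, timepoints)`.
#' @param seed Integer seed for the rotation initialisation.
#' @param var_target PCA variance fraction used when `K` is omitted.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param n_restarts Number of seeded restarts; the rotation with the highest
#'   total negentropy proxy wins (guards against poor local optima).
#' @return A `component_set`: `mixing`, `coeffs`, `variance_explained`,
#'   `row_means`, plus empty `kappa`/`rho`/`label` slots.
#' @export
decompose <- function(combined, K = NULL, seed = 1L, var_target = 0.95,
                      max_iter = 500L, tol = 1e-8, n_restarts = 5L) {
  X <- as.matrix(combined)
  P <- nrow(X); Tn <- ncol(X)
  row_means <- rowMeans(X)
  Xc <- X - row_means

  sv <- svd(Xc)
  ev <- sv$d^2
  if (is.null(K)) {
    K <- which(cumsum(ev) / sum(ev) >= var_target)[1]
    K <- max(2L, min(K, min(P, Tn) - 1L))
  }
  K <- as.integer(K)
  if (K >= min(P, Tn)) {
    stop("K = ", K, " must be < min(regions, timepoints) = ", min(P, Tn))
  }
  if (K < 1) stop("K must be >= 1")

  # whitened sources: rows = K, columns = T samples
  Z <- t(sv$v[, seq_len(K), drop = FALSE]) * sqrt(Tn)

  best <- NULL
  logcosh_gauss <- 0.3745672  # E[log cosh(z)], z standard normal
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + 1009L * (r - 1L))
    W <- sym_orth(matrix(stats::rnorm(K * K), K, K))
    for (it in seq_len(max_iter)) {
      WX <- W %*% Z                     # K x T
      G <- tanh(WX)
      gp <- rowMeans(1 - G^2)           # E[g'(w'x)]
      W1 <- sym_orth((G %*% t(Z)) / Tn - gp * W)
      delta <- max(abs(abs(rowSums(W1 * W)) - 1))
      W <- W1
      if (delta < tol) break
    }
    # negentropy proxy summed over components
    obj <- sum((rowMeans(log(cosh(W %*% Z))) - logcosh_gauss)^2)
    if (is.null(best) || obj > best$obj) best <- list(W = W, obj = obj)
  }
  S <- best$W %*% Z                     # K x T, unit variance rows
  mixing <- t(S)                        # T x K
  # spatial coefficients by least squares (mixing rows are orthonormal here,
  # but solve the normal equations for generality)
  coeffs <- Xc %*% mixing %*% solve(crossprod(mixing))

  # order by variance explained, fix signs
  tot <- sum(Xc^2)
  ve <- colSums(coeffs^2) * (colSums(mixing^2)) / tot
  ord <- order(ve, decreasing = TRUE)
  mixing <- mixing[, ord, drop = FALSE]
  coeffs <- coeffs[, ord, drop = FALSE]
  ve <- ve[ord]
  for (k in seq_len(K)) {
    s <- sign(coeffs[which.max(abs(coeffs[, k])), k])
    if (s < 0) {
      coeffs[, k] <- -coeffs[, k]
      mixing[, k] <- -mixing[, k]
    }
  }
  structure(list(
    mixing = mixing, coeffs = coeffs, variance_explained = ve,
    kappa = rep(NA_real_, K), rho = rep(NA_real_, K),
    label = rep(NA_character_, K), row_means = row_means, seed = seed
  ), class = "component_set")
}

sym_orth <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' Noise-floor rank estimate (Marchenko-Pastur)
#'
#' Estimates the number of above-noise components of a centred data matrix:
#' iteratively treats eigenvalues below the Marchenko-Pastur bulk edge as
#' noise, re-estimates the noise variance from them, and counts the
#' eigenvalues above the edge. Suited to data whose noise is approximately
#' iid across rows (the echo-stacked representation).
#'
#' @param X Centred rows x samples matrix.
#' @return Integer rank estimate (at least 2).
#' @export
mp_rank <- function(X) {
  X <- as.matrix(X)
  Tn <- ncol(X)
  mu <- svd(X, nu = 0, nv = 0)$d^2 / Tn
  K <- 0L
  # the (1 + 3 T^{-2/3}) factor allows for Tracy-Widom fluctuation of the
  # largest noise eigenvalue about the asymptotic bulk edge
  tw <- 1 + 3 * Tn^(-2 / 3)
  for (it in 1:100) {
    bulk <- mu[seq(K + 1L, length(mu))]
    sigma2 <- mean(bulk)
    edge <- sigma2 * (1 + sqrt(length(bulk) / Tn))^2 * tw
    K2 <- sum(mu > edge)
    if (K2 == K) break
    K <- K2
  }
  max(K, 2L)
}

#' @export
print.component_set <- function(x, ...) {
  K <- ncol(x$mixing)
  cat("Component set: K =", K, "| variance explained =",
      round(sum(x$variance_explained), 3), "\n")
  if (!all(is.na(x$label))) {
    cat("  labels:", sum(x$label == "BOLD", na.rm = TRUE), "BOLD /",
        sum(x$label == "non_BOLD", na.rm = TRUE), "non-BOLD\n")
  }
  invisible(x)
}

#' @export
summary.component_set <- function(object, ...) {
  data.frame(component = seq_along(object$kappa),
             kappa = object$kappa, rho = object$rho,
             variance_explained = object$variance_explained,
             label = object$label)
}

#' TE-dependence metrics (kappa, rho) per component
#'
#' For each component and region, regresses every echo's time series onto the
#' component time course to obtain per-echo amplitudes, converts them to
#' percent amplitudes (relative to the echo's mean signal), and fits two
#' one-parameter models: the Delta-S0 model (percent amplitude constant
#' across TE) and the Delta-R2* model (percent amplitude proportional to TE).
#' `kappa` is the mean of the Delta-R2* model's F statistic over regions,
#' weighted by squared spatial coefficients; `rho` is the same for the
#' Delta-S0 model. Degenerate (zero-variance) components get
#' `kappa = rho = 0` with a warning.
#'
#' @param components A [decompose()] `component_set` from this run's combined
#'   series.
#' @param run The `multi_echo_run` the combined series came from.
#' @return The `component_set` with `kappa` and `rho` populated.
#' @export
te_dependence_metrics <- function(components, run) {
  stopifnot(inherits(components, "component_set"),
            inherits(run, "multi_echo_run"))
  E <- dim(run$data)[1]; P <- dim(run$data)[2]; Tn <- dim(run$data)[3]
  if (nrow(components$coeffs) != P || nrow(components$mixing) != Tn) {
    stop("component set does not match this run's dimensions")
  }
  K <- ncol(components$mixing)
  TEs <- run$TEs

  mix <- components$mixing
  mvar <- colSums(scale(mix, scale = FALSE)^2)       # per-component ss
  degenerate <- mvar < .Machine$double.eps * Tn
  if (any(degenerate)) {
    warning("degenerate (zero-variance) component(s): ",
            paste(which(degenerate), collapse = ", "))
  }

  # per-echo amplitudes: beta_e[p, k] from regression of echo data on the
  # (non-degenerate) mixing columns
  ok_cols <- which(!degenerate)
  mixc <- scale(mix[, ok_cols, drop = FALSE], scale = FALSE)
  xtx_inv <- solve(crossprod(mixc))
  beta <- array(0, dim = c(E, P, K))
  mean_e <- matrix(0, P, E)
  for (e in seq_len(E)) {
    De <- run$data[e, , ]
    mean_e[, e] <- rowMeans(De)
    beta[e, , ok_cols] <- (De - mean_e[, e]) %*% mixc %*% xtx_inv
  }

  kappa <- rho <- se_diff <- numeric(K)
  wts_all <- components$coeffs^2
  for (k in seq_len(K)) {
    if (degenerate[k]) next
    d <- t(beta[, , k]) / mean_e                     # P x E percent amplitudes
    # Delta-S0 model: d_e = a          (a = mean over echoes)
    # Delta-R2* model: d_e = b * TE_e  (b = <TE, d>/<TE, TE>)
    sst <- rowSums(d^2)
    a <- rowMeans(d)
    sse_s0 <- rowSums((d - a)^2)
    b <- (d %*% TEs) / sum(TEs^2)
    sse_r2 <- rowSums((d - outer(as.numeric(b), TEs))^2)
    f_s0 <- (sst - sse_s0) / pmax(sse_s0 / (E - 1), .Machine$double.eps)
    f_r2 <- (sst - sse_r2) / pmax(sse_r2 / (E - 1), .Machine$double.eps)
    w <- wts_all[, k]
    if (sum(w) <= 0) w <- rep(1, P)
    w <- w / sum(w)
    kappa[k] <- sum(w * f_r2)
    rho[k] <- sum(w * f_s0)
    # standard error of the weighted mean F difference across regions,
    # used by the conservative statistical tie-break in classification
    diff_k <- f_r2 - f_s0
    se_diff[k] <- sqrt(sum(w^2 * (diff_k - sum(w * diff_k))^2))
  }
  components$kappa <- kappa
  components$rho <- rho
  components$se_diff <- se_diff
  components
}

#' Classify components as BOLD vs non-BOLD
#'
#' A component is labelled BOLD iff `kappa > kappa_rho_ratio * rho`
#' (default ratio 1): its TE dependence fits the Delta-R2* model strictly
#' better than the Delta-S0 model. Ties are conservatively non-BOLD, and the
#' tie-break can be made statistical: with `z_guard > 0` the margin
#' `kappa - kappa_rho_ratio * rho` must exceed `z_guard` standard errors of
#' the weighted per-region F difference, so components whose two fits are
#' indistinguishable (residual noise components) are not accepted on a coin
#' flip. The default `z_guard = 0` is the plain strict-inequality rule (the
#' per-region F statistics are too heavy-tailed at three echoes for the
#' guard to be reliable; it is kept for configurations with more echoes).
#'
#' @param components A `component_set` with kappa/rho populated.
#' @param kappa_rho_ratio Acceptance ratio threshold.
#' @param z_guard Conservative guard, in standard errors.
#' @return The `component_set` with `label` populated; if no component is
#'   BOLD the set is flagged via attribute `empty_bold`.
#' @export
classify_components <- function(components, kappa_rho_ratio = 1,
                                z_guard = 0) {
  stopifnot(inherits(components, "component_set"))
  if (anyNA(components$kappa) || anyNA(components$rho)) {
    stop("kappa/rho not populated; run te_dependence_metrics() first")
  }
  margin <- components$kappa - kappa_rho_ratio * components$rho
  guard <- if (is.null(components$se_diff)) 0 else
    z_guard * components$se_diff
  bold <- margin > guard
  components$label <- ifelse(bold, "BOLD", "non_BOLD")
  attr(components, "empty_bold") <- !any(bold)
  components
}

#' Extract the MEFC coefficient set
#'
#' Restricts the spatial coefficient matrix to BOLD-labelled columns; the
#' number of retained columns is the degrees of freedom `df` that scales the
#' Fisher z transform downstream.
#'
#' @param components A classified `component_set`.
#' @param subject_id Subject identifier carried along.
#' @return An `mefc` object: `coeffs` (region x df), `df`, `subject_id`.
#' @export
build_mefc <- function(components, subject_id = NA_character_) {
  stopifnot(inherits(components, "component_set"))
  if (anyNA(components$label)) stop("components not classified")
  keep <- which(components$label == "BOLD")
  if (!length(keep)) {
    stop("zero BOLD components: subject would be excluded by the ",
         "fewer-than-10-components QC rule")
  }
  structure(list(coeffs = components$coeffs[, keep, drop = FALSE],
                 df = length(keep), subject_id = subject_id,
                 bold_columns = keep),
            class = "mefc")
}

#' @export
print.mefc <- function(x, ...) {
  cat("MEFC coefficients:", nrow(x$coeffs), "regions x", x$df,
      "BOLD components (df =", x$df, ")\n")
  invisible(x)
}

#' Back-project the BOLD components only
#'
#' Reconstructs a denoised region x time series as the product of the BOLD
#' mixing columns and BOLD coefficient rows, with the per-region means added
#' back (quality metrics such as TSNR are computed on this series).
#'
#' @param components A classified `component_set`.
#' @return Region x time matrix.
#' @export
reconstruct_denoised <- function(components) {
  stopifnot(inherits(components, "component_set"))
  if (anyNA(components$label)) stop("components not classified")
  keep <- which(components$label == "BOLD")
  if (!length(keep)) stop("empty BOLD set: nothing to reconstruct")
  components$coeffs[, keep, drop = FALSE] %*%
    t(components$mixing[, keep, drop = FALSE]) + components$row_means
}

#' TE-informed ICA decomposition of a multi-echo run
#'
#' Estimates the component time courses by ICA on the echo-stacked,
#' row-centred data (every echo's region x time block stacked vertically),
#' then expresses the spatial coefficients against the optimally combined
#' series. Delta-R2*-like sources scale with TE across the stacked blocks
#' while Delta-S0-like sources are TE-flat, so the stacked representation
#' separates the two classes far better than the combined series alone can;
#' the returned `mixing`/`coeffs` still reconstruct the combined input in
#' the least-squares sense required downstream.
#'
#' @param run A `multi_echo_run`.
#' @param combined Region x time combined series (computed via
#'   [optimal_combine()] when omitted).
#' @inheritParams decompose
#' @return A `component_set` bound to the combined series (its regions, its
#'   row means), ordered by variance explained in the combined series.
#' @export
decompose_multiecho <- function(run, combined = NULL, K = NULL, seed = 1L,
                                var_target = 0.95, n_restarts = 5L) {
  stopifnot(inherits(run, "multi_echo_run"))
  if (is.null(combined)) combined <- optimal_combine(run)
  E <- dim(run$data)[1]
  stacked <- do.call(rbind, lapply(seq_len(E), function(e) {
    D <- run$data[e, , ]
    D - rowMeans(D)
  }))
  # thermal noise is iid across the stacked rows, so the Marchenko-Pastur
  # noise floor gives a stable default dimension (the 95%-variance rule
  # would count noise eigenvalues here)
  if (is.null(K)) K <- mp_rank(stacked)
  comps <- decompose(stacked, K = K, seed = seed, var_target = var_target,
                     n_restarts = n_restarts)
  mixing <- comps$mixing
  row_means <- rowMeans(combined)
  Xc <- combined - row_means
  coeffs <- Xc %*% mixing %*% solve(crossprod(mixing))

  ve <- colSums(coeffs^2) * colSums(mixing^2) / sum(Xc^2)
  ord <- order(ve, decreasing = TRUE)
  mixing <- mixing[, ord, drop = FALSE]
  coeffs <- coeffs[, ord, drop = FALSE]
  ve <- ve[ord]
  for (k in seq_len(ncol(mixing))) {
    if (coeffs[which.max(abs(coeffs[, k])), k] < 0) {
      coeffs[, k] <- -coeffs[, k]
      mixing[, k] <- -mixing[, k]
    }
  }
  structure(list(
    mixing = mixing, coeffs = coeffs, variance_explained = ve,
    kappa = rep(NA_real_, ncol(mixing)), rho = rep(NA_real_, ncol(mixing)),
    label = rep(NA_character_, ncol(mixing)),
    row_means = row_means, seed = seed
  ), class = "component_set")
}

#' One-call denoising of a multi-echo run
#'
#' Convenience wrapper: optimal combination, TE-informed ICA decomposition
#' ([decompose_multiecho()]), TE-dependence metrics, and classification.
#'
#' @param run A `multi_echo_run`.
#' @param K Number of components (default: 95% PCA variance rule).
#' @param seed ICA seed.
#' @param kappa_rho_ratio See [classify_components()].
#' @return A classified `component_set` with the combined series in
#'   attribute `combined`.
#' @export
denoise_run <- function(run, K = NULL, seed = 1L, kappa_rho_ratio = 1) {
  combined <- optimal_combine(run)
  comps <- decompose_multiecho(run, combined, K = K, seed = seed)
  comps <- te_dependence_metrics(comps, run)
  comps <- classify_components(comps, kappa_rho_ratio)
  attr(comps, "combined") <- combined
  comps
}
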