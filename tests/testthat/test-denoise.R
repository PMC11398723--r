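# a small multi-echo run with hand-planted pure sources, built directly from
# the decay model (independent of the cohort generator)
planted_run <- function(seed = 1, Tn = 400, P = 40, noise = 0.5) {
  set.seed(seed)
  TEs <- c(13.7, 30, 47)
  S0 <- runif(P, 900, 1100)
  T2s <- runif(P, 35, 55)
  src_bold <- scale(matrix((rexp(Tn * 2) - rexp(Tn * 2)) / sqrt(2), Tn, 2))
  src_art <- scale(matrix((rexp(Tn) - rexp(Tn)) / sqrt(2), Tn, 1))
  map_bold <- matrix(0, P, 2)
  map_bold[1:12, 1] <- 1
  map_bold[13:24, 2] <- 1
  map_art <- matrix(0, P, 1)
  map_art[25:36, 1] <- 1.2
  cR2 <- 0.01 * map_bold %*% t(src_bold)
  cS0 <- 0.012 * map_art %*% t(src_art)
  data <- array(0, dim = c(3, P, Tn))
  for (e in 1:3) {
    data[e, , ] <- S0 * exp(-TEs[e] / T2s) *
      (1 + (TEs[e] / 30) * cR2 + cS0) + rnorm(P * Tn, 0, noise)
  }
  structure(list(TEs = TEs, TR = 3, data = data,
                 motion = matrix(0, Tn, 6), subject_id = "planted",
                 internals = list(bold_sources = src_bold,
                                  artifact_sources = src_art)),
            class = "multi_echo_run")
}

test_that("ICA recovers planted sources and is deterministic", {
  set.seed(42)
  Tn <- 500
  src <- scale(cbind(sin(seq_len(Tn) / 7),
                     (rexp(Tn) - rexp(Tn)) / sqrt(2),
                     sign(sin(seq_len(Tn) / 23))))
  A <- matrix(0, 30, 3)
  A[1:10, 1] <- runif(10, 0.8, 1.2)
  A[11:20, 2] <- runif(10, 0.8, 1.2)
  A[21:30, 3] <- runif(10, 0.8, 1.2)
  X <- A %*% t(src) + matrix(rnorm(30 * Tn, 0, 0.01), 30, Tn)
  d1 <- decompose(X, K = 3, seed = 7)
  d2 <- decompose(X, K = 3, seed = 7)
  expect_identical(d1$mixing, d2$mixing)
  C <- abs(cor(d1$mixing, src))
  expect_true(all(apply(C, 2, max) > 0.95))
  # reconstruction property
  recon <- d1$coeffs %*% t(d1$mixing)
  expect_lt(norm(X - rowMeans(X) - recon, "F") / norm(X - rowMeans(X), "F"),
            0.05)
  expect_error(decompose(X, K = 600, seed = 1), "must be <")
  expect_true(all(diff(d1$variance_explained) <= 1e-12))
})

test_that("mp_rank finds the planted dimension and floors at 2 on noise", {
  set.seed(8)
  noise <- matrix(rnorm(200 * 300), 200, 300)
  expect_equal(mp_rank(noise - rowMeans(noise)), 2)
  A <- matrix(rnorm(200 * 5), 200, 5) %*% matrix(rnorm(5 * 300), 5, 300)
  X <- 2 * A + noise
  expect_equal(mp_rank(X - rowMeans(X)), 5)
})

test_that("TE-dependence metrics separate Delta-R2* from Delta-S0 sources", {
  run <- planted_run()
  comps <- decompose_multiecho(run, K = 3, seed = 11)
  comps <- te_dependence_metrics(comps, run)
  C <- abs(cor(comps$mixing, cbind(run$internals$bold_sources,
                                   run$internals$artifact_sources)))
  match_comp <- apply(C, 2, which.max)
  expect_true(all(C[cbind(match_comp, 1:3)] > 0.95))
  bold_comps <- match_comp[1:2]
  art_comp <- match_comp[3]
  expect_true(all(comps$kappa[bold_comps] > comps$rho[bold_comps]))
  expect_gt(comps$rho[art_comp], comps$kappa[art_comp])

  # kappa and rho are invariant to a component sign flip
  flipped <- comps
  flipped$mixing[, 1] <- -flipped$mixing[, 1]
  flipped$coeffs[, 1] <- -flipped$coeffs[, 1]
  flipped <- te_dependence_metrics(flipped, run)
  expect_equal(flipped$kappa, comps$kappa, tolerance = 1e-10)
  expect_equal(flipped$rho, comps$rho, tolerance = 1e-10)
})

test_that("white-noise components score low on both TE models", {
  run <- planted_run(noise = 3)
  comps <- decompose_multiecho(run, K = 6, seed = 11)
  comps <- te_dependence_metrics(comps, run)
  C <- abs(cor(comps$mixing, cbind(run$internals$bold_sources,
                                   run$internals$artifact_sources)))
  planted_comp <- apply(C, 2, which.max)
  noise_comps <- setdiff(seq_len(6), planted_comp)
  planted_strength <- pmax(comps$kappa, comps$rho)
  expect_lt(max(planted_strength[noise_comps]),
            min(planted_strength[planted_comp]))
})

test_that("classification rule, MEFC selection, and reconstruction contracts", {
  run <- planted_run()
  comps <- denoise_run(run, K = 3, seed = 11)
  expect_identical(sort(unique(comps$label)), c("BOLD", "non_BOLD"))
  expect_equal(sum(comps$label == "BOLD"), 2)

  # exact tie -> non-BOLD
  tie <- comps
  tie$kappa <- c(1, 1, 1)
  tie$rho <- c(1, 1, 1)
  tie$se_diff <- NULL
  tie <- classify_components(tie)
  expect_true(all(tie$label == "non_BOLD"))
  expect_true(attr(tie, "empty_bold"))
  expect_error(build_mefc(tie), "QC")

  m <- build_mefc(comps, subject_id = "planted")
  expect_equal(m$df, ncol(m$coeffs))
  expect_identical(m$coeffs,
                   comps$coeffs[, comps$label == "BOLD", drop = FALSE])

  # all-BOLD reconstruction equals the full fit
  allb <- comps
  allb$label <- rep("BOLD", 3)
  recon <- reconstruct_denoised(allb)
  full <- comps$coeffs %*% t(comps$mixing) + comps$row_means
  expect_equal(recon, full, tolerance = 1e-12)
  expect_identical(dim(recon), dim(run$data[1, , ]))
})

test_that("denoising removes most planted artifact variance", {
  run <- planted_run()
  comps <- denoise_run(run, K = 3, seed = 11)
  den <- reconstruct_denoised(comps)
  art <- as.numeric(run$internals$artifact_sources)
  proj_before <- colSums((attr(comps, "combined") %*% art)^2) / sum(art^2)
  proj_after <- colSums((den %*% art)^2) / sum(art^2)
  expect_lt(sum(proj_after) / sum(proj_before), 0.10)
})

test_that("degenerate components warn and score zero", {
  run <- planted_run()
  comps <- decompose_multiecho(run, K = 3, seed = 11)
  comps$mixing[, 2] <- 0
  expect_warning(out <- te_dependence_metrics(comps, run), "degenerate")
  expect_equal(out$kappa[2], 0)
  expect_equal(out$rho[2], 0)
})
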