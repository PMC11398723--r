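atlas34 <- make_atlas(34, 7, seed = 3)

test_that("ground truth encodes the merged/distinct hypothesis", {
  for (scheme in c("subnetworks", "groups")) {
    tm <- make_ground_truth(atlas34, "merged", latent_scheme = scheme, seed = 2)
    td <- make_ground_truth(atlas34, "distinct", latent_scheme = scheme, seed = 2)
    dn_cols <- which(tm$latent_names %in% c("DN_A", "DN_B", "DN_C"))
    lim <- which(atlas34$is_limbic)
    # merged: every LIM parcel loads on at least one DN latent
    expect_true(all(rowSums(abs(tm$latent_loadings[lim, dn_cols,
                                                   drop = FALSE])) > 0))
    # distinct: LIM parcels load only on the LIM latent
    lim_col <- which(td$latent_names == "LIM")
    expect_true(all(td$latent_loadings[lim, lim_col] > 0))
    expect_true(all(td$latent_loadings[lim, -lim_col] == 0))
    expect_length(intersect(tm$bold_component_ids, tm$artifact_component_ids), 0)
  }
  expect_error(make_ground_truth(atlas34, "merged", latent_scheme = "groups",
                                 n_bold = 5), "core network sources")
  expect_error(make_ground_truth(atlas34, "merged",
                                 qc_violations = list(`1` = "bogus")),
               "fd_dvars")
})

test_that("simulation is deterministic and respects the decay model", {
  truth <- make_ground_truth(atlas34, "merged", seed = 2)
  rec <- make_recipe(atlas34, seed = 9, n_timepoints = 50L)
  r1 <- simulate_subject(atlas34, truth, rec)
  r2 <- simulate_subject(atlas34, truth, rec)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$motion, r2$motion)
  # dropout parcels sit strictly below the non-dropout medians
  drop <- atlas34$is_ventral_dropout
  expect_true(max(rec$T2star_map[drop]) < median(rec$T2star_map[!drop]))
  expect_true(max(rec$S0_map[drop]) < median(rec$S0_map[!drop]))
  expect_error(make_recipe(atlas34, seed = 1, TEs = c(30, 13.7, 47)),
               "strictly increasing")
})

test_that("noiseless merged LIM parcels track their assigned DN latent", {
  truth <- make_ground_truth(atlas34, "merged", seed = 2, n_artifact = 0)
  rec <- make_recipe(atlas34, seed = 9, n_timepoints = 300L, noise_sd = 0)
  run <- simulate_subject(atlas34, truth, rec)
  combined <- optimal_combine(run)
  lim <- which(atlas34$is_limbic)
  cl <- truth$planted_lim_clusters
  dn_col <- match(c("DN_A", "DN_B", "DN_C"), truth$latent_names)
  for (i in seq_along(lim)) {
    latent <- run$internals$bold_sources[, dn_col[cl[i]]]
    expect_gt(abs(cor(combined[lim[i], ], latent)), 0.9)
  }
})

test_that("per-echo percent amplitudes are TE-increasing for BOLD, flat for artifacts", {
  truth <- make_ground_truth(atlas34, "merged", seed = 4)
  rec <- make_recipe(atlas34, seed = 12, n_timepoints = 300L, noise_sd = 0)
  run <- simulate_subject(atlas34, truth, rec)
  TEs <- run$TEs
  mean_e <- sapply(seq_along(TEs), function(e) rowMeans(run$data[e, , ]))
  # regress each echo's data onto a planted source, take percent amplitude
  # at the parcel where the source loads most strongly
  percent_amp <- function(src) {
    sc <- src - mean(src)
    sapply(seq_along(TEs), function(e) {
      De <- run$data[e, , ]
      b <- (De - rowMeans(De)) %*% sc / sum(sc^2)
      b / mean_e[, e]
    })
  }
  for (k in c(1, 5, 9)) {                       # a few BOLD latents
    map <- run$internals$bold_maps[, k]
    p <- which.max(abs(map))
    amp <- percent_amp(run$internals$bold_sources[, k])[p, ]
    expect_true(all(diff(abs(amp)) > 0))
  }
  for (j in seq_len(2)) {                       # artifact sources
    map <- run$internals$artifact_maps[, j]
    p <- which.max(abs(map))
    amp <- percent_amp(run$internals$artifact_sources[, j])[p, ]
    expect_lt(max(abs(amp)) - min(abs(amp)), 0.1 * max(abs(amp)))
  }
})

test_that("spike-free runs stay under the FD threshold; spikes land where planted", {
  truth <- make_ground_truth(atlas34, "merged", seed = 2)
  rec <- make_recipe(atlas34, seed = 9, n_timepoints = 200L,
                     motion_spike_rate = 0)
  run <- simulate_subject(atlas34, truth, rec)
  expect_lt(max(framewise_displacement(run$motion)), 0.5)
  rec_s <- make_recipe(atlas34, seed = 9, n_timepoints = 200L,
                       spike_frames = c(70, 140))
  run_s <- simulate_subject(atlas34, truth, rec_s)
  fd <- framewise_displacement(run_s$motion)
  expect_true(all(fd[c(69, 70, 139, 140)] > 0.5))
})

test_that("cohorts share the planted partition and are reproducible", {
  c1 <- simulate_cohort(3, "merged", master_seed = 7, atlas = atlas34,
                        n_timepoints = 40L)
  c2 <- simulate_cohort(3, "merged", master_seed = 7, atlas = atlas34,
                        n_timepoints = 40L)
  expect_identical(c1$truth$planted_partition, c2$truth$planted_partition)
  expect_identical(c1$runs[[2]]$data, c2$runs[[2]]$data)
  expect_error(simulate_cohort(1, "merged", master_seed = 1), ">= 2")
  # subject-specific seeds differ
  expect_false(identical(c1$runs[[1]]$data, c1$runs[[2]]$data))
})

test_that("dropout parcels have lower single-echo TSNR at the longest TE", {
  truth <- make_ground_truth(atlas34, "merged", seed = 6)
  rec <- make_recipe(atlas34, seed = 31, n_timepoints = 300L)
  run <- simulate_subject(atlas34, truth, rec)
  E <- length(run$TEs)
  tsnr3 <- compute_tsnr(run$data[E, , ])$tsnr
  drop <- atlas34$is_ventral_dropout
  expect_lt(mean(tsnr3[drop]), mean(tsnr3[!drop]))
})
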