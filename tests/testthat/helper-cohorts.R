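# Lazily built, cached simulated cohorts and pipeline results. The heavy
# cohorts are shared across test files; seeds are fixed design choices.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, force(expr), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# 20-subject cohorts with the hierarchical subnetwork structure: the
# headline-mechanism and clustering worlds
merged_pipeline <- function() {
  cached("merged20", {
    co <- simulate_cohort(20, "merged", master_seed = 11)
    list(cohort = co, pipe = run_pipeline(co, seed = 101))
  })
}

distinct_pipeline <- function() {
  cached("distinct20", {
    co <- simulate_cohort(20, "distinct", master_seed = 11)
    list(cohort = co, pipe = run_pipeline(co, seed = 101))
  })
}

# the denoising-recovery world: exactly 8 BOLD + 6 artifact planted sources
denoise_cohort <- function() {
  cached("denoise20", {
    simulate_cohort(20, "merged", master_seed = 5,
                    atlas = make_atlas(102, 7, seed = 3),
                    latent_scheme = "groups", n_bold = 8, n_artifact = 6)
  })
}

# the QC-exactness world: flat latents with wide count margins and planted
# violators of all three kinds
qc_pipeline <- function() {
  cached("qc10", {
    co <- simulate_cohort(10, "merged", master_seed = 21,
                          latent_scheme = "groups", n_bold = 16,
                          qc_violations = list(`3` = "fd_dvars",
                                               `7` = "low_tsnr",
                                               `9` = "few_components"))
    list(cohort = co, pipe = run_pipeline(co, seed = 55))
  })
}

# tiny cohort for smoke tests and fixtures
tiny_cohort <- function() {
  cached("tiny", {
    simulate_cohort(2, "merged", master_seed = 3,
                    atlas = make_atlas(34, 7, seed = 3),
                    latent_scheme = "groups", n_bold = 12,
                    n_timepoints = 150L)
  })
}
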