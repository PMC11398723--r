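# End-to-end convenience: cohort -> per-subject denoising, QC, MEFC
# connectivity, and the group-mean matrix.

#' Run the full per-subject pipeline on a simulated cohort
#'
#' For every subject: optimal echo combination, ICA decomposition,
#' TE-dependence classification, MEFC extraction, QC record, and the
#' df-adjusted Fisher-z RSFC matrix; then the group-mean matrix over the
#' retained (or all) subjects.
#'
#' @param cohort An [simulate_cohort()] cohort.
#' @param K Components per subject (default: 95% PCA variance rule).
#' @param seed Base ICA seed; subject i uses `seed + i`.
#' @param kappa_rho_ratio BOLD acceptance ratio (see
#'   [classify_components()]).
#' @param apply_qc Drop excluded subjects before the group mean.
#' @return A `pipeline_result`: `components`, `mefc`, `matrices`, `qc`
#'   (data frame), `group` (group-mean `rsfc_matrix` over kept subjects),
#'   `kept` (indices).
#' @export
run_pipeline <- function(cohort, K = NULL, seed = 1L, kappa_rho_ratio = 1,
                         apply_qc = FALSE) {
  stopifnot(inherits(cohort, "me_cohort"))
  n <- length(cohort$runs)
  components <- vector("list", n)
  mefc <- vector("list", n)
  matrices <- vector("list", n)
  qc_records <- vector("list", n)
  for (i in seq_len(n)) {
    run <- cohort$runs[[i]]
    comps <- denoise_run(run, K = K, seed = seed + i,
                         kappa_rho_ratio = kappa_rho_ratio)
    m <- build_mefc(comps, subject_id = run$subject_id)
    qc_records[[i]] <- qc_record(run, reconstruct_denoised(comps), m$df)
    if (m$df >= 4) {
      pc <- parcellate_coefficients(m, cohort$atlas)
      matrices[[i]] <- rsfc_from_mefc(pc, df = m$df,
                                      subject_id = run$subject_id)
    }  # df <= 3: no z matrix is defined; QC flags the subject anyway
    components[[i]] <- comps
    mefc[[i]] <- m
  }
  qc <- apply_exclusions(qc_records)
  kept <- if (apply_qc) which(!qc$excluded) else seq_len(n)
  kept <- kept[!vapply(matrices[kept], is.null, logical(1))]
  if (length(kept) < 2) stop("fewer than 2 subjects retained after QC")
  structure(list(components = components, mefc = mefc, matrices = matrices,
                 qc = qc, qc_records = qc_records,
                 group = group_mean_matrix(matrices[kept]), kept = kept),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", length(x$matrices), "subjects (",
      length(x$kept), "kept ),",
      nrow(x$group$z), "parcels\n")
  invisible(x)
}
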