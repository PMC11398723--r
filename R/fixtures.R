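# Plain-text fixture round-trip: parcel x time TSV per echo per subject,
# motion TSV (6 columns), atlas TSV, ground-truth JSON, checksum manifest.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated cohort to a plain-text fixture directory
#'
#' One TSV per echo per subject (parcel x time), one motion-parameter TSV per
#' subject, the atlas table, the ground truth as JSON, and a manifest listing
#' every file with its md5 checksum. The manifest is written last, so a
#' partial write leaves no manifest behind.
#'
#' @param cohort An [simulate_cohort()] cohort.
#' @param directory Output directory (created if absent); must be writable.
#' @return The manifest, invisibly.
#' @export
write_fixture <- function(cohort, directory) {
  stopifnot(inherits(cohort, "me_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(directory, ".write-probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("directory not writable: ", directory)
  unlink(probe)

  files <- character(0)
  for (run in cohort$runs) {
    E <- dim(run$data)[1]
    for (e in seq_len(E)) {
      f <- file.path(directory,
                     sprintf("%s_echo-%d.tsv", run$subject_id, e))
      mat <- run$data[e, , ]
      df <- data.frame(parcel_id = cohort$atlas$parcel_id, mat)
      colnames(df) <- c("parcel_id", paste0("t", seq_len(ncol(mat))))
      write_tsv(df, f)
      files <- c(files, f)
    }
    f <- file.path(directory, sprintf("%s_motion.tsv", run$subject_id))
    write_tsv(as.data.frame(run$motion), f)
    files <- c(files, f)
  }
  f_atlas <- file.path(directory, "atlas.tsv")
  write_tsv(as.data.frame(cohort$atlas), f_atlas)
  f_truth <- file.path(directory, "ground_truth.json")
  truth <- cohort$truth
  jsonlite::write_json(list(
    scenario = truth$scenario,
    latent_scheme = truth$latent_scheme,
    latent_names = truth$latent_names,
    latent_groups = truth$latent_groups,
    latent_loadings = truth$latent_loadings,
    artifact_maps = truth$artifact_maps,
    bold_component_ids = truth$bold_component_ids,
    artifact_component_ids = truth$artifact_component_ids,
    planted_partition = truth$planted_partition,
    planted_module_names = truth$planted_module_names,
    planted_lim_clusters = as.list(truth$planted_lim_clusters),
    qc_violations = truth$qc_violations,
    seed = truth$seed,
    scenario_meta = list(master_seed = cohort$master_seed,
                         TEs = cohort$runs[[1]]$TEs,
                         TR = cohort$runs[[1]]$TR)
  ), f_truth, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_atlas, f_truth)

  if (!all(file.exists(files))) {
    stop("partial fixture write: missing ",
         paste(files[!file.exists(files)], collapse = ", "))
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a fixture directory back into an in-memory cohort
#'
#' Inverse of [write_fixture()] up to float round-off in the TSV encoding.
#' Generator internals (latent sources) are not stored in fixtures and are
#' absent from the reloaded runs.
#'
#' @param directory Fixture directory containing a `manifest.json`.
#' @return An `me_cohort`.
#' @export
read_fixture <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", directory)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)

  atlas <- utils::read.delim(file.path(directory, "atlas.tsv"))
  class(atlas) <- c("toy_atlas", "data.frame")
  truth_js <- jsonlite::read_json(file.path(directory, "ground_truth.json"),
                                  simplifyVector = TRUE)
  truth <- structure(list(
    scenario = truth_js$scenario,
    latent_scheme = truth_js$latent_scheme,
    latent_names = truth_js$latent_names,
    latent_groups = truth_js$latent_groups,
    latent_loadings = as.matrix(truth_js$latent_loadings),
    artifact_maps = as.matrix(truth_js$artifact_maps),
    bold_component_ids = truth_js$bold_component_ids,
    artifact_component_ids = truth_js$artifact_component_ids,
    planted_partition = truth_js$planted_partition,
    planted_module_names = truth_js$planted_module_names,
    planted_lim_clusters = unlist(truth_js$planted_lim_clusters),
    qc_violations = truth_js$qc_violations,
    seed = truth_js$seed
  ), class = "ground_truth")

  subj <- sort(unique(sub("_echo-[0-9]+\\.tsv$", "",
                          grep("_echo-", manifest$file, value = TRUE))))
  TEs <- truth_js$scenario_meta$TEs
  TR <- truth_js$scenario_meta$TR
  runs <- lapply(subj, function(s) {
    echo_files <- sort(grep(paste0("^", s, "_echo-"), manifest$file,
                            value = TRUE))
    mats <- lapply(echo_files, function(f) {
      df <- utils::read.delim(file.path(directory, f))
      as.matrix(df[, -1, drop = FALSE])
    })
    P <- nrow(mats[[1]]); Tn <- ncol(mats[[1]])
    data <- array(0, dim = c(length(mats), P, Tn),
                  dimnames = list(paste0("echo", seq_along(mats)), NULL, NULL))
    for (e in seq_along(mats)) data[e, , ] <- mats[[e]]
    motion <- as.matrix(utils::read.delim(
      file.path(directory, sprintf("%s_motion.tsv", s))))
    structure(list(TEs = TEs, TR = TR, data = data, motion = motion,
                   subject_id = s, internals = NULL),
              class = "multi_echo_run")
  })
  structure(list(runs = runs, truth = truth, atlas = atlas,
                 scenario = truth$scenario,
                 master_seed = truth_js$scenario_meta$master_seed),
            class = "me_cohort")
}
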