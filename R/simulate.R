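# Synthetic multi-echo cohort generator.
#
# Signal model per parcel p, echo e, frame t:
#   S_e(p, t) = S0_p * exp(-TE_e / T2*_p) *
#               (1 + (TE_e / TE_SCALE) * cR2(p, t) + cS0(p, t)) + noise
# cR2 is the BOLD-like (Delta R2*) percent-signal series: its per-echo percent
# amplitude grows linearly with TE. cS0 is the artifact (Delta S0) series:
# percent amplitude flat across TE. Latent network time courses are AR(1)
# with Laplace innovations (super-Gaussian, required for ICA identifiability
# and closer to the spiky temporal statistics of real BOLD and artifacts).

TE_SCALE <- 30          # ms; reference TE at which cR2 is expressed in percent
BOLD_AMP <- 0.01        # sd of network percent-signal fluctuation at TE_SCALE
ARTIFACT_AMP <- 0.012   # sd of artifact percent-signal fluctuation
PRIVATE_SD <- 0.2       # parcel-private residual loading
LIM_DN_LOADING <- 0.6   # merged scenario: LIM parcel loading on its DN latent
NETWORK_LOADING <- 0.8  # cortical parcel loading on its network latent
SUBCORT_LOADING <- 0.5  # subcortical loading on its assigned latent
GROUP_COHERENCE <- sqrt(0.3)  # subnetwork latent loading on its group factor
AUX_DENSITY <- 0.35     # auxiliary BOLD maps: fraction of parcels loaded
AUX_SD <- 0.45          # auxiliary BOLD map loading sd
ART_DENSITY <- 0.3      # artifact maps: fraction of parcels loaded
ART_SD <- 0.8           # artifact map loading sd

# BOLD latents per scheme. "subnetworks": one latent per 17-network label
# (minus LIM, which is scenario-dependent), correlated within 7-network
# groups through shared group factors. "groups": one flat latent per
# 7-network group with DN kept split into DN_A/B/C (the minimal structure
# that still expresses the merged-vs-distinct hypothesis).
core_source_names <- function(scenario, latent_scheme = "subnetworks") {
  core <- if (latent_scheme == "subnetworks") {
    setdiff(CORTICAL_NETWORKS, c("LIM_A", "LIM_B"))
  } else {
    c("VIS", "SMN", "DAN", "SAL", "FPN", "DN_A", "DN_B", "DN_C")
  }
  if (scenario == "distinct") core <- c(core, "LIM")
  core
}

# group factor of each latent (NA = free-standing latent)
latent_group_of <- function(latent_names, latent_scheme) {
  if (latent_scheme != "subnetworks") {
    return(rep(NA_character_, length(latent_names)))
  }
  out <- network_group(latent_names)
  out[latent_names %in% c("LIM", "AUX")] <- NA
  out[grepl("^AUX", latent_names)] <- NA
  out
}

subcortical_source <- list(
  subnetworks = c(HIP = "DN_C", AMY = "DN_C", NAC = "DN_A", GP = "SMN_A",
                  PUT = "SMN_A", CAU = "FPN_A", BF = "DN_A"),
  groups = c(HIP = "DN_C", AMY = "DN_C", NAC = "DN_A", GP = "SMN",
             PUT = "SMN", CAU = "FPN", BF = "DN_A")
)

# DN latent carrying each planted limbic sub-cluster (identical across
# schemes: DN_A/B/C exist in both)
lim_cluster_source <- c("DN_A", "DN_B", "DN_C")

#' Ground truth for a simulated cohort
#'
#' Builds the latent loading matrix, planted module partition, planted limbic
#' sub-clusters, and component identity sets for one of two generative
#' scenarios. In scenario `"merged"` every limbic parcel loads on one of the
#' three default-network latents (DN_A/DN_B/DN_C, by planted sub-cluster)
#' plus a private residual, encoding the extended-default-network hypothesis
#' as generative truth; in `"distinct"` limbic parcels load on a private
#' limbic latent instead.
#'
#' @param atlas A [make_atlas()] atlas.
#' @param scenario `"merged"` or `"distinct"`.
#' @param latent_scheme `"subnetworks"` (default): one latent per 17-network
#'   label, correlated within 7-network groups by shared group factors
#'   (coarse modules at low resolution, subnetwork splits at high); or
#'   `"groups"`: one flat latent per 7-network group with DN split into
#'   DN_A/B/C (the minimal scheme, used e.g. to plant exactly 8 BOLD
#'   sources).
#' @param n_bold Number of BOLD (Delta R2*-like) sources; default the core
#'   latent count of the scheme. Values above it add auxiliary BOLD sources
#'   with sparse subject-specific maps.
#' @param n_artifact Number of artifact (Delta S0-like) sources.
#' @param seed Integer seed for the template maps.
#' @param qc_violations Named list: subject index -> character subset of
#'   `c("fd_dvars", "low_tsnr", "few_components")`.
#' @return A `ground_truth` list.
#' @export
make_ground_truth <- function(atlas, scenario = c("merged", "distinct"),
                              latent_scheme = c("subnetworks", "groups"),
                              n_bold = NULL, n_artifact = 6L, seed = 1L,
                              qc_violations = list()) {
  stopifnot(inherits(atlas, "toy_atlas"))
  scenario <- match.arg(scenario)
  latent_scheme <- match.arg(latent_scheme)
  core <- core_source_names(scenario, latent_scheme)
  if (is.null(n_bold)) n_bold <- length(core)
  n_bold <- as.integer(n_bold)
  n_artifact <- as.integer(n_artifact)
  if (n_bold < length(core)) {
    stop("n_bold must be >= ", length(core), " (core network sources) for ",
         "scenario '", scenario, "', scheme '", latent_scheme, "'")
  }
  ok_types <- c("fd_dvars", "low_tsnr", "few_components")
  if (length(qc_violations) &&
      !all(unlist(qc_violations) %in% ok_types)) {
    stop("qc_violations entries must be subsets of: ",
         paste(ok_types, collapse = ", "))
  }

  set.seed(as.integer(seed))
  P <- nrow(atlas)
  src_names <- c(core, if (n_bold > length(core))
    paste0("AUX", seq_len(n_bold - length(core))))

  L <- matrix(0, P, n_bold, dimnames = list(NULL, src_names))
  grp <- network_group(atlas$network_label)

  lim_idx <- which(atlas$is_limbic)
  lim_clusters <- rep_len(1:3, length(lim_idx))
  names(lim_clusters) <- atlas$parcel_id[lim_idx]

  planted <- character(P)
  for (p in seq_len(P)) {
    g <- grp[p]
    if (g == "LIM") {
      k <- lim_clusters[as.character(atlas$parcel_id[p])]
      if (scenario == "merged") {
        src <- lim_cluster_source[k]
        L[p, src] <- LIM_DN_LOADING
        planted[p] <- "DN"
      } else {
        L[p, "LIM"] <- LIM_DN_LOADING
        planted[p] <- "LIM"
      }
    } else if (g == "SUBCORT") {
      src <- subcortical_source[[latent_scheme]][[atlas$network_label[p]]]
      L[p, src] <- SUBCORT_LOADING
      planted[p] <- network_group(src)
    } else {
      src <- if (latent_scheme == "subnetworks") atlas$network_label[p]
             else if (g == "DN") atlas$network_label[p] else g
      L[p, src] <- NETWORK_LOADING
      planted[p] <- g
    }
  }
  # template auxiliary BOLD and artifact maps (sparse, random); subjects
  # redraw these topographies individually in simulate_subject()
  if (n_bold > length(core)) {
    for (j in seq(length(core) + 1L, n_bold)) {
      on <- stats::runif(P) < AUX_DENSITY
      L[on, j] <- stats::rnorm(sum(on), 0, AUX_SD)
    }
  }
  artifact_maps <- matrix(0, P, n_artifact)
  for (j in seq_len(n_artifact)) {
    on <- stats::runif(P) < ART_DENSITY
    artifact_maps[on, j] <- stats::rnorm(sum(on), 0, ART_SD)
  }

  structure(list(
    scenario = scenario,
    latent_scheme = latent_scheme,
    latent_names = src_names,
    latent_groups = latent_group_of(src_names, latent_scheme),
    latent_loadings = L,
    artifact_maps = artifact_maps,
    bold_component_ids = seq_len(n_bold),
    artifact_component_ids = n_bold + seq_len(n_artifact),
    planted_partition = as.integer(factor(planted, levels = unique(planted))),
    planted_module_names = planted,
    planted_lim_clusters = lim_clusters,
    qc_violations = qc_violations,
    seed = as.integer(seed)
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth: scenario =", x$scenario, "|",
      length(x$bold_component_ids), "BOLD +",
      length(x$artifact_component_ids), "artifact sources |",
      max(x$planted_partition), "planted modules\n")
  invisible(x)
}

#' Per-subject simulation recipe
#'
#' Acquisition and noise parameters for one simulated subject. Defaults
#' follow a standard 3T multi-echo protocol (TEs 13.7/30/47 ms, TR 3 s) at
#' desk scale. Ventral-dropout parcels receive baseline intensity and T2*
#' strictly below the non-dropout median, emulating susceptibility signal
#' loss in orbitofrontal/anterior-temporal cortex.
#'
#' @param atlas A [make_atlas()] atlas.
#' @param seed Integer seed.
#' @param n_timepoints Frames per run.
#' @param TR Repetition time, seconds.
#' @param TEs Echo times, ms, strictly increasing.
#' @param noise_sd Thermal noise sd, raw signal units.
#' @param motion_spike_rate Per-frame probability of a 1 mm motion spike.
#' @param spike_frames Optional explicit spike frames (overrides the rate).
#' @param bold_gain Multiplier on BOLD fluctuation amplitude (pathological
#'   values produce low-TSNR subjects).
#' @param n_bold_subject Number of BOLD sources active for this subject
#'   (default: all in the ground truth; used to plant few-component QC
#'   violators).
#' @return A `subject_recipe` list.
#' @export
make_recipe <- function(atlas, seed, n_timepoints = 400L, TR = 3,
                        TEs = c(13.7, 30, 47), noise_sd = 3,
                        motion_spike_rate = 0, spike_frames = NULL,
                        bold_gain = 1, n_bold_subject = NULL) {
  stopifnot(inherits(atlas, "toy_atlas"))
  if (any(diff(TEs) <= 0) || any(TEs <= 0)) {
    stop("TEs must be strictly increasing and positive")
  }
  set.seed(as.integer(seed))
  P <- nrow(atlas)
  S0 <- stats::rnorm(P, 1000, 50)
  T2s <- stats::rnorm(P, 45, 4)
  drop <- atlas$is_ventral_dropout
  if (any(drop)) {
    S0[drop] <- pmin(stats::rnorm(sum(drop), 600, 40),
                     0.9 * stats::median(S0[!drop]))
    T2s[drop] <- pmin(stats::rnorm(sum(drop), 22, 2),
                      0.9 * stats::median(T2s[!drop]))
  }
  S0 <- pmax(S0, 50)
  T2s <- pmax(T2s, 5)
  structure(list(
    seed = as.integer(seed), n_timepoints = as.integer(n_timepoints),
    TR = TR, TEs = TEs, noise_sd = noise_sd,
    motion_spike_rate = motion_spike_rate, spike_frames = spike_frames,
    bold_gain = bold_gain, n_bold_subject = n_bold_subject,
    S0_map = S0, T2star_map = T2s
  ), class = "subject_recipe")
}

# AR(1) series with unit-variance Laplace innovations, unit marginal variance
ar1_laplace <- function(n, k, phi = 0.3) {
  if (k == 0) return(matrix(0, n, 0))
  innov <- matrix((stats::rexp(n * k) - stats::rexp(n * k)) / sqrt(2), n, k)
  x <- apply(innov, 2, function(e) {
    as.numeric(stats::filter(e * sqrt(1 - phi^2), phi,
                             method = "recursive"))
  })
  matrix(x, n, k)
}

#' Simulate one multi-echo run
#'
#' Generates per-echo parcel-by-time signal under the mono-exponential decay
#' model with TE-scaled BOLD (Delta R2*-like) fluctuations, TE-flat artifact
#' (Delta S0-like) fluctuations, thermal noise, and a motion parameter series
#' with optional 1 mm spikes. Motion spikes co-inject a TE-flat signal
#' transient plus a jolt to the BOLD latents, so framewise displacement and
#' DVARS co-occur as the quality-control conjunction rule assumes.
#'
#' @param atlas,truth,recipe Atlas, [make_ground_truth()] truth, and
#'   [make_recipe()] recipe with matching parcel counts.
#' @param subject_id Subject identifier.
#' @return A `multi_echo_run`: `TEs`, `TR`, `data` (echo x parcel x time
#'   array), `motion` (time x 6: translations mm, rotations rad),
#'   `subject_id`, and generator `internals` (sources, maps, clean BOLD
#'   percent signal, spike frames).
#' @export
simulate_subject <- function(atlas, truth, recipe, subject_id = "sub-01") {
  stopifnot(inherits(atlas, "toy_atlas"), inherits(truth, "ground_truth"),
            inherits(recipe, "subject_recipe"))
  P <- nrow(atlas)
  if (nrow(truth$latent_loadings) != P) {
    stop("atlas and ground truth disagree on parcel count")
  }
  if (length(recipe$S0_map) != P) {
    stop("atlas and recipe disagree on parcel count")
  }
  if (anyNA(recipe$S0_map) || anyNA(recipe$T2star_map)) {
    stop("NaN in S0/T2* map")
  }
  if (any(recipe$T2star_map <= 0)) stop("negative or zero T2* in map")

  set.seed(recipe$seed)
  Tn <- recipe$n_timepoints
  TEs <- recipe$TEs
  E <- length(TEs)

  n_bold_all <- length(truth$bold_component_ids)
  n_bold <- if (is.null(recipe$n_bold_subject)) n_bold_all else
    as.integer(recipe$n_bold_subject)
  n_core <- length(core_source_names(truth$scenario, truth$latent_scheme))
  if (n_bold < 2L || n_bold > n_bold_all) {
    stop("n_bold_subject must be in [2, ", n_bold_all, "]")
  }
  n_art <- length(truth$artifact_component_ids)

  # subject-level jitter of the planted network loadings; auxiliary BOLD
  # and artifact topographies are drawn fresh per subject (individual
  # nuisance anatomy) so they carry no shared structure into group averages
  n_core_cols <- min(n_core, n_bold)
  L <- truth$latent_loadings[, seq_len(n_bold), drop = FALSE]
  jit <- matrix(1 + 0.05 * stats::rnorm(length(L)), nrow(L), ncol(L))
  L <- L * jit
  if (n_bold > n_core_cols) {
    for (j in seq(n_core_cols + 1L, n_bold)) {
      L[, j] <- 0
      on <- stats::runif(P) < AUX_DENSITY
      L[on, j] <- stats::rnorm(sum(on), 0, AUX_SD)
    }
  }
  M <- matrix(0, P, n_art)
  for (j in seq_len(n_art)) {
    on <- stats::runif(P) < ART_DENSITY
    M[on, j] <- stats::rnorm(sum(on), 0, ART_SD)
  }

  # BOLD latents: unit-variance AR(1); in the subnetworks scheme each latent
  # shares a 7-network group factor (within-group latent correlation =
  # GROUP_COHERENCE^2), so low-resolution community detection sees coarse
  # networks and high resolution splits the subnetworks
  own <- ar1_laplace(Tn, n_bold)
  grp_lat <- truth$latent_groups[seq_len(n_bold)]
  has_grp <- !is.na(grp_lat)
  bold_src <- own
  if (any(has_grp)) {
    grp_ids <- unique(grp_lat[has_grp])
    G <- ar1_laplace(Tn, length(grp_ids))
    h <- GROUP_COHERENCE
    bold_src[, has_grp] <- h * G[, match(grp_lat[has_grp], grp_ids),
                                 drop = FALSE] +
      sqrt(1 - h^2) * own[, has_grp, drop = FALSE]
  }
  art_src <- ar1_laplace(Tn, n_art)
  private <- ar1_laplace(Tn, P)

  # motion: slow random walk
  motion <- cbind(
    apply(matrix(stats::rnorm(Tn * 3, 0, 0.02), Tn, 3), 2, cumsum),
    apply(matrix(stats::rnorm(Tn * 3, 0, 4e-4), Tn, 3), 2, cumsum)
  )
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")

  spike_frames <- recipe$spike_frames
  if (is.null(spike_frames) && recipe$motion_spike_rate > 0) {
    spike_frames <- which(stats::runif(Tn) < recipe$motion_spike_rate)
    spike_frames <- spike_frames[spike_frames > 1]
  }
  cS0 <- (ARTIFACT_AMP * M) %*% t(art_src)
  if (length(spike_frames)) {
    motion[spike_frames, 1] <- motion[spike_frames, 1] + 1.0
    cS0[, spike_frames] <- cS0[, spike_frames] + 0.03
    bold_src[spike_frames, ] <- bold_src[spike_frames, ] + 4
  }

  cR2 <- recipe$bold_gain * BOLD_AMP *
    (L %*% t(bold_src) + PRIVATE_SD * t(private))

  decay <- recipe$S0_map * exp(-outer(recipe$T2star_map, TEs,
                                      function(t2, te) te / t2))
  data <- array(0, dim = c(E, P, Tn),
                dimnames = list(paste0("echo", seq_len(E)), NULL, NULL))
  for (e in seq_len(E)) {
    clean_e <- decay[, e] * (1 + (TEs[e] / TE_SCALE) * cR2 + cS0)
    data[e, , ] <- clean_e +
      matrix(stats::rnorm(P * Tn, 0, recipe$noise_sd), P, Tn)
  }
  if (anyNA(data)) stop("NaN produced in simulated signal")

  structure(list(
    TEs = TEs, TR = recipe$TR, data = data, motion = motion,
    subject_id = subject_id,
    internals = list(
      bold_sources = bold_src, bold_maps = L,
      artifact_sources = art_src, artifact_maps = M,
      clean_bold = cR2, cS0 = cS0,
      spike_frames = if (length(spike_frames)) spike_frames else integer(0),
      n_bold = n_bold
    )
  ), class = "multi_echo_run")
}

#' @export
print.multi_echo_run <- function(x, ...) {
  d <- dim(x$data)
  cat("Multi-echo run", x$subject_id, ":", d[1], "echoes x", d[2],
      "parcels x", d[3], "frames; TEs =", paste(x$TEs, collapse = "/"),
      "ms, TR =", x$TR, "s\n")
  invisible(x)
}

#' Simulate a multi-echo cohort with shared planted structure
#'
#' Subjects share the ground-truth loading pattern (jittered per subject) and
#' the planted module partition; per-subject seeds are derived
#' deterministically from `master_seed`. Quality-control violations can be
#' planted for named subjects: `"fd_dvars"` (two 1 mm motion spikes with
#' matched signal transients), `"low_tsnr"` (pathological BOLD amplitude
#' inflation so the denoised series fails the TSNR >= 50 rule), and
#' `"few_components"` (only 9 active BOLD sources).
#'
#' @param n_subjects Number of subjects, at least 2.
#' @param scenario `"merged"` or `"distinct"`.
#' @param master_seed Integer master seed.
#' @param atlas Optional atlas; default `make_atlas(102, 7, seed = master_seed)`.
#' @param latent_scheme,n_bold,n_artifact Planted source structure (see
#'   [make_ground_truth()]).
#' @param qc_violations Named list, subject index -> violation types.
#' @param ... Further arguments passed to [make_recipe()].
#' @return An `me_cohort`: list of runs plus `truth`, `atlas`, `scenario`.
#' @export
simulate_cohort <- function(n_subjects, scenario = c("merged", "distinct"),
                            master_seed = 1L, atlas = NULL,
                            latent_scheme = c("subnetworks", "groups"),
                            n_bold = NULL, n_artifact = 6L,
                            qc_violations = list(), ...) {
  scenario <- match.arg(scenario)
  latent_scheme <- match.arg(latent_scheme)
  if (n_subjects < 2) stop("n_subjects must be >= 2 (group statistics undefined)")
  master_seed <- as.integer(master_seed)
  if (is.null(atlas)) atlas <- make_atlas(102, 7, seed = master_seed)
  truth <- make_ground_truth(atlas, scenario, latent_scheme = latent_scheme,
                             n_bold = n_bold,
                             n_artifact = n_artifact, seed = master_seed,
                             qc_violations = qc_violations)
  runs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    seed_i <- (master_seed %% 100000L) * 10007L + 7919L * i
    viol <- qc_violations[[as.character(i)]]
    rec <- make_recipe(
      atlas, seed = seed_i,
      spike_frames = if ("fd_dvars" %in% viol) {
        Tn <- list(...)$n_timepoints
        if (is.null(Tn)) Tn <- 400L
        c(round(Tn / 3), round(2 * Tn / 3))
      } else NULL,
      bold_gain = if ("low_tsnr" %in% viol) 15 else 1,
      n_bold_subject = if ("few_components" %in% viol) 9L else NULL,
      ...
    )
    runs[[i]] <- simulate_subject(atlas, truth, rec,
                                  subject_id = sprintf("sub-%02d", i))
  }
  structure(list(runs = runs, truth = truth, atlas = atlas,
                 scenario = scenario, master_seed = master_seed),
            class = "me_cohort")
}

#' @export
print.me_cohort <- function(x, ...) {
  cat("Multi-echo cohort:", length(x$runs), "subjects, scenario =",
      x$scenario, "\n")
  print(x$atlas)
  invisible(x)
}
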