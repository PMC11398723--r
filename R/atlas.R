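#' Cortical and subcortical network labels
#'
#' The 17 cortical network labels and 7 subcortical structure labels used by
#' the toy parcellation. Cortical labels follow the 17-network naming
#' convention (two visual, two somatomotor, two dorsal-attention, two
#' salience, three frontoparietal, three default, temporoparietal, and two
#' limbic subnetworks); subcortical labels name individual structures.
#'
#' @format Character vectors.
#' @name network_labels
NULL

#' @rdname network_labels
#' @export
CORTICAL_NETWORKS <- c(
  "VIS_A", "VIS_B", "SMN_A", "SMN_B", "DAN_A", "DAN_B", "SAL_A", "SAL_B",
  "FPN_A", "FPN_B", "FPN_C", "DN_A", "DN_B", "DN_C", "TPar", "LIM_A", "LIM_B"
)

#' @rdname network_labels
#' @export
SUBCORTICAL_STRUCTURES <- c("HIP", "AMY", "NAC", "GP", "PUT", "CAU", "BF")

#' Build a toy parcellation atlas
#'
#' Constructs a desk-scale stand-in for a 1,000-region cortical parcellation
#' with 17 network labels plus bilateral subcortical structures. Parcels are
#' assigned to labels round-robin so every label is covered, and hemispheres
#' alternate L/R within each label (subcortical labels are treated as
#' bilateral pairs when the count allows). Limbic parcels (`LIM_A`, `LIM_B`)
#' are flagged both as limbic and as ventral signal-dropout regions (short
#' T2*), mimicking the susceptibility-related signal loss of orbitofrontal
#' and anterior temporal cortex.
#'
#' @param P_cortical Number of cortical parcels; at least 34 (two per
#'   cortical network).
#' @param P_subcortical Number of subcortical parcels; at least 7 (one per
#'   structure).
#' @param seed Integer seed; the atlas is deterministic for a fixed seed.
#' @return A `toy_atlas` data frame with columns `parcel_id`, `hemisphere`,
#'   `network_label`, `is_cortical`, `is_limbic`, `is_ventral_dropout`.
#' @examples
#' atlas <- make_atlas(34, 7, seed = 1)
#' table(atlas$network_label)
#' @export
make_atlas <- function(P_cortical, P_subcortical, seed = 1L) {
  stopifnot(length(P_cortical) == 1, length(P_subcortical) == 1)
  P_cortical <- as.integer(P_cortical)
  P_subcortical <- as.integer(P_subcortical)

  n_cort_lab <- length(CORTICAL_NETWORKS)
  if (P_cortical < 2L * n_cort_lab) {
    # report which labels would be left with fewer than 2 parcels
    covered <- rep(CORTICAL_NETWORKS, length.out = max(P_cortical, 0))
    short <- CORTICAL_NETWORKS[tabulate(match(covered, CORTICAL_NETWORKS),
                                        nbins = n_cort_lab) < 2L]
    stop("P_cortical = ", P_cortical, " cannot cover all 17 networks with ",
         ">= 2 parcels each; under-covered: ", paste(short, collapse = ", "))
  }
  if (P_subcortical < length(SUBCORTICAL_STRUCTURES)) {
    covered <- rep(SUBCORTICAL_STRUCTURES, length.out = max(P_subcortical, 0))
    missing_lab <- setdiff(SUBCORTICAL_STRUCTURES, covered)
    stop("P_subcortical = ", P_subcortical, " cannot cover all subcortical ",
         "structures; missing: ", paste(missing_lab, collapse = ", "))
  }

  set.seed(as.integer(seed))
  cort_lab <- rep(CORTICAL_NETWORKS, length.out = P_cortical)
  cort_lab <- cort_lab[order(match(cort_lab, CORTICAL_NETWORKS))]
  sub_lab <- rep(SUBCORTICAL_STRUCTURES, length.out = P_subcortical)
  sub_lab <- sub_lab[order(match(sub_lab, SUBCORTICAL_STRUCTURES))]

  labels <- c(cort_lab, sub_lab)
  P <- length(labels)
  hemi <- unlist(lapply(split(seq_len(P), factor(labels, levels = unique(labels))),
                        function(idx) rep(c("L", "R"), length.out = length(idx))),
                 use.names = FALSE)
  # restore original order (split() groups by label, but labels are already
  # grouped contiguously so ordering is preserved)
  atlas <- data.frame(
    parcel_id = seq_len(P),
    hemisphere = hemi,
    network_label = labels,
    is_cortical = c(rep(TRUE, P_cortical), rep(FALSE, P_subcortical)),
    stringsAsFactors = FALSE
  )
  atlas$is_limbic <- atlas$network_label %in% c("LIM_A", "LIM_B")
  atlas$is_ventral_dropout <- atlas$is_limbic
  class(atlas) <- c("toy_atlas", "data.frame")
  attr(atlas, "seed") <- as.integer(seed)
  atlas
}

#' @export
print.toy_atlas <- function(x, ...) {
  cat("Toy atlas:", nrow(x), "parcels (",
      sum(x$is_cortical), "cortical,", sum(!x$is_cortical), "subcortical ),",
      sum(x$is_limbic), "limbic\n")
  invisible(x)
}

#' Seven-network warm-start labels
#'
#' Collapses the 17-network atlas labels to a 7-network-style initial
#' assignment for community detection warm starts: VIS, SMN, DAN, SAL, FPN,
#' DN, and LIM kept separate, plus one module for subcortex. The
#' temporoparietal network is grouped with somatomotor (its auditory-adjacent
#' home in this toy signal model). Module ids are contiguous integers.
#'
#' @param atlas A [make_atlas()] atlas.
#' @return Integer vector of initial module ids, one per parcel.
#' @export
yeo7_init <- function(atlas) {
  stopifnot(inherits(atlas, "toy_atlas"))
  grp <- network_group(atlas$network_label)
  as.integer(factor(grp, levels = unique(grp)))
}

# 17-network label -> coarse group used for warm starts and planted modules
network_group <- function(label) {
  map <- c(
    VIS_A = "VIS", VIS_B = "VIS", SMN_A = "SMN", SMN_B = "SMN",
    DAN_A = "DAN", DAN_B = "DAN", SAL_A = "SAL", SAL_B = "SAL",
    FPN_A = "FPN", FPN_B = "FPN", FPN_C = "FPN",
    DN_A = "DN", DN_B = "DN", DN_C = "DN",
    TPar = "SMN", LIM_A = "LIM", LIM_B = "LIM"
  )
  out <- unname(map[label])
  out[is.na(out)] <- "SUBCORT"
  out
}
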