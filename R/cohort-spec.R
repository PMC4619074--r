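#' @include AllClasses.R
NULL

#' Planted hub specification
#'
#' Describes one planted hub-and-spoke dependence structure: a single latent
#' variable per hub drives the hub feature and every spoke feature through a
#' relationship function plus independent noise, so that hub--spoke pairs are
#' strongly associated (Pearson-detectable for `"linear"`, MIC-only for
#' `"quadratic"` and `"sinusoid"`).
#'
#' @param hub_feature feature id of the hub.
#' @param hub_platform platform of the hub feature.
#' @param spokes `data.frame` with columns `feature` and `platform`; at least
#'   4 spokes spanning at least 2 platforms (so a recovered hub can satisfy
#'   the four-or-more-neighbor hub criterion on cross-platform edges).
#' @param relationship one of `"linear"`, `"quadratic"`, `"sinusoid"`.
#' @param effect_size latent-factor loading (in units of the latent's sd).
#' @param driven_by `"histology_latent"` (latent = numeric histology code
#'   plus noise, so the hub separates histology groups) or
#'   `"independent_latent"` (standard normal).
#' @return a validated `hubSpec` list.
#' @export
hubSpec <- function(hub_feature, hub_platform, spokes,
                    relationship = c("linear", "quadratic", "sinusoid"),
                    effect_size = 2,
                    driven_by = c("histology_latent", "independent_latent")) {
  relationship <- match.arg(relationship)
  driven_by <- match.arg(driven_by)
  spokes <- as.data.frame(spokes)
  stopifnot(all(c("feature", "platform") %in% colnames(spokes)))
  if (nrow(spokes) < 4L) {
    stop("a planted hub needs at least 4 spokes")
  }
  if (length(unique(c(spokes$platform, hub_platform))) < 2L) {
    stop("hub and spokes must span at least 2 platforms")
  }
  if (effect_size <= 0) stop("effect_size must be positive")
  structure(
    list(
      hub_feature = hub_feature, hub_platform = hub_platform,
      spokes = spokes, relationship = relationship,
      effect_size = effect_size, driven_by = driven_by
    ),
    class = "hubSpec"
  )
}

.defaultHistologyCounts <- c(
  normal_adjacent = 4, teratoma = 17, dysgerminoma = 8, yst = 8, mixed = 3
)

.defaultHubSpecs <- function(noise_sd = 1) {
  list(hubSpec(
    hub_feature = "SCG001", hub_platform = "stemcell",
    spokes = data.frame(
      feature = c("cg0101", "cg0102", "cg0103", "miR-0001", "miR-0002", "miR-0003"),
      platform = c(rep("methylation", 3), rep("mirna", 3))
    ),
    relationship = "linear", effect_size = 2 * noise_sd,
    driven_by = "histology_latent"
  ))
}

#' Synthetic cohort specification
#'
#' Defaults emulate the study design the pipeline targets: a complete-data
#' cohort of 40 samples over five histology classes (8 yolk sac tumor, 17
#' teratoma, 8 dysgerminoma, 3 mixed, 4 normal-adjacent), 1505 CpG loci (16
#' detection-failed, 84 X-linked, disjoint by construction so 1405 survive
#' QC), 800 miRNAs with 6 positive and 6 negative control probes, an 84-gene
#' qPCR panel with 5 housekeeping genes, and 4 SNPs drawn from Hardy-Weinberg
#' equilibrium at allele frequency 0.3. One linear 6-spoke cross-platform hub
#' is planted by default.
#'
#' @param n_samples total samples; must equal `sum(histology_counts)`.
#' @param histology_counts named integer vector over the five histology
#'   levels.
#' @param n_cpg,n_x_linked,n_detection_fail methylation panel sizes; the
#'   X-linked and detection-fail locus sets are disjoint unless
#'   `allow_flag_overlap`.
#' @param n_mirna,n_pos_controls,n_neg_controls miRNA panel sizes.
#' @param n_genes,n_housekeeping qPCR panel sizes.
#' @param hub_specs list of [hubSpec()] entries (possibly empty).
#' @param noise_sd spoke noise sd on the latent scale.
#' @param seed integer seed; generation is deterministic given the spec.
#' @param allele_freq per-SNP frequency of the first allele.
#' @param exclude_samples named list, platform -> sample ids to blank out
#'   (simulates per-platform incomplete data).
#' @param allow_flag_overlap allow the detection-fail and X-linked locus sets
#'   to overlap (stress testing only).
#' @return a validated `cohortSpec` list.
#' @examples
#' spec <- cohortSpec(seed = 7)
#' spec$n_cpg
#' @export
cohortSpec <- function(n_samples = 40,
                       histology_counts = .defaultHistologyCounts,
                       n_cpg = 1505, n_x_linked = 84, n_detection_fail = 16,
                       n_mirna = 800, n_pos_controls = 6, n_neg_controls = 6,
                       n_genes = 84, n_housekeeping = 5,
                       hub_specs = .defaultHubSpecs(noise_sd),
                       noise_sd = 1, seed = 1,
                       allele_freq = 0.3,
                       exclude_samples = list(),
                       allow_flag_overlap = FALSE) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  spec <- structure(
    list(
      n_samples = n_samples, histology_counts = histology_counts,
      n_cpg = n_cpg, n_x_linked = n_x_linked,
      n_detection_fail = n_detection_fail,
      n_mirna = n_mirna, n_pos_controls = n_pos_controls,
      n_neg_controls = n_neg_controls,
      n_genes = n_genes, n_housekeeping = n_housekeeping,
      hub_specs = hub_specs, noise_sd = noise_sd, seed = seed,
      allele_freq = allele_freq, exclude_samples = exclude_samples,
      allow_flag_overlap = allow_flag_overlap
    ),
    class = "cohortSpec"
  )
  validateCohortSpec(spec)
  spec
}

#' Validate a cohort spec
#'
#' @param spec a [cohortSpec()] list.
#' @return the spec, invisibly; signals an error for an infeasible spec.
#' @export
validateCohortSpec <- function(spec) {
  counts <- c(
    spec$n_samples, spec$n_cpg, spec$n_mirna, spec$n_pos_controls,
    spec$n_neg_controls, spec$n_genes, spec$n_housekeeping
  )
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("all panel counts must be positive integers")
  }
  if (spec$n_x_linked < 0 || spec$n_detection_fail < 0) {
    stop("flag counts must be nonnegative")
  }
  if (!spec$allow_flag_overlap &&
      spec$n_x_linked + spec$n_detection_fail > spec$n_cpg) {
    stop("infeasible spec: n_x_linked + n_detection_fail exceeds n_cpg")
  }
  hc <- spec$histology_counts
  if (!all(names(hc) %in% .HISTOLOGIES)) {
    stop("unknown histology level in histology_counts")
  }
  if (sum(hc) != spec$n_samples) {
    stop("histology counts must sum to n_samples")
  }
  if (spec$noise_sd <= 0) stop("noise_sd must be positive")
  for (h in spec$hub_specs) {
    if (!inherits(h, "hubSpec")) stop("hub_specs entries must be hubSpec()")
  }
  invisible(spec)
}
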