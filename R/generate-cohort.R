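#' @include cohort-spec.R
NULL

.SNP_ALLELES <- list(
  SPRY4_rs4324715 = c("a", "g"),
  BAK1_rs210138 = c("c", "t"),
  DMRT1_rs755383 = c("a", "c"),
  KITLG_rs4474514 = c("g", "t")
)

.AGE_RANGES <- list(
  normal_adjacent = c(1, 19), teratoma = c(0, 21), dysgerminoma = c(7, 45),
  yst = c(0, 19), mixed = c(0, 14)
)

.FEMALE_PROB <- c(
  normal_adjacent = 0.7, teratoma = 0.8, dysgerminoma = 1, yst = 0.5,
  mixed = 0.25
)

# latent relationship functions; input is the standardized latent
.relationshipFun <- function(relationship) {
  switch(relationship,
    linear = function(z) z,
    quadratic = function(z) as.numeric(scale(z^2)),
    sinusoid = function(z) as.numeric(scale(sin(1.5 * pi * z)))
  )
}

#' Generate a seeded synthetic multi-platform cohort
#'
#' Draws a complete multi-platform cohort with the marginal structure the
#' pipeline assumes -- logit-normal methylation beta values with detection
#' p-values and X-linked flags, negative-binomial miRNA counts with
#' positive-control ladder and negative-control background rows under a
#' per-sample lane factor, qPCR Ct panels with housekeeping genes and a
#' per-sample plate shift, Hardy-Weinberg genotypes, and sample annotations
#' -- and plants the hub-and-spoke dependence structure requested by
#' `spec$hub_specs` through one latent variable per hub. Exactly
#' `spec$n_detection_fail` loci fail detection QC (p > 0.05 in at least 25
#' percent of samples) and exactly `spec$n_x_linked` disjoint loci carry the
#' X-linked flag, so the default 1505-locus panel retains 1405 loci after
#' filtering. Generation is deterministic given the spec (including its
#' seed).
#'
#' @param spec a [cohortSpec()].
#' @return a [SyntheticCohort-class].
#' @examples
#' cohort <- generateCohort(cohortSpec(
#'   n_samples = 12,
#'   histology_counts = c(
#'     normal_adjacent = 2, teratoma = 4, dysgerminoma = 2, yst = 3, mixed = 1
#'   ),
#'   n_cpg = 30, n_x_linked = 4, n_detection_fail = 2, n_mirna = 20,
#'   n_genes = 10, hub_specs = list(), seed = 11
#' ))
#' cohort
#' @export
generateCohort <- function(spec = cohortSpec()) {
  validateCohortSpec(spec)
  set.seed(spec$seed)
  n <- spec$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))

  ## ---- annotations -------------------------------------------------------
  histology <- rep(names(spec$histology_counts), spec$histology_counts)
  age <- numeric(n)
  sex <- character(n)
  for (h in unique(histology)) {
    idx <- which(histology == h)
    rg <- .AGE_RANGES[[h]]
    age[idx] <- round(runif(length(idx), rg[1], rg[2]), 1)
    sex[idx] <- ifelse(runif(length(idx)) < .FEMALE_PROB[[h]], "female", "male")
  }
  location <- ifelse(
    sex == "female",
    ifelse(runif(n) < 0.6, "ovary", "extragonadal"),
    ifelse(runif(n) < 0.5, "testis", "extragonadal")
  )
  annotations <- data.frame(
    sample_id = sample_ids, age_years = age, sex = sex,
    location = location, histology = histology,
    age_group = ifelse(age < 10, "<10", ">=10"),
    stringsAsFactors = FALSE
  )

  ## ---- planted latent signals -------------------------------------------
  hist_code <- defaultEncodingConfig()$histology_codes[histology]
  planted <- list()  # per platform: feature -> signal vector
  for (p in .PLATFORMS) planted[[p]] <- list()
  truth_edges <- list()
  truth_hubs <- list()
  for (hub in spec$hub_specs) {
    z <- if (hub$driven_by == "histology_latent") {
      hist_code + rnorm(n, 0, 0.5)
    } else {
      rnorm(n)
    }
    z <- as.numeric(scale(z))
    f <- .relationshipFun(hub$relationship)
    hub_sig <- hub$effect_size * z + rnorm(n, 0, 0.25 * spec$noise_sd)
    planted[[hub$hub_platform]][[hub$hub_feature]] <- hub_sig
    truth_hubs[[length(truth_hubs) + 1L]] <- list(
      feature = hub$hub_feature, platform = hub$hub_platform
    )
    for (k in seq_len(nrow(hub$spokes))) {
      sp_feat <- hub$spokes$feature[k]
      sp_plat <- hub$spokes$platform[k]
      eps <- if (sp_plat == "mirna") 0 else rnorm(n, 0, spec$noise_sd)
      planted[[sp_plat]][[sp_feat]] <- hub$effect_size * f(z) + eps
      truth_edges[[length(truth_edges) + 1L]] <- list(
        feature_a = hub$hub_feature, platform_a = hub$hub_platform,
        feature_b = sp_feat, platform_b = sp_plat,
        relationship = hub$relationship
      )
    }
  }

  ## ---- methylation -------------------------------------------------------
  cpg_ids <- sprintf("cg%04d", seq_len(spec$n_cpg))
  gene_pool <- sprintf("GENE%04d", seq_len(807))
  cpg_genes <- rep_len(gene_pool, spec$n_cpg)
  fail_idx <- seq_len(spec$n_detection_fail)
  x_start <- if (spec$allow_flag_overlap) 1L else spec$n_detection_fail + 1L
  x_idx <- seq(x_start, length.out = spec$n_x_linked)
  chr_x <- rep(FALSE, spec$n_cpg)
  chr_x[x_idx] <- TRUE

  comp <- sample(c(-2.5, 0, 2.5), spec$n_cpg, replace = TRUE,
                 prob = c(0.4, 0.2, 0.4))
  logit_mean <- comp + rnorm(spec$n_cpg, 0, 0.5)
  logit <- matrix(
    logit_mean + rnorm(spec$n_cpg * n, 0, 0.6),
    nrow = spec$n_cpg, ncol = n,
    dimnames = list(cpg_ids, sample_ids)
  )
  for (feat in names(planted$methylation)) {
    if (!feat %in% cpg_ids) stop("planted methylation locus not in panel: ", feat)
    logit[feat, ] <- rnorm(1, 0, 0.3) + 0.35 * planted$methylation[[feat]] +
      rnorm(n, 0, 0.15)
  }
  beta <- plogis(logit)

  detection_p <- matrix(
    runif(spec$n_cpg * n, 0, 0.04),
    nrow = spec$n_cpg, ncol = n, dimnames = list(cpg_ids, sample_ids)
  )
  n_fail_samples <- ceiling(0.3 * n)  # >= the 25 percent QC fraction
  for (i in fail_idx) {
    bad <- sample.int(n, n_fail_samples)
    detection_p[i, bad] <- runif(n_fail_samples, 0.1, 0.6)
  }

  methylation <- OmicsBlock(
    beta, "methylation",
    featureMeta = data.frame(gene_symbol = cpg_genes, chr_x = chr_x)
  )

  ## ---- miRNA -------------------------------------------------------------
  mir_ids <- sprintf("miR-%04d", seq_len(spec$n_mirna))
  lane <- exp(rnorm(n, 0, 0.15))
  base_mu <- exp(rnorm(spec$n_mirna, log(100), 1.2))
  disp <- exp(runif(spec$n_mirna, log(0.05), log(0.5)))
  log_shift <- matrix(0, spec$n_mirna, n, dimnames = list(mir_ids, NULL))
  for (feat in names(planted$mirna)) {
    if (!feat %in% mir_ids) stop("planted miRNA not in panel: ", feat)
    base_mu[match(feat, mir_ids)] <- 800
    disp[match(feat, mir_ids)] <- 0.05
    log_shift[feat, ] <- 0.25 * planted$mirna[[feat]]
  }
  mu <- outer(base_mu, lane) * exp(log_shift)
  counts <- matrix(
    rnbinom(spec$n_mirna * n, mu = mu, size = rep(1 / disp, n)),
    nrow = spec$n_mirna, ncol = n, dimnames = list(mir_ids, sample_ids)
  )

  pos_ids <- sprintf("POS_%s", LETTERS[seq_len(spec$n_pos_controls)])
  ladder <- 16384 / 4^(seq_len(spec$n_pos_controls) - 1)
  pos <- matrix(
    pmax(1, rpois(spec$n_pos_controls * n, lambda = outer(ladder, lane))),
    nrow = spec$n_pos_controls, ncol = n,
    dimnames = list(pos_ids, sample_ids)
  )
  neg_ids <- sprintf("NEG_%s", LETTERS[seq_len(spec$n_neg_controls)])
  neg <- matrix(
    rpois(spec$n_neg_controls * n, 2),
    nrow = spec$n_neg_controls, ncol = n,
    dimnames = list(neg_ids, sample_ids)
  )
  mirna <- OmicsBlock(
    rbind(counts, pos, neg), "mirna",
    featureMeta = data.frame(
      gene_symbol = c(toupper(gsub("-", "", mir_ids)),
                      rep(NA_character_, length(pos_ids) + length(neg_ids))),
      control_role = c(rep("none", spec$n_mirna),
                       rep("positive", spec$n_pos_controls),
                       rep("negative", spec$n_neg_controls))
    )
  )

  ## ---- stem cell qPCR ----------------------------------------------------
  gene_ids <- sprintf("SCG%03d", seq_len(spec$n_genes))
  hk_ids <- sprintf("HK%d", seq_len(spec$n_housekeeping))
  plate <- rnorm(n, 0, 0.7)
  gene_base <- runif(spec$n_genes, 22, 30)
  ct <- matrix(
    gene_base + rep(plate, each = spec$n_genes) +
      rnorm(spec$n_genes * n, 0, 0.4),
    nrow = spec$n_genes, ncol = n, dimnames = list(gene_ids, sample_ids)
  )
  for (feat in names(planted$stemcell)) {
    if (!feat %in% gene_ids) stop("planted qPCR gene not in panel: ", feat)
    ct[feat, ] <- runif(1, 24, 28) + plate - 0.8 * planted$stemcell[[feat]]
  }
  hk_base <- runif(spec$n_housekeeping, 18, 22)
  hk <- matrix(
    hk_base + rep(plate, each = spec$n_housekeeping) +
      rnorm(spec$n_housekeeping * n, 0, 0.1),
    nrow = spec$n_housekeeping, ncol = n, dimnames = list(hk_ids, sample_ids)
  )
  stemcell <- OmicsBlock(
    rbind(ct, hk), "stemcell",
    featureMeta = data.frame(
      gene_symbol = c(gene_ids, hk_ids),
      control_role = c(rep("none", spec$n_genes),
                       rep("housekeeping", spec$n_housekeeping))
    )
  )

  ## ---- genotypes (Hardy-Weinberg) ---------------------------------------
  genotypes <- matrix(
    NA_character_, length(.SNP_ALLELES), n,
    dimnames = list(names(.SNP_ALLELES), sample_ids)
  )
  for (s in names(.SNP_ALLELES)) {
    al <- .SNP_ALLELES[[s]]
    n_first <- rbinom(n, 2, spec$allele_freq)
    genotypes[s, ] <- vapply(n_first, function(k) {
      paste(sort(c(rep(al[1], k), rep(al[2], 2 - k))), collapse = "/")
    }, character(1))
  }

  ## ---- per-platform missingness -----------------------------------------
  blocks <- list(
    methylation = methylation, mirna = mirna, stemcell = stemcell
  )
  for (p in names(spec$exclude_samples)) {
    drop <- intersect(spec$exclude_samples[[p]], sample_ids)
    if (p == "genotype") {
      genotypes[, drop] <- NA_character_
    } else if (p %in% names(blocks)) {
      v <- blockValues(blocks[[p]])
      v[, drop] <- NA_real_
      SummarizedExperiment::assay(blocks[[p]], "values") <- v
    }
  }

  new("SyntheticCohort",
    methylation = blocks$methylation, detectionP = detection_p,
    mirna = blocks$mirna, stemcell = blocks$stemcell,
    genotypes = genotypes, annotations = annotations,
    truth = list(
      planted_edges = truth_edges, planted_hubs = truth_hubs,
      seed = spec$seed
    ),
    spec = unclass(spec)
  )
}

#' Reduced-scale cohort spec for simulation studies
#'
#' The full default panel (1505 CpG loci, 800 miRNAs) yields about 2.6
#' million feature pairs; repeated-seed simulation studies (hub recovery,
#' null calibration) instead use this reduced panel -- 60 CpG loci, 40
#' miRNAs, 20 qPCR genes, the same 40-sample design -- which preserves every
#' structural property under test while keeping an all-pairs MIC scan to a
#' few thousand pairs.
#'
#' @param seed integer seed.
#' @param with_hub plant the default linear 6-spoke cross-platform hub
#'   (`TRUE`) or generate a fully independent null cohort (`FALSE`).
#' @param n_cpg,n_x_linked,n_detection_fail,n_mirna,n_genes reduced panel
#'   sizes.
#' @param ... passed on to [cohortSpec()].
#' @return a [cohortSpec()].
#' @export
smallCohortSpec <- function(seed = 1, with_hub = TRUE, n_cpg = 60,
                            n_x_linked = 6, n_detection_fail = 4,
                            n_mirna = 40, n_genes = 20, ...) {
  hubs <- if (with_hub) {
    list(hubSpec(
      hub_feature = "SCG001", hub_platform = "stemcell",
      spokes = data.frame(
        feature = c("cg0021", "cg0022", "cg0023",
                    "miR-0001", "miR-0002", "miR-0003"),
        platform = c(rep("methylation", 3), rep("mirna", 3))
      ),
      relationship = "linear", effect_size = 2, driven_by = "histology_latent"
    ))
  } else {
    list()
  }
  cohortSpec(
    n_cpg = n_cpg, n_x_linked = n_x_linked,
    n_detection_fail = n_detection_fail,
    n_mirna = n_mirna, n_genes = n_genes,
    hub_specs = hubs, seed = seed, ...
  )
}
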