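# shared fixture builders (everything is generated in code)

# prep every platform of a synthetic cohort and fuse, as the pipeline does
prepAndFuse <- function(cohort) {
  meth <- filterMethylationLoci(cohort@methylation, cohort@detectionP)$block
  mir <- applyNegativeBackground(normalizeMirnaPositive(
    cohort@mirna,
    n_expected = sum(featureMeta(cohort@mirna)$control_role == "positive")
  ))
  dct <- normalizeDeltaCt(
    cohort@stemcell,
    n_expected = sum(featureMeta(cohort@stemcell)$control_role == "housekeeping")
  )
  geno <- encodeGenotypeBlock(cohort@genotypes)
  pheno <- encodePhenotypes(cohort@annotations)
  suppressMessages(buildFusedMatrix(list(meth, mir, dct, geno, pheno)))
}

# a tiny hand-made OmicsBlock
makeBlock <- function(values, platform, ...) {
  meta <- if (...length() > 0) data.frame(...) else NULL
  OmicsBlock(values, platform, featureMeta = meta)
}

# default planted-truth feature set of smallCohortSpec()
smallSpecPlanted <- function() {
  list(
    hub = "SCG001",
    spokes = c("cg0021", "cg0022", "cg0023", "miR-0001", "miR-0002", "miR-0003")
  )
}
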