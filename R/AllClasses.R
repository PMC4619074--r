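#' @include micnet-package.R
NULL

.PLATFORMS <- c("methylation", "mirna", "stemcell", "genotype", "phenotype")
.CONTROL_ROLES <- c("none", "positive", "negative", "housekeeping")
.HISTOLOGIES <- c("normal_adjacent", "teratoma", "dysgerminoma", "yst", "mixed")

#' OmicsBlock: one platform's feature-by-sample matrix
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single platform's numeric feature-by-sample matrix (assay `"values"`)
#' together with per-feature metadata (`gene_symbol`, `chr_x`, `control_role`)
#' in `rowData`. Methylation blocks must hold beta values in \[0, 1\].
#'
#' @slot platform single string, one of `"methylation"`, `"mirna"`,
#'   `"stemcell"`, `"genotype"`, `"phenotype"`.
#' @export
setClass("OmicsBlock",
  contains = "SummarizedExperiment",
  representation(platform = "character")
)

setValidity("OmicsBlock", function(object) {
  msg <- character()
  if (length(object@platform) != 1L || !object@platform %in% .PLATFORMS) {
    msg <- c(msg, sprintf(
      "platform must be one of %s", paste(.PLATFORMS, collapse = ", ")
    ))
  }
  if (anyDuplicated(rownames(object))) {
    msg <- c(msg, "duplicate feature ids")
  }
  if (!"values" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'values' is required")
  } else if (identical(object@platform, "methylation")) {
    v <- SummarizedExperiment::assay(object, "values")
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      msg <- c(msg, "methylation values must lie in [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsBlock
#'
#' @param values numeric feature-by-sample matrix with feature ids as rownames
#'   and sample ids as colnames.
#' @param platform platform label (see [OmicsBlock-class]).
#' @param featureMeta optional `data.frame` (one row per feature) with any of
#'   the columns `gene_symbol`, `chr_x`, `control_role`; missing columns are
#'   filled with defaults (`NA`, `FALSE`, `"none"`).
#' @return an [OmicsBlock-class] object.
#' @examples
#' m <- matrix(runif(6), 2, 3,
#'   dimnames = list(c("cg01", "cg02"), c("S1", "S2", "S3")))
#' OmicsBlock(m, "methylation")
#' @export
OmicsBlock <- function(values, platform, featureMeta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs feature rownames and sample colnames")
  }
  storage.mode(values) <- "double"
  meta <- S4Vectors::DataFrame(
    gene_symbol = rep(NA_character_, nrow(values)),
    chr_x = rep(FALSE, nrow(values)),
    control_role = rep("none", nrow(values)),
    row.names = rownames(values)
  )
  if (!is.null(featureMeta)) {
    featureMeta <- as.data.frame(featureMeta)
    if (nrow(featureMeta) != nrow(values)) {
      stop("featureMeta must have one row per feature")
    }
    for (col in intersect(colnames(featureMeta), colnames(meta))) {
      meta[[col]] <- featureMeta[[col]]
    }
  }
  if (!all(meta$control_role %in% .CONTROL_ROLES)) {
    stop("control_role must be one of ", paste(.CONTROL_ROLES, collapse = ", "))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values), rowData = meta
  )
  new("OmicsBlock", se, platform = platform)
}

#' FusedMatrix: row-stacked multi-platform matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows pool features
#' from several platforms; `rowData` carries a `platform` tag and a
#' `gene_symbol` per row, and the columns are the complete-data sample
#' intersection of the fused blocks.
#'
#' @export
setClass("FusedMatrix", contains = "SummarizedExperiment")

setValidity("FusedMatrix", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("platform", "gene_symbol") %in% colnames(rd))) {
    msg <- c(msg, "rowData needs 'platform' and 'gene_symbol'")
  } else if (!all(rd$platform %in% .PLATFORMS)) {
    msg <- c(msg, "unknown platform tag")
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate row ids")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: generated multi-platform data plus planted truth
#'
#' Container returned by [generateCohort()]: one [OmicsBlock-class] per
#' molecular platform, the methylation detection p-value matrix, genotype
#' calls, sample annotations, the generating spec, and a truth record listing
#' the planted hub-and-spoke correlation structure.
#'
#' @slot methylation,mirna,stemcell per-platform [OmicsBlock-class] objects.
#' @slot detectionP numeric matrix of per-locus, per-sample detection
#'   p-values aligned with the methylation block.
#' @slot genotypes character matrix, SNPs by samples, of normalized diploid
#'   calls such as `"a/g"`.
#' @slot annotations `data.frame` with `sample_id`, `age_years`, `sex`,
#'   `location`, `histology`, `age_group`.
#' @slot truth list: `planted_edges`, `planted_hubs`, `seed`.
#' @slot spec the generating spec (see [cohortSpec()]).
#' @export
setClass("SyntheticCohort",
  representation(
    methylation = "OmicsBlock",
    detectionP = "matrix",
    mirna = "OmicsBlock",
    stemcell = "OmicsBlock",
    genotypes = "matrix",
    annotations = "data.frame",
    truth = "list",
    spec = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!identical(dim(object@detectionP), dim(object@methylation))) {
    msg <- c(msg, "detectionP must align with the methylation block")
  }
  v <- SummarizedExperiment::assay(object@mirna, "values")
  if (any(v < 0, na.rm = TRUE) || any(v != round(v), na.rm = TRUE)) {
    msg <- c(msg, "miRNA counts must be nonnegative integers")
  }
  for (e in object@truth$planted_edges) {
    ok <- .featureExists(object, e$feature_a, e$platform_a) &&
      .featureExists(object, e$feature_b, e$platform_b)
    if (!ok) msg <- c(msg, "planted edge endpoint missing from cohort")
  }
  if (length(msg)) unique(msg) else TRUE
})

.featureExists <- function(cohort, feature, platform) {
  blk <- switch(platform,
    methylation = cohort@methylation,
    mirna = cohort@mirna,
    stemcell = cohort@stemcell,
    NULL
  )
  if (is.null(blk)) {
    return(platform %in% c("genotype", "phenotype"))
  }
  feature %in% rownames(blk)
}

#' CorrelationNetwork: thresholded cross-platform graph
#'
#' Built by [buildNetwork()] from filtered [allPairs()] output. Nodes are
#' platform-tagged features (and phenotype variables); edges carry the
#' Pearson r, the MIC and the larger of the two as `weight`. Components are
#' the connected components of the thresholded edge set (single-linkage
#' grouping at a fixed threshold).
#'
#' @slot graph the underlying `igraph` object.
#' @slot edges the edge `data.frame` the network was built from.
#' @slot config the [networkConfig()] used for filtering.
#' @export
setClass("CorrelationNetwork",
  representation(graph = "ANY", edges = "data.frame", config = "list")
)
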