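#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("blockValues", "OmicsBlock", function(x) {
  SummarizedExperiment::assay(x, "values")
})

#' @rdname accessors
setMethod("blockValues", "FusedMatrix", function(x) {
  SummarizedExperiment::assay(x, "values")
})

#' @rdname accessors
setMethod("platformName", "OmicsBlock", function(x) x@platform)

#' @rdname accessors
setMethod("featureMeta", "OmicsBlock", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @rdname accessors
setMethod("featureMeta", "FusedMatrix", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @rdname accessors
setMethod("sampleIds", "OmicsBlock", function(x) colnames(x))

#' @rdname accessors
setMethod("sampleIds", "FusedMatrix", function(x) colnames(x))

#' @rdname accessors
setMethod("sampleIds", "SyntheticCohort", function(x) {
  x@annotations$sample_id
})

#' @rdname accessors
setMethod("platformTags", "FusedMatrix", function(x) {
  SummarizedExperiment::rowData(x)$platform
})

#' @rdname accessors
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

setMethod("show", "OmicsBlock", function(object) {
  cat(sprintf(
    "OmicsBlock [%s]: %d features x %d samples\n",
    object@platform, nrow(object), ncol(object)
  ))
  roles <- table(SummarizedExperiment::rowData(object)$control_role)
  extra <- roles[setdiff(names(roles), "none")]
  if (length(extra)) {
    cat("  control rows:", paste(names(extra), extra, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "FusedMatrix", function(object) {
  tab <- table(platformTags(object))
  cat(sprintf(
    "FusedMatrix: %d rows x %d samples (%s)\n",
    nrow(object), ncol(object),
    paste(names(tab), tab, sep = "=", collapse = ", ")
  ))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d samples; %d CpG loci, %d miRNA features, %d qPCR genes\n",
    nrow(object@annotations), nrow(object@methylation),
    sum(featureMeta(object@mirna)$control_role == "none"),
    sum(featureMeta(object@stemcell)$control_role == "none")
  ))
  cat(sprintf(
    "  planted: %d hub(s), %d edge(s); seed %s\n",
    length(object@truth$planted_hubs), length(object@truth$planted_edges),
    format(object@truth$seed)
  ))
})

setMethod("show", "CorrelationNetwork", function(object) {
  g <- object@graph
  cat(sprintf(
    "CorrelationNetwork: %d nodes, %d edges, %d component(s); threshold %.2f\n",
    igraph::vcount(g), igraph::ecount(g),
    igraph::count_components(g), object@config$threshold
  ))
})
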