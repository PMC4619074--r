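#' @include AllClasses.R
NULL

#' Accessors for micnet classes
#'
#' `blockValues()` returns the numeric feature-by-sample matrix,
#' `platformName()` the platform label, `featureMeta()` the per-feature
#' metadata as a plain `data.frame`, `sampleIds()` the ordered sample ids,
#' `platformTags()` the per-row platform labels of a [FusedMatrix-class], and
#' `cohortTruth()` the planted-truth record of a [SyntheticCohort-class].
#'
#' @param x an object.
#' @return see the per-method descriptions above.
#' @name accessors
#' @aliases blockValues platformName featureMeta sampleIds platformTags
#'   cohortTruth
#' @examples
#' m <- matrix(1:6, 2, 3,
#'   dimnames = list(c("a", "b"), c("S1", "S2", "S3")))
#' blk <- OmicsBlock(m, "stemcell")
#' blockValues(blk)
#' sampleIds(blk)
NULL

#' @rdname accessors
#' @export
setGeneric("blockValues", function(x) standardGeneric("blockValues"))

#' @rdname accessors
#' @export
setGeneric("platformName", function(x) standardGeneric("platformName"))

#' @rdname accessors
#' @export
setGeneric("featureMeta", function(x) standardGeneric("featureMeta"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("platformTags", function(x) standardGeneric("platformTags"))

#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
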