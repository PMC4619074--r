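#' @include generate-cohort.R
NULL

# full-precision numeric -> character for lossless TSV round trips
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

.writeMatrixTSV <- function(values, meta, path, id_col) {
  df <- data.frame(id = rownames(values), stringsAsFactors = FALSE)
  names(df) <- id_col
  if (!is.null(meta)) df <- cbind(df, meta, stringsAsFactors = FALSE)
  num <- as.data.frame(apply(values, 2, .fmtNum), stringsAsFactors = FALSE)
  colnames(num) <- colnames(values)
  df <- cbind(df, num, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readMatrixTSV <- function(path, id_col, meta_cols = character()) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[id_col]]
  meta <- if (length(meta_cols)) df[meta_cols] else NULL
  keep <- setdiff(colnames(df), c(id_col, meta_cols))
  m <- as.matrix(df[keep])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!is.null(meta)) rownames(meta) <- ids
  list(values = m, meta = meta)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Writes one TSV per platform matrix (feature metadata as leading columns,
#' numeric values at full precision), the detection p-value matrix, genotype
#' calls, sample annotations, and the planted-truth record as JSON. The file
#' set round-trips losslessly through [readCohort()].
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (nrow(cohort@annotations) == 0L) stop("cohort has no samples")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)

  paths <- file.path(dir, c(
    "methylation_beta.tsv", "methylation_detection_p.tsv",
    "mirna_counts.tsv", "stemcell_ct.tsv",
    "genotypes.tsv", "annotations.tsv", "truth.json"
  ))
  names(paths) <- c(
    "beta", "detp", "mirna", "stemcell", "genotypes", "annotations", "truth"
  )

  .writeMatrixTSV(
    blockValues(cohort@methylation),
    featureMeta(cohort@methylation)[c("gene_symbol", "chr_x")],
    paths["beta"], "locus_id"
  )
  .writeMatrixTSV(cohort@detectionP, NULL, paths["detp"], "locus_id")
  .writeMatrixTSV(
    blockValues(cohort@mirna),
    featureMeta(cohort@mirna)[c("gene_symbol", "control_role")],
    paths["mirna"], "feature_id"
  )
  .writeMatrixTSV(
    blockValues(cohort@stemcell),
    featureMeta(cohort@stemcell)[c("gene_symbol", "control_role")],
    paths["stemcell"], "feature_id"
  )

  gt <- data.frame(
    snp_id = rownames(cohort@genotypes),
    as.data.frame(cohort@genotypes, stringsAsFactors = FALSE),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(gt, paths["genotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort@annotations, paths["annotations"], sep = "\t",
              quote = FALSE, row.names = FALSE)

  spec_scalars <- cohort@spec[vapply(cohort@spec, function(x) {
    is.atomic(x) && length(x) >= 1 && !is.null(x)
  }, logical(1))]
  jsonlite::write_json(
    list(
      planted_edges = cohort@truth$planted_edges,
      planted_hubs = cohort@truth$planted_hubs,
      seed = cohort@truth$seed,
      spec = spec_scalars
    ),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory holding the cohort file set.
#' @return a [SyntheticCohort-class].
#' @export
readCohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  beta <- .readMatrixTSV(p("methylation_beta.tsv"), "locus_id",
                         c("gene_symbol", "chr_x"))
  detp <- .readMatrixTSV(p("methylation_detection_p.tsv"), "locus_id")
  mir <- .readMatrixTSV(p("mirna_counts.tsv"), "feature_id",
                        c("gene_symbol", "control_role"))
  sc <- .readMatrixTSV(p("stemcell_ct.tsv"), "feature_id",
                       c("gene_symbol", "control_role"))
  gt_df <- read.delim(p("genotypes.tsv"), check.names = FALSE,
                      stringsAsFactors = FALSE)
  gt <- as.matrix(gt_df[setdiff(colnames(gt_df), "snp_id")])
  rownames(gt) <- gt_df$snp_id
  ann <- read.delim(p("annotations.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
  ann$sample_id <- as.character(ann$sample_id)
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = FALSE)
  spec <- lapply(truth$spec, function(x) {
    if (is.list(x)) unlist(x) else x
  })
  truth <- list(
    planted_edges = lapply(truth$planted_edges, function(e) {
      lapply(e, identity)
    }),
    planted_hubs = lapply(truth$planted_hubs, function(h) lapply(h, identity)),
    seed = truth$seed
  )
  beta$meta$chr_x <- as.logical(beta$meta$chr_x)
  new("SyntheticCohort",
    methylation = OmicsBlock(beta$values, "methylation", beta$meta),
    detectionP = detp$values,
    mirna = OmicsBlock(mir$values, "mirna", mir$meta),
    stemcell = OmicsBlock(sc$values, "stemcell", sc$meta),
    genotypes = gt, annotations = ann, truth = truth, spec = spec
  )
}
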