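#' @include network.R enrichment.R fusion.R platform-prep.R cohort-io.R
NULL

#' Pipeline configuration
#'
#' @param cohort_dir directory of cohort TSVs ([readCohort()] layout), or
#'   `NULL` to generate a synthetic cohort from `synthetic_spec`.
#' @param synthetic_spec a [cohortSpec()] used when `cohort_dir` is `NULL`.
#' @param out_dir output directory for stage artifacts.
#' @param seed global seed; propagated to the synthetic generator and to the
#'   random-gene-list control.
#' @param mic [micParams()]; network [networkConfig()]; encoding
#'   [defaultEncodingConfig()].
#' @param network,encoding stage configurations.
#' @param de_groups two histology levels compared in the differential
#'   stages (miRNA NB test and qPCR fold changes).
#' @param gmt_path optional GMT file of regulator target sets; when `NULL`
#'   the enrichment stage is skipped.
#' @param repeat_without optional histology level: the correlate/network
#'   stages are repeated on the cohort without those samples.
#' @param log2_mirna fuse `log2(x + 1)` miRNA counts instead of the
#'   normalized counts (default `FALSE`).
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(cohort_dir = NULL,
                           synthetic_spec = cohortSpec(),
                           out_dir = tempfile("micnet_run_"),
                           seed = 1,
                           mic = micParams(),
                           network = networkConfig(),
                           encoding = defaultEncodingConfig(),
                           de_groups = c("yst", "dysgerminoma"),
                           gmt_path = NULL,
                           repeat_without = NULL,
                           log2_mirna = FALSE) {
  structure(
    list(
      cohort_dir = cohort_dir, synthetic_spec = synthetic_spec,
      out_dir = out_dir, seed = seed, mic = mic, network = network,
      encoding = encoding, de_groups = de_groups, gmt_path = gmt_path,
      repeat_without = repeat_without, log2_mirna = log2_mirna
    ),
    class = "pipelineConfig"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipelineConfig()] arguments; `synthetic_spec`,
#' `mic` and `network` accept nested maps of the corresponding constructor
#' arguments.
#'
#' @param path YAML file.
#' @return a `pipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("cohort_dir", "out_dir", "seed", "de_groups", "gmt_path",
                "repeat_without", "log2_mirna")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$synthetic_spec)) {
    sargs <- y$synthetic_spec
    if (!is.null(sargs$histology_counts)) {
      sargs$histology_counts <- unlist(sargs$histology_counts)
    }
    args$synthetic_spec <- do.call(cohortSpec, sargs)
  }
  if (!is.null(y$mic)) args$mic <- do.call(micParams, y$mic)
  if (!is.null(y$network)) args$network <- do.call(networkConfig, y$network)
  do.call(pipelineConfig, args)
}

.stageLog <- function(log, stage, ...) {
  entry <- list(...)
  message(sprintf("[%s] %s", stage, paste(
    names(entry), vapply(entry, function(x) paste(format(x), collapse = ","),
                         character(1)),
    sep = "=", collapse = " "
  )))
  log[[stage]] <- c(log[[stage]], entry)
  log
}

.correlateAndNetwork <- function(fused, config, out_dir, tag) {
  pairs <- allPairs(fused, config$mic)
  writePairTable(pairs, file.path(out_dir, paste0("pairs", tag, ".tsv")))
  edges <- filterEdges(pairs, config$network)
  writePairTable(edges, file.path(out_dir, paste0("edges", tag, ".tsv")))
  network <- buildNetwork(edges, config$network)
  writeNetworkGraphML(network, file.path(out_dir, paste0("network", tag, ".graphml")))
  hubs <- findHubs(network)
  list(pairs = pairs, edges = edges, network = network, hubs = hubs)
}

#' Run the full cross-platform analysis pipeline
#'
#' Stages: cohort generation or ingestion; per-platform prep (methylation
#' detection/X-linked filtering, positive-control and background
#' normalization of miRNA counts, housekeeping delta-Ct); differential
#' analysis (NB exact test on rounded normalized miRNA counts, qPCR fold
#' changes and Welch tests, sample clustering); fusion with encoded
#' genotypes and phenotypes; all-pairs Pearson + MIC; cross-platform network
#' and hubs; optional enrichment with the random-gene-list control; optional
#' repeat of the correlate/network stages without one histology. Per-stage
#' artifacts are written under `config$out_dir` and summarized in
#' `manifest.json` (seeds, stage counts, artifact hashes).
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, the manifest list (also written as JSON).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  ## cohort
  if (is.null(config$cohort_dir)) {
    spec <- config$synthetic_spec
    spec$seed <- config$seed
    cohort <- generateCohort(spec)
    writeCohort(cohort, file.path(out, "cohort"))
  } else {
    cohort <- readCohort(config$cohort_dir)
  }
  log <- .stageLog(log, "cohort",
                   n_samples = nrow(cohort@annotations),
                   n_cpg = nrow(cohort@methylation))

  ## prep
  meth <- filterMethylationLoci(cohort@methylation, cohort@detectionP)
  jsonlite::write_json(meth$report, file.path(out, "methylation_qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mirna <- applyNegativeBackground(normalizeMirnaPositive(
    cohort@mirna, n_expected = sum(featureMeta(cohort@mirna)$control_role == "positive")
  ))
  dct <- normalizeDeltaCt(
    cohort@stemcell,
    n_expected = sum(featureMeta(cohort@stemcell)$control_role == "housekeeping")
  )
  log <- .stageLog(log, "prep",
                   loci_retained = meth$report$n_retained,
                   loci_removed_detection = meth$report$n_detection_removed,
                   loci_removed_x = meth$report$n_x_removed)

  ## differential
  ann <- cohort@annotations
  ga <- ann$sample_id[ann$histology == config$de_groups[1]]
  gb <- ann$sample_id[ann$histology == config$de_groups[2]]
  mir_counts <- blockValues(mirna)
  mir_counts <- round(mir_counts[featureMeta(mirna)$control_role == "none",
                                 c(ga, gb), drop = FALSE])
  complete <- colSums(is.na(mir_counts)) == 0
  de <- NULL
  if (sum(complete & colnames(mir_counts) %in% ga) >= 2 &&
      sum(complete & colnames(mir_counts) %in% gb) >= 2) {
    mc <- mir_counts[, complete, drop = FALSE]
    de <- nbTest(mc, ifelse(colnames(mc) %in% ga, "a", "b"))
    write.table(de, file.path(out, "mirna_de.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  fc <- foldChangeDdct(dct, intersect(ga, sampleIds(dct)),
                       intersect(gb, sampleIds(dct)))
  write.table(fc, file.path(out, "stemcell_foldchange.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hc <- hclusterSamples(dct)
  dendrogramNewick(hc, file.path(out, "stemcell_dendrogram.nwk"))
  log <- .stageLog(log, "differential",
                   mirna_tested = if (is.null(de)) 0L else nrow(de),
                   mirna_q05 = if (is.null(de)) 0L else sum(de$q_value < 0.05),
                   genes_3fold = sum(fc$passes_3fold, na.rm = TRUE))

  ## fusion
  geno <- encodeGenotypeBlock(cohort@genotypes, config$encoding$genotype_table)
  pheno <- encodePhenotypes(ann, config$encoding)
  mir_fuse <- mirna
  if (config$log2_mirna) {
    SummarizedExperiment::assay(mir_fuse, "values") <-
      log2(blockValues(mirna) + 1)
  }
  fused <- buildFusedMatrix(list(meth$block, mir_fuse, dct, geno, pheno))
  log <- .stageLog(log, "fusion",
                   rows = nrow(fused), samples = ncol(fused))

  ## correlate + network
  res <- .correlateAndNetwork(fused, config, out, "")
  write.table(res$hubs[c("hub", "platform", "degree")],
              file.path(out, "hubs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  genes <- hubGeneList(res$hubs, featureSymbolMap(fused))
  writeLines(genes, file.path(out, "hub_genes.txt"))
  log <- .stageLog(log, "network",
                   pairs = nrow(res$pairs), edges = nrow(res$edges),
                   hubs = nrow(res$hubs), hub_genes = length(genes))

  ## enrichment (optional)
  if (!is.null(config$gmt_path) && length(genes)) {
    annotation <- readGmt(config$gmt_path)
    universe <- unique(na.omit(featureMeta(fused)$gene_symbol))
    enr <- randomControlFilter(genes, annotation, universe,
                               seed = config$seed)
    write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log <- .stageLog(log, "enrichment",
                     regulators = nrow(enr),
                     retained = sum(enr$significant_after_control))
  }

  ## optional subset re-analysis
  if (!is.null(config$repeat_without)) {
    sub <- subsetSamples(fused, config$repeat_without, annotations = ann)
    res2 <- .correlateAndNetwork(sub, config, out,
                                 paste0("_no_", config$repeat_without))
    log <- .stageLog(log, "subset_network",
                     excluded = config$repeat_without,
                     samples = ncol(sub), edges = nrow(res2$edges),
                     hubs = nrow(res2$hubs))
  }

  artifacts <- list.files(out, recursive = TRUE, full.names = TRUE)
  artifacts <- artifacts[basename(artifacts) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("micnet")),
    seed = config$seed,
    stages = log,
    artifacts = setNames(
      as.list(unname(tools::md5sum(artifacts))),
      sub(paste0(out, "/"), "", artifacts, fixed = TRUE)
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
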