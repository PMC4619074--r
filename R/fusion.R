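#' @include AllClasses.R
NULL

#' Default genotype code table (transition/transversion grouping)
#'
#' Numeric codes for unordered diploid calls, grouping transitions together
#' and separating transversions: -4.0 = t/t, -3.0 = c/t, -2.0 = c/c,
#' -0.5 = g/t, -0.2 = c/g, 0.2 = a/t, 0.5 = a/c, 2.0 = a/a, 3.0 = a/g,
#' 4.0 = g/g.
#'
#' @return named numeric vector keyed by normalized calls (`"a/g"` style,
#'   alleles lowercase and sorted).
#' @export
defaultGenotypeCodes <- function() {
  c(
    "t/t" = -4.0, "c/t" = -3.0, "c/c" = -2.0, "g/t" = -0.5, "c/g" = -0.2,
    "a/t" = 0.2, "a/c" = 0.5, "a/a" = 2.0, "a/g" = 3.0, "g/g" = 4.0
  )
}

.normalizeCall <- function(call) {
  if (is.na(call)) {
    return(NA_character_)
  }
  al <- sort(tolower(strsplit(call, "/", fixed = TRUE)[[1]]))
  if (length(al) != 2L || !all(al %in% c("a", "c", "g", "t"))) {
    stop("malformed diploid call: ", call)
  }
  paste(al, collapse = "/")
}

#' Encode a diploid genotype call as a numeric value
#'
#' Order-insensitive table lookup: `"g/a"` and `"a/g"` map to the same code.
#'
#' @param call diploid call such as `"a/g"` (case-insensitive, either allele
#'   order); `NA` passes through.
#' @param table named numeric code table (default [defaultGenotypeCodes()]).
#' @param context optional label (SNP/sample) used in error messages.
#' @return the numeric code.
#' @examples
#' encodeGenotype("a/g")  # 3
#' encodeGenotype("g/a")  # 3
#' encodeGenotype("t/t")  # -4
#' @export
encodeGenotype <- function(call, table = defaultGenotypeCodes(),
                           context = NULL) {
  key <- .normalizeCall(call)
  if (is.na(key)) {
    return(NA_real_)
  }
  if (!key %in% names(table)) {
    stop(
      "genotype call '", key, "' not in code table",
      if (!is.null(context)) paste0(" (", context, ")") else ""
    )
  }
  unname(table[key])
}

#' Encode a genotype call matrix as a numeric OmicsBlock
#'
#' @param genotypes character matrix, SNPs by samples, of diploid calls.
#' @param table named numeric code table.
#' @return a `"genotype"` [OmicsBlock-class].
#' @export
encodeGenotypeBlock <- function(genotypes, table = defaultGenotypeCodes()) {
  m <- matrix(NA_real_, nrow(genotypes), ncol(genotypes),
              dimnames = dimnames(genotypes))
  for (i in seq_len(nrow(genotypes))) {
    for (j in seq_len(ncol(genotypes))) {
      m[i, j] <- encodeGenotype(
        genotypes[i, j], table,
        context = paste0(rownames(genotypes)[i], ", ", colnames(genotypes)[j])
      )
    }
  }
  OmicsBlock(m, "genotype",
             featureMeta = data.frame(gene_symbol = sub("_rs.*$", "",
                                                        rownames(genotypes))))
}

#' Default phenotype/genotype encoding configuration
#'
#' Numeric codes for the categorical phenotype variables, ordered low to
#' high severity for histology (normal adjacent, teratoma, dysgerminoma,
#' yolk sac tumor, mixed). These orderings are package defaults, stated as
#' assumptions; every map is overridable.
#'
#' @param histology_codes,location_codes,sex_codes named numeric maps
#'   (values must be distinct within each map).
#' @param genotype_table genotype code table (default
#'   [defaultGenotypeCodes()]).
#' @return an `encodingConfig` list.
#' @export
defaultEncodingConfig <- function(
    histology_codes = c(
      normal_adjacent = 0, teratoma = 1, dysgerminoma = 2, yst = 3, mixed = 4
    ),
    location_codes = c(ovary = 0, testis = 1, extragonadal = 2),
    sex_codes = c(male = 0, female = 1),
    genotype_table = defaultGenotypeCodes()) {
  for (m in list(histology_codes, location_codes, sex_codes)) {
    if (anyDuplicated(m)) stop("encoding maps must be injective")
  }
  structure(
    list(
      histology_codes = histology_codes, location_codes = location_codes,
      sex_codes = sex_codes, genotype_table = genotype_table
    ),
    class = "encodingConfig"
  )
}

#' Encode sample annotations as a numeric phenotype block
#'
#' One numeric row per phenotype variable: `age_years` passes through;
#' `sex`, `location` and `histology` are mapped through the configured codes.
#'
#' @param annotations `data.frame` with `sample_id`, `age_years`, `sex`,
#'   `location`, `histology`.
#' @param config an encoding configuration ([defaultEncodingConfig()]).
#' @return a `"phenotype"` [OmicsBlock-class] with rows `age`, `sex`,
#'   `location`, `histology`.
#' @export
encodePhenotypes <- function(annotations, config = defaultEncodingConfig()) {
  lookup <- function(values, map, what) {
    bad <- setdiff(unique(values), names(map))
    if (length(bad)) {
      stop("no ", what, " code for level(s): ", paste(bad, collapse = ", "))
    }
    unname(map[values])
  }
  m <- rbind(
    age = annotations$age_years,
    sex = lookup(annotations$sex, config$sex_codes, "sex"),
    location = lookup(annotations$location, config$location_codes, "location"),
    histology = lookup(annotations$histology, config$histology_codes,
                       "histology")
  )
  colnames(m) <- annotations$sample_id
  OmicsBlock(m, "phenotype",
             featureMeta = data.frame(gene_symbol = rep(NA_character_, 4)))
}

#' Fuse platform blocks into one two-dimensional matrix
#'
#' Row-stacks the blocks with per-row platform tags, excludes control and
#' housekeeping rows, and (by default) restricts the columns to the samples
#' with complete (non-missing) data in every block; dropped samples are
#' reported with a message.
#'
#' @param blocks list of at least two [OmicsBlock-class] objects sharing a
#'   sample-id namespace.
#' @param require_complete keep only samples complete in every block
#'   (default `TRUE`).
#' @return a [FusedMatrix-class].
#' @export
buildFusedMatrix <- function(blocks, require_complete = TRUE) {
  if (length(blocks) < 2L) stop("fusion needs at least 2 platform blocks")
  stopifnot(all(vapply(blocks, is, logical(1), "OmicsBlock")))

  complete_ids <- lapply(blocks, function(b) {
    v <- blockValues(b)
    colnames(v)[colSums(is.na(v)) == 0L]
  })
  all_ids <- unique(unlist(lapply(blocks, function(b) colnames(b))))
  keep <- Reduce(intersect, if (require_complete) {
    complete_ids
  } else {
    lapply(blocks, colnames)
  })
  if (!length(keep)) stop("no sample is present in every block")
  dropped <- setdiff(all_ids, keep)
  if (length(dropped)) {
    message(length(dropped), " sample(s) without complete data excluded: ",
            paste(dropped, collapse = ", "))
  }

  rows <- list()
  tags <- character()
  symbols <- character()
  for (b in blocks) {
    keep_rows <- featureMeta(b)$control_role == "none"
    v <- blockValues(b)[keep_rows, keep, drop = FALSE]
    rows[[length(rows) + 1L]] <- v
    tags <- c(tags, rep(platformName(b), nrow(v)))
    symbols <- c(symbols, featureMeta(b)$gene_symbol[keep_rows])
  }
  m <- do.call(rbind, rows)
  if (anyDuplicated(rownames(m))) {
    stop("duplicate feature ids across fused blocks")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = m),
    rowData = S4Vectors::DataFrame(
      platform = tags, gene_symbol = symbols, row.names = rownames(m)
    )
  )
  new("FusedMatrix", se)
}

#' Drop all samples of one histology from a fused matrix
#'
#' @param fused a [FusedMatrix-class] containing a `histology` phenotype row,
#'   or `annotations` supplied explicitly.
#' @param exclude_histology histology level to remove (e.g. `"yst"`).
#' @param annotations optional annotations `data.frame`; when `NULL` the
#'   fused matrix's own `histology` row is decoded against `config`.
#' @param config encoding configuration used to decode the histology row.
#' @return the subsetted [FusedMatrix-class]; feature rows are unchanged.
#' @export
subsetSamples <- function(fused, exclude_histology,
                          annotations = NULL,
                          config = defaultEncodingConfig()) {
  stopifnot(is(fused, "FusedMatrix"))
  ids <- colnames(fused)
  if (!is.null(annotations)) {
    hist <- annotations$histology[match(ids, annotations$sample_id)]
  } else {
    if (!"histology" %in% rownames(fused)) {
      stop("fused matrix has no histology row and no annotations were given")
    }
    codes <- blockValues(fused)["histology", ]
    hist <- names(config$histology_codes)[match(codes, config$histology_codes)]
  }
  drop <- !is.na(hist) & hist == exclude_histology
  if (all(drop)) stop("excluding '", exclude_histology, "' empties the matrix")
  fused[, !drop]
}
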