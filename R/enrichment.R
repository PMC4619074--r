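#' @include differential.R
NULL

#' Read / write GMT gene-set files
#'
#' GMT: one set per line -- set name, description, then member symbols,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return `readGmt`: named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    setdiff(unique(f[-(1:2)]), "")
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  out
}

#' @rdname readGmt
#' @param sets named list of character vectors (regulator -> targets).
#' @param description per-set description (recycled).
#' @return `writeGmt`: invisibly, `path`.
#' @export
writeGmt <- function(sets, path, description = "") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a gene list
#'
#' For each regulator with target set `T` inside the universe `U`, the
#' overlap with the query list `L` is tested with the hypergeometric upper
#' tail `p = P[X >= overlap]`, `X ~ Hypergeometric(|U|, |T|, |L|)`; q-values
#' are Benjamini-Hochberg over regulators. Query genes outside the universe
#' are dropped with a message. Target sets are intersected with the universe
#' first.
#'
#' @param gene_list character vector of query gene symbols.
#' @param annotation named list of regulator target sets.
#' @param universe character vector of all profiled gene symbols.
#' @return `data.frame` with `regulator`, `overlap`, `set_size`,
#'   `list_size`, `universe_size`, `p_value`, `q_value`.
#' @export
hypergeomEnrich <- function(gene_list, annotation, universe) {
  universe <- unique(universe)
  if (!length(gene_list) || !length(annotation)) {
    stop("empty gene list or annotation")
  }
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    message("dropping ", length(outside), " query gene(s) outside the universe")
  }
  gl <- unique(intersect(gene_list, universe))
  if (!length(gl)) stop("no query gene inside the universe")
  sets <- lapply(annotation, intersect, universe)
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  if (!length(sets)) stop("no annotation set overlaps the universe")
  res <- lapply(names(sets), function(reg) {
    k <- length(intersect(sets[[reg]], gl))
    m <- length(sets[[reg]])
    data.frame(
      regulator = reg, overlap = k, set_size = m, list_size = length(gl),
      universe_size = length(universe),
      p_value = phyper(k - 1, m, length(universe) - m, length(gl),
                       lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, res)
  res$q_value <- bhAdjust(res$p_value)
  rownames(res) <- NULL
  res
}

#' Random-gene-list enrichment control
#'
#' Guards over-representation results against the a priori bias of the
#' profiled molecules: `k_random` gene sets of the query-list size are drawn
#' uniformly without replacement from the universe and enriched identically;
#' a regulator is `significant_after_control` only when its real q-value is
#' below `q_cutoff` and its real p-value is strictly smaller than that
#' regulator's minimum p-value over the random lists. With
#' `require_dominance = FALSE` only the q-value condition applies.
#'
#' @param gene_list,annotation,universe as in [hypergeomEnrich()].
#' @param k_random number of random lists (default 3).
#' @param seed integer seed for the random draws.
#' @param q_cutoff BH significance cutoff (default 0.05).
#' @param require_dominance require strict dominance over the random-list
#'   minima (default `TRUE`).
#' @return the [hypergeomEnrich()] table with `random_min_p` and
#'   `significant_after_control` columns.
#' @export
randomControlFilter <- function(gene_list, annotation, universe,
                                k_random = 3, seed = 1, q_cutoff = 0.05,
                                require_dominance = TRUE) {
  universe <- unique(universe)
  gl <- unique(intersect(gene_list, universe))
  if (length(gl) > length(universe)) stop("list larger than universe")
  real <- hypergeomEnrich(gl, annotation, universe)
  set.seed(seed)
  rand_p <- matrix(NA_real_, nrow(real), k_random,
                   dimnames = list(real$regulator, NULL))
  for (k in seq_len(k_random)) {
    rl <- sample(universe, length(gl))
    rk <- hypergeomEnrich(rl, annotation, universe)
    rand_p[rk$regulator, k] <- rk$p_value
  }
  real$random_min_p <- apply(rand_p, 1, min, na.rm = TRUE)
  real$significant_after_control <- real$q_value < q_cutoff &
    (!require_dominance | real$p_value < real$random_min_p)
  real
}
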