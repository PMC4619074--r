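#' @include AllClasses.R
NULL

#' MIC estimation parameters
#'
#' `alpha` sets the grid budget `B(n) = max(4, floor(n^alpha))`: only grids
#' with `k * l <= B(n)` cells are searched. `clump_factor` caps the number of
#' candidate column boundaries at `clump_factor * max_columns` (the clump
#' merging of the approximation scheme). Pairs with fewer than
#' `min_pairwise_n` complete observations yield a missing MIC, and MIC values
#' computed from fewer than `small_n_warning_threshold` observations carry a
#' small-sample caution (MIC inflates on small samples).
#'
#' @param alpha grid-budget exponent in (0, 1\] (default 0.6).
#' @param clump_factor positive integer (default 15).
#' @param min_pairwise_n minimum complete observations per pair (default 8).
#' @param small_n_warning_threshold warn below this n (default 30).
#' @param max_axis cap on bins per axis (default `Inf`; the budget is usually
#'   the binding constraint).
#' @param exhaustive_small_n for pairs with at most this many complete
#'   observations the row-axis partition is searched exhaustively instead of
#'   mass-equipartitioned, making the estimate exact under the grid budget
#'   (default 12; the dynamic program is exact for the column axis either
#'   way).
#' @return a `micParams` list.
#' @export
micParams <- function(alpha = 0.6, clump_factor = 15, min_pairwise_n = 8,
                      small_n_warning_threshold = 30, max_axis = Inf,
                      exhaustive_small_n = 12) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (clump_factor < 1) stop("clump_factor must be a positive integer")
  if (min_pairwise_n < 4) stop("min_pairwise_n must be at least 4")
  structure(
    list(
      alpha = alpha, clump_factor = as.integer(clump_factor),
      min_pairwise_n = as.integer(min_pairwise_n),
      small_n_warning_threshold = small_n_warning_threshold,
      max_axis = max_axis,
      exhaustive_small_n = as.integer(exhaustive_small_n)
    ),
    class = "micParams"
  )
}

.axisCap <- function(params) {
  if (is.finite(params$max_axis)) as.integer(params$max_axis) else .Machine$integer.max %/% 2L
}

#' Pearson correlation with pairwise-complete handling
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value in
#'   either vector are dropped.
#' @return the sample correlation, or `NA` (with a warning) when fewer than
#'   3 complete pairs remain or either vector is constant.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  r <- .pearson_pair_cpp(as.numeric(x), as.numeric(y))
  if (is.na(r)) warning("constant vector or fewer than 3 complete pairs")
  r
}

#' Approximate Maximal Information Coefficient
#'
#' Grid search over all `k x l` grids with `k * l <= B(n)`: one axis is
#' mass-equipartitioned and the other optimized by dynamic programming over
#' clump boundaries; each grid's mutual information is normalized by
#' `log2(min(k, l))` and the maximum over grids and both axis orientations is
#' returned, so `micApprox(x, y) == micApprox(y, x)` exactly.
#'
#' @param x,y numeric vectors of equal length.
#' @param params a [micParams()] list.
#' @return MIC in \[0, 1\]; `NA` (with a warning) for a constant vector or
#'   fewer than `min_pairwise_n` complete pairs. Noiseless strictly monotone
#'   data give 1.
#' @examples
#' x <- 1:40
#' micApprox(x, (x - mean(x))^2)  # nonlinear dependence, Pearson ~ 0
#' @export
micApprox <- function(x, y, params = micParams()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < params$min_pairwise_n) {
    warning("fewer than min_pairwise_n complete pairs; MIC is NA")
    return(NA_real_)
  }
  if (n < params$small_n_warning_threshold) {
    warning("MIC computed from n = ", n,
            " observations; MIC can inflate on small samples")
  }
  v <- .mic_pair_cpp(as.numeric(x), as.numeric(y), params$alpha,
                     params$clump_factor, .axisCap(params),
                     params$exhaustive_small_n)
  if (is.na(v)) warning("constant vector; MIC is NA")
  v
}

#' Exact small-n MIC by exhaustive grid enumeration
#'
#' Independent verification oracle: enumerates every axis partition whose
#' cuts fall between distinct sorted values (tied values are never split),
#' for all grid shapes with at most `max_axis` bins per axis and
#' `k * l <= B(n)` cells, and returns the exact maximum normalized mutual
#' information. Exponential in n; restricted to `n <= max_n`.
#'
#' @param x,y numeric vectors (complete cases used).
#' @param max_n refuse larger inputs (default 12).
#' @param max_axis bins-per-axis cap (default 4).
#' @param alpha grid-budget exponent, matching [micParams()] (default 0.6).
#' @return the exact MIC under the stated grid constraints.
#' @export
micExactOracle <- function(x, y, max_n = 12, max_axis = 4, alpha = 0.6) {
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  n <- length(x)
  if (n > max_n) stop("micExactOracle is restricted to n <= ", max_n)
  if (n < 4) stop("need at least 4 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("constant vector")
  }
  B <- max(4, floor(n^alpha))

  partitions_of <- function(v) {
    ord <- order(v)
    sv <- v[ord]
    gaps <- which(diff(sv) > 0) # cut after these sorted positions
    parts <- list()
    max_k <- min(max_axis, length(gaps) + 1, B %/% 2)
    for (k in 2:max_k) {
      if (k - 1 > length(gaps)) break
      cuts <- combn(gaps, k - 1, simplify = FALSE)
      for (ct in cuts) {
        bin_sorted <- findInterval(seq_len(n), c(ct + 0.5)) + 1L
        bin <- integer(n)
        bin[ord] <- bin_sorted
        parts[[length(parts) + 1L]] <- list(k = k, bin = bin)
      }
    }
    parts
  }

  px <- partitions_of(x)
  py <- partitions_of(y)
  best <- 0
  for (a in px) {
    for (b in py) {
      if (a$k * b$k > B) next
      tab <- table(a$bin, b$bin)
      mi <- .mutualInfoBits(tab)
      val <- mi / log2(min(a$k, b$k))
      if (val > best) best <- val
    }
  }
  min(best, 1)
}

.mutualInfoBits <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p)
  pc <- colSums(p)
  e <- outer(pr, pc)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

#' All-pairs Pearson and MIC over a fused matrix
#'
#' One row per unordered feature pair (no self-pairs), in row-index order,
#' with pairwise-complete observation counts and the pair weight
#' `max(|pearson_r|, mic)` (missing components treated as non-qualifying).
#'
#' @param fused a [FusedMatrix-class] (or numeric matrix, in which case all
#'   rows are tagged with platform `"phenotype"`).
#' @param params a [micParams()] list.
#' @return `data.frame` with `feature_a`, `platform_a`, `feature_b`,
#'   `platform_b`, `n_used`, `pearson_r`, `mic`, `weight`.
#' @export
allPairs <- function(fused, params = micParams()) {
  if (is(fused, "FusedMatrix")) {
    m <- blockValues(fused)
    plat <- platformTags(fused)
  } else {
    m <- as.matrix(fused)
    plat <- rep("phenotype", nrow(m))
  }
  if (nrow(m) < 2L) stop("need at least 2 rows")
  res <- .allpairs_cpp(m, params$alpha, params$clump_factor,
                       .axisCap(params), params$min_pairwise_n,
                       params$exhaustive_small_n)
  weight <- pmax(abs(res$pearson_r), res$mic, na.rm = TRUE)
  weight[is.na(res$pearson_r) & is.na(res$mic)] <- NA_real_
  data.frame(
    feature_a = rownames(m)[res$i], platform_a = plat[res$i],
    feature_b = rownames(m)[res$j], platform_b = plat[res$j],
    n_used = res$n_used, pearson_r = res$pearson_r, mic = res$mic,
    weight = weight,
    stringsAsFactors = FALSE
  )
}

#' Write an all-pairs table as TSV
#'
#' @param pairs the [allPairs()] output.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writePairTable <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
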