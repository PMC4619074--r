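#' @include AllClasses.R
NULL

#' Methylation beta value from allele signals
#'
#' beta = M / (M + U), the fraction of fluorescent signal from the methylated
#' allele. Vectorized; a locus with both signals zero yields `NA` with a
#' warning (missing measurement). No offset is added to the denominator; an
#' `offset` argument restores the array-software convention if wanted.
#'
#' @param methylated_signal,unmethylated_signal nonnegative signals.
#' @param offset nonnegative constant added to the denominator (default 0).
#' @return beta values in \[0, 1\] (`NA` where both signals are 0 and
#'   `offset` is 0).
#' @examples
#' computeBeta(100, 300)  # 0.25
#' @export
computeBeta <- function(methylated_signal, unmethylated_signal, offset = 0) {
  if (any(methylated_signal < 0, na.rm = TRUE) ||
      any(unmethylated_signal < 0, na.rm = TRUE)) {
    stop("signals must be nonnegative")
  }
  den <- methylated_signal + unmethylated_signal + offset
  bad <- !is.na(den) & den == 0
  if (any(bad)) {
    warning(sum(bad), " locus/loci with zero total signal set to NA")
    den[bad] <- NA_real_
  }
  methylated_signal / den
}

#' Filter methylation loci on detection quality and X linkage
#'
#' Removes every locus whose detection p-value exceeds `detection_alpha` in
#' at least `fail_fraction` of samples (inclusive boundary), and every
#' X-linked locus when `drop_x`. On the default synthetic panel (1505 loci,
#' 16 detection failures, 84 X-linked, disjoint) this retains 1405 loci.
#'
#' @param block methylation [OmicsBlock-class].
#' @param detection_p numeric matrix aligned with `block` (same dimnames).
#' @param fail_fraction fraction of samples in (0, 1\] at which a locus is
#'   dropped (default 0.25).
#' @param detection_alpha detection p-value cutoff (default 0.05).
#' @param drop_x drop loci flagged `chr_x` (default `TRUE`).
#' @return list with the filtered `block` and a `report` list
#'   (`n_input_loci`, `n_detection_removed`, `n_x_removed`, `n_retained`,
#'   `removed_ids`).
#' @export
filterMethylationLoci <- function(block, detection_p, fail_fraction = 0.25,
                                  detection_alpha = 0.05, drop_x = TRUE) {
  stopifnot(is(block, "OmicsBlock"))
  if (fail_fraction <= 0 || fail_fraction > 1) {
    stop("fail_fraction must lie in (0, 1]")
  }
  v <- blockValues(block)
  if (!identical(dim(v), dim(detection_p)) ||
      !identical(rownames(v), rownames(detection_p)) ||
      !identical(colnames(v), colnames(detection_p))) {
    stop("detection_p is not aligned with the methylation block")
  }
  frac_fail <- rowMeans(detection_p > detection_alpha, na.rm = TRUE)
  det_rm <- frac_fail >= fail_fraction
  x_rm <- if (drop_x) featureMeta(block)$chr_x else rep(FALSE, nrow(v))
  removed <- det_rm | x_rm
  report <- list(
    n_input_loci = nrow(v),
    n_detection_removed = sum(det_rm),
    n_x_removed = sum(x_rm),
    n_removed = sum(removed),
    n_retained = sum(!removed),
    removed_ids = rownames(v)[removed]
  )
  list(block = block[!removed, ], report = report)
}

.geomean <- function(x) exp(mean(log(x)))

#' Positive-control normalization of count data
#'
#' Computes, per sample, the geometric mean of the positive-control probes
#' and scales every non-control count by
#' `f_s = mean_s(geomean_s) / geomean_s`, the lane factor that equalizes
#' positive-control geometric means across samples. Positive-control rows
#' are scaled too (so the equalization is assertable); normalized counts are
#' kept as reals.
#'
#' @param block miRNA [OmicsBlock-class] with `control_role == "positive"`
#'   rows.
#' @param n_expected expected number of positive-control rows (default 6).
#' @return the normalized block, with per-sample factors in
#'   `metadata(block)$positive_factors`.
#' @export
normalizeMirnaPositive <- function(block, n_expected = 6) {
  stopifnot(is(block, "OmicsBlock"))
  role <- featureMeta(block)$control_role
  pos <- which(role == "positive")
  if (length(pos) != n_expected) {
    stop("expected ", n_expected, " positive-control rows, found ", length(pos))
  }
  v <- blockValues(block)
  if (any(v[pos, ] <= 0, na.rm = TRUE)) {
    bad <- colnames(v)[apply(v[pos, , drop = FALSE] <= 0, 2, any)]
    stop("nonpositive positive-control count in sample(s): ",
         paste(na.omit(bad), collapse = ", "))
  }
  gm <- apply(v[pos, , drop = FALSE], 2, .geomean)
  f <- mean(gm) / gm
  v_norm <- sweep(v, 2, f, `*`)
  out <- block
  SummarizedExperiment::assay(out, "values") <- v_norm
  S4Vectors::metadata(out)$positive_factors <- f
  out
}

#' Upper-quantile negative-control background floor
#'
#' Per sample, the background `b_s` is the configured upper quantile
#' (linear interpolation, default 0.75) of that sample's negative-control
#' counts; every non-control count below `b_s` is floored to `b_s` and
#' flagged below-background. Flooring (rather than subtraction) keeps counts
#' nonnegative and negative-binomial modeling valid.
#'
#' @param block miRNA [OmicsBlock-class] with `control_role == "negative"`
#'   rows.
#' @param quantile background quantile in \[0, 1\] (default 0.75).
#' @return the block with floored values; the logical below-background flag
#'   matrix is stored as assay `"below_background"` and the per-sample
#'   backgrounds in `metadata(block)$background`.
#' @export
applyNegativeBackground <- function(block, quantile = 0.75) {
  stopifnot(is(block, "OmicsBlock"))
  role <- featureMeta(block)$control_role
  neg <- which(role == "negative")
  if (!length(neg)) stop("no negative-control rows present")
  v <- blockValues(block)
  b <- apply(v[neg, , drop = FALSE], 2, stats::quantile, probs = quantile,
             na.rm = TRUE, type = 7)
  noncontrol <- role == "none"
  flag <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  floor_m <- matrix(rep(b, each = nrow(v)), nrow(v), ncol(v))
  low <- noncontrol & !is.na(v) & v < floor_m
  flag[low] <- TRUE
  v[low] <- floor_m[low]
  out <- block
  SummarizedExperiment::assay(out, "values") <- v
  SummarizedExperiment::assay(out, "below_background", withDimnames = FALSE) <- flag
  S4Vectors::metadata(out)$background <- b
  out
}

#' Housekeeping delta-Ct normalization
#'
#' `deltaCt(g, s) = Ct(g, s) - mean(Ct(housekeeping, s))`; housekeeping rows
#' are removed from the output. A sample missing any housekeeping Ct has all
#' its delta-Ct values set missing (with a message). The output is invariant
#' to adding a per-sample constant to all Ct rows (plate-shift invariance).
#'
#' @param block qPCR Ct [OmicsBlock-class] with
#'   `control_role == "housekeeping"` rows.
#' @param n_expected expected number of housekeeping rows (default 5).
#' @return delta-Ct [OmicsBlock-class] without the housekeeping rows.
#' @export
normalizeDeltaCt <- function(block, n_expected = 5) {
  stopifnot(is(block, "OmicsBlock"))
  role <- featureMeta(block)$control_role
  hk <- which(role == "housekeeping")
  if (length(hk) != n_expected) {
    stop("expected ", n_expected, " housekeeping rows, found ", length(hk))
  }
  v <- blockValues(block)
  hk_mean <- colMeans(v[hk, , drop = FALSE])
  if (anyNA(hk_mean)) {
    message("samples with missing housekeeping Ct set to NA: ",
            paste(colnames(v)[is.na(hk_mean)], collapse = ", "))
  }
  dct <- sweep(v[-hk, , drop = FALSE], 2, hk_mean, `-`)
  OmicsBlock(dct, "stemcell",
             featureMeta = featureMeta(block)[-hk, , drop = FALSE])
}
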