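#' @include AllClasses.R
NULL

#' Negative-binomial exact test for count differences between two groups
#'
#' For each feature, the two group sums are modeled as sums of independent
#' negative-binomial counts sharing a pooled mean and a per-feature
#' dispersion fit by maximum likelihood on all samples blind to the group
#' labels (floored at 1e-8). Conditioning on the total, the two-sided exact
#' p-value is the probability mass of all count splits `(a, b)` with `a + b`
#' equal to the observed total whose probability does not exceed the observed
#' split's, normalized by the total mass of all splits. No cross-feature
#' dispersion shrinkage or trend fitting is applied; blind (label-free)
#' per-feature estimation keeps the test's type-I rate near nominal at small
#' group sizes, at the cost of conservatism for strongly shifted features.
#'
#' @param counts nonnegative integer feature-by-sample matrix.
#' @param groups two-level factor (or coercible) over the columns; each level
#'   needs at least 2 samples.
#' @return `data.frame` with `feature`, `mean_a`, `mean_b`, `dispersion`,
#'   `p_value`, `q_value` (Benjamini-Hochberg over features).
#' @examples
#' set.seed(1)
#' m <- matrix(rnbinom(60, mu = 50, size = 5), 10, 6,
#'   dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
#' nbTest(m, rep(c("a", "b"), each = 3))
#' @export
nbTest <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE) ||
      any(counts != round(counts), na.rm = TRUE)) {
    stop("counts must be nonnegative integers; round normalized values first")
  }
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  na <- length(ia)
  nb <- length(ib)

  res <- lapply(seq_len(nrow(counts)), function(i) {
    xa <- counts[i, ia]
    xb <- counts[i, ib]
    mu <- mean(c(xa, xb))
    disp <- .nbBlindDispersion(c(xa, xb))
    p <- .nbExactP(sum(xa), sum(xb), na, nb, mu, disp)
    c(mean_a = mean(xa), mean_b = mean(xb), dispersion = disp, p_value = p)
  })
  res <- as.data.frame(do.call(rbind, res))
  data.frame(
    feature = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    res,
    q_value = bhAdjust(res$p_value),
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-feature NB dispersion, maximum likelihood over all samples with the
# mean fixed at the sample mean (blind to group labels); floored at 1e-8
.nbBlindDispersion <- function(x, floor = 1e-8, ceiling = 10) {
  mu <- mean(x)
  if (mu == 0 || var(x) == 0) {
    return(floor)
  }
  nll <- function(log_disp) {
    -sum(dnbinom(x, mu = mu, size = exp(-log_disp), log = TRUE))
  }
  opt <- optimize(nll, c(log(floor), log(ceiling)))
  max(exp(opt$minimum), floor)
}

.nbExactP <- function(ka, kb, na, nb, mu, disp) {
  total <- ka + kb
  if (total == 0 || mu == 0) {
    return(1)
  }
  ks <- 0:total
  pa <- dnbinom(ks, mu = na * mu, size = na / disp)
  pb <- dnbinom(total - ks, mu = nb * mu, size = nb / disp)
  probs <- pa * pb
  denom <- sum(probs)
  if (denom == 0) {
    return(1)
  }
  pobs <- probs[ka + 1]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]) / denom)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return q-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Fold change from delta-Ct values (2^-ddCt)
#'
#' `ddCt = mean(deltaCt, group_a) - mean(deltaCt, group_b)`;
#' `fold = 2^(-ddCt)`. A gene is flagged as a 3-fold change when
#' `|log2(fold)| > 1.58` (the log2-fold threshold equivalent to 3-fold).
#'
#' @param dct delta-Ct [OmicsBlock-class] (or numeric matrix).
#' @param group_a,group_b disjoint nonempty character vectors of sample ids.
#' @param log2_threshold flag threshold on `|log2(fold)|` (default 1.58).
#' @return `data.frame` with `gene`, `delta_delta_ct`, `fold_change`,
#'   `log2_fold`, `passes_3fold`, `missing` (gene absent in a whole group).
#' @export
foldChangeDdct <- function(dct, group_a, group_b, log2_threshold = 1.58) {
  v <- if (is(dct, "OmicsBlock")) blockValues(dct) else as.matrix(dct)
  if (!length(group_a) || !length(group_b)) stop("groups must be nonempty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  missing_cols <- setdiff(c(group_a, group_b), colnames(v))
  if (length(missing_cols)) {
    stop("unknown sample id(s): ", paste(missing_cols, collapse = ", "))
  }
  ma <- rowMeans(v[, group_a, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(v[, group_b, drop = FALSE], na.rm = TRUE)
  ddct <- ma - mb
  miss <- !is.finite(ddct)
  ddct[miss] <- NA_real_
  data.frame(
    gene = rownames(v) %||% as.character(seq_len(nrow(v))),
    delta_delta_ct = ddct,
    fold_change = 2^(-ddct),
    log2_fold = -ddct,
    passes_3fold = !miss & abs(-ddct) > log2_threshold,
    missing = miss,
    row.names = NULL
  )
}

#' Two-group test on delta-Ct values, per gene
#'
#' Two-sided Welch (unequal-variance) t-test of group_a vs group_b delta-Ct
#' values; chosen because measurement variance is not expected to be equal
#' across histology groups. A rank-based alternative
#' (`method = "wilcoxon"`) is available. Degenerate genes (zero variance in
#' both groups with equal means) get p = 1.
#'
#' @inheritParams foldChangeDdct
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @return `data.frame` with `gene` and `p_value`.
#' @export
welchTestDct <- function(dct, group_a, group_b,
                         method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  v <- if (is(dct, "OmicsBlock")) blockValues(dct) else as.matrix(dct)
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  p <- vapply(seq_len(nrow(v)), function(i) {
    xa <- na.omit(v[i, group_a])
    xb <- na.omit(v[i, group_b])
    if (length(xa) < 2 || length(xb) < 2) {
      return(NA_real_)
    }
    if (sd(xa) == 0 && sd(xb) == 0) {
      return(if (mean(xa) == mean(xb)) 1 else 0)
    }
    tryCatch(
      if (method == "welch") {
        t.test(xa, xb)$p.value
      } else {
        suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
      },
      error = function(e) NA_real_
    )
  }, numeric(1))
  data.frame(gene = rownames(v) %||% as.character(seq_len(nrow(v))),
             p_value = p, row.names = NULL)
}

#' Hierarchical clustering of samples (city-block, average linkage)
#'
#' Agglomerative clustering of the sample columns using the Manhattan
#' (city-block) metric and average linkage. Missing entries are handled
#' pairwise-complete with proportional rescaling (the [stats::dist()]
#' convention); a sample with all-missing values is excluded with a message.
#'
#' @param m numeric feature-by-sample matrix (or [OmicsBlock-class]).
#' @param metric distance metric for [stats::dist()] (default
#'   `"manhattan"`).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return an `hclust` object (merge heights are nondecreasing for this
#'   metric/linkage pair).
#' @export
hclusterSamples <- function(m, metric = "manhattan", linkage = "average") {
  v <- if (is(m, "OmicsBlock")) blockValues(m) else as.matrix(m)
  if (ncol(v) < 2L) stop("need at least 2 samples to cluster")
  all_na <- colSums(!is.na(v)) == 0L
  if (any(all_na)) {
    message("excluding all-missing sample(s): ",
            paste(colnames(v)[all_na], collapse = ", "))
    v <- v[, !all_na, drop = FALSE]
  }
  hclust(dist(t(v), method = metric), method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an `hclust` object.
#' @param file optional path; when given the tree is written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
dendrogramNewick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
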