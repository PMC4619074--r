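test_that("nb test gives p = 1 for identical groups and validates input", {
  m <- matrix(7L, 4, 6, dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
  res <- nbTest(m, rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, rep(1, 4), tolerance = 1e-9)
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  expect_error(nbTest(m / 2, rep(c("a", "b"), each = 3)), "integers")
  expect_error(nbTest(m, rep(c("a", "b"), c(5, 1))), "at least 2")
  expect_error(nbTest(m, rep("a", 6)), "two groups")
})

test_that("nb test is calibrated under the null and powerful under shift", {
  set.seed(42)
  m <- matrix(rnbinom(2000 * 6, mu = 50, size = 5), 2000, 6,
              dimnames = list(paste0("f", 1:2000), paste0("s", 1:6)))
  res <- nbTest(m, rep(c("a", "b"), each = 3))
  rate <- mean(res$p_value < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  # no anticonservatism over the operating range of rejection levels
  alphas <- seq(0.005, 0.1, by = 0.005)
  expect_lt(max(ecdf(res$p_value)(alphas) - alphas), 0.03)

  set.seed(43)
  mp <- cbind(
    matrix(rnbinom(200 * 4, mu = 50, size = 10), 200, 4),
    matrix(rnbinom(200 * 4, mu = 400, size = 10), 200, 4)
  )
  dimnames(mp) <- list(paste0("g", 1:200), paste0("s", 1:8))
  rp <- nbTest(mp, rep(c("a", "b"), each = 4))
  expect_gte(mean(rp$q_value < 0.05), 0.9)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  # monotone in p; fixed points (flat profiles) are left unchanged
  set.seed(1)
  p <- runif(50)
  q <- bhAdjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p))
  expect_equal(bhAdjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ddCt fold changes flag 3-fold (log2 > 1.58) and are antisymmetric", {
  dct <- matrix(
    c(5, 5, 5, 6, 6, 6, 6.58, 6.58, 6.58, 6.59, 6.59, 6.59),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("flat", "one_cycle", "at_thresh", "over_thresh"),
                    c("A1", "A2", "A3"))
  )
  dct <- cbind(dct, matrix(5, 4, 3, dimnames = list(NULL, c("B1", "B2", "B3"))))
  res <- foldChangeDdct(dct, c("A1", "A2", "A3"), c("B1", "B2", "B3"))
  expect_equal(res$fold_change[res$gene == "flat"], 1)
  expect_false(res$passes_3fold[res$gene == "flat"])
  # ddCt = +1 -> fold 0.5, log2 fold = -1
  expect_equal(res$fold_change[res$gene == "one_cycle"], 0.5)
  expect_equal(res$log2_fold[res$gene == "one_cycle"], -1)
  # |log2 fold| = 1.58 exactly: not flagged (strictly above fires)
  expect_false(res$passes_3fold[res$gene == "at_thresh"])
  expect_true(res$passes_3fold[res$gene == "over_thresh"])

  # a true 3-fold change sits just above the 1.58 cutoff
  d3 <- matrix(c(rep(-log2(3), 3), rep(0, 3)), 1,
               dimnames = list("g", c("A1", "A2", "A3", "B1", "B2", "B3")))
  r3 <- foldChangeDdct(d3, c("A1", "A2", "A3"), c("B1", "B2", "B3"))
  expect_equal(r3$fold_change, 3, tolerance = 1e-12)
  expect_true(r3$passes_3fold)

  # antisymmetry: fold(a,b) * fold(b,a) = 1 per gene
  fwd <- foldChangeDdct(dct, c("A1", "A2", "A3"), c("B1", "B2", "B3"))
  rev <- foldChangeDdct(dct, c("B1", "B2", "B3"), c("A1", "A2", "A3"))
  expect_equal(fwd$fold_change * rev$fold_change, rep(1, 4))

  expect_error(foldChangeDdct(dct, c("A1", "B1"), c("B1", "B2")), "disjoint")
})

test_that("Welch test on dCt is calibrated and detects shifts", {
  set.seed(11)
  null_m <- matrix(rnorm(2000 * 17), 2000, 17,
                   dimnames = list(NULL, paste0("s", 1:17)))
  ga <- paste0("s", 1:8)
  gb <- paste0("s", 9:17)
  p0 <- welchTestDct(null_m, ga, gb)$p_value
  expect_gte(mean(p0 < 0.05), 0.03)
  expect_lte(mean(p0 < 0.05), 0.07)

  shift_m <- null_m
  shift_m[, gb] <- shift_m[, gb] + 3
  p1 <- welchTestDct(shift_m, ga, gb)$p_value
  expect_gte(mean(p1 < 0.05), 0.95)

  # degenerate: identical constant groups -> p = 1
  const <- matrix(2, 1, 17, dimnames = list("g", paste0("s", 1:17)))
  expect_equal(welchTestDct(const, ga, gb)$p_value, 1)
})

test_that("sample clustering reproduces hand agglomeration on the line", {
  # 1-D city block points 0, 1, 10, 11: pairs merge at height 1,
  # final average-linkage merge at 10
  m <- matrix(c(0, 1, 10, 11), 1, dimnames = list("f", paste0("s", 1:4)))
  hc <- hclusterSamples(m)
  expect_equal(sort(hc$height), c(1, 1, 10))
  expect_true(all(diff(hc$height) >= -1e-12))

  # identical pair merges first at height 0
  m2 <- matrix(c(1, 1, 9), 1, dimnames = list("f", c("a", "b", "c")))
  hc2 <- hclusterSamples(m2)
  expect_equal(hc2$height[1], 0)

  # column order only relabels the dendrogram
  set.seed(3)
  m3 <- matrix(rnorm(40), 5, 8, dimnames = list(NULL, paste0("s", 1:8)))
  perm <- sample(8)
  h_a <- hclusterSamples(m3)
  h_b <- hclusterSamples(m3[, perm])
  expect_equal(sort(h_a$height), sort(h_b$height))

  # all-missing sample is excluded with a message
  m4 <- m3
  m4[, 1] <- NA
  expect_message(h4 <- hclusterSamples(m4), "all-missing")
  expect_equal(length(h4$order), 7)

  # Newick export round-trips through ape
  nwk <- dendrogramNewick(hclusterSamples(m3))
  expect_equal(length(ape::read.tree(text = nwk)$tip.label), 8)
})
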