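test_that("beta is the methylated fraction of total signal", {
  expect_equal(computeBeta(500, 0), 1)
  expect_equal(computeBeta(300, 300), 0.5)
  expect_equal(computeBeta(100, 300), 0.25)
  expect_warning(b <- computeBeta(0, 0), "zero total signal")
  expect_true(is.na(b))
  expect_error(computeBeta(-1, 5), "nonnegative")
  # vectorized with an offset option
  expect_equal(computeBeta(c(100, 300), c(300, 100)), c(0.25, 0.75))
  expect_equal(computeBeta(100, 300, offset = 100), 0.2)
})

test_that("locus filter removes the union of detection failures and chrX", {
  n <- 8
  beta <- matrix(runif(5 * n), 5, n,
                 dimnames = list(paste0("cg", 1:5), paste0("S", 1:n)))
  detp <- matrix(0.01, 5, n, dimnames = dimnames(beta))
  detp[1, 1:2] <- 0.2            # 2/8 = 25% failing -> removed (inclusive)
  detp[2, 1] <- 0.2              # 1/8 -> retained
  blk <- makeBlock(beta, "methylation",
                   gene_symbol = paste0("G", 1:5),
                   chr_x = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- filterMethylationLoci(blk, detp)
  expect_setequal(out$report$removed_ids, c("cg1", "cg3"))
  expect_equal(out$report$n_retained, 3)
  expect_equal(out$report$n_detection_removed, 1)
  expect_equal(out$report$n_x_removed, 1)

  # no-op on a clean panel
  clean <- filterMethylationLoci(
    makeBlock(beta, "methylation", chr_x = rep(FALSE, 5)), detp * 0 + 0.01
  )
  expect_equal(clean$report$n_retained, 5)

  # idempotent: re-filtering the filtered block removes nothing
  again <- filterMethylationLoci(out$block, detp[rownames(out$block), ])
  expect_equal(again$report$n_removed, 0)

  expect_error(filterMethylationLoci(blk, detp[, 1:3]), "not aligned")
})

test_that("positive-control normalization equalizes control geomeans", {
  counts <- rbind(
    m1 = c(10, 40), m2 = c(20, 80), m3 = c(5, 30),
    p1 = c(100, 400), p2 = c(100, 400), p3 = c(100, 400),
    p4 = c(100, 400), p5 = c(100, 400), p6 = c(100, 400)
  )
  colnames(counts) <- c("A", "B")
  blk <- makeBlock(counts, "mirna",
                   control_role = c(rep("none", 3), rep("positive", 6)))
  out <- normalizeMirnaPositive(blk)
  f <- S4Vectors::metadata(out)$positive_factors
  # geomeans 100 and 400, cohort mean 250 -> factors 2.5 and 0.625
  expect_equal(unname(f), c(2.5, 0.625))
  v <- blockValues(out)
  gm <- apply(v[4:9, ], 2, function(x) exp(mean(log(x))))
  expect_equal(unname(gm[1]), unname(gm[2]), tolerance = 1e-9)
  # rank order within each sample is preserved
  expect_equal(order(v[1:3, "A"]), order(counts[1:3, "A"]))

  # scale invariance: doubling one sample's counts halves its relative
  # factor, so its normalized counts change only by the global rescaling of
  # the cohort target (the mean positive-control geomean)
  doubled <- counts
  doubled[, "A"] <- doubled[, "A"] * 2
  blk2 <- makeBlock(doubled, "mirna",
                    control_role = c(rep("none", 3), rep("positive", 6)))
  out2 <- normalizeMirnaPositive(blk2)
  f2 <- S4Vectors::metadata(out2)$positive_factors
  target_ratio <- mean(c(200, 400)) / mean(c(100, 400))
  expect_equal(unname(f2["A"] / f["A"]), target_ratio / 2)
  expect_equal(blockValues(out2)[1:3, "A"], v[1:3, "A"] * target_ratio)
  expect_equal(blockValues(out2)[1:3, "B"], v[1:3, "B"] * target_ratio)

  bad <- counts
  bad["p1", "A"] <- 0
  expect_error(
    normalizeMirnaPositive(makeBlock(
      bad, "mirna", control_role = c(rep("none", 3), rep("positive", 6))
    )),
    "sample"
  )
})

test_that("negative-control background floors low counts and flags them", {
  counts <- rbind(
    m1 = c(2, 10), m2 = c(3.25, 1), m3 = c(50, 0),
    n1 = c(1, 0), n2 = c(2, 0), n3 = c(3, 0), n4 = c(4, 0)
  )
  colnames(counts) <- c("A", "B")
  blk <- makeBlock(counts, "mirna",
                   control_role = c(rep("none", 3), rep("negative", 4)))
  out <- applyNegativeBackground(blk)
  b <- S4Vectors::metadata(out)$background
  expect_equal(unname(b["A"]), 3.25)  # type-7 quantile of {1,2,3,4}
  expect_equal(unname(b["B"]), 0)
  v <- blockValues(out)
  flags <- SummarizedExperiment::assay(out, "below_background")
  expect_equal(v["m1", "A"], 3.25)
  expect_true(flags["m1", "A"])
  expect_equal(v["m2", "A"], 3.25)   # equal to background: unchanged
  expect_false(flags["m2", "A"])
  expect_equal(v["m3", "A"], 50)
  # zero background floors nothing
  expect_equal(v[1:3, "B"], counts[1:3, "B"])
  expect_false(any(flags[, "B"]))
  expect_error(
    applyNegativeBackground(makeBlock(counts[1:3, ], "mirna",
                                      control_role = rep("none", 3))),
    "negative-control"
  )
})

test_that("delta-Ct normalization centers on the housekeeping mean", {
  ct <- rbind(
    g1 = c(24, 25), g2 = c(20, 21),
    h1 = c(18, 19), h2 = c(19, 20), h3 = c(20, 21), h4 = c(21, 22),
    h5 = c(22, 23)
  )
  colnames(ct) <- c("A", "B")
  blk <- makeBlock(ct, "stemcell",
                   gene_symbol = rownames(ct),
                   control_role = c("none", "none", rep("housekeeping", 5)))
  out <- normalizeDeltaCt(blk)
  expect_equal(nrow(out), 2)
  expect_equal(blockValues(out)["g1", "A"], 4)  # housekeeping mean = 20
  expect_equal(blockValues(out)["g2", "A"], 0)

  # plate-shift invariance: adding a per-sample constant changes nothing
  shifted <- sweep(ct, 2, c(1.7, -0.4), `+`)
  blk2 <- makeBlock(shifted, "stemcell",
                    gene_symbol = rownames(ct),
                    control_role = c("none", "none", rep("housekeeping", 5)))
  expect_equal(blockValues(normalizeDeltaCt(blk2)), blockValues(out))

  expect_error(normalizeDeltaCt(blk, n_expected = 4), "housekeeping")
})
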