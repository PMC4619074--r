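test_that("generation is deterministic and respects the spec's panel counts", {
  spec <- smallCohortSpec(seed = 5)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(blockValues(a@methylation), blockValues(b@methylation))
  expect_identical(blockValues(a@mirna), blockValues(b@mirna))
  expect_identical(blockValues(a@stemcell), blockValues(b@stemcell))
  expect_identical(a@genotypes, b@genotypes)
  expect_identical(a@annotations, b@annotations)

  expect_equal(nrow(a@methylation), spec$n_cpg)
  expect_equal(sum(featureMeta(a@methylation)$chr_x), spec$n_x_linked)
  frac_fail <- rowMeans(a@detectionP > 0.05)
  expect_equal(sum(frac_fail >= 0.25), spec$n_detection_fail)
  expect_equal(nrow(a@annotations), spec$n_samples)
  expect_equal(unname(table(a@annotations$histology)["yst"]), 8)
})

test_that("marginals are sane: beta in [0,1], counts overdispersed integers", {
  co <- generateCohort(smallCohortSpec(seed = 2, n_mirna = 100))
  beta <- blockValues(co@methylation)
  expect_true(all(beta >= 0 & beta <= 1))
  counts <- blockValues(co@mirna)
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  mir <- counts[featureMeta(co@mirna)$control_role == "none", ]
  vm <- apply(mir, 1, var) - rowMeans(mir)
  expect_gt(mean(vm > 0), 0.95)
})

test_that("empty hub list yields an independent cohort with empty truth", {
  co <- generateCohort(smallCohortSpec(seed = 3, with_hub = FALSE))
  expect_length(cohortTruth(co)$planted_edges, 0)
  expect_length(cohortTruth(co)$planted_hubs, 0)
})

test_that("planted linear hub-spoke pairs exceed |r| 0.75 in >=90% of seeds", {
  # realizability calibration at effect_size = 2 * noise_sd, n = 40, on the
  # normalized per-platform values the correlation stage consumes (plate and
  # lane effects are nuisance noise that prep removes)
  hits <- 0L
  total <- 0L
  for (s in 1:100) {
    co <- generateCohort(smallCohortSpec(seed = s))
    tr <- cohortTruth(co)
    prepped <- list(
      methylation = blockValues(
        filterMethylationLoci(co@methylation, co@detectionP)$block
      ),
      mirna = blockValues(
        applyNegativeBackground(normalizeMirnaPositive(co@mirna))
      ),
      stemcell = blockValues(normalizeDeltaCt(co@stemcell))
    )
    for (e in tr$planted_edges) {
      r <- cor(prepped[[e$platform_a]][e$feature_a, ],
               prepped[[e$platform_b]][e$feature_b, ])
      total <- total + 1L
      if (abs(r) > 0.75) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("infeasible and malformed specs are rejected", {
  expect_error(cohortSpec(n_cpg = 50, n_x_linked = 40, n_detection_fail = 20),
               "infeasible")
  expect_error(cohortSpec(histology_counts = c(yst = 10)), "sum to n_samples")
  expect_error(cohortSpec(noise_sd = -1), "noise_sd")
  expect_error(
    hubSpec("h", "stemcell",
            data.frame(feature = c("a", "b", "c"),
                       platform = rep("mirna", 3))),
    "at least 4 spokes"
  )
})

test_that("cohorts round-trip losslessly through the TSV writers", {
  co <- generateCohort(smallCohortSpec(seed = 9))
  dir <- withr::local_tempdir()
  paths <- writeCohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- readCohort(dir)
  expect_identical(blockValues(back@methylation), blockValues(co@methylation))
  expect_identical(back@detectionP, co@detectionP)
  expect_identical(blockValues(back@mirna), blockValues(co@mirna))
  expect_identical(blockValues(back@stemcell), blockValues(co@stemcell))
  expect_identical(back@genotypes, co@genotypes)
  expect_identical(back@annotations, co@annotations)
  expect_identical(
    featureMeta(back@methylation)$chr_x, featureMeta(co@methylation)$chr_x
  )
  expect_equal(length(back@truth$planted_edges), length(co@truth$planted_edges))

  # writing twice gives identical bytes
  dir2 <- withr::local_tempdir()
  writeCohort(co, dir2)
  for (f in basename(paths)) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})

test_that("per-platform missingness masks blank the requested samples", {
  co <- generateCohort(smallCohortSpec(
    seed = 4, exclude_samples = list(mirna = "S001")
  ))
  expect_true(all(is.na(blockValues(co@mirna)[, "S001"])))
  expect_false(anyNA(blockValues(co@methylation)[, "S001"]))
})
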