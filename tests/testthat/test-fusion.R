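test_that("genotype encoding reproduces the full transition/transversion table", {
  codes <- defaultGenotypeCodes()
  expect_length(codes, 10)
  expect_equal(encodeGenotype("a/g"), 3.0)
  expect_equal(encodeGenotype("g/a"), 3.0)  # order-insensitive
  expect_equal(encodeGenotype("t/t"), -4.0)
  expect_equal(encodeGenotype("C/T"), -3.0) # case-insensitive
  got <- vapply(names(codes), encodeGenotype, numeric(1))
  expect_equal(unname(got), unname(codes))
  expect_true(!anyDuplicated(codes))  # injective lookup

  expect_error(
    encodeGenotype("a/a", table = codes[names(codes) != "a/a"],
                   context = "KITLG, S01"),
    "KITLG, S01"
  )
  expect_error(encodeGenotype("a/x"), "malformed")
  expect_true(is.na(encodeGenotype(NA_character_)))
})

test_that("phenotype encoding maps severity orderings and passes age through", {
  ann <- data.frame(
    sample_id = c("S1", "S2", "S3"),
    age_years = c(13.5, 2, 8),
    sex = c("female", "male", "female"),
    location = c("ovary", "testis", "extragonadal"),
    histology = c("normal_adjacent", "yst", "dysgerminoma")
  )
  blk <- encodePhenotypes(ann)
  v <- blockValues(blk)
  expect_equal(v["histology", "S1"], 0)  # normal adjacent anchors at 0
  expect_equal(v["histology", "S2"], 3)
  expect_equal(v["age", "S1"], 13.5)
  expect_equal(platformName(blk), "phenotype")

  # two samples differing only in sex differ only in the sex row
  ann2 <- ann
  ann2$sex[1] <- "male"
  v2 <- blockValues(encodePhenotypes(ann2))
  diffs <- rownames(v)[rowSums(v != v2) > 0]
  expect_equal(diffs, "sex")

  expect_error(encodePhenotypes(transform(ann, histology = "unknown")),
               "histology")
})

test_that("fusion stacks platforms over the complete-sample intersection", {
  samples <- paste0("S", 1:4)
  b1 <- makeBlock(
    matrix(runif(8), 2, 4, dimnames = list(c("cg1", "cg2"), samples)),
    "methylation", gene_symbol = c("G1", "G2")
  )
  m2 <- matrix(rpois(12, 10), 3, 4,
               dimnames = list(c("miR1", "miR2", "POS_A"), samples))
  b2 <- makeBlock(m2, "mirna", gene_symbol = c("M1", "M2", NA),
                  control_role = c("none", "none", "positive"))

  fused <- buildFusedMatrix(list(b1, b2))
  expect_s4_class(fused, "FusedMatrix")
  expect_equal(ncol(fused), 4)
  expect_equal(nrow(fused), 4)  # control row excluded
  expect_false("POS_A" %in% rownames(fused))
  expect_equal(unname(table(platformTags(fused))["methylation"]), 2)

  # a sample missing in one block is dropped from the fusion
  m2na <- m2
  m2na[, "S3"] <- NA
  b2na <- makeBlock(m2na, "mirna", gene_symbol = c("M1", "M2", NA),
                    control_role = c("none", "none", "positive"))
  expect_message(f2 <- buildFusedMatrix(list(b1, b2na)), "S3")
  expect_setequal(colnames(f2), c("S1", "S2", "S4"))

  expect_error(buildFusedMatrix(list(b1)), "at least 2")
  b_disjoint <- makeBlock(
    matrix(1:2, 1, 2, dimnames = list("x", c("T1", "T2"))), "stemcell"
  )
  expect_error(suppressMessages(buildFusedMatrix(list(b1, b_disjoint))),
               "no sample")
})

test_that("histology subsetting drops exactly the excluded samples", {
  co <- generateCohort(smallCohortSpec(seed = 6))
  fused <- prepAndFuse(co)
  expect_equal(ncol(fused), 40)
  sub <- subsetSamples(fused, "yst")
  expect_equal(ncol(sub), 32)
  expect_equal(nrow(sub), nrow(fused))
  # idempotent; absent histology is the identity
  expect_equal(ncol(subsetSamples(sub, "yst")), 32)
  expect_equal(dim(subsetSamples(sub, "dummy_level")), dim(sub))
  # decoding the histology row agrees with the annotations
  sub2 <- subsetSamples(fused, "yst", annotations = co@annotations)
  expect_identical(colnames(sub), colnames(sub2))

  # fused row count = sum of block rows minus controls/housekeeping
  spec <- co@spec
  expect_equal(
    nrow(fused),
    (spec$n_cpg - spec$n_detection_fail - spec$n_x_linked) + spec$n_mirna +
      spec$n_genes + 4 + 4
  )
})
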