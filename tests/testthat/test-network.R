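makePairs <- function() {
  data.frame(
    feature_a = c("cg1", "miR1", "miR1", "g1", "g2"),
    platform_a = c("methylation", "mirna", "mirna", "stemcell", "stemcell"),
    feature_b = c("cg2", "cg1", "g1", "cg3", "cg2"),
    platform_b = c("methylation", "methylation", "stemcell", "methylation",
                   "methylation"),
    n_used = 40L,
    pearson_r = c(0.9, 0.80, -0.9, 0.2, 0.70),
    mic = c(0.9, 0.30, 0.4, 0.85, 0.70),
    stringsAsFactors = FALSE
  )
}

test_that("edge filter enforces cross-platform and threshold rules", {
  e <- filterEdges(makePairs())
  # same-platform pair excluded even at mic 0.9
  expect_false(any(e$feature_a == "cg1" & e$feature_b == "cg2"))
  # pearson 0.80 / mic 0.30 kept with weight 0.80 (the larger qualifier)
  row <- e[e$feature_a == "miR1" & e$feature_b == "cg1", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$weight, 0.80)
  # anti-correlation qualifies via |r| by default, not in signed mode
  expect_true(any(e$feature_a == "miR1" & e$feature_b == "g1"))
  signed <- filterEdges(makePairs(), networkConfig(use_absolute_pearson = FALSE))
  expect_false(any(signed$feature_a == "miR1" & signed$feature_b == "g1"))
  # mic-only edge keeps the mic as weight
  expect_equal(e$weight[e$feature_a == "g1"], 0.85)
  # both components below threshold: excluded
  expect_false(any(e$feature_a == "g2"))
  # missing components never qualify
  p <- makePairs()
  p$pearson_r[2] <- NA
  expect_false(any(filterEdges(p)$feature_b == "cg1"))
  # pair order is irrelevant
  perm <- makePairs()[c(4, 2, 5, 1, 3), ]
  e2 <- filterEdges(perm)
  expect_setequal(paste(e2$feature_a, e2$feature_b),
                  paste(e$feature_a, e$feature_b))
})

test_that("networks are transitive-closure components with degree-4 hubs", {
  edges <- data.frame(
    feature_a = c("a", "b", "x"),
    platform_a = c("mirna", "methylation", "stemcell"),
    feature_b = c("b", "c", "y"),
    platform_b = c("methylation", "stemcell", "mirna"),
    n_used = 40L, pearson_r = 0.9, mic = 0.2, weight = 0.9
  )
  net <- buildNetwork(edges)
  g <- net@graph
  expect_equal(igraph::count_components(g), 2)
  comp <- igraph::V(g)$component
  expect_setequal(unique(comp), c("a", "x"))  # named by smallest member

  # star with 4 spokes is a hub; 3 spokes is not
  star <- function(k) data.frame(
    feature_a = "hub", platform_a = "stemcell",
    feature_b = paste0("s", 1:k), platform_b = "mirna",
    n_used = 40L, pearson_r = 0.9, mic = 0.2, weight = 0.9
  )
  expect_equal(findHubs(buildNetwork(star(4)))$hub, "hub")
  expect_equal(nrow(findHubs(buildNetwork(star(3)))), 0)
  expect_equal(findHubs(buildNetwork(star(5)))$degree, 5)
  expect_setequal(findHubs(buildNetwork(star(4)))$neighbors[[1]],
                  paste0("s", 1:4))

  # empty edge list -> empty network, no hubs
  empty <- buildNetwork(edges[0, ])
  expect_equal(igraph::vcount(empty@graph), 0)
  expect_equal(nrow(findHubs(empty)), 0)
})

test_that("hub sets shrink as the threshold rises", {
  co <- generateCohort(smallCohortSpec(seed = 12))
  pairs <- allPairs(prepAndFuse(co))
  hubs_at <- function(th) {
    cfg <- networkConfig(threshold = th)
    findHubs(buildNetwork(filterEdges(pairs, cfg), cfg))$hub
  }
  h75 <- hubs_at(0.75)
  h85 <- hubs_at(0.85)
  h95 <- hubs_at(0.95)
  expect_true(all(h85 %in% h75))
  expect_true(all(h95 %in% h85))
  # no same-platform edge ever appears
  e <- filterEdges(pairs)
  expect_false(any(e$platform_a == e$platform_b))
})

test_that("hub gene lists map features to unique symbols and drop unnamed", {
  report <- data.frame(
    hub = "g1", platform = "stemcell", degree = 4, stringsAsFactors = FALSE
  )
  report$neighbors <- list(c("miR1", "cg1", "age", "cg2"))
  map <- c(g1 = "G1", miR1 = "MIRX", cg1 = "G2", cg2 = "G1", age = NA)
  expect_message(gl <- hubGeneList(report, map), "without a gene symbol")
  expect_setequal(gl, c("G1", "MIRX", "G2"))  # deduplicated, age dropped
  expect_equal(hubGeneList(report[0, ], map), character())
})

test_that("planted hubs are recovered and nulls stay empty (10-seed check)", {
  planted <- smallSpecPlanted()
  allowed <- c(planted$hub, planted$spokes, "histology", "age", "sex",
               "location")
  recovered <- 0L
  clean <- 0L
  for (s in 1:10) {
    co <- generateCohort(smallCohortSpec(seed = 100 + s))
    hubs <- findHubs(buildNetwork(filterEdges(allPairs(prepAndFuse(co)))))$hub
    if (planted$hub %in% hubs) recovered <- recovered + 1L
    if (all(hubs %in% allowed)) clean <- clean + 1L
  }
  expect_gte(recovered, 9L)
  expect_gte(clean, 9L)

  null_empty <- 0L
  cfg <- networkConfig(threshold = 0.95)
  for (s in 1:10) {
    co <- generateCohort(smallCohortSpec(seed = 200 + s, with_hub = FALSE))
    hubs <- findHubs(buildNetwork(filterEdges(allPairs(prepAndFuse(co)), cfg),
                                  cfg))
    if (nrow(hubs) == 0L) null_empty <- null_empty + 1L
  }
  expect_gte(null_empty, 9L)
})

test_that("GraphML export writes node and edge attributes", {
  edges <- data.frame(
    feature_a = "hub", platform_a = "stemcell",
    feature_b = paste0("s", 1:4), platform_b = "mirna",
    n_used = 40L, pearson_r = 0.9, mic = 0.2, weight = 0.9
  )
  net <- buildNetwork(edges)
  f <- withr::local_tempfile(fileext = ".graphml")
  writeNetworkGraphML(net, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g2), 5)
  expect_true("platform" %in% igraph::vertex_attr_names(g2))
  expect_true("weight" %in% igraph::edge_attr_names(g2))
})
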