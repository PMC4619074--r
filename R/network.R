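#' @include association.R
NULL

#' Network construction configuration
#'
#' @param threshold correlation threshold in (0, 1\] (default 0.75): a pair
#'   becomes an edge when `|pearson_r|` (or `pearson_r` if
#'   `use_absolute_pearson = FALSE`) or `mic` reaches the threshold.
#' @param min_hub_degree a node with at least this many neighbors is a hub
#'   (default 4).
#' @param use_absolute_pearson qualify anti-correlations too (default
#'   `TRUE`).
#' @return a `networkConfig` list.
#' @export
networkConfig <- function(threshold = 0.75, min_hub_degree = 4,
                          use_absolute_pearson = TRUE) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (min_hub_degree < 1) stop("min_hub_degree must be at least 1")
  structure(
    list(
      threshold = threshold, min_hub_degree = as.integer(min_hub_degree),
      use_absolute_pearson = use_absolute_pearson
    ),
    class = "networkConfig"
  )
}

#' Filter correlation pairs to thresholded cross-platform edges
#'
#' Keeps a pair only when its two features come from different platforms
#' (a phenotype variable pairs with any molecular platform) and either the
#' Pearson magnitude or the MIC reaches the threshold. The edge weight is the
#' larger of the qualifying magnitudes; missing components never qualify.
#'
#' @param pairs the [allPairs()] table.
#' @param config a [networkConfig()].
#' @return the edge subset of `pairs`, with a `weight` column equal to the
#'   larger qualifying magnitude.
#' @export
filterEdges <- function(pairs, config = networkConfig()) {
  pr <- if (config$use_absolute_pearson) abs(pairs$pearson_r) else pairs$pearson_r
  pr_ok <- !is.na(pr) & pr >= config$threshold
  mic_ok <- !is.na(pairs$mic) & pairs$mic >= config$threshold
  cross <- pairs$platform_a != pairs$platform_b
  keep <- cross & (pr_ok | mic_ok)
  out <- pairs[keep, , drop = FALSE]
  qual_p <- ifelse(pr_ok[keep], abs(out$pearson_r), -Inf)
  qual_m <- ifelse(mic_ok[keep], out$mic, -Inf)
  out$weight <- pmax(qual_p, qual_m)
  rownames(out) <- NULL
  out
}

#' Build a correlation network from filtered edges
#'
#' Nodes are the edge endpoints; components are the connected components of
#' the edge set -- single-linkage grouping at a fixed threshold is exactly
#' the transitive closure of above-threshold pairs. Component ids are
#' deterministic (named after their lexicographically smallest member).
#'
#' @param edges a [filterEdges()] table (possibly empty).
#' @param config a [networkConfig()] (stored for hub detection).
#' @return a [CorrelationNetwork-class].
#' @export
buildNetwork <- function(edges, config = networkConfig()) {
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges[c("feature_a", "feature_b", "weight", "pearson_r", "mic")],
      directed = FALSE
    )
    plat <- c(
      setNames(edges$platform_a, edges$feature_a),
      setNames(edges$platform_b, edges$feature_b)
    )
    igraph::V(g)$platform <- unname(plat[igraph::V(g)$name])
    comp <- igraph::components(g)
    labels <- vapply(seq_len(comp$no), function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1))
    igraph::V(g)$component <- labels[comp$membership]
    igraph::V(g)$degree <- igraph::degree(g)
    igraph::V(g)$is_hub <- igraph::degree(g) >= config$min_hub_degree
  } else {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  }
  new("CorrelationNetwork", graph = g, edges = edges,
      config = unclass(config))
}

#' Identify network hubs
#'
#' Hubs are the nodes with at least `min_hub_degree` neighbors; the report
#' lists each hub's neighbors.
#'
#' @param network a [CorrelationNetwork-class].
#' @param config optional [networkConfig()] overriding the stored one.
#' @return `data.frame` with `hub`, `platform`, `degree` and a list-column
#'   `neighbors`; zero rows when there is no hub.
#' @export
findHubs <- function(network, config = NULL) {
  stopifnot(is(network, "CorrelationNetwork"))
  cfg <- if (is.null(config)) network@config else unclass(config)
  g <- network@graph
  if (igraph::vcount(g) == 0L) {
    return(data.frame(
      hub = character(), platform = character(), degree = integer()
    ))
  }
  deg <- igraph::degree(g)
  hubs <- sort(names(deg)[deg >= cfg$min_hub_degree])
  nb <- lapply(hubs, function(h) {
    sort(igraph::V(g)$name[as.integer(igraph::neighbors(g, h))])
  })
  out <- data.frame(
    hub = hubs,
    platform = igraph::V(g)$platform[match(hubs, igraph::V(g)$name)],
    degree = unname(deg[hubs]),
    stringsAsFactors = FALSE
  )
  out$neighbors <- nb
  out
}

#' Gene symbols of hubs and their neighbors
#'
#' Concatenates hubs and neighbors, maps features to gene symbols through
#' the supplied mapping, drops features without a symbol (phenotype
#' variables, unannotated probes; reported with a message) and deduplicates.
#'
#' @param hub_report the [findHubs()] output.
#' @param symbol_map named character vector, feature id -> gene symbol
#'   (e.g. from `featureMeta()` of a [FusedMatrix-class]).
#' @return unique gene symbols (possibly empty).
#' @export
hubGeneList <- function(hub_report, symbol_map) {
  feats <- unique(c(hub_report$hub, unlist(hub_report$neighbors)))
  if (!length(feats)) {
    return(character())
  }
  sym <- symbol_map[feats]
  no_sym <- feats[is.na(sym) | sym == ""]
  if (length(no_sym)) {
    message("dropping ", length(no_sym), " feature(s) without a gene symbol: ",
            paste(head(no_sym, 10), collapse = ", "))
  }
  unique(unname(sym[!is.na(sym) & sym != ""]))
}

#' Map fused-matrix features to gene symbols
#'
#' @param fused a [FusedMatrix-class].
#' @return named character vector, feature id -> gene symbol.
#' @export
featureSymbolMap <- function(fused) {
  rd <- featureMeta(fused)
  setNames(rd$gene_symbol, rownames(rd))
}

#' Export a correlation network as GraphML
#'
#' Node attributes: `platform`, `component`, `is_hub`, `degree`; edge
#' attributes: `weight`, `pearson_r`, `mic`.
#'
#' @param network a [CorrelationNetwork-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeNetworkGraphML <- function(network, path) {
  igraph::write_graph(network@graph, path, format = "graphml")
  invisible(path)
}
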