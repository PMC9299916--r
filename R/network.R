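#' Weighted undirected MoA networks
#'
#' Every weed species resistant to two or more MoAs acts as a link between
#' those MoAs, which supports two complementary graphs over the same nodes:
#' the *prevalence* network, whose edge weights count the species resistant
#' to both MoAs of a pair, and the *proximity* network, whose edge weights
#' are the Jaccard similarities of the two resistant-species sets.
#'
#' A `moa_network` is a list with elements
#' * `nodes` — data.frame `moa`, `prevalence` (resistant-species count, NA
#'   when unknown), `cluster` (partition index, NA when not assigned);
#' * `edges` — data.frame `moa_a`, `moa_b`, `weight`, positive-weight pairs
#'   only (what gets drawn/exported);
#' * `pairs` — data.frame over all C(n,2) unordered pairs including
#'   zero-weight ones (the accounting vector used for correlation);
#' * `flavour` — `"prevalence"` or `"proximity"`.
#'
#' @name moa_network
NULL

new_moa_network <- function(nodes, pairs, flavour) {
  edges <- pairs[pairs$weight > 0, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, pairs = pairs,
                 flavour = flavour),
            class = "moa_network")
}

#' @export
print.moa_network <- function(x, ...) {
  cat(sprintf("moa_network (%s): %d nodes, %d edges (of %d pairs)\n",
              x$flavour, nrow(x$nodes), nrow(x$edges), nrow(x$pairs)))
  invisible(x)
}

all_pairs <- function(ids) {
  cmb <- utils::combn(ids, 2L)
  data.frame(moa_a = cmb[1L, ], moa_b = cmb[2L, ], stringsAsFactors = FALSE)
}

#' Build the prevalence network
#'
#' Edge weight between two MoAs = number of species resistant to both
#' (the size of the intersection of their species sets); node attribute
#' `prevalence` = number of species resistant to that MoA. Pairs sharing no
#' species are kept in the pair accounting but omitted from the edge set.
#'
#' @param x a consolidated [incidence_matrix] with at least 2 MoAs.
#' @param partition optional named integer vector (e.g. from
#'   [cut_dendrogram()]) stored as the `cluster` node attribute.
#' @return a [moa_network] of flavour `"prevalence"` (integer weights).
#' @export
build_prevalence_network <- function(x, partition = NULL) {
  stopifnot(inherits(x, "incidence_matrix"))
  if (nrow(x) < 2L) stop("need at least 2 MoAs", call. = FALSE)
  m <- unclass(x)
  shared <- tcrossprod(m)
  nodes <- data.frame(moa = rownames(m),
                      prevalence = as.integer(rowSums(m)),
                      cluster = cluster_of(rownames(m), partition),
                      stringsAsFactors = FALSE)
  pairs <- all_pairs(rownames(m))
  pairs$weight <- as.integer(shared[cbind(pairs$moa_a, pairs$moa_b)])
  new_moa_network(nodes, pairs, "prevalence")
}

#' Build the proximity network
#'
#' The complete graph over MoAs with edge weights equal to the off-diagonal
#' Jaccard similarities of a proximity matrix.
#'
#' @param prox a `proximity_matrix`.
#' @param partition optional named integer vector (cluster node attribute).
#' @param prevalence optional named integer vector of per-MoA
#'   resistant-species counts (not derivable from similarities alone).
#' @return a [moa_network] of flavour `"proximity"` (weights in \[0, 1\]).
#' @export
build_proximity_network <- function(prox, partition = NULL,
                                    prevalence = NULL) {
  stopifnot(inherits(prox, "proximity_matrix"))
  ids <- rownames(prox)
  prev <- rep(NA_integer_, length(ids))
  if (!is.null(prevalence)) prev <- as.integer(prevalence[ids])
  nodes <- data.frame(moa = ids, prevalence = prev,
                      cluster = cluster_of(ids, partition),
                      stringsAsFactors = FALSE)
  pairs <- all_pairs(ids)
  pairs$weight <- unclass(prox)[cbind(pairs$moa_a, pairs$moa_b)]
  new_moa_network(nodes, pairs, "proximity")
}

cluster_of <- function(ids, partition) {
  if (is.null(partition)) return(rep(NA_integer_, length(ids)))
  as.integer(partition[ids])
}

#' Correlate two MoA networks
#'
#' Pearson correlation between the weight vectors of two networks over the
#' *same* node set, taken over all C(n,2) unordered pairs — zero-weight
#' pairs included, so with 10 MoAs the test has C(10,2) - 2 = 43 degrees of
#' freedom. Reported alongside r are the two-sided P value from the t
#' transform and R-squared, the share of variation in one network's weights
#' explained by the other's.
#'
#' @param a,b two [moa_network] objects with identical node sets.
#' @return a `stat_result` list: `estimate` (r), `statistic` (t), `df`,
#'   `p_value`, `r_squared`, `n` (number of pairs).
#' @export
correlate_networks <- function(a, b) {
  stopifnot(inherits(a, "moa_network"), inherits(b, "moa_network"))
  if (!setequal(a$nodes$moa, b$nodes$moa)) {
    stop("networks must share the same node set", call. = FALSE)
  }
  key <- function(p) paste(pmin(p$moa_a, p$moa_b), pmax(p$moa_a, p$moa_b),
                           sep = "\r")
  wa <- setNames(a$pairs$weight, key(a$pairs))
  wb <- setNames(b$pairs$weight, key(b$pairs))
  wb <- wb[names(wa)]
  if (anyNA(wb)) stop("pair sets do not align", call. = FALSE)
  pearson_result(wa, wb)
}

# shared Pearson machinery: r, t statistic, df, two-sided P
pearson_result <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant weight vector", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  stat_result(estimate = unname(ct$estimate),
              statistic = unname(ct$statistic),
              df = unname(ct$parameter),
              p_value = ct$p.value,
              n = length(x),
              r_squared = unname(ct$estimate)^2)
}

#' Container for a simple test result
#'
#' @param estimate effect estimate (r, percentage, ...).
#' @param statistic test statistic.
#' @param df degrees of freedom (scalar or vector).
#' @param p_value P value in \[0, 1\].
#' @param n sample size the statistic was computed on.
#' @param ... further named diagnostics kept verbatim.
#' @return list of class `stat_result`.
#' @export
stat_result <- function(estimate = NA_real_, statistic = NA_real_,
                        df = NA_integer_, p_value = NA_real_,
                        n = NA_integer_, ...) {
  structure(list(estimate = estimate, statistic = statistic, df = df,
                 p_value = p_value, n = n, ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("stat_result: estimate = %.4g, statistic = %.4g, df = %s, P = %.4g (n = %d)\n",
              x$estimate, x$statistic, paste(x$df, collapse = ","),
              x$p_value, x$n))
  invisible(x)
}

#' Convert a MoA network to an igraph graph
#'
#' @param net a [moa_network].
#' @return an [igraph::graph] with node attributes `prevalence` and
#'   `cluster` and edge attribute `weight` (positive-weight edges only).
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "moa_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a MoA network
#'
#' `write_network_graphml()` writes GraphML (via igraph);
#' `write_network_gexf()` writes minimal GEXF 1.2 with the same node and
#' edge attributes; `write_network_edgelist()` writes the edge list as CSV
#' (`moa_a,moa_b,weight`). All three carry raw weights so any external
#' layout tool can reproduce force-directed drawings.
#'
#' @param net a [moa_network].
#' @param path output path.
#' @param all_pairs for the edge-list export, include zero-weight pairs
#'   (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_gexf <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  nodes <- net$nodes
  node_xml <- sprintf(
    '      <node id="%s" label="%s">\n        <attvalues><attvalue for="0" value="%s"/><attvalue for="1" value="%s"/></attvalues>\n      </node>',
    esc(nodes$moa), esc(nodes$moa),
    ifelse(is.na(nodes$prevalence), "", nodes$prevalence),
    ifelse(is.na(nodes$cluster), "", nodes$cluster))
  e <- net$edges
  edge_xml <- if (nrow(e)) sprintf(
    '      <edge id="%d" source="%s" target="%s" weight="%.10g"/>',
    seq_len(nrow(e)) - 1L, esc(e$moa_a), esc(e$moa_b), e$weight) else character(0)
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    sprintf('  <graph defaultedgetype="undirected" mode="static" label="%s">',
            esc(net$flavour)),
    '    <attributes class="node">',
    '      <attribute id="0" title="prevalence" type="integer"/>',
    '      <attribute id="1" title="cluster" type="integer"/>',
    '    </attributes>',
    '    <nodes>', node_xml, '    </nodes>',
    '    <edges>', edge_xml, '    </edges>',
    '  </graph>', '</gexf>')
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(net, path, all_pairs = FALSE) {
  tab <- if (all_pairs) net$pairs else net$edges
  write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Plot a MoA network on a deterministic circular layout
#'
#' Nodes on a circle in label order, sized by prevalence where known,
#' coloured by cluster; edge width proportional to weight. Force-directed
#' layouts are deliberately not computed here — export the graph and lay it
#' out externally for publication figures.
#'
#' @param x a [moa_network].
#' @param edge_scale multiplier for edge widths.
#' @param ... passed to [igraph::plot.igraph()].
#' @return `x`, invisibly.
#' @export
plot.moa_network <- function(x, edge_scale = NULL, ...) {
  g <- as_igraph(x)
  w <- igraph::E(g)$weight
  if (is.null(edge_scale)) edge_scale <- 4 / max(w)
  prev <- igraph::V(g)$prevalence
  size <- if (all(is.na(prev))) 12 else 8 + 12 * prev / max(prev, na.rm = TRUE)
  cl <- igraph::V(g)$cluster
  pal <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e")
  col <- ifelse(is.na(cl), "grey70", pal[(cl - 1L) %% length(pal) + 1L])
  igraph::plot.igraph(g, layout = igraph::layout_in_circle(g),
                      edge.width = w * edge_scale, vertex.size = size,
                      vertex.color = col, ...)
  invisible(x)
}
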