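#' Weighted protein association network
#'
#' A simple undirected graph whose nodes are protein symbols and whose edge
#' weights are interaction confidences in (0, 1]. Backed by igraph.
#'
#' @param nodes character vector of node symbols
#' @param edges data.frame with columns \code{protein_a}, \code{protein_b},
#'   \code{confidence}
#' @param label free-text label, conventionally \code{"disease"},
#'   \code{"drug"} or \code{"merged"}
#' @param isolated symbols that belong to the input member set but carry no
#'   qualifying interaction (reported, not clustered)
#' @return object of class \code{weighted_network}
#' @export
weighted_network <- function(nodes, edges, label = "network",
                             isolated = character(0)) {
  nodes <- sort(unique(as.character(nodes)))
  if (nrow(edges) > 0) {
    if (any(edges$protein_a == edges$protein_b))
      stopf("self-loop in edge set")
    if (any(edges$confidence <= 0) || any(edges$confidence > 1))
      stopf("edge weights must be in (0, 1]")
    missing <- setdiff(c(edges$protein_a, edges$protein_b), nodes)
    if (length(missing) > 0)
      stopf("edge endpoint '%s' not in node set", missing[1])
    cp <- canonical_pairs(edges$protein_a, edges$protein_b)
    if (anyDuplicated(cp$key)) stopf("duplicate edge in edge set")
    ord <- order(cp$a, cp$b)
    edges <- data.frame(protein_a = cp$a[ord], protein_b = cp$b[ord],
                        confidence = edges$confidence[ord],
                        stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges) > 0)
      data.frame(from = edges$protein_a, to = edges$protein_b,
                 weight = edges$confidence, stringsAsFactors = FALSE)
    else data.frame(from = character(0), to = character(0),
                    weight = numeric(0)),
    directed = FALSE, vertices = data.frame(name = nodes))
  structure(list(graph = g, label = label,
                 isolated = sort(unique(as.character(isolated)))),
            class = "weighted_network")
}

#' Node symbols of a network
#' @param net a \code{weighted_network}
#' @return sorted character vector
#' @export
network_nodes <- function(net) sort(igraph::V(net$graph)$name)

#' Edge table of a network
#' @param net a \code{weighted_network}
#' @return data.frame \code{protein_a}, \code{protein_b}, \code{confidence},
#'   canonically ordered
#' @export
network_edges <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0)
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g, names = TRUE)
  cp <- canonical_pairs(el[, 1], el[, 2])
  ord <- order(cp$a, cp$b)
  data.frame(protein_a = cp$a[ord], protein_b = cp$b[ord],
             confidence = igraph::E(g)$weight[ord],
             stringsAsFactors = FALSE)
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network [%s]: %d nodes, %d edges, %d isolated member(s)\n",
              x$label, igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$isolated)))
  invisible(x)
}

#' Build an induced weighted network from a member set
#'
#' Keeps exactly the interaction records whose two endpoints are both in
#' \code{members} and whose confidence passes \code{cutoff} (inclusive
#' \code{>=} by default; \code{strict = TRUE} uses \code{>}). Members with
#' no qualifying interaction are reported in \code{$isolated} and, unless
#' \code{keep_isolated}, excluded from the node set so that downstream
#' clustering sees only the connected part.
#'
#' @param members character vector of symbols
#' @param interactions interaction table as from \code{\link{read_edge_table}}
#' @param cutoff confidence threshold in \[0, 1\] (e.g. 0.4 for a broad
#'   disease network, 0.7 for a high-reliability target network)
#' @param keep_isolated keep degree-0 members as nodes
#' @param strict use a strict \code{>} comparison
#' @param label network label
#' @return a \code{\link{weighted_network}}
#' @export
build_network <- function(members, interactions, cutoff,
                          keep_isolated = FALSE, strict = FALSE,
                          label = "network") {
  if (!is_scalar_number(cutoff) || cutoff < 0 || cutoff > 1)
    stopf("cutoff must be a number in [0, 1]")
  members <- sort(unique(as.character(members)))
  pass <- if (strict) interactions$confidence > cutoff
          else interactions$confidence >= cutoff
  keep <- pass &
    interactions$protein_a %in% members &
    interactions$protein_b %in% members
  ed <- interactions[keep, , drop = FALSE]
  connected <- sort(unique(c(ed$protein_a, ed$protein_b)))
  isolated <- setdiff(members, connected)
  nodes <- if (keep_isolated) members else connected
  weighted_network(nodes, ed, label = label, isolated = isolated)
}

#' Merge disease and drug networks over a background interaction table
#'
#' The union graph keeps all nodes and edges of both networks (duplicate
#' edges keep the maximum weight) and additionally pulls in background
#' interactions that join a node of \code{d} to a node of \code{h}, are
#' absent from both inputs, and pass \code{cross_cutoff}. These cross edges
#' are what bridges the two module sets into one graph.
#'
#' @param d,h \code{weighted_network} objects (disease and drug)
#' @param background interaction table (may be \code{NULL} for none)
#' @param cross_cutoff confidence threshold for the added cross edges
#' @param strict use a strict \code{>} comparison for \code{cross_cutoff}
#' @return a \code{\link{weighted_network}} labelled \code{"merged"}
#' @export
merge_networks <- function(d, h, background = NULL, cross_cutoff = 0.7,
                           strict = FALSE) {
  if (!is_scalar_number(cross_cutoff) || cross_cutoff < 0 || cross_cutoff > 1)
    stopf("cross_cutoff must be a number in [0, 1]")
  vd <- network_nodes(d); vh <- network_nodes(h)
  nodes <- union(vd, vh)
  ed <- rbind(network_edges(d), network_edges(h))
  if (!is.null(background) && nrow(background) > 0) {
    pass <- if (strict) background$confidence > cross_cutoff
            else background$confidence >= cross_cutoff
    cross <- pass &
      ((background$protein_a %in% vd & background$protein_b %in% vh) |
       (background$protein_a %in% vh & background$protein_b %in% vd)) &
      background$protein_a != background$protein_b
    ed <- rbind(ed, background[cross, , drop = FALSE])
  }
  if (nrow(ed) > 0) {
    cp <- canonical_pairs(ed$protein_a, ed$protein_b)
    conf <- tapply(ed$confidence, cp$key, max)
    keys <- sort(names(conf))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    ed <- data.frame(protein_a = vapply(parts, `[[`, "", 1),
                     protein_b = vapply(parts, `[[`, "", 2),
                     confidence = as.numeric(conf[keys]),
                     stringsAsFactors = FALSE)
  }
  iso <- setdiff(union(d$isolated, h$isolated), nodes)
  weighted_network(nodes, ed, label = "merged", isolated = iso)
}
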