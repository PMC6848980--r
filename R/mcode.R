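#' MCODE parameter set
#'
#' The canonical published defaults of the molecular complex detection
#' algorithm: degree cutoff 2, node score cutoff 0.2, k-core 2, haircut on,
#' fluff off, maximum expansion depth 100. Edge weights never influence
#' clustering; density thresholding happens upstream at network build time.
#'
#' @param degree_cutoff minimum degree for a vertex to receive a weight
#' @param node_score_cutoff expansion tolerance in \[0, 1\]: a neighbor joins
#'   if its weight is at least \code{seed_weight * (1 - node_score_cutoff)}
#' @param k_core minimum core a candidate complex must contain
#' @param haircut iteratively strip members with intra-module degree < 2
#' @param fluff add boundary vertices whose neighborhood density exceeds
#'   \code{fluff_density} (off by default so modules stay disjoint)
#' @param fluff_density density threshold for fluff
#' @param max_depth breadth-first expansion depth limit from the seed
#' @return list of class \code{mcode_params}
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.5, max_depth = 100) {
  stopifnot(degree_cutoff >= 1, node_score_cutoff >= 0,
            node_score_cutoff <= 1, k_core >= 2, max_depth >= 1,
            is.logical(haircut), is.logical(fluff))
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density = fluff_density,
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

graph_density2 <- function(g) {
  v <- igraph::vcount(g)
  if (v < 2) return(0)
  2 * igraph::ecount(g) / (v * (v - 1))
}

#' MCODE vertex weighting
#'
#' The weight of a vertex is \code{k_max * density} of the highest k-core
#' of its closed neighborhood, where density of a graph with V vertices and
#' E edges is \code{2E / (V(V-1))}. Vertices with degree below
#' \code{degree_cutoff}, or whose neighborhood has no core, get weight 0.
#'
#' @param net a \code{weighted_network} or igraph graph
#' @param degree_cutoff minimum degree
#' @return named numeric vector of weights
#' @export
vertex_weights <- function(net, degree_cutoff = 2) {
  g <- if (inherits(net, "weighted_network")) net$graph else net
  vs <- igraph::V(g)$name
  deg <- igraph::degree(g)
  w <- stats::setNames(numeric(length(vs)), vs)
  for (v in vs) {
    if (deg[[v]] < degree_cutoff) next
    nb <- c(v, names(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax < 1) next
    top <- igraph::induced_subgraph(sub, names(core)[core >= kmax])
    w[[v]] <- kmax * graph_density2(top)
  }
  w
}

#' Find dense modules with MCODE
#'
#' Seeded greedy complex prediction: vertices are visited in decreasing
#' weight order (ties broken lexicographically by symbol, for full
#' reproducibility); from each unvisited seed with positive weight,
#' neighbors whose weight is at least \code{seed_weight * (1 -
#' node_score_cutoff)} are included breadth-first up to \code{max_depth};
#' every included vertex is marked visited, so the modules of one
#' clustering are pairwise disjoint. Candidates lacking a \code{k_core}
#' are discarded; haircut iteratively removes members with intra-module
#' degree < 2. Module score is intra-module density times size. Modules
#' are returned sorted by score descending, then size descending, then
#' lexicographically smallest member, and ranked 1..k.
#'
#' @param net a \code{weighted_network} or igraph graph
#' @param params an \code{\link{mcode_params}} object
#' @return list of unlabelled \code{module} objects (see
#'   \code{\link{assign_labels}})
#' @export
find_modules <- function(net, params = mcode_params()) {
  g <- if (inherits(net, "weighted_network")) net$graph else net
  if (igraph::ecount(g) == 0) return(list())
  w <- vertex_weights(g, params$degree_cutoff)
  vs <- names(w)
  ord <- vs[order(-w, vs)]
  visited <- stats::setNames(logical(length(vs)), vs)
  out <- list()

  for (seed in ord) {
    if (visited[[seed]] || w[[seed]] <= 0) next
    thr <- w[[seed]] * (1 - params$node_score_cutoff)
    members <- seed
    visited[[seed]] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < params$max_depth) {
      nxt <- character(0)
      for (u in frontier) {
        for (nb in sort(names(igraph::neighbors(g, u)))) {
          if (!visited[[nb]] && w[[nb]] >= thr) {
            visited[[nb]] <- TRUE
            members <- c(members, nb)
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    if (params$fluff) {
      extra <- character(0)
      for (u in sort(members)) {
        for (nb in sort(names(igraph::neighbors(g, u)))) {
          if (nb %in% members || nb %in% extra) next
          nbg <- igraph::induced_subgraph(
            g, c(nb, names(igraph::neighbors(g, nb))))
          if (graph_density2(nbg) > params$fluff_density)
            extra <- c(extra, nb)
        }
      }
      members <- c(members, extra)
      sub <- igraph::induced_subgraph(g, members)
    }
    if (params$haircut) {
      repeat {
        deg <- igraph::degree(sub)
        drop <- names(deg)[deg < 2]
        if (length(drop) == 0 || igraph::vcount(sub) - length(drop) < 2)
          break
        sub <- igraph::delete_vertices(sub, drop)
      }
      if (any(igraph::degree(sub) < 2)) next
      members <- igraph::V(sub)$name
    }
    if (length(members) < 2) next
    score <- graph_density2(sub) * igraph::vcount(sub)
    out[[length(out) + 1]] <- new_module(members = sort(members),
                                         score = score)
  }

  if (length(out) == 0) return(out)
  first <- vapply(out, function(m) m$members[1], "")
  sizes <- vapply(out, function(m) length(m$members), 0L)
  scores <- vapply(out, `[[`, 0, "score")
  ord <- order(-scores, -sizes, first)
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

#' Module constructor
#'
#' @param members character vector of node symbols
#' @param score MCODE score (intra-module density times size)
#' @param id module id, assigned by \code{\link{assign_labels}}
#' @param origin \code{"S"} (disease) or \code{"H"} (drug)
#' @param rank rank by descending score
#' @return object of class \code{module}
#' @export
new_module <- function(members, score, id = NA_character_,
                       origin = NA_character_, rank = NA_integer_) {
  structure(list(id = id, origin = origin, members = sort(unique(members)),
                 score = score, rank = as.integer(rank)),
            class = "module")
}

#' @export
print.module <- function(x, ...) {
  cat(sprintf("module %s (origin %s, rank %s): %d members, score %.4g\n",
              x$id, x$origin, x$rank, length(x$members), x$score))
  invisible(x)
}

#' Label ranked modules by origin
#'
#' Assigns ids \code{"S-module k"} or \code{"H-module k"} by rank.
#'
#' @param modules ranked module list from \code{\link{find_modules}}
#' @param origin \code{"S"} or \code{"H"}
#' @return module list with ids and origins set
#' @export
assign_labels <- function(modules, origin = c("S", "H")) {
  origin <- match.arg(origin)
  for (i in seq_along(modules)) {
    modules[[i]]$origin <- origin
    modules[[i]]$rank <- i
    modules[[i]]$id <- sprintf("%s-module %d", origin, i)
  }
  modules
}

#' Cluster a network and label the modules
#'
#' Convenience wrapper: \code{\link{find_modules}} followed by
#' \code{\link{assign_labels}}.
#'
#' @inheritParams find_modules
#' @inheritParams assign_labels
#' @return labelled module list
#' @export
mcode_cluster <- function(net, origin = c("S", "H"),
                          params = mcode_params()) {
  assign_labels(find_modules(net, params), match.arg(origin))
}
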