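#' Connectivity between a pair of modules
#'
#' For modules \eqn{M_x} and \eqn{M_y} inside the union graph \code{g}:
#' \code{t} is the number of shared nodes, the candidate pair set is every
#' unordered pair \{u, v\} with one endpoint in each module (u != v, each
#' pair counted once, so \code{n = |A||B| - t - choose(t, 2)}), \code{x} is
#' the number of candidate pairs joined by an edge of \code{g}, and
#' \code{cross_edges} lists those edges with their confidence weights.
#' Intra-module edges (both endpoints in the same module only) never count.
#'
#' @param a,b \code{module} objects with distinct ids
#' @param g the merged \code{weighted_network} containing both modules
#' @return object of class \code{pair_connectivity} with fields
#'   \code{module_a}, \code{module_b}, \code{t}, \code{x}, \code{n},
#'   \code{cross_edges}
#' @export
pair_connectivity <- function(a, b, g) {
  stopifnot(inherits(a, "module"), inherits(b, "module"))
  if (identical(a$id, b$id) && !is.na(a$id))
    stopf("pair_connectivity needs two distinct modules")
  nodes <- network_nodes(g)
  missing <- setdiff(c(a$members, b$members), nodes)
  if (length(missing) > 0)
    stopf("module member '%s' is not a node of the network", missing[1])
  A <- a$members; B <- b$members
  t <- length(intersect(A, B))
  n <- length(A) * length(B) - t - choose(t, 2)
  ed <- network_edges(g)
  sel <- (ed$protein_a %in% A & ed$protein_b %in% B) |
         (ed$protein_a %in% B & ed$protein_b %in% A)
  cross <- ed[sel, , drop = FALSE]
  structure(list(module_a = a$id, module_b = b$id,
                 t = as.integer(t), x = nrow(cross), n = as.integer(n),
                 cross_edges = data.frame(node_i = cross$protein_a,
                                          node_j = cross$protein_b,
                                          weight = cross$confidence,
                                          stringsAsFactors = FALSE)),
            class = "pair_connectivity")
}

#' Exact hypergeometric upper tail
#'
#' \deqn{p = \sum_{k=x}^{n} \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}}}
#' the probability of at least \code{x} successes in \code{n} draws without
#' replacement from a population of \code{N} containing \code{M} successes.
#' Terms with impossible \code{k} contribute zero. Used both for
#' inter-module connection significance and for pathway enrichment.
#'
#' @param x observed successes (integer, \code{0 <= x <= n})
#' @param n number of draws (\code{n <= N})
#' @param M successes in the population (\code{M <= N})
#' @param N population size
#' @return upper-tail probability in \[0, 1\]
#' @export
hypergeom_upper_tail <- function(x, n, M, N) {
  vals <- c(x, n, M, N)
  if (any(!is.finite(vals)) || any(vals != round(vals)))
    stopf("x, n, M, N must be integers")
  if (x < 0 || x > n) stopf("x must satisfy 0 <= x <= n")
  if (n > N) stopf("n must satisfy n <= N")
  if (M < 0 || M > N) stopf("M must satisfy 0 <= M <= N")
  stats::phyper(x - 1, M, N - M, n, lower.tail = FALSE)
}

#' Coupling score of a module pair
#'
#' \deqn{CS = 2t + \sum_{i \in M_x, j \in M_y} a_{ij}} — twice the number of
#' shared nodes plus the sum of confidence weights over the cross-module
#' edges, each unordered edge counted once. Symmetric in the two modules.
#'
#' @param pc a \code{\link{pair_connectivity}} result
#' @return non-negative numeric coupling score
#' @export
coupling_score <- function(pc) {
  stopifnot(inherits(pc, "pair_connectivity"))
  2 * pc$t + sum(pc$cross_edges$weight)
}

empty_map_edges <- function() {
  data.frame(module_a = character(0), module_b = character(0),
             t = integer(0), x = integer(0), n = integer(0),
             p_value = numeric(0), coupling_score = numeric(0),
             stringsAsFactors = FALSE)
}

new_modular_map <- function(modules, edges, alpha, M, N, scope,
                            pairs = NULL) {
  structure(list(modules = modules, edges = edges, alpha = alpha,
                 M = M, N = N, scope = scope, pairs = pairs),
            class = "modular_map")
}

#' @export
print.modular_map <- function(x, ...) {
  cat(sprintf(
    "modular_map: %d modules, %d significant pair(s) at alpha = %s (M = %s, N = %s)\n",
    length(x$modules), nrow(x$edges), format(x$alpha), format(x$M),
    format(x$N)))
  invisible(x)
}

#' Build the modular map
#'
#' Evaluates every module pair in scope inside the union graph: accumulates
#' the network totals \code{M} (observed inter-module connections) and
#' \code{N} (possible inter-module interactions) over those pairs, computes
#' each pair's hypergeometric upper-tail p-value for its observed \code{x}
#' out of \code{n} candidate slots, and retains pairs with \code{p <= alpha}
#' together with their coupling scores. Edges are ordered by p ascending,
#' coupling score descending, then id pair.
#'
#' @param modules list of labelled \code{module} objects (both origins for
#'   the default cross-origin scope)
#' @param g merged \code{weighted_network}
#' @param alpha significance level (inclusive; default 0.05)
#' @param scope \code{"cross_origin_only"} considers only S-by-H pairs;
#'   \code{"all_pairs"} considers every unordered module pair (e.g. for a
#'   within-network module map)
#' @param p_adjust \code{"none"} (raw p-values, the default) or \code{"BH"}
#'   (Benjamini-Hochberg; filtering then uses the adjusted values, reported
#'   in an extra \code{p_adjusted} column)
#' @return object of class \code{modular_map} with fields \code{modules},
#'   \code{edges}, \code{alpha}, \code{M}, \code{N}, \code{scope}, and
#'   \code{pairs} (per-pair connectivity including cross edges)
#' @export
build_modular_map <- function(modules, g, alpha = 0.05,
                              scope = c("cross_origin_only", "all_pairs"),
                              p_adjust = c("none", "BH")) {
  scope <- match.arg(scope)
  p_adjust <- match.arg(p_adjust)
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1)
    stopf("alpha must be in (0, 1]")
  if (length(modules) < 2)
    return(new_modular_map(modules, empty_map_edges(), alpha,
                           0L, 0L, scope))

  ids <- vapply(modules, `[[`, "", "id")
  if (anyDuplicated(ids)) stopf("module ids must be unique")
  origins <- vapply(modules, `[[`, "", "origin")
  idx <- utils::combn(length(modules), 2)
  if (scope == "cross_origin_only") {
    keep <- origins[idx[1, ]] != origins[idx[2, ]]
    idx <- idx[, keep, drop = FALSE]
  }
  if (ncol(idx) == 0)
    return(new_modular_map(modules, empty_map_edges(), alpha, 0L, 0L, scope))

  pcs <- lapply(seq_len(ncol(idx)), function(j)
    pair_connectivity(modules[[idx[1, j]]], modules[[idx[2, j]]], g))
  M <- sum(vapply(pcs, `[[`, 0L, "x"))
  N <- sum(vapply(pcs, `[[`, 0L, "n"))
  p <- vapply(pcs, function(pc) hypergeom_upper_tail(pc$x, pc$n, M, N), 0)
  cs <- vapply(pcs, coupling_score, 0)

  ed <- data.frame(
    module_a = vapply(pcs, `[[`, "", "module_a"),
    module_b = vapply(pcs, `[[`, "", "module_b"),
    t = vapply(pcs, `[[`, 0L, "t"),
    x = vapply(pcs, `[[`, 0L, "x"),
    n = vapply(pcs, `[[`, 0L, "n"),
    p_value = p, coupling_score = cs,
    stringsAsFactors = FALSE)
  if (p_adjust == "BH") {
    ed$p_adjusted <- stats::p.adjust(ed$p_value, method = "BH")
    keep <- ed$p_adjusted <= alpha
  } else {
    keep <- ed$p_value <= alpha
  }
  ed <- ed[keep, , drop = FALSE]
  pcs <- pcs[keep]
  ord <- order(ed$p_value, -ed$coupling_score, ed$module_a, ed$module_b)
  ed <- ed[ord, , drop = FALSE]
  rownames(ed) <- NULL
  new_modular_map(modules, ed, alpha, as.integer(M), as.integer(N), scope,
                  pairs = pcs[ord])
}
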