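# Independent oracles and small graph builders shared across the suite.

# Exhaustive hypergeometric upper tail: enumerate every one of the
# choose(N, n) equally likely draws of n items from {1..N} (successes are
# items 1..M) and count draws with at least x successes. Deliberately does
# not touch stats::phyper.
hyper_tail_enum <- function(x, n, M, N) {
  if (n == 0) return(if (x == 0) 1 else 0)
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= M)
  if (n == 1) succ <- as.numeric(draws <= M)
  sum(succ >= x) / ncol(draws)
}

# Brute-force pair connectivity: enumerate candidate unordered pairs by a
# double loop and scan the edge table directly.
pair_connectivity_oracle <- function(A, B, edges) {
  key <- function(u, v) paste(pmin(u, v), pmax(u, v))
  cand <- character(0)
  for (u in A) for (v in B) if (u != v) cand <- c(cand, key(u, v))
  cand <- unique(cand)
  ekey <- key(edges$protein_a, edges$protein_b)
  hit <- ekey %in% cand
  list(t = length(intersect(A, B)), n = length(cand), x = sum(hit),
       weight_sum = sum(edges$confidence[hit]))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

edge_df <- function(a, b, w) {
  data.frame(protein_a = a, protein_b = b, confidence = w,
             stringsAsFactors = FALSE)
}

# complete graph edge table on the given symbols
clique_edges <- function(nodes, w = 0.9) {
  cmb <- utils::combn(sort(nodes), 2)
  edge_df(cmb[1, ], cmb[2, ], w)
}

random_interactions <- function(nodes, n_edges, seed) {
  set.seed(seed)
  cmb <- utils::combn(nodes, 2)
  pick <- sample.int(ncol(cmb), min(n_edges, ncol(cmb)))
  edge_df(cmb[1, pick], cmb[2, pick],
          round(stats::runif(length(pick), 0.4, 1), 3))
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
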