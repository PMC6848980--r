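test_that("planted networks realise exact cliques and empty backgrounds", {
  sc <- planted_scenario(8, planted = list(5), p_in = 1, p_out = 0,
                         seed = 2)
  pg <- make_planted_network(sc)
  expect_equal(nrow(network_edges(pg$network)), choose(5, 2))

  sc0 <- planted_scenario(10, planted = list(), p_in = 1, p_out = 0,
                          seed = 2)
  expect_equal(nrow(network_edges(make_planted_network(sc0)$network)), 0)

  expect_error(planted_scenario(10, planted = list(c("P001", "P002"),
                                                   c("P002", "P003")),
                                p_in = 1, p_out = 0),
               "disjoint")
})

test_that("generation is deterministic under a fixed seed", {
  sc <- planted_scenario(30, planted = list(6, 5), p_in = 0.9, p_out = 0.05,
                         seed = 77)
  f1 <- tempfile(); f2 <- tempfile()
  write_network(make_planted_network(sc)$network, f1)
  write_network(make_planted_network(sc)$network, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the generator does not disturb the caller's RNG stream
  set.seed(5); before <- stats::runif(1)
  set.seed(5); invisible(make_planted_network(sc)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("edge counts match their binomial expectation over 200 seeds", {
  n_in_pairs <- choose(6, 2)
  sc_base <- function(seed) planted_scenario(
    25, planted = list(6), p_in = 0.7, p_out = 0.1, seed = seed)
  counts <- vapply(1:200, function(s) {
    ed <- network_edges(make_planted_network(sc_base(s))$network)
    nrow(ed)
  }, 0)
  n_out_pairs <- choose(25, 2) - n_in_pairs
  mu <- n_in_pairs * 0.7 + n_out_pairs * 0.1
  sdv <- sqrt(n_in_pairs * 0.7 * 0.3 + n_out_pairs * 0.1 * 0.9)
  expect_lt(abs(mean(counts) - mu), 3 * sdv / sqrt(200))
})

test_that("paired scenarios share nodes and realise cross budgets exactly", {
  d_sc <- planted_scenario(30, planted = list(10, 6), p_in = 1, p_out = 0.02,
                           prefix = "D", seed = 3)
  h_sc <- planted_scenario(30, planted = list(9, 5), p_in = 1, p_out = 0.02,
                           prefix = "H", seed = 4)
  sc <- paired_scenario(d_sc, h_sc, n_shared = 3, shared_pair = c(1, 1),
                        cross = list(list(pair = c(1, 1), budget = 10)),
                        seed = 5)
  pn <- make_paired_networks(sc)
  shared <- intersect(network_nodes(pn$disease$network),
                      network_nodes(pn$drug$network))
  expect_length(shared, 3)
  expect_equal(sort(pn$truth$shared_nodes), sort(shared))
  expect_equal(nrow(pn$background), 10)
  # every budget edge joins the designated planted pair
  A <- pn$disease$truth[[1]]; B <- pn$drug$truth[[1]]
  expect_true(all((pn$background$protein_a %in% A &
                   pn$background$protein_b %in% B) |
                  (pn$background$protein_a %in% B &
                   pn$background$protein_b %in% A)))

  # zero budget adds no cross edges at merge time
  sc0 <- paired_scenario(d_sc, h_sc, n_shared = 3, shared_pair = c(1, 1),
                         cross = list(), seed = 5)
  pn0 <- make_paired_networks(sc0)
  m <- merge_networks(pn0$disease$network, pn0$drug$network,
                      pn0$background, cross_cutoff = 0.7)
  expect_equal(nrow(pn0$background), 0)

  # an impossible budget errors
  sc_big <- paired_scenario(d_sc, h_sc, n_shared = 0,
                            cross = list(list(pair = c(2, 2), budget = 10^6)),
                            seed = 5)
  expect_error(make_paired_networks(sc_big), "exceeds")
})

test_that("the truly coupled pair ranks first in the modular map", {
  d_sc <- planted_scenario(40, planted = list(10, 7), p_in = 1, p_out = 0.02,
                           prefix = "D", seed = 11)
  h_sc <- planted_scenario(40, planted = list(9, 6), p_in = 1, p_out = 0.02,
                           prefix = "H", seed = 12)
  sc <- paired_scenario(d_sc, h_sc, n_shared = 3, shared_pair = c(1, 1),
                        cross = list(list(pair = c(1, 1), budget = 15)),
                        seed = 13)
  pn <- make_paired_networks(sc)
  merged <- merge_networks(pn$disease$network, pn$drug$network,
                           pn$background, cross_cutoff = 0.7)
  smods <- mcode_cluster(pn$disease$network, "S")
  hmods <- mcode_cluster(pn$drug$network, "H")
  map <- build_modular_map(c(smods, hmods), merged, alpha = 1)
  top <- map$edges[1, ]
  # S-module 1 is the larger disease clique, H-module 1 the larger drug one
  expect_equal(top$module_a, "S-module 1")
  expect_equal(top$module_b, "H-module 1")
  expect_true(top$p_value <= min(map$edges$p_value))
})
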