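mod <- function(members, id = NA_character_, origin = NA_character_)
  new_module(members, score = 1, id = id, origin = origin)

test_that("pair connectivity counts shared nodes, slots and cross edges", {
  g <- weighted_network(c("A", "B", "C"),
                        edge_df(c("A", "A"), c("B", "C"), c(0.5, 0.9)))
  pc <- pair_connectivity(mod(c("A", "B"), "m1"), mod(c("B", "C"), "m2"), g)
  expect_equal(pc$t, 1)
  expect_equal(pc$n, 3)
  expect_equal(pc$x, 2)

  g0 <- weighted_network(c("A", "B"), edge_df(character(0), character(0),
                                              numeric(0)))
  pc <- pair_connectivity(mod("A", "m1"), mod("B", "m2"), g0)
  expect_equal(unlist(pc[c("t", "x", "n")]), c(t = 0, x = 0, n = 1))

  g3 <- weighted_network(c("A", "B", "C"), edge_df(character(0),
                                                   character(0), numeric(0)))
  pc <- pair_connectivity(mod(c("A", "B", "C"), "m1"),
                          mod(c("A", "B", "C"), "m2"), g3)
  expect_equal(unlist(pc[c("t", "x", "n")]), c(t = 3, x = 0, n = 3))

  expect_error(
    pair_connectivity(mod(c("A", "ZZZ"), "m1"), mod("B", "m2"), g),
    "ZZZ")
})

test_that("pair connectivity matches brute-force enumeration and is symmetric", {
  for (seed in 1:8) {
    set.seed(seed)
    uni <- sprintf("P%02d", 1:14)
    A <- sample(uni, sample(2:6, 1))
    B <- sample(uni, sample(2:6, 1))
    ed <- random_interactions(uni, 30, seed + 500)
    g <- weighted_network(uni, ed)
    a <- mod(A, "a"); b <- mod(B, "b")
    pc <- pair_connectivity(a, b, g)
    orc <- pair_connectivity_oracle(A, B, ed)
    expect_equal(pc$t, orc$t)
    expect_equal(pc$n, orc$n)
    expect_equal(pc$x, orc$x)
    expect_equal(sum(pc$cross_edges$weight), orc$weight_sum)

    rev <- pair_connectivity(b, a, g)
    expect_equal(rev$t, pc$t)
    expect_equal(rev$x, pc$x)
    expect_equal(rev$n, pc$n)
    expect_equal(coupling_score(rev), coupling_score(pc))
  }
})

test_that("hypergeometric upper tail handles closed forms and bounds", {
  expect_equal(hypergeom_upper_tail(0, 3, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(2, 3, 5, 10), 0.5)
  # x beyond the number of available successes is impossible
  expect_equal(hypergeom_upper_tail(4, 4, 3, 10), 0)
  expect_error(hypergeom_upper_tail(-1, 3, 5, 10), "x must")
  expect_error(hypergeom_upper_tail(4, 3, 5, 10), "x must")
  expect_error(hypergeom_upper_tail(1, 11, 5, 10), "n must")
  expect_error(hypergeom_upper_tail(1, 3, 11, 10), "M must")
  expect_error(hypergeom_upper_tail(0.5, 3, 5, 10), "integers")
})

test_that("p decreases monotonically in x at fixed (n, M, N)", {
  p <- vapply(0:6, function(x) hypergeom_upper_tail(x, 6, 20, 60), 0)
  expect_true(all(diff(p) < 0))
})

test_that("coupling score is 2t plus the cross-edge weight sum", {
  g <- weighted_network(c("A", "B"), edge_df("A", "B", 0.8))
  pc <- pair_connectivity(mod("A", "m1"), mod("B", "m2"), g)
  expect_equal(coupling_score(pc), 0.8)

  g2 <- weighted_network(c("A", "B", "C"), edge_df("A", "C", 0.9))
  pc <- pair_connectivity(mod(c("A", "B"), "m1"), mod(c("B", "C"), "m2"), g2)
  expect_equal(coupling_score(pc), 2 * 1 + 0.9)

  g3 <- weighted_network(c("A", "B"), edge_df(character(0), character(0),
                                              numeric(0)))
  pc <- pair_connectivity(mod("A", "m1"), mod("B", "m2"), g3)
  expect_equal(coupling_score(pc), 0)
})

test_that("the modular map keeps significant pairs in deterministic order", {
  # two disjoint unconnected modules at alpha 1: one edge, x = 0, p = 1
  g <- weighted_network(LETTERS[1:4], edge_df(character(0), character(0),
                                              numeric(0)))
  mods <- c(assign_labels(list(new_module(c("A", "B"), 1)), "S"),
            assign_labels(list(new_module(c("C", "D"), 1)), "H"))
  map <- build_modular_map(mods, g, alpha = 1)
  expect_equal(nrow(map$edges), 1)
  expect_equal(map$edges$x, 0)
  expect_equal(map$edges$p_value, 1)
  expect_equal(map$edges$coupling_score, 0)

  expect_equal(nrow(build_modular_map(mods[1], g, alpha = 1)$edges), 0)
})

test_that("a pair carrying all inter-module edges gets the minimum p", {
  # 4 modules, 10 cross edges all between S1 and H1
  s1 <- sprintf("S1_%d", 1:5); s2 <- sprintf("S2_%d", 1:5)
  h1 <- sprintf("H1_%d", 1:5); h2 <- sprintf("H2_%d", 1:5)
  cross <- expand.grid(a = s1, b = h1, stringsAsFactors = FALSE)[1:10, ]
  g <- weighted_network(c(s1, s2, h1, h2),
                        edge_df(cross$a, cross$b, rep(0.8, 10)))
  mods <- c(assign_labels(list(new_module(s1, 2), new_module(s2, 1)), "S"),
            assign_labels(list(new_module(h1, 2), new_module(h2, 1)), "H"))
  map <- build_modular_map(mods, g, alpha = 1, scope = "cross_origin_only")
  expect_equal(map$M, 10L)
  expect_equal(map$N, 100L)
  expect_equal(map$edges$module_a[1], "S-module 1")
  expect_equal(map$edges$module_b[1], "H-module 1")
  expect_true(all(map$edges$p_value[1] < map$edges$p_value[-1]))

  # all-pairs scope also counts within-origin pairs
  map_all <- build_modular_map(mods, g, alpha = 1, scope = "all_pairs")
  expect_equal(nrow(map_all$edges), 6)
})

test_that("BH adjustment filters on adjusted p-values", {
  s1 <- sprintf("S1_%d", 1:4); h1 <- sprintf("H1_%d", 1:4)
  s2 <- sprintf("S2_%d", 1:4); h2 <- sprintf("H2_%d", 1:4)
  cross <- expand.grid(a = s1, b = h1, stringsAsFactors = FALSE)
  g <- weighted_network(c(s1, s2, h1, h2),
                        edge_df(cross$a, cross$b, rep(0.9, nrow(cross))))
  mods <- c(assign_labels(list(new_module(s1, 2), new_module(s2, 1)), "S"),
            assign_labels(list(new_module(h1, 2), new_module(h2, 1)), "H"))
  map <- build_modular_map(mods, g, alpha = 0.05, p_adjust = "BH")
  expect_true(all(map$edges$p_adjusted <= 0.05))
  expect_true(all(map$edges$p_adjusted >= map$edges$p_value))
})

test_that("adding a cross edge or a shared node shifts CS by w and 2", {
  for (seed in 1:5) {
    set.seed(seed)
    uni <- sprintf("P%02d", 1:12)
    A <- sample(uni, 4); B <- sample(setdiff(uni, A), 4)
    ed <- random_interactions(uni, 20, seed + 900)
    g <- weighted_network(uni, ed)
    pc <- pair_connectivity(mod(A, "a"), mod(B, "b"), g)
    cs <- coupling_score(pc)

    # add one new cross edge of weight w
    free <- expand.grid(a = A, b = B, stringsAsFactors = FALSE)
    key <- paste(pmin(free$a, free$b), pmax(free$a, free$b))
    ekey <- paste(pmin(ed$protein_a, ed$protein_b),
                  pmax(ed$protein_a, ed$protein_b))
    free <- free[!(key %in% ekey), , drop = FALSE]
    w <- 0.42
    g2 <- weighted_network(uni, rbind(ed, edge_df(free$a[1], free$b[1], w)))
    cs2 <- coupling_score(pair_connectivity(mod(A, "a"), mod(B, "b"), g2))
    expect_equal(cs2, cs + w, tolerance = 1e-12)

    # promote one B-only member into A as a shared node: t rises by 1 and
    # every formerly counted A-B cross edge stays counted, so CS rises by
    # exactly 2 plus the weights of edges newly crossing
    shared <- setdiff(B, A)[1]
    A2 <- c(A, shared)
    pc3 <- pair_connectivity(mod(A2, "a"), mod(B, "b"), g)
    extra <- sum(ed$confidence[
      (ed$protein_a == shared & ed$protein_b %in% setdiff(B, A2)) |
      (ed$protein_b == shared & ed$protein_a %in% setdiff(B, A2))])
    expect_equal(coupling_score(pc3), cs + 2 + extra, tolerance = 1e-12)
  }
})
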