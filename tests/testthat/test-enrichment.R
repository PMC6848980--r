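bg20 <- sprintf("g%02d", 1:20)

test_that("enrichment p-values follow the hypergeometric model", {
  sets <- gene_set_collection(list(pw = "g01"),
                              background = sprintf("g%02d", 1:10))
  rec <- enrich("g01", sets, alpha = 1, module_id = "m")
  expect_equal(rec$p_value, 0.1)

  # module of 5 with 3 hits in a 4-gene pathway, background of 20
  sets <- gene_set_collection(list(pw = bg20[1:4]), background = bg20)
  module <- c(bg20[1:3], bg20[10:11])
  rec <- enrich(module, sets, alpha = 1, module_id = "m")
  expect_equal(rec$p_value, hyper_tail_enum(3, 5, 4, 20), tolerance = 1e-12)
  expect_equal(rec$hit_genes, paste(bg20[1:3], collapse = ";"))

  # zero overlap with every pathway gives no records below alpha < 1
  sets <- gene_set_collection(list(pw = bg20[1:4]), background = bg20)
  expect_equal(nrow(enrich(bg20[10:12], sets, alpha = 0.99,
                           module_id = "m")), 0)

  expect_error(enrich(c("nope1", "nope2"), sets, module_id = "m"),
               "not annotated")
})

test_that("the representative term is the minimum-p record with id tie-break", {
  rec <- data.frame(module_id = "m", pathway_id = c("hsa04066", "hsa04010"),
                    pathway_name = c("b", "a"), p_value = c(0.02, 0.01),
                    stringsAsFactors = FALSE)
  expect_equal(representative_term(rec)$pathway_id, "hsa04010")
  rec$p_value <- c(0.01, 0.01)
  expect_equal(representative_term(rec)$pathway_id, "hsa04010")
  expect_error(representative_term(rec[0, ]), "no enrichment records")
})

test_that("category profiles count distinct pathways and sum to one", {
  cmap <- category_map(data.frame(
    pathway_id = c("p1", "p2", "p3", "p4"),
    category_code = c("3.2", "3.2", "6.10", "6.10"),
    category_name = c("Signal transduction", "Signal transduction",
                      "Infectious diseases: Parasitic",
                      "Infectious diseases: Parasitic"),
    stringsAsFactors = FALSE))
  rec <- data.frame(pathway_id = c("p1", "p2", "p3", "p4", "p4"),
                    stringsAsFactors = FALSE)
  prof <- categorize(rec, cmap)
  expect_equal(sum(prof$fraction), 1)
  expect_equal(prof$fraction, c(0.5, 0.5))

  # unknown pathways roll into unclassified
  prof2 <- categorize(data.frame(pathway_id = c("p1", "zzz")), cmap)
  expect_true("unclassified" %in% prof2$category)

  # grouping pools categories under one label
  grp <- c("3.2" = "pooled", "6.10" = "pooled")
  prof3 <- categorize(rec, cmap, grouping = grp)
  expect_equal(prof3$n_pathways, 4L)
  expect_equal(prof3$category, "pooled")
})

test_that("bridgeness intersects the two groups' significant pathway unions", {
  s_rec <- data.frame(module_id = c("S-module 1", "S-module 1"),
                      pathway_id = c("TNF", "HIF-1"),
                      p_value = c(0.01, 0.02), stringsAsFactors = FALSE)
  h_rec <- data.frame(module_id = c("H-module 1", "H-module 2"),
                      pathway_id = c("TNF", "PI3K-Akt"),
                      p_value = c(0.001, 0.03), stringsAsFactors = FALSE)
  br <- bridgeness(s_rec, h_rec, "S-module 1", c("H-module 1", "H-module 2"))
  expect_equal(br$overlap_pathways, "TNF")

  h_dis <- data.frame(module_id = "H-module 1", pathway_id = "Other",
                      p_value = 0.01, stringsAsFactors = FALSE)
  br2 <- bridgeness(s_rec, h_dis, "S-module 1", "H-module 1")
  expect_equal(br2$overlap_pathways, character(0))

  # insignificant records never contribute
  h_ns <- h_rec; h_ns$p_value <- c(0.2, 0.03)
  br3 <- bridgeness(s_rec, h_ns, "S-module 1", c("H-module 1", "H-module 2"))
  expect_equal(br3$overlap_pathways, character(0))
  expect_error(bridgeness(s_rec, h_rec, character(0), "H-module 1"),
               "non-empty")
})

test_that("adding a module to a group never shrinks the overlap", {
  set.seed(21)
  paths <- sprintf("pw%02d", 1:15)
  mk <- function(mods) do.call(rbind, lapply(mods, function(m)
    data.frame(module_id = m, pathway_id = sample(paths, 6),
               p_value = stats::runif(6, 0, 0.05),
               stringsAsFactors = FALSE)))
  s_rec <- mk(c("S-module 1", "S-module 2", "S-module 3"))
  h_rec <- mk(c("H-module 1", "H-module 2"))
  small <- bridgeness(s_rec, h_rec, "S-module 1", "H-module 1")
  grown <- bridgeness(s_rec, h_rec, c("S-module 1", "S-module 2"),
                      "H-module 1")
  expect_true(all(small$overlap_pathways %in% grown$overlap_pathways))
  # overlap is contained in each side's union
  expect_true(all(grown$overlap_pathways %in% s_rec$pathway_id))
  expect_true(all(grown$overlap_pathways %in% h_rec$pathway_id))
})

test_that("enrichment p-values are sub-uniform under random modules", {
  set.seed(17)
  bg <- sprintf("g%03d", 1:80)
  sets <- gene_set_collection(
    stats::setNames(lapply(c(8, 12, 16, 20), function(k) sample(bg, k)),
                    paste0("pw", 1:4)),
    background = bg)
  alpha <- 0.05
  R <- 2000
  hits <- 0L; total <- 0L
  for (r in seq_len(R)) {
    m <- sample(bg, 10)
    rec <- enrich(m, sets, alpha = 1, module_id = "null")
    p <- rec$p_value[match(paste0("pw", 1:4), rec$pathway_id)]
    p[is.na(p)] <- 1
    hits <- hits + sum(p <= alpha)
    total <- total + 4L
  }
  eps <- 3 * sqrt(alpha * (1 - alpha) / total)
  expect_lte(hits / total, alpha + eps)
})

test_that("the packaged bridgeness fixture loads with its printed metadata", {
  fx <- hljdd_bridgeness_fixture()
  expect_equal(length(unique(fx$h_records$pathway_id)), 14)
  expect_equal(length(unique(fx$s_records$pathway_id)), 14)
  tnf <- fx$h_records[fx$h_records$pathway_id == "hsa04668", ]
  expect_equal(unique(tnf$p_value), 1.52e-14)
  expect_setequal(tnf$module_id, c("H-module 1", "H-module 2"))
  tryp <- fx$s_records[fx$s_records$pathway_id == "hsa05143", ]
  expect_setequal(strsplit(tryp$hit_genes, ";")[[1]],
                  c("VCAM1", "TNF", "APOA1", "GNAQ"))
  # the calcium-pathway analogue here: representative term of the S side
  # of the fixture is the minimum-p record
  expect_equal(representative_term(fx$s_records)$pathway_id, "hsa05143")
})
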