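#' Planted-module network scenario
#'
#' Describes a random graph with clique-like planted modules over a sparse
#' Erdos-Renyi background: node pairs inside a planted module are joined
#' with probability \code{p_in}, all other pairs with \code{p_out}, and
#' edge weights are i.i.d. uniform on \code{weight_range} (defaulting to
#' \[0.4, 1\], mimicking STRING combined scores above a 0.4 confidence
#' floor).
#'
#' @param n_nodes total node count
#' @param planted list of integer sizes, or list of explicit member
#'   character vectors; planted modules must be disjoint
#' @param p_in within-module edge probability (> p_out)
#' @param p_out background edge probability
#' @param weight_range length-2 numeric in (0, 1]
#' @param prefix node name prefix
#' @param seed integer seed; same seed gives identical output
#' @return list of class \code{planted_scenario}
#' @export
planted_scenario <- function(n_nodes, planted = list(), p_in = 1,
                             p_out = 0.02, weight_range = c(0.4, 1),
                             prefix = "P", seed = 1) {
  stopifnot(p_out >= 0, p_out <= 1, p_in > 0, p_in <= 1, p_in > p_out,
            length(weight_range) == 2, weight_range[1] > 0,
            weight_range[2] <= 1, weight_range[1] <= weight_range[2])
  nodes <- sprintf("%s%03d", prefix, seq_len(n_nodes))
  if (length(planted) > 0 && is.numeric(planted[[1]])) {
    sizes <- unlist(planted)
    if (sum(sizes) > n_nodes) stopf("planted sizes exceed node count")
    off <- cumsum(c(0, sizes[-length(sizes)]))
    planted <- lapply(seq_along(sizes), function(i)
      nodes[(off[i] + 1):(off[i] + sizes[i])])
  }
  allp <- unlist(planted)
  if (anyDuplicated(allp)) stopf("planted modules must be disjoint")
  if (!all(allp %in% nodes)) stopf("planted members must be scenario nodes")
  structure(list(n_nodes = n_nodes, nodes = nodes, planted = planted,
                 p_in = p_in, p_out = p_out, weight_range = weight_range,
                 seed = as.integer(seed)),
            class = "planted_scenario")
}

#' Generate a planted-module network
#'
#' Draws every node pair independently (within-module probability
#' \code{p_in}, elsewhere \code{p_out}) in a fixed canonical pair order, so
#' the same seed always yields the same network.
#'
#' @param sc a \code{\link{planted_scenario}}
#' @param label network label
#' @return list with \code{network} (a \code{weighted_network}) and
#'   \code{truth} (list of planted member sets)
#' @export
make_planted_network <- function(sc, label = "network") {
  stopifnot(inherits(sc, "planted_scenario"))
  nodes <- sc$nodes
  module_of <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  for (i in seq_along(sc$planted)) module_of[sc$planted[[i]]] <- i
  idx <- utils::combn(length(nodes), 2)
  a <- nodes[idx[1, ]]; b <- nodes[idx[2, ]]
  same <- !is.na(module_of[a]) & !is.na(module_of[b]) &
    module_of[a] == module_of[b]
  prob <- ifelse(same, sc$p_in, sc$p_out)
  ed <- with_seed(sc$seed, {
    u <- stats::runif(length(prob))
    on <- u < prob
    w <- stats::runif(sum(on), sc$weight_range[1], sc$weight_range[2])
    data.frame(protein_a = a[on], protein_b = b[on], confidence = w,
               stringsAsFactors = FALSE)
  })
  net <- weighted_network(nodes, ed, label = label)
  list(network = net, truth = sc$planted)
}

#' Paired disease/drug scenario
#'
#' Two planted scenarios over partially overlapping protein universes: the
#' first \code{n_shared} members of drug module \code{shared_pair[2]} are
#' identified with the first members of disease module
#' \code{shared_pair[1]} (shared nodes sit inside planted modules, as
#' direct targets concentrate in core disease modules). A background
#' interaction table carries exactly the budgeted cross edges between the
#' designated module pairs, with weights uniform on
#' \code{cross_weight_range}.
#'
#' @param disease,drug \code{\link{planted_scenario}} objects (use distinct
#'   prefixes)
#' @param n_shared number of shared nodes
#' @param shared_pair integer pair (disease module index, drug module index)
#'   hosting the shared nodes
#' @param cross list of lists \code{list(pair = c(i, j), budget = k)}
#'   giving exact cross-edge counts between disease module i and drug
#'   module j
#' @param cross_weight_range weights for cross edges, default \[0.7, 1\]
#' @param seed integer seed
#' @return list of class \code{paired_scenario}
#' @export
paired_scenario <- function(disease, drug, n_shared = 0,
                            shared_pair = c(1, 1), cross = list(),
                            cross_weight_range = c(0.7, 1), seed = 1) {
  stopifnot(inherits(disease, "planted_scenario"),
            inherits(drug, "planted_scenario"))
  if (n_shared > 0) {
    stopifnot(length(disease$planted) >= shared_pair[1],
              length(drug$planted) >= shared_pair[2])
    if (n_shared > length(disease$planted[[shared_pair[1]]]) ||
        n_shared > length(drug$planted[[shared_pair[2]]]))
      stopf("n_shared exceeds designated module size")
  }
  structure(list(disease = disease, drug = drug, n_shared = n_shared,
                 shared_pair = shared_pair, cross = cross,
                 cross_weight_range = cross_weight_range,
                 seed = as.integer(seed)),
            class = "paired_scenario")
}

#' Generate paired disease/drug networks with a cross-edge background
#'
#' Builds both planted networks, renames the designated drug-module members
#' to their shared disease counterparts, and samples exactly the budgeted
#' cross edges into the background table (an error if a budget exceeds the
#' available slots). Ground truth records the shared nodes and which module
#' pairs are truly coupled.
#'
#' @param sc a \code{\link{paired_scenario}}
#' @return list with \code{disease} and \code{drug} networks (each with
#'   \code{$network} and \code{$truth}), \code{background} (interaction
#'   data.frame), and \code{truth} (shared nodes, coupled pairs, budgets)
#' @export
make_paired_networks <- function(sc) {
  stopifnot(inherits(sc, "paired_scenario"))
  d <- make_planted_network(sc$disease, label = "disease")
  h <- make_planted_network(sc$drug, label = "drug")

  shared <- character(0)
  if (sc$n_shared > 0) {
    from <- sort(sc$drug$planted[[sc$shared_pair[2]]])[seq_len(sc$n_shared)]
    to <- sort(sc$disease$planted[[sc$shared_pair[1]]])[seq_len(sc$n_shared)]
    ren <- stats::setNames(to, from)
    rename <- function(x) ifelse(x %in% names(ren), ren[x], x)
    hn <- network_nodes(h$network)
    ed <- network_edges(h$network)
    ed$protein_a <- unname(rename(ed$protein_a))
    ed$protein_b <- unname(rename(ed$protein_b))
    h$network <- weighted_network(unname(rename(hn)), ed, label = "drug",
                                  isolated = unname(rename(h$network$isolated)))
    h$truth <- lapply(h$truth, function(m) sort(unname(rename(m))))
    shared <- to
  }

  bg <- data.frame(protein_a = character(0), protein_b = character(0),
                   confidence = numeric(0), stringsAsFactors = FALSE)
  coupled <- list()
  if (length(sc$cross) > 0) {
    bg_list <- with_seed(sc$seed + 1L, lapply(sc$cross, function(cr) {
      A <- d$truth[[cr$pair[1]]]
      B <- h$truth[[cr$pair[2]]]
      pairs <- expand.grid(a = A, b = B, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
      cp <- canonical_pairs(pairs$a, pairs$b)
      keep <- !duplicated(cp$key)
      slots <- data.frame(a = cp$a[keep], b = cp$b[keep],
                          stringsAsFactors = FALSE)
      # exclude slots already realized inside either network
      existing <- c(canonical_pairs(network_edges(d$network)$protein_a,
                                    network_edges(d$network)$protein_b)$key,
                    canonical_pairs(network_edges(h$network)$protein_a,
                                    network_edges(h$network)$protein_b)$key)
      free <- !(paste(slots$a, slots$b, sep = "\r") %in% existing)
      slots <- slots[free, , drop = FALSE]
      if (cr$budget > nrow(slots))
        stopf("cross-edge budget %d exceeds %d available slots",
              cr$budget, nrow(slots))
      slots <- slots[order(slots$a, slots$b), , drop = FALSE]
      pick <- sort(sample.int(nrow(slots), cr$budget))
      data.frame(protein_a = slots$a[pick], protein_b = slots$b[pick],
                 confidence = stats::runif(cr$budget,
                                           sc$cross_weight_range[1],
                                           sc$cross_weight_range[2]),
                 stringsAsFactors = FALSE)
    }))
    bg <- do.call(rbind, bg_list)
    coupled <- lapply(sc$cross, `[[`, "pair")
  }
  if (sc$n_shared > 0)
    coupled <- unique(c(coupled, list(sc$shared_pair)))

  list(disease = d, drug = h, background = bg,
       truth = list(shared_nodes = shared, coupled_pairs = coupled,
                    budgets = lapply(sc$cross, `[[`, "budget")))
}

#' Write paired-scenario pipeline inputs to a directory
#'
#' Emits the flat files \code{\link{run_pipeline}} consumes: disease and
#' drug gene lists, a single combined interaction table (both networks'
#' edges plus the cross-edge background) and a ground-truth JSON.
#'
#' @param pn a \code{\link{make_paired_networks}} result
#' @param dir output directory (created if needed)
#' @return named list of file paths, invisibly
#' @export
write_paired_inputs <- function(pn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    disease_genes = file.path(dir, "disease_genes.txt"),
    drug_genes = file.path(dir, "drug_genes.txt"),
    edges = file.path(dir, "edges.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  writeLines(network_nodes(pn$disease$network), paths$disease_genes)
  writeLines(network_nodes(pn$drug$network), paths$drug_genes)
  ed <- rbind(network_edges(pn$disease$network),
              network_edges(pn$drug$network), pn$background)
  cp <- canonical_pairs(ed$protein_a, ed$protein_b)
  conf <- tapply(ed$confidence, cp$key, max)
  keys <- sort(names(conf))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(protein_a = vapply(parts, `[[`, "", 1),
                    protein_b = vapply(parts, `[[`, "", 2),
                    confidence = sprintf("%.17g", as.numeric(conf[keys])),
                    stringsAsFactors = FALSE)
  utils::write.table(out, paths$edges, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(pn$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Packaged bridgeness fixture: HLJDD / stroke overlapping pathways
#'
#' A curated, literature-reported table of the 14 KEGG pathways jointly
#' enriched in three stroke-network modules (S-modules 1, 3, 4) and three
#' herbal-formula target modules (H-modules 1, 2, 8) from a published
#' network-pharmacology case study of Huang-Lian-Jie-Du Decoction on
#' ischemic stroke. The p-values and hit-gene lists are carried verbatim
#' as fixture metadata (their enrichment background is not recomputable
#' here); the fixture exercises the bridgeness and category-profiling
#' operations at desk scale.
#'
#' @return list with \code{s_records} and \code{h_records} (annotated
#'   enrichment data.frames), \code{cmap} (a \code{category_map}),
#'   \code{s_group} and \code{h_group} (the module id groups)
#' @export
hljdd_bridgeness_fixture <- function() {
  path <- system.file("extdata", "hljdd_stroke_bridgeness.tsv",
                      package = "modcoupler", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  cmap <- category_map(df[c("pathway_id", "category_code", "category_name")])

  h_rows <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    mods <- trimws(strsplit(df$h_modules[i], ",", fixed = TRUE)[[1]])
    data.frame(module_id = sprintf("H-module %s", mods),
               pathway_id = df$pathway_id[i],
               pathway_name = df$pathway_name[i],
               p_value = as.numeric(df$h_pvalue[i]),
               n_hits = length(strsplit(df$h_genes[i], ";")[[1]]),
               hit_genes = df$h_genes[i],
               stringsAsFactors = FALSE)
  }))
  s_rows <- data.frame(module_id = sprintf("S-module %s", df$s_module),
                       pathway_id = df$pathway_id,
                       pathway_name = df$pathway_name,
                       p_value = as.numeric(df$s_pvalue),
                       n_hits = lengths(strsplit(df$s_genes, ";")),
                       hit_genes = df$s_genes,
                       stringsAsFactors = FALSE)
  list(s_records = annotate_categories(s_rows, cmap),
       h_records = annotate_categories(h_rows, cmap),
       cmap = cmap,
       s_group = c("S-module 1", "S-module 3", "S-module 4"),
       h_group = c("H-module 1", "H-module 2", "H-module 8"))
}
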