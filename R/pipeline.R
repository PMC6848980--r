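#' Pipeline configuration
#'
#' Collects every input path and parameter of the end-to-end analysis.
#' Defaults mirror the reference study conditions: disease-network cutoff
#' 0.4 (broad scope), drug-network cutoff 0.7 (high reliability), cross
#' cutoff 0.7 for background edges added at merge time, and alpha 0.05 for
#' the modular map and enrichment.
#'
#' @param disease_genes,drug_genes paths to gene-list files
#' @param edges path to the interaction table used for both builds and as
#'   the merge background
#' @param score_scale score dialect of \code{edges} (see
#'   \code{\link{read_edge_table}})
#' @param disease_cutoff,drug_cutoff,cross_cutoff confidence thresholds
#' @param alpha significance level for the modular map and enrichment
#' @param mcode an \code{\link{mcode_params}} object
#' @param scope modular-map scope (see \code{\link{build_modular_map}})
#' @param gmt optional path to a GMT gene-set file (enables enrichment)
#' @param categories optional path to a category map TSV
#' @param grouping optional grouping preset name (see
#'   \code{\link{grouping_preset}})
#' @param s_group,h_group optional module id groups for a bridgeness report
#' @param out_dir output directory for all artifacts
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic)
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(disease_genes, drug_genes, edges,
                            score_scale = "unit",
                            disease_cutoff = 0.4, drug_cutoff = 0.7,
                            cross_cutoff = 0.7, alpha = 0.05,
                            mcode = mcode_params(),
                            scope = "cross_origin_only",
                            gmt = NULL, categories = NULL, grouping = NULL,
                            s_group = NULL, h_group = NULL,
                            out_dir = tempfile("modcoupler_run_"),
                            seed = 1) {
  for (v in c(disease_cutoff, drug_cutoff, cross_cutoff))
    if (!is_scalar_number(v) || v < 0 || v > 1)
      stopf("cutoffs must be numbers in [0, 1]")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1)
    stopf("alpha must be in (0, 1]")
  structure(list(disease_genes = disease_genes, drug_genes = drug_genes,
                 edges = edges, score_scale = score_scale,
                 disease_cutoff = disease_cutoff, drug_cutoff = drug_cutoff,
                 cross_cutoff = cross_cutoff, alpha = alpha, mcode = mcode,
                 scope = scope, gmt = gmt, categories = categories,
                 grouping = grouping, s_group = s_group, h_group = h_group,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}; the
#' \code{mcode} key may be a mapping of \code{\link{mcode_params}} fields.
#'
#' @param path YAML file
#' @return a \code{pipeline_config}
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$mcode)) y$mcode <- do.call(mcode_params, y$mcode)
  do.call(pipeline_config, y)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full inter-module coupling pipeline
#'
#' Stages, in order: read inputs; build the disease network (induced
#' subgraph at \code{disease_cutoff}) and drug network (at
#' \code{drug_cutoff}); cluster each with MCODE into labelled S- and
#' H-modules; merge the two networks over the interaction background
#' (cross edges at \code{cross_cutoff}); build the modular map
#' (hypergeometric significance + coupling scores); intersect the gene
#' sets into direct targets and localise them in the S-modules; and, when
#' gene sets are configured, enrich all modules and emit a bridgeness
#' report for the configured (or map-derived) module groups. All
#' intermediate artifacts are written under \code{out_dir} and a manifest
#' (input checksums, parameters, per-stage counts) is returned and written
#' as \code{manifest.json}. Reruns with identical inputs and config
#' produce byte-identical manifests.
#'
#' @param cfg a \code{\link{pipeline_config}} or path to a YAML config
#' @return the manifest, invisibly readable from
#'   \code{file.path(cfg$out_dir, "manifest.json")}
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))

  log_stage("[read] loading interaction table")
  inputs <- pipeline_stage("read", {
    list(edges = read_edge_table(cfg$edges, cfg$score_scale))
  })

  log_stage("[build] disease network (cutoff %g)", cfg$disease_cutoff)
  dnet <- pipeline_stage("build", {
    inputs$disease <- read_gene_list(cfg$disease_genes)
    build_network(inputs$disease, inputs$edges, cfg$disease_cutoff,
                  label = "disease")
  })
  log_stage("[build] drug network (cutoff %g)", cfg$drug_cutoff)
  hnet <- pipeline_stage("build", {
    inputs$drug <- read_gene_list(cfg$drug_genes)
    build_network(inputs$drug, inputs$edges, cfg$drug_cutoff, label = "drug")
  })

  log_stage("[cluster] MCODE on both networks")
  smods <- pipeline_stage("cluster", mcode_cluster(dnet, "S", cfg$mcode))
  hmods <- pipeline_stage("cluster", mcode_cluster(hnet, "H", cfg$mcode))

  log_stage("[merge] union graph (cross cutoff %g)", cfg$cross_cutoff)
  merged <- pipeline_stage("merge", merge_networks(
    dnet, hnet, inputs$edges, cfg$cross_cutoff))

  log_stage("[couple] modular map (alpha %g)", cfg$alpha)
  map <- pipeline_stage("couple", build_modular_map(
    c(smods, hmods), merged, alpha = cfg$alpha, scope = cfg$scope))

  log_stage("[targets] direct-target localisation")
  targets <- pipeline_stage("targets", direct_targets(inputs$disease,
                                                      inputs$drug))
  target_report <- if (length(targets) > 0 && length(smods) > 0)
    pipeline_stage("targets", localize(targets, smods))
  else NULL

  enr <- NULL; bridge <- NULL; cmap <- NULL
  if (!is.null(cfg$gmt)) {
    log_stage("[enrich] pathway enrichment")
    sets <- pipeline_stage("enrich", read_gmt(cfg$gmt))
    if (!is.null(cfg$categories))
      cmap <- pipeline_stage("enrich", read_category_map(cfg$categories))
    enr <- pipeline_stage("enrich", suppressWarnings(
      enrich_modules(c(smods, hmods), sets, cfg$alpha)))
    s_group <- cfg$s_group
    h_group <- cfg$h_group
    if (is.null(s_group) && nrow(map$edges) > 0)
      s_group <- sort(unique(grep("^S-", c(map$edges$module_a,
                                           map$edges$module_b),
                                  value = TRUE)))
    if (is.null(h_group) && nrow(map$edges) > 0)
      h_group <- sort(unique(grep("^H-", c(map$edges$module_a,
                                           map$edges$module_b),
                                  value = TRUE)))
    if (length(s_group) > 0 && length(h_group) > 0) {
      log_stage("[bridge] bridgeness report")
      grouping <- if (!is.null(cfg$grouping)) grouping_preset(cfg$grouping)
      bridge <- pipeline_stage("bridge", bridgeness(
        enr[grepl("^S-", enr$module_id), , drop = FALSE],
        enr[grepl("^H-", enr$module_id), , drop = FALSE],
        s_group, h_group, cmap = cmap, alpha = cfg$alpha,
        grouping = grouping))
    }
  }

  log_stage("[write] artifacts -> %s", cfg$out_dir)
  out <- function(f) file.path(cfg$out_dir, f)
  write_network(dnet, out("disease_network.json"))
  write_network(hnet, out("drug_network.json"))
  write_network(merged, out("merged_network.json"))
  write_module_table(smods, out("s_modules.tsv"))
  write_module_table(hmods, out("h_modules.tsv"))
  write_modular_map(map, out("modular_map.tsv"), format = "tsv")
  write_modular_map(map, out("modular_map.json"), format = "json")
  if (!is.null(enr))
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

  manifest <- list(
    tool = "modcoupler",
    version = as.character(utils::packageVersion("modcoupler")),
    seed = cfg$seed,
    inputs = list(
      disease_genes = unname(tools::md5sum(cfg$disease_genes)),
      drug_genes = unname(tools::md5sum(cfg$drug_genes)),
      edges = unname(tools::md5sum(cfg$edges))),
    parameters = list(
      score_scale = cfg$score_scale,
      disease_cutoff = cfg$disease_cutoff, drug_cutoff = cfg$drug_cutoff,
      cross_cutoff = cfg$cross_cutoff, alpha = cfg$alpha,
      scope = cfg$scope, mcode = unclass(cfg$mcode)),
    counts = list(
      disease_members = length(inputs$disease),
      drug_members = length(inputs$drug),
      disease_nodes = length(network_nodes(dnet)),
      disease_edges = nrow(network_edges(dnet)),
      disease_isolated = length(dnet$isolated),
      drug_nodes = length(network_nodes(hnet)),
      drug_edges = nrow(network_edges(hnet)),
      drug_isolated = length(hnet$isolated),
      s_modules = length(smods),
      h_modules = length(hmods),
      merged_nodes = length(network_nodes(merged)),
      merged_edges = nrow(network_edges(merged)),
      significant_pairs = nrow(map$edges),
      direct_targets = length(targets),
      overlap_pathways = if (!is.null(bridge))
        length(bridge$overlap_pathways) else NA))
  if (!is.null(target_report))
    manifest$direct_target_report <- list(
      per_module = target_report$per_module,
      unassigned = target_report$unassigned,
      unassigned_percentage = target_report$unassigned_percentage)
  if (!is.null(bridge))
    manifest$bridgeness <- list(
      s_group = bridge$s_group, h_group = bridge$h_group,
      overlap_pathways = bridge$overlap_pathways,
      category_profile = bridge$category_profile)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
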