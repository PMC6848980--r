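#' Hypergeometric pathway enrichment of one module
#'
#' One-sided overrepresentation test: for each pathway, the p-value is the
#' hypergeometric upper tail with \code{x} = module-pathway hits, \code{n} =
#' annotated module members, \code{M} = pathway size and \code{N} =
#' background size (equivalent to a one-tailed Fisher test). Records with
#' \code{p <= alpha} are returned sorted by p, ties by pathway id.
#'
#' @param module a \code{module} object, or a character vector of members
#'   (then \code{module_id} should be given)
#' @param sets a \code{\link{gene_set_collection}}
#' @param alpha significance level (inclusive)
#' @param module_id id used in the output when \code{module} is a plain
#'   character vector
#' @return data.frame with columns \code{module_id}, \code{pathway_id},
#'   \code{pathway_name}, \code{p_value}, \code{n_hits}, \code{hit_genes}
#'   (semicolon-joined)
#' @export
enrich <- function(module, sets, alpha = 0.05, module_id = NULL) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1)
    stopf("alpha must be in (0, 1]")
  members <- if (inherits(module, "module")) module$members else unique(module)
  id <- if (inherits(module, "module")) module$id else (module_id %||% "module")
  annotated <- intersect(members, sets$background)
  if (length(annotated) == 0) stopf("module not annotated")
  n <- length(annotated)
  N <- length(sets$background)
  rows <- lapply(names(sets$members), function(pid) {
    pw <- sets$members[[pid]]
    hits <- sort(intersect(annotated, pw))
    p <- hypergeom_upper_tail(length(hits), n, length(pw), N)
    list(pid = pid, p = p, hits = hits)
  })
  p <- vapply(rows, `[[`, 0, "p")
  nh <- vapply(rows, function(r) length(r$hits), 0L)
  keep <- which(p <= alpha & nh > 0)
  df <- data.frame(
    module_id = rep(id, length(keep)),
    pathway_id = vapply(rows[keep], `[[`, "", "pid"),
    pathway_name = unname(sets$pathway_names[
      vapply(rows[keep], `[[`, "", "pid")]),
    p_value = p[keep],
    n_hits = nh[keep],
    hit_genes = vapply(rows[keep], function(r)
      paste(r$hits, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  df <- df[order(df$p_value, df$pathway_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Enrich several modules at once
#'
#' @param modules list of \code{module} objects
#' @param sets a \code{\link{gene_set_collection}}
#' @param alpha significance level
#' @return row-bound enrichment data.frame over all modules; modules with
#'   no annotated member are skipped with a warning
#' @export
enrich_modules <- function(modules, sets, alpha = 0.05) {
  out <- lapply(modules, function(m) {
    tryCatch(enrich(m, sets, alpha), error = function(e) {
      if (grepl("not annotated", conditionMessage(e))) {
        warning(sprintf("module %s has no annotated member; skipped", m$id),
                call. = FALSE)
        NULL
      } else stop(e)
    })
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0)
    return(data.frame(module_id = character(0), pathway_id = character(0),
                      pathway_name = character(0), p_value = numeric(0),
                      n_hits = integer(0), hit_genes = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Representative enrichment term
#'
#' The minimum-p record of a module's enrichment, used to annotate the
#' module on the modular map; ties are broken by lexicographic pathway id.
#'
#' @param records enrichment data.frame (non-empty)
#' @return single-row data.frame
#' @export
representative_term <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stopf("no enrichment records")
  records[order(records$p_value, records$pathway_id), , drop = FALSE][1, ,
                                                                      drop = FALSE]
}

#' Attach category annotations to enrichment records
#'
#' @param records enrichment data.frame
#' @param cmap a \code{category_map}
#' @return records with \code{category_code} and \code{category_name}
#'   columns appended ("unclassified" where unmapped)
#' @export
annotate_categories <- function(records, cmap) {
  cat <- lookup_category(cmap, records$pathway_id)
  records$category_code <- cat$category_code
  records$category_name <- cat$category_name
  records
}

#' Category grouping presets
#'
#' Named pools of KEGG top-level categories used for headline shares. The
#' \code{"signal_transduction"} preset pools codes 3.2 (signal
#' transduction) and 3.3 (signaling molecules and interaction) into one
#' "signal transduction-related" group — the pooling behind a 6-of-14 =
#' 42.86\% share in the packaged bridgeness fixture.
#'
#' @param name preset name
#' @return named character vector mapping category codes to group labels
#' @export
grouping_preset <- function(name = c("signal_transduction")) {
  name <- match.arg(name)
  switch(name,
         signal_transduction = c("3.2" = "signal transduction-related",
                                 "3.3" = "signal transduction-related"))
}

#' Category profile of enriched pathways
#'
#' Counts distinct pathways per category (or per group when a grouping is
#' supplied; ungrouped categories keep their own label) and reports each
#' category's fraction of the distinct pathway total. Fractions sum to 1.
#'
#' @param records enrichment data.frame
#' @param cmap a \code{category_map}
#' @param grouping optional named character vector code -> group label
#'   (see \code{\link{grouping_preset}})
#' @return data.frame of class \code{category_profile} with columns
#'   \code{category}, \code{codes}, \code{n_pathways}, \code{fraction},
#'   \code{percentage} (half-up, 2 decimals)
#' @export
categorize <- function(records, cmap, grouping = NULL) {
  ids <- unique(records$pathway_id)
  if (length(ids) == 0)
    return(structure(data.frame(category = character(0), codes = character(0),
                                n_pathways = integer(0), fraction = numeric(0),
                                percentage = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("category_profile", "data.frame")))
  cat <- lookup_category(cmap, ids)
  label <- ifelse(cat$category_code == "unclassified", "unclassified",
                  paste(cat$category_code, cat$category_name))
  if (!is.null(grouping)) {
    grouped <- cat$category_code %in% names(grouping)
    label[grouped] <- unname(grouping[cat$category_code[grouped]])
  }
  n <- tapply(ids, label, length)
  codes <- tapply(cat$category_code, label, function(z)
    paste(sort(unique(z)), collapse = ";"))
  labs <- sort(names(n))
  out <- data.frame(
    category = labs,
    codes = as.character(codes[labs]),
    n_pathways = as.integer(n[labs]),
    fraction = as.integer(n[labs]) / length(ids),
    stringsAsFactors = FALSE)
  out$percentage <- round_half_up(100 * out$fraction, 2)
  out <- out[order(-out$n_pathways, out$category), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("category_profile", "data.frame"))
}

#' Bridgeness report between module groups
#'
#' The bridgeness of a group of disease (S) modules and a group of drug (H)
#' modules is characterised by their overlapping enriched pathways: the
#' intersection of the union of significant pathways across the S group
#' with the union across the H group. The report carries both sides'
#' records for the overlap plus its category profile.
#'
#' @param s_records,h_records enrichment data.frames (with
#'   \code{module_id} column) covering the candidate modules
#' @param s_group,h_group character vectors of module ids
#' @param cmap optional \code{category_map} for the category profile
#' @param alpha significance filter applied to both sides (inclusive)
#' @param grouping optional grouping for the profile
#' @return object of class \code{bridgeness_report}
#' @export
bridgeness <- function(s_records, h_records, s_group, h_group,
                       cmap = NULL, alpha = 0.05, grouping = NULL) {
  if (length(s_group) == 0 || length(h_group) == 0)
    stopf("module groups must be non-empty")
  pick <- function(rec, group) {
    rec[rec$module_id %in% group & rec$p_value <= alpha, , drop = FALSE]
  }
  s_sel <- pick(s_records, s_group)
  h_sel <- pick(h_records, h_group)
  overlap <- sort(intersect(unique(s_sel$pathway_id),
                            unique(h_sel$pathway_id)))
  s_over <- s_sel[s_sel$pathway_id %in% overlap, , drop = FALSE]
  h_over <- h_sel[h_sel$pathway_id %in% overlap, , drop = FALSE]
  profile <- if (!is.null(cmap) && length(overlap) > 0)
    categorize(data.frame(pathway_id = overlap, stringsAsFactors = FALSE),
               cmap, grouping)
  else NULL
  structure(list(s_group = s_group, h_group = h_group,
                 overlap_pathways = overlap,
                 s_records = s_over, h_records = h_over,
                 category_profile = profile, alpha = alpha),
            class = "bridgeness_report")
}

#' @export
print.bridgeness_report <- function(x, ...) {
  cat(sprintf(
    "bridgeness_report: %d overlapping pathway(s) between {%s} and {%s} at alpha = %s\n",
    length(x$overlap_pathways), paste(x$s_group, collapse = ", "),
    paste(x$h_group, collapse = ", "), format(x$alpha)))
  if (!is.null(x$category_profile) && nrow(x$category_profile) > 0) {
    for (i in seq_len(nrow(x$category_profile)))
      cat(sprintf("  %s: %d (%.2f%%)\n", x$category_profile$category[i],
                  x$category_profile$n_pathways[i],
                  x$category_profile$percentage[i]))
  }
  invisible(x)
}
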