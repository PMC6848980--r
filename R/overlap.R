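#' Direct targets: intersection of disease and drug protein sets
#'
#' Proteins present in both the disease gene set and the drug putative-target
#' set are the candidates for direct regulation.
#'
#' @param disease,drug character vectors of symbols
#' @return lexicographically sorted character vector
#' @export
direct_targets <- function(disease, drug) {
  sort(intersect(unique(disease), unique(drug)))
}

#' Localise direct targets within modules
#'
#' Counts how many targets fall in each module (modules must be pairwise
#' disjoint) and how many are in no module, with percentages of the total
#' target count rounded half-up to 2 decimals — e.g. 12 of 28 targets in
#' one module is 42.86\%.
#'
#' @param targets character vector of target symbols (non-empty)
#' @param modules list of \code{module} objects, pairwise disjoint
#' @return object of class \code{direct_target_report}: \code{targets},
#'   \code{per_module} (data.frame \code{module_id}, \code{count},
#'   \code{percentage}), \code{unassigned}, \code{unassigned_percentage}
#' @export
localize <- function(targets, modules) {
  targets <- sort(unique(targets))
  if (length(targets) == 0) stopf("no targets")
  all_members <- unlist(lapply(modules, `[[`, "members"))
  dup <- all_members[duplicated(all_members)]
  if (length(dup) > 0)
    stopf("modules are not disjoint: '%s' appears in more than one", dup[1])
  counts <- vapply(modules, function(m)
    length(intersect(targets, m$members)), 0L)
  ids <- vapply(modules, `[[`, "", "id")
  per <- data.frame(module_id = ids, count = counts,
                    percentage = round_half_up(100 * counts / length(targets), 2),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  unassigned <- length(targets) - sum(counts)
  structure(list(targets = targets, per_module = per,
                 unassigned = as.integer(unassigned),
                 unassigned_percentage =
                   round_half_up(100 * unassigned / length(targets), 2)),
            class = "direct_target_report")
}

#' @export
print.direct_target_report <- function(x, ...) {
  cat(sprintf("direct_target_report: %d targets, %d unassigned (%.2f%%)\n",
              length(x$targets), x$unassigned, x$unassigned_percentage))
  hit <- x$per_module[x$per_module$count > 0, , drop = FALSE]
  if (nrow(hit) > 0) {
    for (i in seq_len(nrow(hit)))
      cat(sprintf("  %s: %d (%.2f%%)\n", hit$module_id[i], hit$count[i],
                  hit$percentage[i]))
  }
  invisible(x)
}

#' Combined target share of a module subset
#'
#' Percentage of all targets that fall in the given modules, recomputed
#' from the raw counts (not by summing rounded per-module percentages) and
#' rounded half-up to 2 decimals — e.g. 12 + 4 of 28 gives 57.14\%.
#'
#' @param report a \code{\link{localize}} result
#' @param module_ids character vector of module ids
#' @return list with \code{count} and \code{percentage}
#' @export
localize_share <- function(report, module_ids) {
  stopifnot(inherits(report, "direct_target_report"))
  missing <- setdiff(module_ids, report$per_module$module_id)
  if (length(missing) > 0) stopf("unknown module id '%s'", missing[1])
  sel <- report$per_module$module_id %in% module_ids
  cnt <- sum(report$per_module$count[sel])
  list(count = as.integer(cnt),
       percentage = round_half_up(100 * cnt / length(report$targets), 2))
}
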