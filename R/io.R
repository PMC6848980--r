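#' Read a gene/protein symbol list
#'
#' One symbol per line; lines starting with \code{#} are comments and blank
#' lines are skipped. Symbols are whitespace-trimmed, case-preserved and
#' deduplicated; the returned set is sorted so the result does not depend on
#' input line order.
#'
#' @param source path to a text file, or a connection
#' @return sorted character vector of unique symbols
#' @export
read_gene_list <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stopf("no symbols")
  sort(unique(lines))
}

#' Read a STRING-dialect interaction table
#'
#' Whitespace/tab-delimited columns \code{protein_a}, \code{protein_b},
#' \code{score}. \code{score_scale} declares the score dialect: \code{"unit"}
#' for reals in \[0, 1\] or \code{"string1000"} for STRING integer combined
#' scores in \[0, 1000\] (normalised by 1000). Self-loops are dropped with a
#' warning; duplicate unordered pairs are collapsed keeping the maximum
#' confidence, so the result is invariant to row shuffling and to swapping
#' the two endpoint columns.
#'
#' @param source path or connection
#' @param score_scale \code{"unit"} or \code{"string1000"}
#' @return data.frame with columns \code{protein_a}, \code{protein_b},
#'   \code{confidence} (confidence in \[0, 1\]), canonically ordered
#' @export
read_edge_table <- function(source, score_scale = c("unit", "string1000")) {
  score_scale <- match.arg(score_scale)
  lines <- readLines(source, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0) stopf("empty edge table")

  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  # a single header row naming the columns is tolerated
  if (nf[1] == 3 && is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    fields <- fields[-1]; lineno <- lineno[-1]; nf <- nf[-1]
  }
  if (length(fields) == 0) stopf("empty edge table")
  bad <- which(nf != 3)
  if (length(bad) > 0)
    stopf("malformed edge table: expected 3 columns on line %d, found %d",
          lineno[bad[1]], nf[bad[1]])

  a <- vapply(fields, `[[`, "", 1)
  b <- vapply(fields, `[[`, "", 2)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(s))
    stopf("non-numeric score on line %d", lineno[which(is.na(s))[1]])

  hi <- if (score_scale == "string1000") 1000 else 1
  out_of_range <- which(s < 0 | s > hi)
  if (length(out_of_range) > 0)
    stopf("score %g outside [0, %g] on line %d", s[out_of_range[1]], hi,
          lineno[out_of_range[1]])
  if (score_scale == "string1000") s <- s / 1000

  self <- a == b
  if (any(self)) {
    warning(sprintf("dropped %d self-loop record(s)", sum(self)),
            call. = FALSE)
    a <- a[!self]; b <- b[!self]; s <- s[!self]
  }

  cp <- canonical_pairs(a, b)
  conf <- tapply(s, cp$key, max)
  keys <- sort(names(conf))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(
    protein_a = vapply(parts, `[[`, "", 1),
    protein_b = vapply(parts, `[[`, "", 2),
    confidence = as.numeric(conf[keys]),
    stringsAsFactors = FALSE
  )
}

#' Gene-set collection
#'
#' Container for pathway gene sets plus an annotation background. Every
#' member symbol must be in the background and member sets must be
#' non-empty.
#'
#' @param members named list of character vectors (names are pathway ids)
#' @param pathway_names optional named character vector of display names
#' @param background optional character vector; defaults to the union of
#'   all members
#' @return object of class \code{gene_set_collection}
#' @export
gene_set_collection <- function(members, pathway_names = NULL,
                                background = NULL) {
  if (is.null(names(members)) || anyDuplicated(names(members)))
    stopf("gene sets must have unique pathway ids")
  if (any(lengths(members) == 0)) stopf("pathway member sets must be non-empty")
  members <- lapply(members, function(m) sort(unique(m)))
  if (is.null(background)) background <- sort(unique(unlist(members)))
  else {
    background <- sort(unique(background))
    missing <- setdiff(unlist(members), background)
    if (length(missing) > 0)
      stopf("member symbol '%s' not in background", missing[1])
  }
  if (is.null(pathway_names))
    pathway_names <- stats::setNames(names(members), names(members))
  structure(
    list(members = members,
         pathway_names = pathway_names[names(members)],
         background = background),
    class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d pathways, background of %d symbols\n",
              length(x$members), length(x$background)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard Gene Matrix Transposed: one set per line, tab-separated fields
#' \code{id}, \code{description}, then member symbols. Background defaults
#' to the union of all members unless supplied.
#'
#' @param source path or connection
#' @param background optional character vector overriding the background
#' @return a \code{\link{gene_set_collection}}
#' @export
read_gmt <- function(source, background = NULL) {
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stopf("GMT line %d has fewer than 3 fields", short[1])
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids))
    stopf("duplicate pathway id '%s'", ids[duplicated(ids)][1])
  nm <- stats::setNames(vapply(fields, `[[`, "", 2), ids)
  members <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
  gene_set_collection(members, pathway_names = nm, background = background)
}

#' Read a pathway category map
#'
#' TSV with columns \code{pathway_id}, \code{category_code},
#' \code{category_name}. Category codes follow the KEGG pathway-map
#' numbering pattern \code{digit(s).digit(s)} (e.g. \code{3.2} for signal
#' transduction). Lookups for pathways absent from the map yield the
#' \code{"unclassified"} category.
#'
#' @param source path or connection
#' @return data.frame of class \code{category_map}
#' @export
read_category_map <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) > 0 && identical(fields[[1]][1], "pathway_id"))
    fields <- fields[-1]
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0) stopf("category map row %d does not have 3 fields", bad[1])
  df <- data.frame(
    pathway_id = vapply(fields, `[[`, "", 1),
    category_code = vapply(fields, `[[`, "", 2),
    category_name = vapply(fields, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
  category_map(df)
}

#' Construct a category map from a data.frame
#'
#' @param df data.frame with columns \code{pathway_id}, \code{category_code},
#'   \code{category_name}
#' @return data.frame of class \code{category_map}
#' @export
category_map <- function(df) {
  need <- c("pathway_id", "category_code", "category_name")
  if (!all(need %in% names(df))) stopf("category map needs columns %s",
                                       paste(need, collapse = ", "))
  bad <- !grepl("^[0-9]+\\.[0-9]+$", df$category_code)
  if (any(bad))
    stopf("invalid category code '%s' (expected digits.digits)",
          df$category_code[bad][1])
  if (anyDuplicated(df$pathway_id))
    stopf("duplicate pathway id in category map")
  structure(df[need], class = c("category_map", "data.frame"))
}

#' Look up categories for pathway ids
#'
#' @param cmap a \code{category_map}
#' @param pathway_ids character vector
#' @return data.frame with \code{pathway_id}, \code{category_code},
#'   \code{category_name}; unmapped ids get code and name "unclassified"
#' @export
lookup_category <- function(cmap, pathway_ids) {
  idx <- match(pathway_ids, cmap$pathway_id)
  data.frame(
    pathway_id = pathway_ids,
    category_code = ifelse(is.na(idx), "unclassified", cmap$category_code[idx]),
    category_name = ifelse(is.na(idx), "unclassified", cmap$category_name[idx]),
    stringsAsFactors = FALSE
  )
}

modular_map_columns <- c("module_a", "module_b", "t", "x", "n",
                         "p_value", "coupling_score")

#' Write a modular map
#'
#' Serialises a \code{\link{build_modular_map}} result. The TSV format has
#' the fixed columns \code{module_a, module_b, t, x, n, p_value,
#' coupling_score} with numerics at full precision; JSON additionally
#' carries the module node list, alpha and the network-pair totals; GraphML
#' is written through igraph and loads in standard graph readers.
#'
#' @param map a \code{modular_map}
#' @param path output file path
#' @param format \code{"tsv"}, \code{"json"} or \code{"graphml"}
#' @return the path, invisibly
#' @export
write_modular_map <- function(map, path, format = c("tsv", "json", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(map, "modular_map"))
  ed <- map$edges
  if (format == "tsv") {
    out <- data.frame(
      module_a = ed$module_a, module_b = ed$module_b,
      t = ed$t, x = ed$x, n = ed$n,
      p_value = sprintf("%.17g", ed$p_value),
      coupling_score = sprintf("%.17g", ed$coupling_score),
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else if (format == "json") {
    nodes <- lapply(map$modules, function(m)
      list(id = m$id, origin = m$origin, rank = m$rank, score = m$score,
           members = as.list(m$members)))
    obj <- list(nodes = nodes,
                edges = ed[modular_map_columns],
                alpha = map$alpha, M = map$M, N = map$N, scope = map$scope)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    ids <- vapply(map$modules, `[[`, "", "id")
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(
      g, length(ids), name = ids,
      origin = vapply(map$modules, `[[`, "", "origin"),
      score = vapply(map$modules, `[[`, 0, "score"))
    if (nrow(ed) > 0) {
      g <- igraph::add_edges(g, rbind(match(ed$module_a, ids),
                                      match(ed$module_b, ids)))
      for (col in c("t", "x", "n", "p_value", "coupling_score"))
        g <- igraph::set_edge_attr(g, col, value = ed[[col]])
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a modular map written by \code{\link{write_modular_map}}
#'
#' TSV yields the edge table only (nodes are the edge endpoints); JSON
#' restores nodes, edges, alpha and totals.
#'
#' @param path input file
#' @param format \code{"tsv"} or \code{"json"}
#' @return a \code{modular_map}
#' @export
read_modular_map <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "character",
                                           "integer", "integer", "integer",
                                           "numeric", "numeric"),
                            stringsAsFactors = FALSE)
    names(df) <- modular_map_columns
    ids <- sort(unique(c(df$module_a, df$module_b)))
    mods <- lapply(ids, function(i)
      new_module(members = character(0), score = NA_real_, id = i,
                 origin = substr(i, 1, 1)))
    new_modular_map(mods, df, alpha = NA_real_, M = NA_integer_,
                    N = NA_integer_, scope = NA_character_)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
    mods <- lapply(seq_along(obj$nodes$id %||% character(0)), function(i)
      new_module(members = unlist(obj$nodes$members[[i]]),
                 score = obj$nodes$score[i], id = obj$nodes$id[i],
                 origin = obj$nodes$origin[i], rank = obj$nodes$rank[i]))
    if (is.null(mods)) mods <- list()
    ed <- obj$edges
    if (length(ed) == 0 || is.null(nrow(ed)))
      ed <- empty_map_edges()
    ed <- as.data.frame(ed, stringsAsFactors = FALSE)[modular_map_columns]
    new_modular_map(mods, ed, alpha = obj$alpha, M = obj$M, N = obj$N,
                    scope = obj$scope)
  }
}

#' Write a weighted network to JSON
#'
#' @param net a \code{weighted_network}
#' @param path output file
#' @return the path, invisibly
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  ed <- network_edges(net)
  jsonlite::write_json(
    list(label = net$label,
         nodes = network_nodes(net),
         isolated = net$isolated,
         edges = ed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a weighted network written by \code{\link{write_network}}
#'
#' @param path input file
#' @return a \code{weighted_network}
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  ed <- obj$edges
  if (length(ed) == 0 || is.null(nrow(ed)))
    ed <- data.frame(protein_a = character(0), protein_b = character(0),
                     confidence = numeric(0), stringsAsFactors = FALSE)
  weighted_network(nodes = unlist(obj$nodes) %||% character(0),
                   edges = ed, label = obj$label,
                   isolated = unlist(obj$isolated) %||% character(0))
}

#' Write a module table
#'
#' TSV columns: \code{module_id, rank, score, size, members} (members
#' semicolon-joined).
#'
#' @param modules list of \code{module} objects
#' @param path output file
#' @return the path, invisibly
#' @export
write_module_table <- function(modules, path) {
  df <- data.frame(
    module_id = vapply(modules, `[[`, "", "id"),
    rank = vapply(modules, `[[`, 0L, "rank"),
    score = sprintf("%.17g", vapply(modules, `[[`, 0, "score")),
    size = vapply(modules, function(m) length(m$members), 0L),
    members = vapply(modules, function(m) paste(m$members, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a module table written by \code{\link{write_module_table}}
#'
#' Module origin is recovered from the id prefix ("S-module k" / "H-module k").
#'
#' @param path input file
#' @return list of \code{module} objects
#' @export
read_module_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "numeric",
                                         "integer", "character"))
  lapply(seq_len(nrow(df)), function(i)
    new_module(members = strsplit(df$members[i], ";", fixed = TRUE)[[1]],
               score = df$score[i], id = df$module_id[i],
               origin = substr(df$module_id[i], 1, 1), rank = df$rank[i]))
}
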