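# Readers/writers for the plain-text interchange formats used by both arms:
# expression TSV + group-label JSON, GMT gene sets, edge-list CSV, GraphML.

#' Read / write a gene-set collection in GMT format
#'
#' GMT is tab-separated: set id, description, then one member per field.
#'
#' @param path File path.
#' @return `read_gmt()`: a `geneset_collection` tibble (`set_id`, `name`,
#'   `genes` list-column).
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' u <- sprintf("G%02d", 1:20)
#' write_gmt(sim_geneset_collection(u, 3, c(4, 6), seed = 1), f)
#' read_gmt(f)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", bad[1]),
          class = "ductnet_input_error")
  }
  out <- tibble(
    set_id = map_chr(parts, 1),
    name = map_chr(parts, 2),
    genes = map(parts, function(p) unique(p[-(1:2)]))
  )
  class(out) <- c("geneset_collection", class(out))
  out
}

#' @rdname read_gmt
#' @param collection A `geneset_collection` tibble.
#' @export
write_gmt <- function(collection, path) {
  lines <- map_chr(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set_id[i], collection$name[i], collection$genes[[i]]),
          collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an expression matrix as TSV with a JSON group sidecar
#'
#' The TSV holds `gene_id` plus one column per sample; the sidecar JSON maps
#' sample names to group labels.
#'
#' @param sim An `expression_sim` (or any list with `expr` and `groups`).
#' @param path TSV path; the sidecar is written at `<path>.groups.json`.
#' @return `read_expression()`: list with `expr` and `groups` tibbles.
#' @export
write_expression <- function(sim, path) {
  readr::write_tsv(sim$expr, path)
  jsonlite::write_json(
    as.list(setNames(sim$groups$group, sim$groups$sample)),
    paste0(path, ".groups.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE)
  g <- jsonlite::read_json(paste0(path, ".groups.json"), simplifyVector = TRUE)
  list(expr = expr,
       groups = tibble(sample = names(g), group = unname(unlist(g))))
}

#' Write / read a typed edge list as CSV
#'
#' Columns `source`, `target`, `relation`.
#' @param edges Tibble with columns `source`, `target`, `relation`.
#' @param path File path.
#' @export
write_edges <- function(edges, path) {
  readr::write_csv(edges[, c("source", "target", "relation")], path)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  readr::read_csv(path, col_types = "ccc")
}

#' Export a hierarchical network (or typed graph) to GraphML
#'
#' Node attribute `level` (and `role`) and edge attribute `relation` are
#' carried into the file, so external viewers can lay the hierarchy out.
#'
#' @param network A `hier_network` from [build_hierarchy()], or a
#'   `reg_graph` from [ingest_graph()].
#' @param path Output file path.
#' @export
write_graphml <- function(network, path) {
  if (inherits(network, "hier_network")) {
    nodes <- network$levels
    edges <- network$edges
  } else if (inherits(network, "reg_graph")) {
    nodes <- network$nodes
    edges <- network$edges
  } else {
    abort("`network` must be a hier_network or reg_graph.",
          class = "ductnet_input_error")
  }
  g <- igraph::graph_from_data_frame(
    edges[, intersect(c("source", "target", "relation"), names(edges))],
    directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
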