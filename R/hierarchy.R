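#' Ingest a relation-typed regulator edge table
#'
#' Builds the typed digraph that hierarchical layering consumes. Edges carry
#' exactly one relation label among `affected`, `activated`, `inhibited`
#' (the three adjacency matrices of a knowledge-base export share one node
#' index, so a plain edge list represents them faithfully). Self-loops are
#' dropped with a note; duplicate (source, target, relation) triples are
#' collapsed. Nodes are created on first mention; declared DEG and upstream
#' identifiers are added even when they touch no edge.
#'
#' @param edge_table Data frame with columns `source`, `target`, `relation`.
#' @param deg_list Character vector of DEG identifiers (role `deg`).
#' @param upstream Character vector of declared upstream regulators (role
#'   `upstream_regulator`); all other mentioned nodes are tagged
#'   `candidate_regulator`.
#' @return A list of class `reg_graph`: `edges` (sorted, deduplicated
#'   tibble), `nodes` (tibble `node`, `role`).
#' @examples
#' g <- ingest_graph(
#'   data.frame(source = "R1", target = "G1", relation = "activated"),
#'   deg_list = "G1", upstream = character(0))
#' g$nodes
#' @export
ingest_graph <- function(edge_table, deg_list = character(0),
                         upstream = character(0)) {
  needed <- c("source", "target", "relation")
  if (!all(needed %in% names(edge_table))) {
    abort("`edge_table` must have columns source, target, relation.",
          class = "ductnet_input_error")
  }
  edges <- tibble(source = as.character(edge_table$source),
                  target = as.character(edge_table$target),
                  relation = as.character(edge_table$relation))
  allowed <- c("affected", "activated", "inhibited")
  bad <- which(!(edges$relation %in% allowed))
  if (length(bad) > 0) {
    abort(sprintf("unknown relation %s in edge row %d (allowed: %s)",
                  dQuote(edges$relation[bad[1]]), bad[1],
                  paste(allowed, collapse = ", ")),
          class = "ductnet_input_error")
  }
  loops <- edges$source == edges$target
  if (any(loops)) {
    inform(sprintf("%d self-loop(s) dropped", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- distinct(edges) |> arrange(.data$source, .data$target, .data$relation)

  deg_list <- unique(as.character(deg_list))
  upstream <- unique(as.character(upstream))
  both <- intersect(deg_list, upstream)
  if (length(both) > 0) {
    abort(sprintf("node(s) declared both DEG and upstream: %s",
                  paste(head(both, 5), collapse = ", ")),
          class = "ductnet_input_error")
  }
  nodes <- sort(unique(c(edges$source, edges$target, deg_list, upstream)))
  role <- ifelse(nodes %in% deg_list, "deg",
                 ifelse(nodes %in% upstream, "upstream_regulator",
                        "candidate_regulator"))
  structure(list(edges = edges, nodes = tibble(node = nodes, role = role)),
            class = "reg_graph")
}

#' @export
print.reg_graph <- function(x, ...) {
  cat(sprintf("<reg_graph> %d nodes (%d deg, %d upstream, %d candidate), %d typed edges\n",
              nrow(x$nodes), sum(x$nodes$role == "deg"),
              sum(x$nodes$role == "upstream_regulator"),
              sum(x$nodes$role == "candidate_regulator"), nrow(x$edges)))
  invisible(x)
}

#' Layer a regulator graph above a function's DEG set
#'
#' Iterative minimal-level identification: level 0 is the function's DEG
#' set; level 1 is every not-yet-assigned candidate or upstream regulator
#' with at least one outgoing edge (any relation type) into level 0; level
#' i+1 likewise regulates level i directly. Iteration stops at the fixpoint,
#' when a pass adds no node. Each node therefore receives the smallest
#' positive level at which it can regulate the layer below — equivalently
#' its breadth-first distance to the DEG layer along reversed edges — and
#' nodes with no directed path into the DEG set are excluded. Retained edges
#' run from an assigned node into any strictly lower assigned level.
#'
#' Relation labels never influence the layering; they are kept as edge
#' annotation for export. Nodes tagged `deg` that are not in
#' `function_degs` are not eligible as intermediates.
#'
#' @param graph A `reg_graph` from [ingest_graph()].
#' @param function_degs Character vector; must be a subset of the graph's
#'   `deg`-tagged nodes. Empty input yields an empty network with a warning.
#' @param candidates Optional character vector restricting which
#'   candidate/upstream nodes may enter the hierarchy (e.g. a predicted
#'   regulator list); default: all of them.
#' @param function_label Label stored on the result.
#' @return A list of class `hier_network`: `function_label`, `levels`
#'   (tibble `node`, `level`, `role`; level 0 = DEGs), `edges` (retained
#'   edges with `from_level`, `to_level`), `iterations` (passes to fixpoint,
#'   the final empty pass included).
#' @examples
#' g <- ingest_graph(
#'   data.frame(source = c("U", "R2", "R1"), target = c("R2", "R1", "G1"),
#'              relation = "activated"),
#'   deg_list = "G1", upstream = "U")
#' build_hierarchy(g, "G1")$levels
#' @export
build_hierarchy <- function(graph, function_degs, candidates = NULL,
                            function_label = "function") {
  if (!inherits(graph, "reg_graph")) {
    abort("`graph` must come from ingest_graph().", class = "ductnet_input_error")
  }
  function_degs <- unique(as.character(function_degs))
  deg_nodes <- graph$nodes$node[graph$nodes$role == "deg"]
  stray <- setdiff(function_degs, deg_nodes)
  if (length(stray) > 0) {
    abort(sprintf("function DEG(s) not tagged deg in the graph: %s",
                  paste(head(stray, 5), collapse = ", ")),
          class = "ductnet_input_error")
  }
  if (length(function_degs) == 0) {
    warn("empty function DEG set; returning an empty network")
    return(structure(list(function_label = function_label,
                          levels = tibble(node = character(0), level = integer(0),
                                          role = character(0)),
                          edges = tibble(source = character(0), target = character(0),
                                         relation = character(0),
                                         from_level = integer(0), to_level = integer(0)),
                          iterations = 0L),
                     class = "hier_network"))
  }

  eligible <- graph$nodes$node[graph$nodes$role %in%
                                 c("candidate_regulator", "upstream_regulator")]
  if (!is.null(candidates)) eligible <- intersect(eligible, as.character(candidates))

  # outgoing targets per eligible source, relation labels ignored
  edges <- graph$edges
  targets_of <- split(edges$target, edges$source)

  level_of <- setNames(rep(0L, length(function_degs)), function_degs)
  unassigned <- setdiff(eligible, function_degs)
  frontier <- function_degs
  iterations <- 0L
  lv <- 0L
  repeat {
    iterations <- iterations + 1L
    frontier_set <- frontier
    newly <- unassigned[vapply(unassigned, function(nd) {
      any(targets_of[[nd]] %in% frontier_set)
    }, logical(1))]
    if (length(newly) == 0) break
    lv <- lv + 1L
    level_of[newly] <- lv
    unassigned <- setdiff(unassigned, newly)
    frontier <- newly
  }

  levels_tbl <- tibble(node = names(level_of), level = unname(level_of)) |>
    left_join(graph$nodes, by = "node") |>
    arrange(.data$level, .data$node)

  kept <- edges |>
    mutate(from_level = level_of[.data$source], to_level = level_of[.data$target]) |>
    filter(!is.na(.data$from_level), !is.na(.data$to_level),
           .data$to_level < .data$from_level) |>
    arrange(.data$from_level, .data$source, .data$target)

  structure(list(function_label = function_label, levels = levels_tbl,
                 edges = kept, iterations = iterations),
            class = "hier_network")
}

#' @export
print.hier_network <- function(x, ...) {
  if (nrow(x$levels) == 0) {
    cat(sprintf("<hier_network> '%s': empty\n", x$function_label))
    return(invisible(x))
  }
  tab <- table(x$levels$level)
  cat(sprintf("<hier_network> '%s': %d nodes over levels 0..%d (%s), %d edges, %d iterations to fixpoint\n",
              x$function_label, nrow(x$levels), max(x$levels$level),
              paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
              nrow(x$edges), x$iterations))
  invisible(x)
}

#' @method tidy hier_network
#' @export
tidy.hier_network <- function(x, ...) x$levels

#' @method glance hier_network
#' @export
glance.hier_network <- function(x, ...) {
  tibble(function_label = x$function_label,
         n_nodes = nrow(x$levels),
         n_deg = sum(x$levels$level == 0),
         n_intermediate = sum(x$levels$level >= 1),
         max_level = if (nrow(x$levels)) max(x$levels$level) else NA_integer_,
         n_edges = nrow(x$edges),
         iterations = x$iterations)
}

#' Node multiplicity across per-function hierarchical networks
#'
#' For each node appearing at level >= 1 (intermediate or upstream) in any
#' network, counts the number of networks containing it. DEG-layer
#' membership does not count: the object of interest is common intermediate
#' factors, not shared target genes.
#'
#' @param networks List of `hier_network` objects (>= 2).
#' @return Tibble of class `node_multiplicity`: `node`, `n_found`, ordered
#'   by decreasing count then node id; attribute `n_networks`.
#' @export
network_multiplicity <- function(networks) {
  if (length(networks) < 2L) {
    abort("multiplicity needs at least two networks.", class = "ductnet_input_error")
  }
  ok <- vapply(networks, inherits, logical(1), what = "hier_network")
  if (!all(ok)) {
    abort("all elements must be hier_network objects.", class = "ductnet_input_error")
  }
  per_net <- map(networks, function(nw) unique(nw$levels$node[nw$levels$level >= 1]))
  counts <- table(unlist(per_net))
  if (length(counts) == 0) {
    out <- tibble(node = character(0), n_found = integer(0))
    attr(out, "n_networks") <- length(networks)
    class(out) <- c("node_multiplicity", class(out))
    return(out)
  }
  out <- tibble(node = names(counts), n_found = as.integer(counts)) |>
    arrange(desc(.data$n_found), .data$node)
  attr(out, "n_networks") <- length(networks)
  class(out) <- c("node_multiplicity", class(out))
  out
}

#' Common intermediate regulators across functions
#'
#' Selects the nodes found in at least `threshold` networks (default: all of
#' them, i.e. multiplicity equal to the number of networks), optionally
#' intersected with a pathway membership list (e.g. the union of the best
#' signaling-pathway overlaps).
#'
#' @param multiplicity A `node_multiplicity` from [network_multiplicity()].
#' @param pathway_members Optional character vector to intersect with.
#' @param threshold Minimum multiplicity; default the number of networks.
#' @return Sorted character vector of node identifiers.
#' @export
common_intermediates <- function(multiplicity, pathway_members = NULL,
                                 threshold = NULL) {
  n_networks <- attr(multiplicity, "n_networks")
  threshold <- threshold %||% n_networks
  assert_count(threshold, "threshold", min = 1L)
  out <- multiplicity$node[multiplicity$n_found >= threshold]
  if (!is.null(pathway_members)) {
    out <- intersect(out, as.character(pathway_members))
  }
  sort(out)
}
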