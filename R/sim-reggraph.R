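#' Simulate a layered, relation-typed regulator graph with known levels
#'
#' Builds the kind of knowledge-base digraph that hierarchical layering
#' consumes: level 0 is a DEG layer, levels 1..`n_levels` are regulators, and
#' every planted edge runs from a level i+1 node to a level i node. Each edge
#' carries one of the three relation labels (affected / activated /
#' inhibited), drawn uniformly. Optional noise edges are sampled under the
#' constraint level(target) >= level(source) - 1 (with source level >= 1),
#' which leaves every node's shortest reversed-edge distance to the DEG layer
#' equal to its planted level, so layering remains exactly recoverable.
#'
#' @param n_levels Number of regulator levels above the DEG layer (>= 1);
#'   the top level is tagged as the upstream-regulator layer.
#' @param nodes_per_level Nodes in each layer (DEG layer included).
#' @param n_noise_edges Number of extra non-planted edges to add.
#' @param seed Integer seed.
#'
#' @return A list of class `reggraph_sim`:
#'   \describe{
#'     \item{edges}{tibble `source`, `target`, `relation`.}
#'     \item{truth}{tibble `node`, `level` (0 = DEG layer).}
#'     \item{deg_ids, upstream_ids}{character vectors of the bottom and top layers.}
#'     \item{params}{generating parameters.}
#'   }
#' @examples
#' g <- sim_regulatory_graph(n_levels = 3, nodes_per_level = 5, seed = 1)
#' g$edges
#' @export
sim_regulatory_graph <- function(n_levels, nodes_per_level,
                                 n_noise_edges = 0, seed = 1) {
  n_levels <- assert_count(n_levels, "n_levels", min = 1L)
  nodes_per_level <- assert_count(nodes_per_level, "nodes_per_level", min = 1L)
  n_noise_edges <- assert_count(n_noise_edges, "n_noise_edges")

  relations <- c("affected", "activated", "inhibited")
  layer_ids <- function(lv) {
    if (lv == 0) sprintf("DEG%03d", seq_len(nodes_per_level))
    else sprintf("R%d_%03d", lv, seq_len(nodes_per_level))
  }

  with_seed(seed, {
    truth <- tibble(
      node = unlist(lapply(0:n_levels, layer_ids)),
      level = rep(0:n_levels, each = nodes_per_level)
    )

    edges <- purrr::map_dfr(seq_len(n_levels), function(lv) {
      src <- layer_ids(lv)
      below <- layer_ids(lv - 1L)
      # every upper node regulates >= 1 node of the layer directly below
      purrr::map_dfr(src, function(s) {
        n_tgt <- 1L + rbinom(1L, min(2L, length(below) - 1L), 0.5)
        tibble(source = s, target = sample(below, min(n_tgt, length(below))))
      })
    })

    if (n_noise_edges > 0) {
      lvl <- setNames(truth$level, truth$node)
      pool_src <- truth$node[truth$level >= 1]
      got <- 0L
      tries <- 0L
      noise <- list()
      existing <- paste(edges$source, edges$target)
      while (got < n_noise_edges && tries < 200L * n_noise_edges) {
        tries <- tries + 1L
        s <- sample(pool_src, 1L)
        ok_tgt <- truth$node[truth$level >= lvl[[s]] - 1L & truth$node != s]
        if (length(ok_tgt) == 0) next
        t <- sample(ok_tgt, 1L)
        key <- paste(s, t)
        if (key %in% existing) next
        existing <- c(existing, key)
        noise[[length(noise) + 1L]] <- tibble(source = s, target = t)
        got <- got + 1L
      }
      if (got < n_noise_edges) {
        warn(sprintf("only %d of %d requested noise edges could be placed", got, n_noise_edges))
      }
      edges <- bind_rows(edges, bind_rows(noise))
    }

    edges$relation <- sample(relations, nrow(edges), replace = TRUE)
    edges <- arrange(edges, .data$source, .data$target)

    structure(list(
      edges = edges,
      truth = truth,
      deg_ids = layer_ids(0L),
      upstream_ids = layer_ids(n_levels),
      params = list(n_levels = n_levels, nodes_per_level = nodes_per_level,
                    n_noise_edges = n_noise_edges, seed = seed)
    ), class = "reggraph_sim")
  })
}

#' @export
print.reggraph_sim <- function(x, ...) {
  cat(sprintf("<reggraph_sim> %d levels x %d nodes, %d edges (%d noise requested), seed %d\n",
              x$params$n_levels, x$params$nodes_per_level, nrow(x$edges),
              x$params$n_noise_edges, x$params$seed))
  invisible(x)
}
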