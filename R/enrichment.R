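#' Hypergeometric over-representation of a DEG list in one gene set
#'
#' Computes the overlap `k` between a DEG list (size `n`) and a gene set
#' (size `K` after restriction to the universe of `N` genes), the one-sided
#' upper-tail hypergeometric probability of observing at least `k` overlaps,
#' and the affected proportion `k / K`.
#'
#' @param deg_list Character vector of DEG identifiers; must be a subset of
#'   `universe`.
#' @param gene_set Character vector of set members, or a one-row slice of a
#'   `geneset_collection`. Members outside the universe are dropped (a note
#'   reports how many).
#' @param universe Character vector: the gene background (all genes on the
#'   array).
#' @param set_id Optional label carried into the output.
#' @return One-row tibble: `set_id`, `K`, `n`, `N`, `k`, `p_hyper`,
#'   `affected_proportion`.
#' @examples
#' overlap_test(c("a", "b"), c("b", "c"), letters[1:10])
#' @export
overlap_test <- function(deg_list, gene_set, universe, set_id = NA_character_) {
  if (length(universe) == 0) {
    abort("`universe` must be non-empty.", class = "ductnet_input_error")
  }
  universe <- unique(as.character(universe))
  deg_list <- unique(as.character(deg_list))
  members <- if (is.data.frame(gene_set)) {
    if (!is.na(gene_set$set_id[1])) set_id <- gene_set$set_id[1]
    unique(as.character(gene_set$genes[[1]]))
  } else {
    unique(as.character(gene_set))
  }

  stray <- setdiff(deg_list, universe)
  if (length(stray) > 0) {
    abort(sprintf("DEG gene(s) outside the universe: %s",
                  paste(head(stray, 5), collapse = ", ")),
          class = "ductnet_input_error")
  }
  dropped <- sum(!(members %in% universe))
  if (dropped > 0) {
    inform(sprintf("%d set member(s) absent from the universe were dropped", dropped))
  }
  members <- intersect(members, universe)

  N <- length(universe)
  K <- length(members)
  n <- length(deg_list)
  k <- length(intersect(members, deg_list))
  p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)

  tibble(set_id = set_id, K = K, n = n, N = N, k = k,
         p_hyper = p,
         affected_proportion = if (K == 0) NA_real_ else k / K)
}

#' Proportion of a gene set affected by the perturbation
#'
#' The fraction of set members that appear in the DEG list:
#' `|members intersect deg_list| / |members|`.
#'
#' @param gene_set Character vector of set members (non-empty), or a one-row
#'   slice of a `geneset_collection`.
#' @param deg_list Character vector of DEG identifiers.
#' @return A single fraction in \[0, 1\].
#' @examples
#' affected_proportion(c("a", "b", "c", "d"), c("a", "x"))
#' @export
affected_proportion <- function(gene_set, deg_list) {
  members <- if (is.data.frame(gene_set)) unique(as.character(gene_set$genes[[1]]))
             else unique(as.character(gene_set))
  if (length(members) == 0) {
    abort("`gene_set` must be non-empty.", class = "ductnet_input_error")
  }
  length(intersect(members, unique(as.character(deg_list)))) / length(members)
}

#' Rank a gene-set collection by over-representation
#'
#' Runs [overlap_test()] on every set of a collection and orders the rows by
#' ascending hypergeometric p-value, ties broken by descending affected
#' proportion and then lexicographic `set_id`.
#'
#' @param collection A `geneset_collection` tibble (columns `set_id`, `name`,
#'   `genes` list-column), e.g. from [sim_geneset_collection()] or
#'   [read_gmt()].
#' @param deg_list,universe As in [overlap_test()].
#' @param top Number of top rows to return (default all).
#' @param adjust If `TRUE`, add a BH-adjusted column `p_adj` across the
#'   collection (off by default; raw overlap p-values are reported).
#' @return Tibble of class `enrichment_table`, one row per set (truncated to
#'   `top`), ordered best-first.
#' @examples
#' u <- sprintf("G%03d", 1:50)
#' coll <- sim_geneset_collection(u, 4, c(5, 10), seed = 1)
#' rank_sets(coll, deg_list = u[1:10], universe = u, top = 2)
#' @export
rank_sets <- function(collection, deg_list, universe, top = Inf, adjust = FALSE) {
  if (nrow(collection) == 0) {
    abort("`collection` must contain at least one set.", class = "ductnet_input_error")
  }
  rows <- purrr::map_dfr(seq_len(nrow(collection)), function(i) {
    r <- overlap_test(deg_list, collection$genes[[i]], universe,
                      set_id = collection$set_id[i])
    r$name <- collection$name[i] %||% NA_character_
    r
  })
  if (adjust) rows$p_adj <- bh_adjust(rows$p_hyper)
  rows <- arrange(rows, .data$p_hyper, desc(.data$affected_proportion), .data$set_id)
  out <- head(rows, top)
  class(out) <- c("enrichment_table", class(out))
  out
}

#' @method glance enrichment_table
#' @export
glance.enrichment_table <- function(x, ...) {
  tibble(n_sets = nrow(x), best_set = x$set_id[1], best_p = x$p_hyper[1],
         n_nominal = sum(x$p_hyper < 0.05))
}

#' @method tidy enrichment_table
#' @export
tidy.enrichment_table <- function(x, ...) as_tibble(unclass(x))
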