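#' Simulate a gene-set collection, optionally with a planted enriched set
#'
#' Draws `n_sets` random subsets of a gene universe, emulating a Biological
#' Process / pathway collection. One set can be planted to overlap a supplied
#' DEG list by a requested fraction of its size, so downstream enrichment has
#' a known positive.
#'
#' @param universe Character vector of gene identifiers (non-empty).
#' @param n_sets Number of sets.
#' @param size_range Length-2 integer vector `c(min, max)`; every set size is
#'   drawn uniformly in this range (`max <= length(universe)`).
#' @param planted Optional list with elements `set_index` (which set to
#'   plant), `fraction` (target overlap fraction of the set size, in \[0,1\])
#'   and `deg_list` (character vector the overlap is planted against).
#' @param seed Integer seed.
#'
#' @return A tibble of class `geneset_collection` with columns `set_id`,
#'   `name`, `genes` (list-column of character vectors).
#' @examples
#' sets <- sim_geneset_collection(sprintf("G%03d", 1:100), n_sets = 5,
#'                                size_range = c(10, 20), seed = 1)
#' sets
#' @export
sim_geneset_collection <- function(universe, n_sets, size_range,
                                   planted = NULL, seed = 1) {
  if (length(universe) == 0) {
    abort("`universe` must be a non-empty gene list.", class = "ductnet_input_error")
  }
  universe <- unique(as.character(universe))
  n_sets <- assert_count(n_sets, "n_sets", min = 1L)
  if (length(size_range) != 2L || any(size_range < 1) ||
      size_range[2] < size_range[1]) {
    abort("`size_range` must be c(min, max) with 1 <= min <= max.",
          class = "ductnet_input_error")
  }
  if (size_range[2] > length(universe)) {
    abort("maximum set size exceeds the universe size.",
          class = "ductnet_input_error")
  }

  with_seed(seed, {
    size_pool <- seq(size_range[1], size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_sets, replace = TRUE)]
    genes <- map(sizes, function(s) sort(sample(universe, s)))

    if (!is.null(planted)) {
      i <- assert_count(planted$set_index, "planted$set_index", min = 1L)
      if (i > n_sets) {
        abort("`planted$set_index` exceeds `n_sets`.", class = "ductnet_input_error")
      }
      frac <- assert_scalar_number(planted$fraction, "planted$fraction", 0, 1)
      deg <- intersect(as.character(planted$deg_list), universe)
      s <- sizes[i]
      k <- round(frac * s)
      if (k > length(deg)) {
        abort("DEG list too small to plant the requested overlap.",
              class = "ductnet_input_error")
      }
      non_deg <- setdiff(universe, deg)
      if (s - k > length(non_deg)) {
        abort("universe too small outside the DEG list to plant the requested overlap.",
              class = "ductnet_input_error")
      }
      genes[[i]] <- sort(c(sample(deg, k), sample(non_deg, s - k)))
    }

    out <- tibble(
      set_id = sprintf("SET%03d", seq_len(n_sets)),
      name = sprintf("synthetic gene set %d", seq_len(n_sets)),
      genes = genes
    )
    class(out) <- c("geneset_collection", class(out))
    out
  })
}
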