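#' Simulate a two-group expression matrix with planted differential expression
#'
#' Generates an RMA-like two-group microarray experiment: per-gene log2
#' baselines are drawn uniformly in \[6, 12\] log2 units, every measurement
#' adds Gaussian noise on the log2 scale, and a chosen subset of genes is
#' shifted by `log2(effect)` in group B (direction up or down at random).
#' Values are returned on the linear intensity scale.
#'
#' @param n_genes Number of genes (rows).
#' @param n_de Number of differentially expressed genes to plant
#'   (`n_de <= n_genes`).
#' @param effect Linear fold-change magnitude of planted genes (> 1).
#' @param n_per_group Samples per group (>= 2); the default matches a
#'   triplicate design.
#' @param noise_sd Standard deviation of measurement noise on the log2 scale.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#'
#' @return A list of class `expression_sim` with elements
#'   \describe{
#'     \item{expr}{tibble, `gene_id` plus one column per sample (linear scale).}
#'     \item{groups}{tibble with columns `sample`, `group` (levels "A", "B").}
#'     \item{truth}{tibble `gene_id`, `is_de`, `direction` ("up"/"down"/"none"),
#'       `effect` (planted linear ratio, 1 for null genes).}
#'     \item{params}{the generating parameters, including the seed.}
#'   }
#' @examples
#' sim <- sim_expression(n_genes = 50, n_de = 5, effect = 4, seed = 1)
#' head(sim$expr)
#' @export
sim_expression <- function(n_genes, n_de, effect = 4, n_per_group = 3,
                           noise_sd = 0.25, seed = 1) {
  n_genes <- assert_count(n_genes, "n_genes", min = 1L)
  n_de <- assert_count(n_de, "n_de")
  n_per_group <- assert_count(n_per_group, "n_per_group", min = 2L)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  if (n_de > n_genes) {
    abort("`n_de` cannot exceed `n_genes`.", class = "ductnet_input_error")
  }
  assert_scalar_number(effect, "effect", min = 1, strict_min = TRUE)

  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  samples <- c(sprintf("A%d", seq_len(n_per_group)),
               sprintf("B%d", seq_len(n_per_group)))
  group <- rep(c("A", "B"), each = n_per_group)

  with_seed(seed, {
    baseline <- runif(n_genes, 6, 12)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    dir_up <- rbinom(length(de_idx), 1, 0.5) == 1
    shift <- numeric(n_genes)
    shift[de_idx] <- ifelse(dir_up, log2(effect), -log2(effect))

    log2_mat <- matrix(baseline, n_genes, 2L * n_per_group) +
      matrix(rnorm(n_genes * 2L * n_per_group, sd = noise_sd), n_genes)
    log2_mat[, group == "B"] <- log2_mat[, group == "B"] + shift
    lin <- 2^log2_mat
    colnames(lin) <- samples

    direction <- rep("none", n_genes)
    direction[de_idx] <- ifelse(dir_up, "up", "down")

    structure(list(
      expr = bind_cols(tibble(gene_id = gene_ids), as_tibble(lin)),
      groups = tibble(sample = samples, group = group),
      truth = tibble(
        gene_id = gene_ids,
        is_de = seq_len(n_genes) %in% de_idx,
        direction = direction,
        effect = ifelse(direction == "none", 1, effect)
      ),
      params = list(n_genes = n_genes, n_de = n_de, effect = effect,
                    n_per_group = n_per_group, noise_sd = noise_sd, seed = seed)
    ), class = "expression_sim")
  })
}

#' @export
print.expression_sim <- function(x, ...) {
  cat(sprintf(
    "<expression_sim> %d genes x %d samples (%d per group), %d planted DE at fold %.3g, log2 noise sd %.3g, seed %d\n",
    x$params$n_genes, 2L * x$params$n_per_group, x$params$n_per_group,
    x$params$n_de, x$params$effect, x$params$noise_sd, x$params$seed))
  invisible(x)
}
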