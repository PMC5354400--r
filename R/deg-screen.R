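#' Per-gene two-group statistics on an expression matrix
#'
#' Computes, for every gene, the linear-scale group means, the folded
#' variation factor `max(r, 1/r)` with `r = mean_B / mean_A`, the direction
#' of change in group B relative to group A, and a raw p-value from a
#' two-sample t-test on log2 intensities. The default pools the variances
#' (Student), the same unpaired test the study applies to every group
#' comparison; with triplicates the pooled test keeps its 4 degrees of
#' freedom, whereas the Welch variant (available via `var_equal = FALSE`)
#' re-estimates them per gene, which at n = 3 is so unstable that it costs
#' much of the screen's sensitivity.
#'
#' @param expr Tibble or data frame: `gene_id` column plus one numeric column
#'   per sample. Linear-scale intensities unless `log2_input = TRUE`.
#' @param groups Data frame with columns `sample`, `group`; `group` must take
#'   exactly two values, compared as A (reference) vs B.
#' @param log2_input If `TRUE`, `expr` holds log2 intensities and is
#'   exponentiated internally for the means/ratio.
#' @param var_equal Pool the within-group variances (default) or use the
#'   Welch unequal-variance test.
#'
#' @return Tibble: `gene_id`, `mean_a`, `mean_b`, `variation_factor`,
#'   `direction` ("up"/"down"/"none", B relative to A), `p_raw`.
#'
#' @details Degenerate genes with zero variance in both groups get
#'   `p_raw = 1` when the group means are equal; if the means differ with
#'   zero pooled variance, `p_raw = 0` is assigned with a warning, so a
#'   pathological gene cannot poison a whole screen with NaN.
#' @examples
#' sim <- sim_expression(20, 2, effect = 4, seed = 1)
#' gene_stats(sim$expr, sim$groups)
#' @export
gene_stats <- function(expr, groups, log2_input = FALSE, var_equal = TRUE) {
  if (!"gene_id" %in% names(expr)) {
    abort("`expr` must contain a `gene_id` column.", class = "ductnet_input_error")
  }
  if (!all(c("sample", "group") %in% names(groups))) {
    abort("`groups` must have columns `sample` and `group`.",
          class = "ductnet_input_error")
  }
  lv <- sort(unique(as.character(groups$group)))
  if (length(lv) != 2L) {
    abort("`groups$group` must take exactly two values.", class = "ductnet_input_error")
  }
  sa <- as.character(groups$sample[groups$group == lv[1]])
  sb <- as.character(groups$sample[groups$group == lv[2]])
  if (length(sa) < 2L || length(sb) < 2L) {
    abort("each group needs at least two samples.", class = "ductnet_input_error")
  }
  missing_cols <- setdiff(c(sa, sb), names(expr))
  if (length(missing_cols) > 0) {
    abort(sprintf("samples absent from `expr`: %s", paste(missing_cols, collapse = ", ")),
          class = "ductnet_input_error")
  }

  ma <- as.matrix(expr[, sa])
  mb <- as.matrix(expr[, sb])
  if (anyNA(ma) || anyNA(mb)) {
    abort("expression values must not be missing.", class = "ductnet_input_error")
  }
  if (log2_input) {
    la <- ma; lb <- mb
    ma <- 2^ma; mb <- 2^mb
  } else {
    if (any(ma <= 0) || any(mb <= 0)) {
      abort("linear-scale intensities must all be positive.",
            class = "ductnet_input_error")
    }
    la <- log2(ma); lb <- log2(mb)
  }

  na <- ncol(la); nb <- ncol(lb)
  mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
  mla <- rowMeans(la); mlb <- rowMeans(lb)
  va <- rowSums((la - mla)^2) / (na - 1)
  vb <- rowSums((lb - mlb)^2) / (nb - 1)

  if (var_equal) {
    pooled <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- pooled * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(se2))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (mla - mlb) / sqrt(se2)
  p_raw <- 2 * pt(-abs(tstat), df)

  degenerate <- se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & (mla == mlb)
    p_raw[eq] <- 1
    if (any(degenerate & !eq)) {
      warn(sprintf("%d gene(s) have zero within-group variance but different means; p_raw set to 0",
                   sum(degenerate & !eq)))
      p_raw[degenerate & !eq] <- 0
    }
  }

  r <- mean_b / mean_a
  tibble(
    gene_id = as.character(expr$gene_id),
    mean_a = mean_a,
    mean_b = mean_b,
    variation_factor = pmax(r, 1 / r),
    direction = case_when(r > 1 ~ "up", r < 1 ~ "down", TRUE ~ "none"),
    p_raw = p_raw
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate control by the step-up rule: order the p-values
#' ascending, set `q_(i) = min_{j >= i} p_(j) * m / j` capped at 1, and
#' return the adjusted values in the original order.
#'
#' @param p Numeric vector of p-values, all in \[0, 1\].
#' @return Numeric vector of adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04, 0.80))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must all lie in [0, 1].", class = "ductnet_input_error")
  }
  p.adjust(p, method = "BH")
}

#' Flag differentially expressed genes by the dual criterion
#'
#' Applies the screen's dual rule to per-gene statistics: a gene is a DEG
#' when its folded variation factor is at least `fc_threshold` (non-strict,
#' default 2.3) and its BH-adjusted p-value is strictly below `alpha`
#' (default 0.05).
#'
#' @param stats Tibble from [gene_stats()].
#' @param fc_threshold Folded linear-ratio threshold (>= comparison).
#' @param alpha Adjusted-p significance level (< comparison).
#' @return A tibble of class `deg_table`: the input columns plus `p_adj` and
#'   `is_deg`, with the thresholds stored as attributes.
#' @examples
#' sim <- sim_expression(100, 10, effect = 4, seed = 1)
#' degs <- select_degs(gene_stats(sim$expr, sim$groups))
#' sum(degs$is_deg)
#' @export
select_degs <- function(stats, fc_threshold = 2.3, alpha = 0.05) {
  needed <- c("gene_id", "variation_factor", "p_raw")
  if (!all(needed %in% names(stats))) {
    abort(sprintf("`stats` must contain columns: %s", paste(needed, collapse = ", ")),
          class = "ductnet_input_error")
  }
  assert_scalar_number(fc_threshold, "fc_threshold", min = 1)
  assert_scalar_number(alpha, "alpha", 0, 1)

  out <- as_tibble(stats)
  out$p_adj <- bh_adjust(out$p_raw)
  out$is_deg <- out$variation_factor >= fc_threshold & out$p_adj < alpha
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("deg_table", class(out))
  out
}

#' Extract the ordered DEG identifier set from a `deg_table`
#' @param deg_table Result of [select_degs()].
#' @return Sorted character vector of DEG gene ids.
#' @export
deg_ids <- function(deg_table) {
  sort(deg_table$gene_id[deg_table$is_deg])
}

#' @method glance deg_table
#' @export
glance.deg_table <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_deg = sum(x$is_deg),
    n_up = sum(x$is_deg & x$direction == "up"),
    n_down = sum(x$is_deg & x$direction == "down"),
    fc_threshold = attr(x, "fc_threshold"),
    alpha = attr(x, "alpha")
  )
}

#' @method tidy deg_table
#' @export
tidy.deg_table <- function(x, ...) {
  as_tibble(unclass(x))
}
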