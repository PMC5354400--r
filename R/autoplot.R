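# ggplot2 views of the main result types.

#' Volcano-style view of a DEG screen
#'
#' Folded variation factor (log2 scale) against -log10 adjusted p, with the
#' dual-criterion thresholds drawn and DEGs highlighted.
#'
#' @param object A `deg_table` from [select_degs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(object, ...) {
  fc <- attr(object, "fc_threshold")
  alpha <- attr(object, "alpha")
  df <- tidy(object) |>
    mutate(signed_log2_vf = ifelse(.data$direction == "down", -1, 1) *
             log2(.data$variation_factor))
  ggplot2::ggplot(df, ggplot2::aes(.data$signed_log2_vf, -log10(.data$p_adj),
                                   colour = .data$is_deg)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-log2(fc), log2(fc)), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "signed log2 variation factor", y = "-log10 adjusted p",
                  colour = "DEG") +
    ggplot2::theme_minimal()
}

#' Bar view of gene-set over-representation
#'
#' @param object An `enrichment_table` from [rank_sets()].
#' @param top How many sets to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, top = 10, ...) {
  df <- head(tidy(object), top)
  df$set_id <- factor(df$set_id, levels = rev(df$set_id))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p_hyper), .data$set_id,
                                   fill = .data$affected_proportion)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 overlap p", y = NULL, fill = "affected\nproportion") +
    ggplot2::theme_minimal()
}

#' Layered view of a hierarchical regulator network
#'
#' Nodes on horizontal layers by level (DEGs at the bottom), retained
#' regulatory edges drawn between layers.
#'
#' @param object A `hier_network` from [build_hierarchy()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hier_network
#' @export
autoplot.hier_network <- function(object, ...) {
  lv <- object$levels
  if (nrow(lv) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::annotate("text", 0, 0, label = "empty network"))
  }
  lv <- lv |>
    group_by(.data$level) |>
    mutate(x = (row_number() - 1) - (n() - 1) / 2) |>
    ungroup()
  ed <- object$edges |>
    left_join(lv |> select(node, x, level), by = c(source = "node")) |>
    rename(x0 = "x", y0 = "level") |>
    left_join(lv |> select(node, x, level), by = c(target = "node")) |>
    rename(x1 = "x", y1 = "level")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       colour = .data$relation),
                          alpha = 0.5) +
    ggplot2::geom_point(data = lv, ggplot2::aes(.data$x, .data$level), size = 2) +
    ggplot2::geom_text(data = lv, ggplot2::aes(.data$x, .data$level, label = .data$node),
                       vjust = -1, size = 2.5) +
    ggplot2::scale_y_continuous(breaks = unique(lv$level)) +
    ggplot2::labs(x = NULL, y = "level (0 = DEGs)",
                  title = object$function_label, colour = "relation") +
    ggplot2::theme_minimal()
}

#' Image view of a quantified whole mount
#'
#' Skeleton overlay (white) with branch clusters (green) and endpoints
#' (red) over the source response.
#'
#' @param object A `duct_quant` from [quantify_wholemount()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot duct_quant
#' @export
autoplot.duct_quant <- function(object, ...) {
  sk <- object$skeleton
  nb <- matrix(0, nrow(sk), ncol(sk))
  for (dr in -1:1) for (dc in -1:1) if (dr || dc) nb <- nb + shift_mat(sk * 1, dr, dc)
  df <- expand.grid(row = seq_len(nrow(sk)), col = seq_len(ncol(sk)))
  df$response <- as.vector(object$response)
  df$class <- "background"
  df$class[as.vector(sk)] <- "skeleton"
  df$class[as.vector(sk & nb >= 3)] <- "branch"
  df$class[as.vector(sk & nb <= 1)] <- "sprout"
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$response), fill = "grey20") +
    ggplot2::geom_point(data = df[df$class != "background", ],
                        ggplot2::aes(colour = .data$class), size = 0.3) +
    ggplot2::scale_colour_manual(values = c(skeleton = "white", branch = "green3",
                                            sprout = "red")) +
    ggplot2::scale_alpha(range = c(0, 1), guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_void()
}
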