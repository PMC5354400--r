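# Closed-form quantifications shared across the figures: doubling time
# under constant exponential growth, delta-delta-Ct relative expression,
# and the unpaired Student t-test contract used by every group comparison.

#' Doubling time under constant exponential growth
#'
#' `DT = t * ln(2) / ln(nt / n0)` from two viable-cell measurements.
#'
#' @param n0 Signal at t = 0 (> 0).
#' @param nt Signal at time `t` (> 0).
#' @param t Elapsed time, hours (> 0).
#' @return One-row tibble: `doubling_time_h`, `declining` (TRUE when
#'   `nt < n0`; the doubling time is then negative).
#' @examples
#' doubling_time(100, 800, 72)  # three doublings in 72 h -> 24 h
#' @export
doubling_time <- function(n0, nt, t) {
  assert_scalar_number(n0, "n0", min = 0, strict_min = TRUE)
  assert_scalar_number(nt, "nt", min = 0, strict_min = TRUE)
  assert_scalar_number(t, "t", min = 0, strict_min = TRUE)
  if (nt == n0) {
    abort("no growth: nt equals n0, doubling time is undefined.",
          class = "ductnet_no_growth_error")
  }
  dt <- t * log(2) / log(nt / n0)
  if (nt < n0) {
    warn("declining culture: negative doubling time reported")
  }
  tibble(doubling_time_h = dt, declining = nt < n0)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample `dCt = ct_target - ct_reference`; then
#' `ddCt = dCt_condition - dCt_control` and the linear fold change is
#' `2^(-ddCt)` relative to the housekeeping reference.
#'
#' @param condition,control Lists (or one-row data frames) with elements
#'   `ct_target` and `ct_reference`, finite positive cycle thresholds.
#' @return One-row tibble: `dct_condition`, `dct_control`, `ddct`, `fold`.
#' @examples
#' ddct_fold(list(ct_target = 20, ct_reference = 15),
#'           list(ct_target = 22, ct_reference = 15))
#' @export
ddct_fold <- function(condition, control) {
  grab <- function(x, lab) {
    for (f in c("ct_target", "ct_reference")) {
      v <- x[[f]]
      if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
        abort(sprintf("`%s$%s` must be a finite positive Ct value.", lab, f),
              class = "ductnet_input_error")
      }
    }
    x[["ct_target"]] - x[["ct_reference"]]
  }
  dct_cond <- grab(condition, "condition")
  dct_ctrl <- grab(control, "control")
  ddct <- dct_cond - dct_ctrl
  tibble(dct_condition = dct_cond, dct_control = dct_ctrl,
         ddct = ddct, fold = 2^(-ddct))
}

#' Unpaired two-sample Student t-test
#'
#' Equal-variance (pooled SD) by default, matching the named test; Welch is
#' available behind `var_equal = FALSE`. Significance uses a strict
#' comparison, `p < alpha`.
#'
#' @param a,b Numeric vectors, each with at least two values.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @return One-row tibble: `t`, `df`, `p`, `significant`, `mean_a`,
#'   `mean_b`. `t` carries the sign of `mean(a) - mean(b)`.
#' @examples
#' unpaired_t(c(1, 2, 3), c(4, 5, 6))
#' @export
unpaired_t <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("both samples need at least two values.", class = "ductnet_input_error")
  }
  if (anyNA(a) || anyNA(b)) {
    abort("samples must not contain missing values.", class = "ductnet_input_error")
  }
  assert_scalar_number(alpha, "alpha", 0, 1)
  if (sd(a) == 0 && sd(b) == 0) {
    # degenerate: no within-group variability
    t_stat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    p <- if (mean(a) == mean(b)) 1 else 0
    df <- length(a) + length(b) - 2
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  tibble(t = t_stat, df = df, p = p, significant = p < alpha,
         mean_a = mean(a), mean_b = mean(b))
}
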