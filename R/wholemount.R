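# Whole-mount ductal tree quantification: vesselness enhancement,
# hard-threshold segmentation, topology-preserving thinning, and skeleton
# morphometry.

# out[r, c] = m[r + dr, c + dc], zero-padded
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  r1 <- max(1, 1 - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1, 1 - dc); c2 <- min(nc, nc - dc)
  if (r1 <= r2 && c1 <= c2) {
    out[r1:r2, c1:c2] <- m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  }
  out
}

# 8-connected component labels (EBImage::bwlabel is 4-connected)
label8 <- function(mask) {
  mask <- mask != 0
  idx <- which(mask)
  if (length(idx) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  id_of <- match(seq_along(mask), idx)  # linear index -> vertex id
  edges <- list()
  nr <- nrow(mask)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    both <- mask & (shift_mat(mask, off[1], off[2]) > 0)
    from <- which(both)
    if (length(from)) {
      to <- from + off[1] + off[2] * nr
      edges[[length(edges) + 1L]] <- cbind(id_of[from], id_of[to])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[idx] <- as.integer(comp)
  lab
}

#' Construct a whole-mount image object
#'
#' @param pixels Numeric matrix of grayscale values; rescaled to \[0,1\] if
#'   outside that range.
#' @param pixel_size Physical pixel size, mm/px.
#' @param polarity `"ducts_dark"` (stained whole mounts) or `"ducts_bright"`.
#' @return List of class `wholemount_image`.
#' @export
wm_image <- function(pixels, pixel_size = 1, polarity = c("ducts_dark", "ducts_bright")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(!is.finite(pixels))) {
    abort("`pixels` must be a finite numeric matrix.", class = "ductnet_input_error")
  }
  assert_scalar_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1) {
    pixels <- if (diff(rng) > 0) (pixels - rng[1]) / diff(rng) else pixels * 0
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, polarity = polarity),
            class = "wholemount_image")
}

gaussian_hessian <- function(img, sigma) {
  radius <- max(2L, ceiling(3 * sigma))
  radius <- min(radius, (min(dim(img)) - 1L) %/% 2L)  # kernel must fit the image
  x <- (-radius):radius
  g <- dnorm(x, sd = sigma); g <- g / sum(g)
  dg <- (-x / sigma^2) * g
  ddg <- ((x^2 - sigma^2) / sigma^4) * g
  ddg <- ddg - mean(ddg)   # zero DC response despite kernel truncation
  f2 <- function(k) EBImage::filter2(img, k, boundary = "replicate")
  # rows = y, cols = x; scale-normalized second derivatives (x sigma^2)
  list(
    hxx = sigma^2 * f2(outer(g, ddg)),
    hyy = sigma^2 * f2(outer(ddg, g)),
    hxy = sigma^2 * f2(outer(dg, dg))
  )
}

#' Multiscale Frangi vesselness enhancement
#'
#' Ridge-likeness from the eigenvalues of the scale-normalized Gaussian
#' Hessian. At each scale sigma the Hessian is computed with
#' Gaussian-derivative filtering and multiplied by sigma^2; with eigenvalues
#' ordered `|lambda1| <= |lambda2|`, the response is 0 where
#' `lambda2 > 0` (bright-ridge convention; dark-duct images are inverted
#' first) and otherwise
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with blobness
#' `Rb = lambda1 / lambda2` and structureness `S = sqrt(lambda1^2 +
#' lambda2^2)`. The final response is the pixel-wise maximum over scales.
#'
#' @param image A `wholemount_image`, or a numeric matrix in \[0,1\]
#'   combined with the `polarity` argument.
#' @param sigmas Strictly increasing Gaussian scales in px; default a
#'   7-point geometric series from 1 to 8 px.
#' @param beta Blobness sensitivity (> 0), default 0.5.
#' @param c Structureness sensitivity: a positive number, or the default
#'   policy `"half_max_hessian_norm"` (half the maximum Hessian Frobenius
#'   norm, per scale).
#' @param polarity Used when `image` is a plain matrix.
#' @return Numeric matrix in \[0,1\] (same size as the input).
#' @examples
#' img <- matrix(1, 64, 64); img[30:34, ] <- 0   # dark horizontal duct
#' v <- frangi_vesselness(img, sigmas = c(1, 2, 4))
#' @export
frangi_vesselness <- function(image, sigmas = 2^seq(0, 3, length.out = 7),
                              beta = 0.5, c = "half_max_hessian_norm",
                              polarity = c("ducts_dark", "ducts_bright")) {
  if (inherits(image, "wholemount_image")) {
    img <- image$pixels
    polarity <- image$polarity
  } else {
    polarity <- match.arg(polarity)
    img <- image
  }
  if (length(sigmas) == 0) {
    abort("`sigmas` must contain at least one scale.", class = "ductnet_input_error")
  }
  if (any(sigmas <= 0) || is.unsorted(sigmas, strictly = TRUE)) {
    abort("`sigmas` must be strictly increasing and positive.",
          class = "ductnet_input_error")
  }
  assert_scalar_number(beta, "beta", min = 0, strict_min = TRUE)
  if (is.numeric(c)) assert_scalar_number(c, "c", min = 0, strict_min = TRUE)
  else if (!identical(c, "half_max_hessian_norm")) {
    abort("`c` must be a positive number or \"half_max_hessian_norm\".",
          class = "ductnet_input_error")
  }
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 1) {
    img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  }
  if (polarity == "ducts_dark") img <- 1 - img   # bright-ridge convention

  response <- matrix(0, nrow(img), ncol(img))
  for (sigma in sigmas) {
    h <- gaussian_hessian(img, sigma)
    hxx <- as.numeric(h$hxx); hyy <- as.numeric(h$hyy); hxy <- as.numeric(h$hxy)
    tmp <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    e1 <- (hxx + hyy) / 2 + tmp
    e2 <- (hxx + hyy) / 2 - tmp
    swap <- abs(e1) > abs(e2)
    l2 <- ifelse(swap, e1, e2)   # larger magnitude
    l1 <- ifelse(swap, e2, e1)
    s2 <- l1^2 + l2^2
    c_val <- if (is.numeric(c)) c else sqrt(max(s2)) / 2
    if (c_val < 1e-8) next   # flat field at this scale (numerical dust only)
    rb2 <- ifelse(l2 == 0, 0, (l1 / l2)^2)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * c_val^2)))
    v[l2 >= 0] <- 0
    response <- pmax(response, matrix(v, nrow(img)))
  }
  response
}

#' Hard-threshold segmentation of a vesselness response
#'
#' @param response Numeric matrix in \[0,1\] (a vesselness response, or any
#'   bright-foreground image).
#' @param policy Either a fixed threshold value in \[0,1\], or `"otsu"` to
#'   derive it from the response histogram.
#' @param min_object_px Connected components (8-connectivity) smaller than
#'   this are removed; default 50.
#' @return Logical matrix: `response >= threshold`, speckle removed. The
#'   threshold actually used is attached as attribute `threshold`.
#' @export
segment <- function(response, policy = "otsu", min_object_px = 50) {
  min_object_px <- assert_count(min_object_px, "min_object_px")
  if (is.numeric(policy)) {
    if (length(policy) != 1 || is.na(policy) || policy < 0 || policy > 1) {
      abort("a fixed threshold must lie in [0, 1].", class = "ductnet_input_error")
    }
    thr <- policy
  } else if (identical(policy, "otsu")) {
    thr <- EBImage::otsu(response, range = c(0, 1))
  } else {
    abort("`policy` must be a threshold value or \"otsu\".",
          class = "ductnet_input_error")
  }
  mask <- response >= thr
  if (min_object_px > 0 && any(mask)) {
    lab <- label8(mask)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_object_px)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  attr(mask, "threshold") <- as.numeric(thr)
  mask
}

guo_hall_pass <- function(m, odd) {
  p2 <- shift_mat(m, -1L, 0L); p3 <- shift_mat(m, -1L, 1L)
  p4 <- shift_mat(m, 0L, 1L);  p5 <- shift_mat(m, 1L, 1L)
  p6 <- shift_mat(m, 1L, 0L);  p7 <- shift_mat(m, 1L, -1L)
  p8 <- shift_mat(m, 0L, -1L); p9 <- shift_mat(m, -1L, -1L)
  C <- ((1 - p2) * pmax(p3, p4)) + ((1 - p4) * pmax(p5, p6)) +
    ((1 - p6) * pmax(p7, p8)) + ((1 - p8) * pmax(p9, p2))
  N1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
  N2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
  N <- pmin(N1, N2)
  m0 <- if (odd) pmax(pmax(p6, p7), 1 - p9) * p8 else pmax(pmax(p2, p3), 1 - p5) * p4
  del <- (m == 1) & (C == 1) & (N >= 2) & (N <= 3) & (m0 == 0)
  m[del] <- 0
  m
}

#' Topology-preserving skeletonization (Guo-Hall thinning)
#'
#' Iteratively peels the binary mask with the two-subiteration Guo-Hall
#' scheme until stable, yielding a 1-px-wide, 8-connected medial skeleton
#' with the same connected components and holes as the mask. A final cleanup
#' pass removes residual pixels of any 2x2 solid block whose deletion does
#' not change local connectivity.
#'
#' @param mask Logical (or 0/1) matrix. An empty mask yields an empty
#'   skeleton.
#' @return Logical matrix.
#' @export
skeletonize <- function(mask) {
  if (!is.matrix(mask)) {
    abort("`mask` must be a matrix.", class = "ductnet_input_error")
  }
  m <- (mask != 0) * 1
  if (!any(m == 1)) return(mask != 0 & FALSE)
  repeat {
    before <- m
    m <- guo_hall_pass(m, odd = TRUE)
    m <- guo_hall_pass(m, odd = FALSE)
    if (identical(m, before)) break
  }
  # cleanup: break residual 2x2 blocks (thick junctions can survive thinning)
  for (pass in 1:8) {
    blk <- m * shift_mat(m, 0L, 1L) * shift_mat(m, 1L, 0L) * shift_mat(m, 1L, 1L)
    if (!any(blk == 1)) break
    changed <- FALSE
    for (i in which(blk == 1)) {
      r <- ((i - 1) %% nrow(m)) + 1; cc <- ((i - 1) %/% nrow(m)) + 1
      for (off in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
        rr <- r + off[1]; c2 <- cc + off[2]
        if (m[rr, c2] == 1 && is_simple_pixel(m, rr, c2)) {
          m[rr, c2] <- 0
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) {
      # no block pixel is locally simple (dense junction): fall back to a
      # global test — delete a block pixel that keeps the component count
      n_comp <- max(label8(m == 1), 0L)
      for (i in which(blk == 1)) {
        r <- ((i - 1) %% nrow(m)) + 1; cc <- ((i - 1) %/% nrow(m)) + 1
        for (off in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
          rr <- r + off[1]; c2 <- cc + off[2]
          if (m[rr, c2] == 1) {
            m[rr, c2] <- 0
            if (max(label8(m == 1), 0L) == n_comp) { changed <- TRUE; break }
            m[rr, c2] <- 1
          }
        }
        if (changed) break
      }
      if (!changed) break
    }
  }
  m == 1
}

# a pixel is simple if removing it keeps its 8-neighborhood foreground
# connected and it is not an endpoint
is_simple_pixel <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  ring_off <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                   c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  vals <- vapply(ring_off, function(o) {
    rr <- r + o[1]; cc <- c + o[2]
    if (rr < 1 || rr > nr || cc < 1 || cc > nc) 0 else m[rr, cc]
  }, numeric(1))
  if (sum(vals) < 2) return(FALSE)
  # crossing number around the ring (p2 p3 p4 p5 p6 p7 p8 p9 order)
  transitions <- sum(vals == 0 & c(vals[-1], vals[1]) == 1)
  transitions == 1
}

#' Morphometry of a 1-px skeleton
#'
#' Endpoints (sprouts) are skeleton pixels with at most one 8-connected
#' skeleton neighbor; branch pixels have three or more, and 8-connected
#' clusters of branch pixels are merged and counted once (thinning leaves
#' adjacent junction pixels, which would otherwise inflate the branch
#' count). Extension length sums skeleton adjacencies: 1 per orthogonal
#' step, sqrt(2) per diagonal step. The longest shortest path through the
#' skeleton (its geodesic diameter) is reported alongside.
#'
#' @param skeleton Logical matrix from [skeletonize()]. A solid 2x2 block
#'   anywhere raises an error advising re-skeletonization.
#' @param pixel_size Optional mm/px; fills the `_mm` columns.
#' @param exclude_root If `TRUE`, `n_sprout` is additionally reported with
#'   one endpoint per connected component subtracted (`n_sprout_no_root`),
#'   for trees whose root entry point should not count as a sprout.
#' @return One-row tibble of class `duct_metrics`: `extension_px`,
#'   `extension_mm`, `n_branch`, `n_sprout`, `n_sprout_no_root`,
#'   `n_components`, `longest_path_px`, `longest_path_mm`.
#' @export
skeleton_metrics <- function(skeleton, pixel_size = NULL, exclude_root = FALSE) {
  if (!is.matrix(skeleton)) {
    abort("`skeleton` must be a matrix.", class = "ductnet_input_error")
  }
  sk <- (skeleton != 0) * 1
  if (!is.null(pixel_size)) assert_scalar_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)

  if (any(sk * shift_mat(sk, 0L, 1L) * shift_mat(sk, 1L, 0L) * shift_mat(sk, 1L, 1L) == 1)) {
    abort("skeleton contains a solid 2x2 block; re-skeletonize the mask first.",
          class = "ductnet_input_error")
  }

  n_orth <- sum(sk * shift_mat(sk, 0L, 1L)) + sum(sk * shift_mat(sk, 1L, 0L))
  n_diag <- sum(sk * shift_mat(sk, 1L, 1L)) + sum(sk * shift_mat(sk, 1L, -1L))
  extension_px <- n_orth + sqrt(2) * n_diag

  nb <- matrix(0, nrow(sk), ncol(sk))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr || dc) nb <- nb + shift_mat(sk, dr, dc)
  }
  n_sprout <- sum(sk == 1 & nb <= 1)
  branch_px <- sk == 1 & nb >= 3
  n_branch <- if (any(branch_px)) max(label8(branch_px)) else 0L

  lab <- label8(sk == 1)
  n_comp <- max(lab, 0L)
  longest <- skeleton_diameter_px(sk)

  out <- tibble(
    extension_px = extension_px,
    extension_mm = if (is.null(pixel_size)) NA_real_ else extension_px * pixel_size,
    n_branch = as.integer(n_branch),
    n_sprout = as.integer(n_sprout),
    n_sprout_no_root = if (exclude_root) as.integer(max(n_sprout - n_comp, 0L)) else NA_integer_,
    n_components = as.integer(n_comp),
    longest_path_px = longest,
    longest_path_mm = if (is.null(pixel_size)) NA_real_ else longest * pixel_size
  )
  class(out) <- c("duct_metrics", class(out))
  out
}

# geodesic diameter of the skeleton pixel graph (orthogonal steps weight 1,
# diagonal sqrt(2)); exact on trees via double sweep per component
skeleton_diameter_px <- function(sk) {
  idx <- which(sk == 1)
  if (length(idx) == 0) return(0)
  if (length(idx) == 1) return(0)
  nr <- nrow(sk)
  ed <- list(); w <- list()
  for (off in list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2)))) {
    both <- (sk == 1) & (shift_mat(sk, off[1], off[2]) == 1)
    from <- which(both)
    if (length(from)) {
      ed[[length(ed) + 1L]] <- cbind(match(from, idx), match(from + off[1] + off[2] * nr, idx))
      w[[length(w) + 1L]] <- rep(off[3], length(from))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ed)) {
    g <- igraph::add_edges(g, t(do.call(rbind, ed)))
    igraph::E(g)$weight <- unlist(w)
  }
  comp <- igraph::components(g)$membership
  best <- 0
  for (cp in unique(comp)) {
    vs <- which(comp == cp)
    d1 <- igraph::distances(g, v = vs[1], to = vs)
    far <- vs[which.max(d1)]
    d2 <- igraph::distances(g, v = far, to = vs)
    best <- max(best, max(d2[is.finite(d2)]))
  }
  best
}

#' Compare skeleton metrics between two groups of animals
#'
#' Unpaired two-sample Student t-test (equal variance) per metric, with
#' group means and standard errors.
#'
#' @param data Tibble: one row per animal/image, a grouping column plus
#'   numeric metric columns.
#' @param group Name of the grouping column (two levels, each with >= 2
#'   rows).
#' @param metrics Character vector of metric columns; default every numeric
#'   column except the grouping one.
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble of class `group_comparison`: one row per metric with
#'   `mean_<level>`, `sem_<level>`, `t`, `df`, `p`, `significant`.
#' @export
compare_groups <- function(data, group = "group", metrics = NULL, alpha = 0.05) {
  if (!group %in% names(data)) {
    abort(sprintf("grouping column `%s` not found.", group), class = "ductnet_input_error")
  }
  gl <- as.character(data[[group]])
  lv <- sort(unique(gl))
  if (length(lv) != 2L) {
    abort("exactly two groups are required.", class = "ductnet_input_error")
  }
  for (l in lv) {
    if (sum(gl == l) < 2L) {
      abort(sprintf("group `%s` has fewer than 2 animals.", l),
            class = "ductnet_input_error")
    }
  }
  if (is.null(metrics)) {
    metrics <- names(data)[vapply(data, is.numeric, logical(1))]
    metrics <- setdiff(metrics, group)
  }
  sem <- function(x) sd(x) / sqrt(length(x))
  out <- purrr::map_dfr(metrics, function(mcol) {
    a <- data[[mcol]][gl == lv[1]]
    b <- data[[mcol]][gl == lv[2]]
    tt <- unpaired_t(a, b, alpha = alpha)
    tibble(metric = mcol,
           mean_a = mean(a), sem_a = sem(a),
           mean_b = mean(b), sem_b = sem(b),
           t = tt$t, df = tt$df, p = tt$p, significant = tt$significant)
  })
  names(out)[names(out) == "mean_a"] <- paste0("mean_", lv[1])
  names(out)[names(out) == "sem_a"] <- paste0("sem_", lv[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", lv[2])
  names(out)[names(out) == "sem_b"] <- paste0("sem_", lv[2])
  attr(out, "groups") <- lv
  class(out) <- c("group_comparison", class(out))
  out
}

#' Quantify one whole-mount image end to end
#'
#' Chains vesselness enhancement, segmentation, skeletonization and
#' morphometry with the package defaults.
#'
#' @param image A `wholemount_image`, a `wholemount_sim`, or a numeric
#'   matrix (then `polarity`/`pixel_size` apply).
#' @param sigmas,beta,c Passed to [frangi_vesselness()].
#' @param policy,min_object_px Passed to [segment()].
#' @param pixel_size,polarity Used when `image` is a plain matrix.
#' @param exclude_root Passed to [skeleton_metrics()].
#' @return List of class `duct_quant`: `response`, `mask`, `skeleton`,
#'   `metrics` (a `duct_metrics` row).
#' @export
quantify_wholemount <- function(image, sigmas = 2^seq(0, 3, length.out = 7),
                                beta = 0.5, c = "half_max_hessian_norm",
                                policy = "otsu", min_object_px = 50,
                                pixel_size = 1, polarity = "ducts_dark",
                                exclude_root = FALSE) {
  if (inherits(image, "wholemount_sim")) {
    image <- wm_image(image$image, pixel_size = image$truth$pixel_size,
                      polarity = "ducts_dark")
  } else if (!inherits(image, "wholemount_image")) {
    image <- wm_image(image, pixel_size = pixel_size, polarity = polarity)
  }
  response <- frangi_vesselness(image, sigmas = sigmas, beta = beta, c = c)
  mask <- segment(response, policy = policy, min_object_px = min_object_px)
  skel <- skeletonize(mask)
  metrics <- skeleton_metrics(skel, pixel_size = image$pixel_size,
                              exclude_root = exclude_root)
  structure(list(response = response, mask = mask, skeleton = skel,
                 metrics = metrics, pixel_size = image$pixel_size),
            class = "duct_quant")
}

#' @export
print.duct_quant <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<duct_quant> extension %.1f px, %d branch point(s), %d sprout(s), %d component(s)\n",
              m$extension_px, m$n_branch, m$n_sprout, m$n_components))
  invisible(x)
}

#' @method tidy duct_quant
#' @export
tidy.duct_quant <- function(x, ...) x$metrics

#' Dice overlap between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#' @param a,b Logical matrices of equal size.
#' @return Scalar in \[0,1\].
#' @export
dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  if (!all(dim(a) == dim(b))) {
    abort("masks must have identical dimensions.", class = "ductnet_input_error")
  }
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
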