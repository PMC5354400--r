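#' Simulate a whole-mount image of a branching ductal tree
#'
#' Draws a random, open (self-avoiding) binary-branching tree from a root
#' near the bottom image edge and renders every segment as a tube with a
#' Gaussian cross-section, dark on a light background as in a carmine-stained
#' whole mount. Additive Gaussian noise is applied last. The returned truth
#' stores the full segment topology, so branch/tip counts and total
#' centerline length are recomputable by walking the stored tree.
#'
#' At each branch generation a node splits into two children with probability
#' `branch_prob`; child headings are the parent heading plus/minus
#' (30 degrees + uniform jitter). A candidate child that would run closer
#' than about one tube diameter to already-drawn ducts is re-drawn a few
#' times and dropped if it cannot be placed, which keeps the rendered tree
#' open so its topology is recoverable from the image.
#'
#' @param depth Number of branching generations (0 = a single root segment).
#' @param segment_length Length-2 numeric range (px) segment lengths are
#'   drawn from.
#' @param tube_width Tube width in px, interpreted as the full width at half
#'   maximum of the Gaussian cross-section (>= 1).
#' @param angle_jitter Half-width (degrees) of the uniform jitter added to
#'   the 30-degree branch half-angle.
#' @param branch_prob Probability that a node at each generation branches.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (image scale, \[0,1\]).
#' @param pixel_size Physical pixel size in mm/px.
#' @param size Length-2 integer image dimensions (rows, cols).
#' @param bg Background intensity; `contrast` is subtracted on the ducts.
#' @param contrast Peak intensity drop at duct centerlines.
#' @param seed Integer seed.
#'
#' @return A list of class `wholemount_sim`:
#'   \describe{
#'     \item{image}{numeric matrix in \[0,1\], ducts dark.}
#'     \item{centerline_mask, tube_mask}{logical matrices; the tube mask is
#'       the set of pixels within half a tube width of a centerline.}
#'     \item{truth}{list: `segments` tibble (id, parent, generation, x0, y0,
#'       x1, y1, length_px), `centerline` list of per-segment pixel
#'       coordinate matrices, `n_branch`, `n_tip`, `total_length_px`,
#'       `total_length_mm`, `tube_width`, `pixel_size`, `noise_sd`, `seed`,
#'       `clipped` flag.}
#'   }
#' @examples
#' sim <- sim_wholemount(depth = 2, seed = 1, size = c(192, 192))
#' sim$truth$n_branch
#' @export
sim_wholemount <- function(depth = 3, segment_length = c(25, 45),
                           tube_width = 5, angle_jitter = 10,
                           branch_prob = 0.9, noise_sd = 0,
                           pixel_size = 0.02, size = c(384, 384),
                           bg = 0.85, contrast = 0.6, seed = 1) {
  depth <- assert_count(depth, "depth")
  assert_scalar_number(tube_width, "tube_width", min = 1)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  assert_scalar_number(branch_prob, "branch_prob", 0, 1)
  if (length(segment_length) != 2L || any(segment_length <= 0) ||
      segment_length[2] < segment_length[1]) {
    abort("`segment_length` must be c(min, max) with 0 < min <= max.",
          class = "ductnet_input_error")
  }

  nr <- assert_count(size[1], "size[1]", min = 32L)
  nc <- assert_count(size[2], "size[2]", min = 32L)
  clearance <- 2 * tube_width + 2   # keeps rendered tubes from fusing
  excl_arc <- 2 * clearance   # arc length near a junction exempt from clearance

  seg_points <- function(x0, y0, x1, y1) {
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.4)))
    cbind(x = x0 + t * (x1 - x0), y = y0 + t * (y1 - y0), arc = t * len)
  }
  min_cross_dist <- function(p, q) {
    if (nrow(p) == 0 || nrow(q) == 0) return(Inf)
    # smallest pairwise distance between two point sets
    d2 <- outer(p[, 1], q[, 1], "-")^2 + outer(p[, 2], q[, 2], "-")^2
    sqrt(min(d2))
  }

  with_seed(seed, {
    segs <- list()   # each: list(id, parent, gen, x0, y0, x1, y1, pts)
    placeable <- function(pts, parent_id, sibling_id) {
      for (e in segs) {
        p <- pts
        q <- e$pts
        if (e$id == parent_id) {
          p <- p[p[, "arc"] > excl_arc, , drop = FALSE]
          q_arc_from_end <- max(q[, "arc"]) - q[, "arc"]
          q <- q[q_arc_from_end > excl_arc, , drop = FALSE]
        } else if (!is.na(sibling_id) && e$id == sibling_id) {
          p <- p[p[, "arc"] > excl_arc, , drop = FALSE]
          q <- q[q[, "arc"] > excl_arc, , drop = FALSE]
        }
        if (min_cross_dist(p, q) <= clearance) return(FALSE)
      }
      TRUE
    }

    add_segment <- function(x0, y0, theta, gen, parent_id, sibling_id) {
      for (try in 1:5) {
        th <- theta + if (try == 1) 0 else runif(1, -angle_jitter, angle_jitter)
        len <- runif(1, segment_length[1], segment_length[2])
        x1 <- x0 + len * cos(th * pi / 180)
        y1 <- y0 - len * sin(th * pi / 180)
        pts <- seg_points(x0, y0, x1, y1)
        if (placeable(pts, parent_id, sibling_id)) {
          id <- length(segs) + 1L
          segs[[id]] <<- list(id = id, parent = parent_id, gen = gen,
                              x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                              theta = th, pts = pts)
          return(id)
        }
      }
      NA_integer_
    }

    grow <- function(seg_id, gens_left) {
      if (gens_left == 0L) return(invisible())
      if (runif(1) > branch_prob) return(invisible())
      s <- segs[[seg_id]]
      half <- 30 + runif(1, -angle_jitter, angle_jitter)
      c1 <- add_segment(s$x1, s$y1, s$theta + half, s$gen + 1L, seg_id, NA_integer_)
      half2 <- 30 + runif(1, -angle_jitter, angle_jitter)
      c2 <- add_segment(s$x1, s$y1, s$theta - half2, s$gen + 1L, seg_id, c1)
      for (child in c(c1, c2)) {
        if (!is.na(child)) grow(child, gens_left - 1L)
      }
      invisible()
    }

    root <- add_segment(nc / 2, nr - 8, 90, 0L, 0L, NA_integer_)
    grow(root, depth)

    seg_tbl <- purrr::map_dfr(segs, function(s) {
      tibble(id = s$id, parent = s$parent, generation = s$gen,
             x0 = s$x0, y0 = s$y0, x1 = s$x1, y1 = s$y1,
             length_px = sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2))
    })
    n_children <- table(factor(seg_tbl$parent, levels = seg_tbl$id))
    n_branch <- sum(n_children == 2L)
    n_tip <- sum(n_children == 0L)

    # rasterize centerlines
    centerline <- map(segs, function(s) {
      px <- unique(round(s$pts[, c("y", "x"), drop = FALSE]))
      colnames(px) <- c("row", "col")
      px
    })
    all_px <- do.call(rbind, centerline)
    clipped <- any(all_px[, "row"] < 1 | all_px[, "row"] > nr |
                     all_px[, "col"] < 1 | all_px[, "col"] > nc)
    if (clipped) {
      warn("generated tree exceeds the image bounds; rendering is clipped")
    }
    keep <- all_px[, "row"] >= 1 & all_px[, "row"] <= nr &
      all_px[, "col"] >= 1 & all_px[, "col"] <= nc
    all_px <- all_px[keep, , drop = FALSE]

    cl_mask <- matrix(FALSE, nr, nc)
    cl_mask[all_px] <- TRUE

    # distance of every pixel to the nearest centerline pixel
    d <- matrix(EBImage::imageData(EBImage::distmap(1 - cl_mask)), nr, nc)
    sigma <- tube_width / (2 * sqrt(2 * log(2)))  # FWHM = tube_width
    profile <- contrast * exp(-d^2 / (2 * sigma^2))
    profile[d > 2 * tube_width] <- 0              # finite tube support
    img <- matrix(bg, nr, nc) - profile
    if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
    img <- pmin(pmax(img, 0), 1)

    structure(list(
      image = img,
      centerline_mask = cl_mask,
      tube_mask = d <= tube_width / 2,
      truth = list(
        segments = seg_tbl,
        centerline = centerline,
        n_branch = as.integer(n_branch),
        n_tip = as.integer(n_tip),
        n_endpoint = as.integer(n_tip) + 1L,   # tips plus the root entry

        total_length_px = sum(seg_tbl$length_px),
        total_length_mm = sum(seg_tbl$length_px) * pixel_size,
        tube_width = tube_width,
        pixel_size = pixel_size,
        noise_sd = noise_sd,
        seed = seed,
        clipped = clipped
      ),
      params = list(depth = depth, segment_length = segment_length,
                    tube_width = tube_width, angle_jitter = angle_jitter,
                    branch_prob = branch_prob, noise_sd = noise_sd,
                    pixel_size = pixel_size, size = c(nr, nc),
                    bg = bg, contrast = contrast, seed = seed)
    ), class = "wholemount_sim")
  })
}

#' @export
print.wholemount_sim <- function(x, ...) {
  cat(sprintf(
    "<wholemount_sim> %dx%d px, %d segments, %d branch points, %d tips, total length %.1f px (%.2f mm)%s\n",
    nrow(x$image), ncol(x$image), nrow(x$truth$segments), x$truth$n_branch,
    x$truth$n_tip, x$truth$total_length_px, x$truth$total_length_mm,
    if (x$truth$clipped) " [clipped]" else ""))
  invisible(x)
}
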