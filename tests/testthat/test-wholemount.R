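test_that("vesselness is zero on flat fields and ignores constant offsets", {
  expect_true(all(frangi_vesselness(matrix(0.5, 48, 48)) == 0))
  img <- make_tube_image(96, 96)
  v1 <- frangi_vesselness(img)
  v2 <- frangi_vesselness(img + 0.1)  # still inside [0,1]
  expect_equal(v1, v2, tolerance = 1e-8)
  expect_true(all(v1 >= 0 & v1 <= 1))
  expect_error(frangi_vesselness(img, sigmas = numeric(0)), class = "ductnet_input_error")
  expect_error(frangi_vesselness(img, sigmas = c(2, 1)), class = "ductnet_input_error")
})

test_that("a tube lights up its centerline; a blob is penalized", {
  img <- make_tube_image(128, 128, width = 6)
  v <- frangi_vesselness(img)
  centerline <- v[64, 15:114]
  background <- v[c(1:40, 88:128), ]
  expect_gt(mean(centerline), 10 * max(mean(background), 1e-12))

  vb <- frangi_vesselness(make_blob_image(128, 128, width = 6))
  expect_lt(max(vb), mean(centerline))  # isotropic structure scores lower

  # vertical tube behaves identically (rotation by 90 degrees)
  vv <- frangi_vesselness(make_tube_image(128, 128, width = 6, horizontal = FALSE))
  expect_equal(mean(vv[15:114, 64]), mean(centerline), tolerance = 1e-6)
})

test_that("segment applies the hard threshold and removes speckle", {
  resp <- matrix(0, 20, 20)
  resp[5, 1:15] <- 0.6
  resp[15, 3] <- 1.0            # isolated bright speck
  m0 <- segment(resp, policy = 0, min_object_px = 0)
  expect_equal(sum(m0), 400)    # threshold 0 keeps everything >= 0
  m1 <- segment(resp, policy = 1, min_object_px = 0)
  expect_equal(sum(m1), 1)      # only the exact-1 pixel survives
  mt <- segment(resp, policy = 0.5, min_object_px = 5)
  expect_equal(sum(mt), 15)     # the speck is below min_object_px
  expect_error(segment(resp, policy = 1.5), class = "ductnet_input_error")
  expect_error(segment(resp, policy = "median"), class = "ductnet_input_error")
})

test_that("skeletonize thins a bar to a line and preserves topology", {
  bar <- matrix(FALSE, 20, 120)
  bar[9:11, 11:110] <- TRUE
  sk <- skeletonize(bar)
  expect_true(any(sk))
  rows_used <- unique(which(sk, arr.ind = TRUE)[, 1])
  expect_length(rows_used, 1)                    # a single 1-px line
  m <- skeleton_metrics(sk)
  expect_equal(m$n_branch, 0L)
  expect_equal(m$n_sprout, 2L)

  expect_equal(sum(skeletonize(matrix(FALSE, 5, 5))), 0)

  # a ring keeps its hole: no endpoints, one component
  th <- seq(0, 2 * pi, length.out = 400)
  ring <- matrix(FALSE, 60, 60)
  for (rad in c(18, 19, 20, 21)) {
    ring[cbind(round(30 + rad * sin(th)), round(30 + rad * cos(th)))] <- TRUE
  }
  skr <- skeletonize(ring)
  mr <- skeleton_metrics(skr)
  expect_equal(mr$n_sprout, 0L)
  expect_equal(mr$n_components, 1L)
})

test_that("skeleton metrics match hand counts on canonical fixtures", {
  # straight 1-px line of 100 pixels: 99 orthogonal steps
  line <- matrix(FALSE, 10, 120)
  line[5, 11:110] <- TRUE
  m <- skeleton_metrics(line, pixel_size = 0.02)
  expect_equal(m$extension_px, 99)
  expect_equal(m$extension_mm, 99 * 0.02)
  expect_equal(m$n_branch, 0L)
  expect_equal(m$n_sprout, 2L)
  expect_equal(m$longest_path_px, 99)

  y <- make_y_skeleton(41)
  my <- skeleton_metrics(y)
  expect_equal(my$n_branch, 1L)
  expect_equal(my$n_sprout, 3L)

  # counts are invariant under rotation and reflection
  for (tf in list(function(x) t(x),
                  function(x) x[nrow(x):1, ],
                  function(x) x[, ncol(x):1])) {
    mt <- skeleton_metrics(tf(y))
    expect_equal(mt$n_branch, 1L)
    expect_equal(mt$n_sprout, 3L)
    expect_equal(mt$extension_px, my$extension_px)
  }

  # a 2x2 block is rejected as non-thin
  fat <- matrix(FALSE, 6, 6)
  fat[2:3, 2:3] <- TRUE
  expect_error(skeleton_metrics(fat), class = "ductnet_input_error",
               regexp = "re-skeletonize")
})

test_that("generated noiseless trees are recovered exactly", {
  ok <- 0
  errs <- c()
  for (s in 1:5) {
    sim <- sim_wholemount(depth = 3, noise_sd = 0, seed = s)
    mask <- segment(1 - sim$image, policy = "otsu", min_object_px = 50)
    mm <- skeleton_metrics(skeletonize(mask), pixel_size = sim$truth$pixel_size)
    ok <- ok + (mm$n_branch == sim$truth$n_branch &&
                  mm$n_sprout == sim$truth$n_endpoint)
    errs <- c(errs, abs(mm$extension_px - sim$truth$total_length_px) /
                sim$truth$total_length_px)
    # tree Euler identity: sum over junction clusters of (degree - 2)
    # equals endpoints - 2 for one acyclic component
    sk <- skeletonize(mask)
    degs <- junction_cluster_degrees(sk)
    expect_equal(sum(degs - 2L), mm$n_sprout - 2L)
  }
  expect_equal(ok, 5)
  expect_lt(mean(errs), 0.05)
})

test_that("full pipeline segments generated trees accurately", {
  sim <- sim_wholemount(depth = 3, noise_sd = 0, seed = 3)
  q <- quantify_wholemount(sim, sigmas = c(1, 2, 3))
  expect_gte(dice(q$mask, sim$tube_mask), 0.9)
  expect_equal(q$metrics$n_branch, sim$truth$n_branch)
  expect_equal(q$metrics$n_sprout, sim$truth$n_endpoint)

  noisy <- sim_wholemount(depth = 3, noise_sd = 0.05, seed = 3)
  qn <- quantify_wholemount(noisy, sigmas = c(1, 2, 3))
  expect_gte(dice(qn$mask, noisy$tube_mask), 0.8)
})

test_that("compare_groups reports pooled t per metric and validates groups", {
  d <- tibble::tibble(
    group = rep(c("wt", "tg"), each = 3),
    extension = c(1, 2, 3, 4, 5, 6),
    branches = c(5, 5, 5, 5, 5, 5)
  )
  cmp <- compare_groups(d, metrics = c("extension", "branches"))
  ext <- cmp[cmp$metric == "extension", ]
  expect_equal(ext$t, 3.674, tolerance = 1e-3)   # tg sorts first: (4,5,6) vs (1,2,3)
  expect_equal(ext$df, 4)
  br <- cmp[cmp$metric == "branches", ]
  expect_equal(br$t, 0)
  expect_equal(br$p, 1)

  expect_error(compare_groups(d[-(1:2), ]), class = "ductnet_input_error", regexp = "wt")
  d3 <- d
  d3$group[1] <- "third"
  expect_error(compare_groups(d3), class = "ductnet_input_error")
})
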