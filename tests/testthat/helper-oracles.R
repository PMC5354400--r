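# Independent oracles used across the suite. Each is deliberately naive:
# direct enumeration or textbook formulas, sharing no code with the package.

# step-up FDR adjustment by literal enumeration of min_{j >= i} p_(j) m / j
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# P(overlap >= k) by enumerating every possible DEG draw of size n from N
# genes, K of which belong to the set
hyper_enum <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# pooled-variance two-sample t, written out
student_t_brute <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# minimal distance to the DEG layer along reversed edges, via igraph, with
# intermediate vertices restricted to the eligible set
bfs_levels <- function(edges, degs, eligible) {
  nodes <- union(union(edges$source, edges$target), union(degs, eligible))
  keep <- edges$source %in% c(eligible) & edges$target %in% c(eligible, degs)
  sub <- edges[keep, c("source", "target")]
  g <- igraph::graph_from_data_frame(sub, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  d <- igraph::distances(g, v = nodes, to = degs, mode = "out")
  lev <- apply(d, 1, min)
  lev <- lev[is.finite(lev)]
  lev <- lev[names(lev) %in% c(eligible, degs)]
  lev[setdiff(names(lev), degs)]
}

# random relation-typed digraph for property tests
random_typed_graph <- function(n_nodes, n_edges, n_deg, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%04d", seq_len(n_nodes))
    degs <- sample(nodes, n_deg)
    src <- sample(nodes, n_edges, replace = TRUE)
    tgt <- sample(nodes, n_edges, replace = TRUE)
    ok <- src != tgt
    list(
      edges = data.frame(source = src[ok], target = tgt[ok],
                         relation = sample(c("affected", "activated", "inhibited"),
                                           sum(ok), replace = TRUE)),
      degs = degs
    )
  })
}

# per-junction-cluster degree bookkeeping for the tree Euler identity
junction_cluster_degrees <- function(skeleton) {
  sk <- skeleton != 0
  nb <- matrix(0, nrow(sk), ncol(sk))
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1), c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  shp <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0, nr, nc)
    r1 <- max(1, 1 - dr); r2 <- min(nr, nr - dr)
    c1 <- max(1, 1 - dc); c2 <- min(nc, nc - dc)
    if (r1 <= r2 && c1 <= c2) out[r1:r2, c1:c2] <- m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
    out
  }
  for (o in offs) nb <- nb + shp(sk * 1, o[1], o[2])
  branch <- sk & nb >= 3
  if (!any(branch)) return(integer(0))
  # label branch clusters by flood fill over the 8-neighborhood
  lab <- matrix(0L, nrow(sk), ncol(sk))
  cur <- 0L
  todo <- which(branch)
  for (i in todo) {
    if (lab[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (lab[j] > 0) next
      lab[j] <- cur
      r <- ((j - 1) %% nrow(sk)) + 1; cc <- ((j - 1) %/% nrow(sk)) + 1
      for (o in offs) {
        rr <- r + o[1]; c2 <- cc + o[2]
        if (rr >= 1 && rr <= nrow(sk) && c2 >= 1 && c2 <= ncol(sk) &&
            branch[rr, c2] && lab[rr, c2] == 0) {
          queue <- c(queue, (c2 - 1) * nrow(sk) + rr)
        }
      }
    }
  }
  # degree of a cluster = adjacencies between its pixels and non-branch skeleton
  vapply(seq_len(cur), function(cl) {
    deg <- 0L
    for (j in which(lab == cl)) {
      r <- ((j - 1) %% nrow(sk)) + 1; cc <- ((j - 1) %/% nrow(sk)) + 1
      for (o in offs) {
        rr <- r + o[1]; c2 <- cc + o[2]
        if (rr >= 1 && rr <= nrow(sk) && c2 >= 1 && c2 <= ncol(sk) &&
            sk[rr, c2] && !branch[rr, c2]) deg <- deg + 1L
      }
    }
    deg
  }, integer(1))
}

# small rendered fixtures
make_tube_image <- function(nr = 128, nc = 128, width = 6, horizontal = TRUE,
                            bg = 0.85, contrast = 0.6) {
  d <- if (horizontal) abs(row(matrix(0, nr, nc)) - round(nr / 2))
       else abs(col(matrix(0, nr, nc)) - round(nc / 2))
  sigma <- width / (2 * sqrt(2 * log(2)))
  bg - contrast * exp(-d^2 / (2 * sigma^2))
}

make_blob_image <- function(nr = 128, nc = 128, width = 6,
                            bg = 0.85, contrast = 0.6) {
  d <- sqrt((row(matrix(0, nr, nc)) - round(nr / 2))^2 +
              (col(matrix(0, nr, nc)) - round(nc / 2))^2)
  sigma <- width / (2 * sqrt(2 * log(2)))
  bg - contrast * exp(-d^2 / (2 * sigma^2))
}

# Y-shaped 1-px skeleton: three straight arms meeting at one pixel
make_y_skeleton <- function(n = 41) {
  sk <- matrix(FALSE, n, n)
  cx <- (n + 1) / 2
  sk[cx:n, cx] <- TRUE                      # stem straight down
  for (i in 0:(cx - 2)) {
    sk[cx - 1 - i, cx - 1 - i] <- TRUE      # upper-left arm
    sk[cx - 1 - i, cx + 1 + i] <- TRUE      # upper-right arm
  }
  sk[cx, cx] <- TRUE
  sk
}
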