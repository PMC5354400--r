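chain_graph <- function() {
  ingest_graph(
    data.frame(source = c("U", "R2", "R1"),
               target = c("R2", "R1", "G1"),
               relation = c("affected", "activated", "inhibited")),
    deg_list = "G1", upstream = "U")
}

test_that("ingest_graph cleans, types and tags the digraph", {
  g <- chain_graph()
  expect_s3_class(g, "reg_graph")
  expect_setequal(g$nodes$node, c("U", "R2", "R1", "G1"))
  expect_equal(g$nodes$role[g$nodes$node == "G1"], "deg")
  expect_equal(g$nodes$role[g$nodes$node == "U"], "upstream_regulator")
  expect_equal(g$nodes$role[g$nodes$node == "R1"], "candidate_regulator")

  # empty edge table keeps declared nodes
  e0 <- ingest_graph(data.frame(source = character(0), target = character(0),
                                relation = character(0)),
                     deg_list = c("G1", "G2"), upstream = "U")
  expect_setequal(e0$nodes$node, c("G1", "G2", "U"))

  # duplicates collapse, self-loops drop with a note
  dup <- data.frame(source = c("A", "A", "B"), target = c("G1", "G1", "B"),
                    relation = "activated")
  expect_message(gd <- ingest_graph(dup, deg_list = "G1"), "self-loop")
  expect_equal(nrow(gd$edges), 1)

  # unknown relation labels are rejected with the row number
  bad <- data.frame(source = c("A", "B"), target = c("G1", "G1"),
                    relation = c("activated", "phosphorylates"))
  expect_error(ingest_graph(bad, deg_list = "G1"),
               class = "ductnet_input_error", regexp = "row 2")
})

test_that("build_hierarchy layers the chain and counts iterations to fixpoint", {
  h <- build_hierarchy(chain_graph(), "G1")
  lv <- setNames(h$levels$level, h$levels$node)
  expect_equal(lv[["G1"]], 0L)
  expect_equal(lv[["R1"]], 1L)
  expect_equal(lv[["R2"]], 2L)
  expect_equal(lv[["U"]], 3L)
  expect_equal(h$iterations, 4L)  # 3 productive passes + the empty one
  expect_equal(nrow(h$edges), 3)
})

test_that("unreachable candidates are excluded and minimality holds", {
  edges <- data.frame(
    source = c("R1", "Rboth", "Rboth", "Orphan"),
    target = c("G1", "G1", "R1", "Nowhere"),
    relation = "affected")
  g <- ingest_graph(edges, deg_list = "G1")
  h <- build_hierarchy(g, "G1")
  lv <- setNames(h$levels$level, h$levels$node)
  # a node with edges into level 0 and level 1 takes the minimal level 1
  expect_equal(lv[["Rboth"]], 1L)
  expect_false("Orphan" %in% h$levels$node)
  expect_false("Nowhere" %in% h$levels$node)
})

test_that("an empty function DEG set gives an empty network with a warning", {
  expect_warning(h <- build_hierarchy(chain_graph(), character(0)), "empty")
  expect_equal(nrow(h$levels), 0)
  expect_error(build_hierarchy(chain_graph(), "NOT_A_DEG"),
               class = "ductnet_input_error")
})

test_that("layering equals reverse-BFS distance on random graphs", {
  for (s in 1:12) {
    rg <- random_typed_graph(n_nodes = 80, n_edges = 240, n_deg = 15, seed = s)
    g <- ingest_graph(rg$edges, deg_list = rg$degs)
    h <- build_hierarchy(g, rg$degs)
    eligible <- g$nodes$node[g$nodes$role != "deg"]
    oracle <- bfs_levels(g$edges, rg$degs, eligible)
    got <- setNames(h$levels$level, h$levels$node)
    got <- got[h$levels$level >= 1]
    expect_equal(sort(names(got)), sort(names(oracle)))
    expect_equal(got[sort(names(got))], oracle[sort(names(oracle))])
    # fixpoint in at most |nodes| + 1 iterations
    expect_lte(h$iterations, nrow(g$nodes) + 1)
  }
})

test_that("relation labels never influence level assignment", {
  rg <- random_typed_graph(60, 180, 10, seed = 33)
  g1 <- ingest_graph(rg$edges, deg_list = rg$degs)
  relabeled <- rg$edges
  relabeled$relation <- "inhibited"
  g2 <- ingest_graph(relabeled, deg_list = rg$degs)
  h1 <- build_hierarchy(g1, rg$degs)
  h2 <- build_hierarchy(g2, rg$degs)
  expect_equal(h1$levels[c("node", "level")], h2$levels[c("node", "level")])
})

test_that("edge edits move levels monotonically", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      rg <- random_typed_graph(40, 100, 8, seed = rep + 100)
      g <- ingest_graph(rg$edges, deg_list = rg$degs)
      h <- build_hierarchy(g, rg$degs)
      base <- setNames(h$levels$level, h$levels$node)
      # adding an edge from a layered node straight into a DEG can only
      # lower (or keep) levels
      cand <- h$levels$node[h$levels$level >= 2]
      if (length(cand) == 0) next
      extra <- rbind(g$edges,
                     data.frame(source = cand[1], target = rg$degs[1],
                                relation = "activated"))
      h2 <- build_hierarchy(ingest_graph(extra, deg_list = rg$degs), rg$degs)
      after <- setNames(h2$levels$level, h2$levels$node)
      shared <- intersect(names(base), names(after))
      expect_true(all(after[shared] <= base[shared]))
      # deleting one edge can only raise levels or drop nodes
      drop1 <- g$edges[-sample(nrow(g$edges), 1), ]
      h3 <- build_hierarchy(ingest_graph(drop1, deg_list = rg$degs), rg$degs)
      lv3 <- setNames(h3$levels$level, h3$levels$node)
      shared3 <- intersect(names(base), names(lv3))
      expect_true(all(lv3[shared3] >= base[shared3]))
    }
  })
})

test_that("planted levels are recovered exactly from generated graphs", {
  for (s in 1:10) {
    rg <- sim_regulatory_graph(3, 7, n_noise_edges = 0, seed = s)
    g <- ingest_graph(rg$edges, deg_list = rg$deg_ids, upstream = rg$upstream_ids)
    h <- build_hierarchy(g, rg$deg_ids)
    merged <- merge(rg$truth, h$levels, by = "node")
    expect_equal(nrow(merged), nrow(rg$truth))
    expect_equal(merged$level.x, merged$level.y)
  }
})

test_that("multiplicity counts intermediate membership across networks", {
  mk <- function(inter, degs = "G1") {
    edges <- data.frame(source = inter, target = degs[1], relation = "affected")
    build_hierarchy(ingest_graph(edges, deg_list = degs), degs,
                    function_label = paste(inter, collapse = "+"))
  }
  same <- lapply(1:4, function(i) mk(c("A", "B")))
  m <- network_multiplicity(same)
  expect_equal(m$n_found, c(4L, 4L))

  disjoint <- lapply(1:4, function(i) mk(paste0("X", i)))
  m2 <- network_multiplicity(disjoint)
  expect_true(all(m2$n_found == 1L))

  mixed <- list(mk(c("S", "A1")), mk(c("S", "A2")), mk(c("S", "A3")), mk("A4"))
  m3 <- network_multiplicity(mixed)
  expect_equal(m3$n_found[m3$node == "S"], 3L)
  # DEG-layer membership is never counted
  expect_false("G1" %in% m3$node)

  expect_error(network_multiplicity(mixed[1]), class = "ductnet_input_error")
  # common intermediates: maximal count, optional pathway filter
  expect_equal(common_intermediates(m3, threshold = 3), "S")
  expect_equal(common_intermediates(m3, pathway_members = c("A4"), threshold = 3),
               character(0))
})
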