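test_that("overlap_test matches exhaustive enumeration on small universes", {
  # saturated draw: p = 1 whatever the set
  u <- letters[1:10]
  r <- overlap_test(u, u[1:4], u)
  expect_equal(r$p_hyper, 1)

  # N=10, K=5, n=5, k=5: single favourable draw among C(10,5)
  r <- overlap_test(letters[1:5], letters[1:5], u)
  expect_equal(r$p_hyper, 1 / 252)
  expect_equal(r$p_hyper, hyper_enum(10, 5, 5, 5))

  # a spread of (N, K, n, k) against the enumeration oracle
  for (N in c(6, 9, 12)) {
    uu <- sprintf("g%02d", 1:N)
    for (K in c(2, N %/% 2, N - 1)) {
      for (n in c(2, N %/% 2)) {
        for (k in max(0, n - (N - K)):min(K, n)) {
          deg <- c(uu[seq_len(k)], uu[K + seq_len(n - k)])
          r <- overlap_test(deg, uu[seq_len(K)], uu)
          expect_equal(r$p_hyper, hyper_enum(N, K, n, k), tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
          expect_equal(r$k, k)
        }
      }
    }
  }
})

test_that("affected proportion is the overlap fraction of the set", {
  expect_equal(affected_proportion(letters[1:10], letters[11:20]), 0)
  expect_equal(affected_proportion(letters[1:5], letters[1:10]), 1)
  expect_equal(affected_proportion(c("a", "b", "c", "d"), c("a", "d", "x")), 0.5)
  expect_error(affected_proportion(character(0), "a"), class = "ductnet_input_error")
  # planted collections hit the requested fraction
  u <- sprintf("G%03d", 1:100)
  deg <- u[1:40]
  coll <- sim_geneset_collection(u, 3, c(20, 20),
                                 planted = list(set_index = 3, fraction = 0.5,
                                                deg_list = deg), seed = 5)
  expect_equal(affected_proportion(coll$genes[[3]], deg), 0.5)
})

test_that("overlap_test validates universe membership", {
  expect_error(overlap_test(c("a", "zz"), c("a", "b"), letters[1:5]),
               class = "ductnet_input_error", regexp = "zz")
  expect_error(overlap_test("a", "b", character(0)), class = "ductnet_input_error")
  expect_message(r <- overlap_test("a", c("a", "zz"), letters[1:5]), "dropped")
  expect_equal(r$K, 1)
})

test_that("rank_sets orders by p, breaks ties by affected proportion, truncates", {
  u <- sprintf("G%03d", 1:80)
  deg <- u[1:20]
  coll <- sim_geneset_collection(u, 6, c(10, 15),
                                 planted = list(set_index = 4, fraction = 0.9,
                                                deg_list = deg), seed = 6)
  ranked <- rank_sets(coll, deg, u)
  expect_equal(ranked$set_id[1], "SET004")
  expect_true(!is.unsorted(ranked$p_hyper))
  expect_equal(nrow(rank_sets(coll, deg, u, top = 4)), 4)
  one <- rank_sets(coll[3, ], deg, u)
  expect_equal(nrow(one), 1)
  # enrichment p depends only on (N, K, n, k): relabeling genes changes nothing
  relabel <- setNames(sprintf("X%03d", seq_along(u)), u)
  coll2 <- coll
  coll2$genes <- lapply(coll$genes, function(g) unname(relabel[g]))
  ranked2 <- rank_sets(coll2, unname(relabel[deg]), unname(relabel[u]))
  expect_equal(ranked2$p_hyper, ranked$p_hyper)
})

test_that("growing the universe with non-DEG genes sharpens the overlap p", {
  # with k, K, n fixed, a larger background makes >= k overlaps rarer under
  # the null, so p_hyper can only shrink as inert genes join the universe
  u <- sprintf("G%03d", 1:30)
  deg <- u[1:8]
  set <- u[5:16]
  p0 <- overlap_test(deg, set, u)$p_hyper
  p1 <- overlap_test(deg, set, c(u, "EXTRA1"))$p_hyper
  p2 <- overlap_test(deg, set, c(u, sprintf("EXTRA%d", 1:10)))$p_hyper
  expect_true(p0 >= p1 && p1 >= p2)
})
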