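# Builds a complete synthetic transcriptomics bundle on disk: an expression
# matrix with planted DE, four function gene sets, a pathway collection, and
# a regulator graph in which five intermediates are shared by all four
# functions (two of them pathway members).
make_transcriptomics_bundle <- function(dir, seed = 101) {
  sim <- sim_expression(300, 60, effect = 4, n_per_group = 3,
                        noise_sd = 0.25, seed = seed)
  expr_path <- file.path(dir, "expr.tsv")
  write_expression(sim, expr_path)

  degs <- deg_ids(select_degs(gene_stats(sim$expr, sim$groups)))
  stopifnot(length(degs) >= 40)
  fn_degs <- split(degs[1:40], rep(1:4, each = 10))

  universe <- sim$expr$gene_id
  non_deg <- setdiff(universe, degs)
  go <- tibble::tibble(
    set_id = sprintf("FN%d", 1:4),
    name = c("signal transduction", "cell proliferation",
             "receptor signaling", "apoptotic process"),
    genes = lapply(1:4, function(i) c(fn_degs[[i]], non_deg[(i * 5):(i * 5 + 4)]))
  )
  go_path <- file.path(dir, "go.gmt")
  write_gmt(go, go_path)

  shared <- sprintf("S%d", 1:5)
  pathway <- tibble::tibble(
    set_id = c("PW1", "PW2"),
    name = c("jak-stat-like", "unrelated"),
    genes = list(c("S1", "S2", degs[1:8]), non_deg[100:110])
  )
  kegg_path <- file.path(dir, "kegg.gmt")
  write_gmt(pathway, kegg_path)

  edges <- do.call(rbind, c(
    # each shared intermediate regulates one DEG of every function
    lapply(seq_along(shared), function(i) {
      data.frame(source = shared[i],
                 target = vapply(fn_degs, `[`, "", i),
                 relation = "activated")
    }),
    # one private intermediate per function
    lapply(1:4, function(i) {
      data.frame(source = sprintf("PRIV%d", i), target = fn_degs[[i]][1:2],
                 relation = "affected")
    }),
    # upstream regulator drives the shared intermediates
    list(data.frame(source = "UP", target = shared, relation = "inhibited"))
  ))
  graph_path <- file.path(dir, "graph.csv")
  write_edges(edges, graph_path)

  list(
    config = list(
      expression = expr_path, genesets_go = go_path, genesets_kegg = kegg_path,
      graph = graph_path, upstream = "UP",
      functions = list(signal = "FN1", proliferation = "FN2",
                       receptor = "FN3", apoptosis = "FN4")),
    shared = shared, pathway_shared = c("S1", "S2")
  )
}

dir_md5 <- function(d) {
  fs <- sort(list.files(d, recursive = TRUE, full.names = TRUE))
  out <- tools::md5sum(fs)
  names(out) <- basename(names(out))
  out
}

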