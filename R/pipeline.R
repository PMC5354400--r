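# End-to-end orchestration of the two analysis arms from a single config
# (list or YAML file), with a JSON manifest of every parameter actually used
# so any run can be reproduced bit for bit.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config), class = "ductnet_input_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a list or a YAML file path.", class = "ductnet_input_error")
  }
  config
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(list())
  md5 <- tools::md5sum(paths)
  purrr::imap(as.list(unname(md5)), function(h, i) {
    list(path = paths[i], md5 = h)
  })
}

write_manifest <- function(out_dir, arm, params, inputs) {
  manifest <- list(
    package = "ductnet",
    version = as.character(utils::packageVersion("ductnet")),
    arm = arm,
    parameters = params,
    inputs = file_digest(inputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Run the transcriptomics arm end to end
#'
#' Expression matrix to DEG table, gene-set over-representation, one
#' hierarchical regulator network per declared cellular function, node
#' multiplicity across the networks, and the common-intermediate list.
#'
#' @param config List or YAML path with elements:
#'   \describe{
#'     \item{expression}{path to the TSV written by [write_expression()]
#'       (sidecar `<path>.groups.json` expected).}
#'     \item{genesets_go}{GMT path of the function collection.}
#'     \item{genesets_kegg}{optional GMT path of the pathway collection;
#'       the union of the `pathway_top` best overlaps filters the common
#'       intermediates.}
#'     \item{graph}{CSV edge list (source, target, relation).}
#'     \item{upstream}{character vector of declared upstream regulators.}
#'     \item{functions}{named list mapping a function label to a `set_id`
#'       of the GO collection; each function's DEG layer is the DEG list
#'       intersected with that set.}
#'     \item{fc_threshold, alpha}{screen thresholds, defaults 2.3 / 0.05.}
#'     \item{pathway_top}{how many best pathway overlaps to union,
#'       default 4.}
#'   }
#' @param out_dir Output directory (created if needed). Tables are TSV,
#'   networks GraphML, plus `manifest.json`.
#' @return (Invisibly) a list with `deg_table`, `enrichment_go`,
#'   `enrichment_kegg`, `networks`, `multiplicity`, `common`, `manifest`.
#' @export
run_transcriptomics <- function(config, out_dir) {
  config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fc <- config$fc_threshold %||% 2.3
  alpha <- config$alpha %||% 0.05
  pathway_top <- config$pathway_top %||% 4

  stage <- function(name, path, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("stage `%s` failed on %s: %s", name, path %||% "<memory>",
                    conditionMessage(e)),
            class = "ductnet_stage_error")
    })
  }

  dat <- stage("expression", config$expression,
               read_expression(config$expression))
  universe <- as.character(dat$expr$gene_id)

  degs <- stage("deg_screen", config$expression, {
    select_degs(gene_stats(dat$expr, dat$groups), fc_threshold = fc, alpha = alpha)
  })
  deg_list <- deg_ids(degs)
  if (length(deg_list) == 0) {
    warn("no genes pass the DEG screen; networks will be empty")
  }
  readr::write_tsv(tidy(degs), file.path(out_dir, "deg_table.tsv"))

  go <- stage("enrichment_go", config$genesets_go, read_gmt(config$genesets_go))
  enr_go <- rank_sets(go, deg_list, universe)
  readr::write_tsv(tidy(enr_go), file.path(out_dir, "enrichment_go.tsv"))

  enr_kegg <- NULL
  pathway_members <- NULL
  if (!is.null(config$genesets_kegg)) {
    kegg <- stage("enrichment_kegg", config$genesets_kegg, read_gmt(config$genesets_kegg))
    enr_kegg <- rank_sets(kegg, deg_list, universe)
    readr::write_tsv(tidy(enr_kegg), file.path(out_dir, "enrichment_kegg.tsv"))
    best <- head(enr_kegg$set_id, pathway_top)
    pathway_members <- sort(unique(unlist(kegg$genes[match(best, kegg$set_id)])))
  }

  edge_tbl <- stage("graph", config$graph, read_edges(config$graph))
  graph <- ingest_graph(edge_tbl, deg_list = deg_list,
                        upstream = as.character(config$upstream %||% character(0)))

  fns <- config$functions %||% list()
  networks <- purrr::imap(fns, function(set_id, label) {
    members <- go$genes[[match(set_id, go$set_id)]]
    if (is.null(members)) {
      abort(sprintf("function `%s` references unknown set `%s`", label, set_id),
            class = "ductnet_input_error")
    }
    fn_degs <- intersect(deg_list, members)
    nw <- withCallingHandlers(
      build_hierarchy(graph, fn_degs, function_label = label),
      warning = function(w) invokeRestart("muffleWarning"))
    readr::write_tsv(nw$levels, file.path(out_dir, sprintf("levels_%s.tsv", label)))
    if (nrow(nw$levels) > 0) {
      write_graphml(nw, file.path(out_dir, sprintf("network_%s.graphml", label)))
    }
    nw
  })

  multiplicity <- NULL
  common <- character(0)
  if (length(networks) >= 2L) {
    multiplicity <- network_multiplicity(networks)
    readr::write_tsv(multiplicity, file.path(out_dir, "multiplicity.tsv"))
    common <- common_intermediates(multiplicity, pathway_members = pathway_members)
    writeLines(common, file.path(out_dir, "common_intermediates.txt"))
  }

  manifest <- write_manifest(
    out_dir, "transcriptomics",
    params = list(fc_threshold = fc, alpha = alpha, pathway_top = pathway_top,
                  functions = fns, upstream = config$upstream %||% character(0),
                  n_universe = length(universe), n_deg = length(deg_list)),
    inputs = unlist(c(config$expression, paste0(config$expression, ".groups.json"),
                      config$genesets_go, config$genesets_kegg, config$graph)))

  invisible(list(deg_table = degs, enrichment_go = enr_go,
                 enrichment_kegg = enr_kegg, networks = networks,
                 multiplicity = multiplicity, common = common,
                 manifest = manifest))
}

read_gray_image <- function(path) {
  lower <- tolower(path)
  px <- if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("package `tiff` is required to read TIFF images.", class = "ductnet_input_error")
    }
    tiff::readTIFF(path)
  } else if (grepl("\\.png$", lower)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("package `png` is required to read PNG images.", class = "ductnet_input_error")
    }
    png::readPNG(path)
  } else {
    abort(sprintf("unreadable image (expected TIFF or PNG): %s", path),
          class = "ductnet_input_error")
  }
  if (length(dim(px)) == 3L) px <- apply(px[, , 1:min(3, dim(px)[3]), drop = FALSE], c(1, 2), mean)
  px
}

#' Run the whole-mount arm end to end
#'
#' Per-image vesselness, segmentation, skeletonization and morphometry,
#' followed by a two-group comparison when groups are declared.
#'
#' @param config List or YAML path with elements:
#'   \describe{
#'     \item{images}{either a named list of in-memory matrices /
#'       `wholemount_image` / `wholemount_sim` objects, or a data frame /
#'       list with `path` (TIFF/PNG) and optional `group`.}
#'     \item{groups}{optional character vector of group labels, parallel to
#'       `images`.}
#'     \item{pixel_size}{mm/px, default 1.}
#'     \item{sigmas, beta, c, policy, min_object_px}{pipeline parameters;
#'       package defaults when absent.}
#'   }
#' @param out_dir Output directory: `metrics.tsv`, `comparison.tsv` (when
#'   two groups are present), one skeleton overlay PNG per image (white
#'   skeleton, green branch clusters, red endpoints) when the `png` package
#'   is available, and `manifest.json`.
#' @return (Invisibly) list with `metrics`, `comparison`, `manifest`.
#' @export
run_wholemount <- function(config, out_dir) {
  config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sigmas <- config$sigmas %||% 2^seq(0, 3, length.out = 7)
  beta <- config$beta %||% 0.5
  cpar <- config$c %||% "half_max_hessian_norm"
  policy <- config$policy %||% "otsu"
  min_object_px <- config$min_object_px %||% 50
  pixel_size <- config$pixel_size %||% 1

  imgs <- config$images
  if (is.null(imgs) || length(imgs) == 0) {
    abort("config must declare at least one image.", class = "ductnet_input_error")
  }
  paths <- character(0)
  if (is.data.frame(imgs)) imgs <- split(imgs, seq_len(nrow(imgs)))

  groups <- config$groups
  items <- purrr::imap(imgs, function(im, nm) {
    label <- if (is.character(nm) && nzchar(nm)) nm else paste0("image", nm)
    grp <- NA_character_
    if (is.list(im) && !is.null(im$path) && !inherits(im, "wholemount_sim")) {
      paths <<- c(paths, im$path)
      grp <- as.character(im$group %||% NA_character_)
      label <- sub("\\.(tiff?|png)$", "", basename(im$path))
      im <- read_gray_image(im$path)
    }
    list(label = label, group = grp, image = im)
  })
  if (!is.null(groups)) {
    for (i in seq_along(items)) items[[i]]$group <- as.character(groups[i])
  }

  results <- map(items, function(it) {
    quantify_wholemount(it$image, sigmas = sigmas, beta = beta, c = cpar,
                        policy = policy, min_object_px = min_object_px,
                        pixel_size = pixel_size)
  })

  metrics <- purrr::map_dfr(seq_along(items), function(i) {
    bind_cols(tibble(image = items[[i]]$label, group = items[[i]]$group),
              results[[i]]$metrics)
  })
  readr::write_tsv(metrics, file.path(out_dir, "metrics.tsv"))

  if (requireNamespace("png", quietly = TRUE)) {
    for (i in seq_along(items)) {
      ov <- skeleton_overlay(items[[i]]$image, results[[i]]$skeleton)
      png::writePNG(ov, file.path(out_dir, sprintf("overlay_%s.png", items[[i]]$label)))
    }
  }

  comparison <- NULL
  gl <- metrics$group
  if (length(unique(gl[!is.na(gl)])) == 2L && all(!is.na(gl))) {
    comparison <- compare_groups(
      metrics, group = "group",
      metrics = c("extension_px", "n_branch", "n_sprout"))
    readr::write_tsv(comparison, file.path(out_dir, "comparison.tsv"))
  }

  manifest <- write_manifest(
    out_dir, "wholemount",
    params = list(sigmas = sigmas, beta = beta, c = cpar, policy = policy,
                  min_object_px = min_object_px, pixel_size = pixel_size,
                  n_images = length(items)),
    inputs = paths)

  invisible(list(metrics = metrics, comparison = comparison, manifest = manifest))
}

# RGB overlay mirroring the standard color code: white skeleton, green
# branch clusters, red endpoints on the (dimmed) source image
skeleton_overlay <- function(image, skeleton) {
  if (inherits(image, "wholemount_sim")) image <- image$image
  if (inherits(image, "wholemount_image")) image <- image$pixels
  rng <- range(image)
  base <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  sk <- skeleton != 0
  nb <- matrix(0, nrow(sk), ncol(sk))
  for (dr in -1:1) for (dc in -1:1) if (dr || dc) nb <- nb + shift_mat(sk * 1, dr, dc)
  ends <- sk & nb <= 1
  branch <- sk & nb >= 3
  r <- base; g <- base; b <- base
  r[sk] <- 1; g[sk] <- 1; b[sk] <- 1
  r[branch] <- 0; g[branch] <- 1; b[branch] <- 0
  r[ends] <- 1; g[ends] <- 0; b[ends] <- 0
  out <- array(0, c(nrow(base), ncol(base), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
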