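#' 95% confidence ellipse of a 2-D point cloud
#'
#' Normal-theory ellipse: centre at the sample mean, principal axes along
#' the eigenvectors of the sample covariance, semi-axis lengths
#' `sqrt(qchisq(level, 2) * eigenvalue)`. For a standard bivariate normal
#' at level 0.95 this is a circle of radius ~2.448.
#'
#' @param points n x 2 numeric matrix, `n >= 3`.
#' @param level Coverage level in (0, 1).
#' @return A list with `center`, `axes` (semi-axis lengths, descending),
#'   `angle` (orientation of the major axis, radians), `cov`, `level`.
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  points <- as.matrix(points)
  if (nrow(points) < 3 || ncol(points) != 2) stop("need an n x 2 matrix, n >= 3")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  ctr <- colMeans(points)
  cv <- stats::cov(points)
  eg <- eigen(cv, symmetric = TRUE)
  if (any(eg$values < .Machine$double.eps * max(eg$values, 1))) {
    warning("degenerate covariance: ellipse collapses to a zero-width axis")
    eg$values <- pmax(eg$values, 0)
  }
  list(
    center = ctr,
    axes = sqrt(stats::qchisq(level, df = 2) * eg$values),
    angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
    cov = cv, level = level
  )
}

# polygon tracing a confidence ellipse (for plotting)
ellipse_path <- function(ellipse, n = 120) {
  th <- seq(0, 2 * pi, length.out = n)
  rot <- matrix(
    c(
      cos(ellipse$angle), sin(ellipse$angle),
      -sin(ellipse$angle), cos(ellipse$angle)
    ), 2, 2
  )
  pts <- cbind(ellipse$axes[1] * cos(th), ellipse$axes[2] * sin(th)) %*% t(rot)
  sweep(pts, 2, ellipse$center, "+")
}

#' Is a point inside a confidence ellipse?
#'
#' @param ellipse A [confidence_ellipse()] result.
#' @param points n x 2 matrix.
#' @return Logical vector: Mahalanobis distance within the chi-square
#'   radius.
#' @export
in_ellipse <- function(ellipse, points) {
  d2 <- stats::mahalanobis(as.matrix(points), ellipse$center, ellipse$cov)
  d2 <= stats::qchisq(ellipse$level, df = 2)
}

#' Pipeline configuration
#'
#' Exactly one of `input` (a cohort CSV path) or `synthetic` (a
#' [cohort_config()]) must be supplied. The master seed spawns named
#' substreams for the cohort, the embedding and any simulation, so fixing
#' it makes the whole run reproducible bit for bit.
#'
#' @param input Path to a cohort CSV, or `NULL`.
#' @param synthetic A [cohort_config()], or `NULL`.
#' @param embed An [embed_config()].
#' @param k_min,k_max Cluster range explored.
#' @param choose_k Selected k (default 3; `NULL` lets the silhouette
#'   decide).
#' @param assoc An [assoc_config()].
#' @param out_dir Output directory for the artifacts.
#' @param seed Master seed.
#' @param make_plots Write figure files (requires ggplot2).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = cohort_config(),
                            embed = embed_config(), k_min = 2, k_max = 10,
                            choose_k = 3, assoc = assoc_config(),
                            out_dir = tempfile("fatigueclust_run_"),
                            seed = 1L, make_plots = FALSE) {
  if (is.null(input) == is.null(synthetic)) {
    stop("supply exactly one of `input` (a CSV path) or `synthetic` (a cohort_config)")
  }
  structure(
    list(
      input = input, synthetic = synthetic, embed = embed,
      k_min = k_min, k_max = k_max, choose_k = choose_k, assoc = assoc,
      out_dir = out_dir, seed = as.integer(seed),
      make_plots = isTRUE(make_plots)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `input` or `synthetic` (the latter holding
#' [read_cohort_config()] keys), `embed` ([embed_config()] fields),
#' `k_min`, `k_max`, `choose_k`, `assoc` ([assoc_config()] fields),
#' `out_dir`, `seed`, `make_plots`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synthetic <- NULL
  if (is.null(y$input)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(y$synthetic %||% list(), tmp)
    synthetic <- read_cohort_config(tmp)
  }
  embed <- do.call(embed_config, y$embed %||% list())
  assoc <- do.call(assoc_config, y$assoc %||% list())
  pipeline_config(
    input = y$input, synthetic = synthetic, embed = embed,
    k_min = y$k_min %||% 2, k_max = y$k_max %||% 10,
    choose_k = y$choose_k %||% 3, assoc = assoc,
    out_dir = y$out_dir %||% tempfile("fatigueclust_run_"),
    seed = y$seed %||% 1L, make_plots = isTRUE(y$make_plots)
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

# write a data frame as deterministic UTF-8 CSV
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the full phenotyping pipeline
#'
#' Stages, in order: synthesize or load the cohort; score the instruments;
#' standardize the clustering features; embed with exact t-SNE; Ward-cluster
#' the embedding and evaluate k over the configured range; relabel clusters
#' by ascending fatigue; profile the clusters; run the association battery;
#' write every table plus a machine-readable run manifest. A failure in any
#' stage aborts with a stage-named error. Two runs with the same
#' configuration and master seed produce byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_artifacts`: list with `paths` (the
#'   written artifact files), `out_dir`, and the in-memory results
#'   (`cohort`, `embedding`, `keval`, `assignments`, `profile`,
#'   `associations`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  cohort <- stage("cohort", {
    if (!is.null(config$input)) {
      if (!file.exists(config$input)) stop("input file not found: ", config$input)
      utils::read.csv(config$input, stringsAsFactors = FALSE)
    } else {
      cc <- config$synthetic
      cc$seed <- substream_seed(config$seed, "cohort")
      generate_cohort(cc)
    }
  })
  cohort <- stage("score", score_cohort(cohort))
  feats <- stage("standardize", {
    assert_cols(cohort, config$embed$features)
    standardize_features(cohort, config$embed$features)
  })
  embedding <- stage("embed", {
    ec <- config$embed
    ec$seed <- substream_seed(config$seed, "tsne")
    tsne_embed(feats, ec)
  })
  keval <- stage("cluster", {
    evaluate_k_range(embedding$coords,
      k_min = config$k_min,
      k_max = config$k_max, choose_k = config$choose_k
    )
  })
  assignments <- stage("cluster", {
    cl <- cut_tree(attr(keval, "tree"), attr(keval, "chosen_k"))
    relabel_by_fss(cl, cohort$fss_score, cohort$phq9_score)
  })
  sil <- stage("cluster", silhouette_scores(embedding$coords, assignments))
  profile <- stage("profile", profile_clusters(cohort, assignments))
  assoc <- stage("associate", associations(cohort, config$assoc))

  paths <- list(
    cohort = write_table(cohort, out("cohort.csv")),
    embedding = write_table(
      data.frame(
        id = cohort$id, tsne1 = embedding$coords[, 1],
        tsne2 = embedding$coords[, 2]
      ), out("embedding.csv")
    ),
    assignments = write_table(
      data.frame(
        id = cohort$id, cluster = as.integer(assignments),
        silhouette = sil$widths
      ), out("assignments.csv")
    ),
    k_evaluation = write_table(as.data.frame(keval), out("keval.csv")),
    dendrogram = {
      writeLines(
        export_newick(attr(keval, "tree"), labels = cohort$id),
        out("tree.nwk")
      )
      out("tree.nwk")
    },
    profile = write_table(as.data.frame(profile), out("profile.csv")),
    correlations = write_table(assoc$pairs, out("correlations.csv")),
    partial = write_table(assoc$partial, out("partial_correlations.csv")),
    stratified = write_table(assoc$stratified$table, out("stratified.csv"))
  )
  if ("true_cluster" %in% names(cohort)) {
    paths$truth <- write_table(
      cohort[c("id", "true_cluster")], out("cohort_truth.csv")
    )
  }
  manifest <- list(
    package = "fatigueclust",
    version = as.character(utils::packageVersion("fatigueclust")),
    seed = config$seed,
    substreams = list(
      cohort = substream_seed(config$seed, "cohort"),
      tsne = substream_seed(config$seed, "tsne")
    ),
    config = serialize_config(config),
    artifacts = lapply(paths, basename),
    cluster_labels = as.list(attr(profile, "cluster_labels")),
    chosen_k = attr(keval, "chosen_k"),
    optimal_k = attr(keval, "optimal_k")
  )
  jsonlite::write_json(manifest, out("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  paths$manifest <- out("manifest.json")
  if (config$make_plots) {
    paths$figure_clusters <- stage(
      "report",
      plot_embedding_clusters(
        embedding$coords, assignments, cohort$fss_score,
        out("clusters.png")
      )
    )
  }
  structure(
    list(
      paths = paths, out_dir = config$out_dir, cohort = cohort,
      embedding = embedding, keval = keval, assignments = assignments,
      profile = profile, associations = assoc
    ),
    class = "run_artifacts"
  )
}

# flatten a pipeline_config into plain lists for the JSON manifest
serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), strip)
    } else {
      x
    }
  }
  strip(config)
}

#' Re-run a pipeline from its manifest
#'
#' Reconstructs the [pipeline_config()] stored in a `manifest.json` and
#' runs it into `out_dir`, reproducing the original artifacts exactly.
#'
#' @param manifest_path Path to a manifest written by [run_pipeline()].
#' @param out_dir Output directory (default: a fresh temporary directory).
#' @return The [run_pipeline()] artifacts.
#' @export
rerun_from_manifest <- function(manifest_path,
                                out_dir = tempfile("fatigueclust_rerun_")) {
  mf <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  cfg <- mf$config
  # NULL fields serialize as empty objects; normalise them back
  cfg <- lapply(cfg, function(v) if (length(v)) v else NULL)
  synthetic <- NULL
  if (!is.null(cfg$synthetic)) {
    sc <- cfg$synthetic
    specs <- lapply(sc$cluster_specs, function(cs) {
      cluster_spec(
        label = cs$label, weight = cs$weight,
        age = as.numeric(unlist(cs$age)),
        bmi = as.numeric(unlist(cs$bmi)),
        years_dx = as.numeric(unlist(cs$years_dx)),
        phq9 = as.numeric(unlist(cs$phq9)),
        isi = as.numeric(unlist(cs$isi)),
        fss = as.numeric(unlist(cs$fss)),
        male_frac = cs$male_frac
      )
    })
    targets <- do.call(rbind, lapply(sc$rank_corr_targets, function(r) {
      as.numeric(unlist(r))
    }))
    dimnames(targets) <- dimnames(default_rank_corr_targets())
    synthetic <- cohort_config(
      n = sc$n, cluster_specs = specs, rank_corr_targets = targets,
      seed = sc$seed, item_level = isTRUE(sc$item_level)
    )
  }
  ec <- lapply(cfg$embed, function(v) if (is.list(v)) unlist(v) else v)
  ac <- lapply(cfg$assoc, function(v) if (is.list(v)) unlist(v) else v)
  config <- pipeline_config(
    input = cfg$input, synthetic = synthetic,
    embed = embed_config(
      features = unlist(ec$features), out_dims = ec$out_dims,
      perplexity = ec$perplexity, max_iter = ec$max_iter,
      pca_init = ec$pca_init, auto_perplexity = ec$auto_perplexity,
      seed = ec$seed, learning_rate = ec$learning_rate,
      exaggeration = ec$exaggeration
    ),
    k_min = cfg$k_min, k_max = cfg$k_max, choose_k = cfg$choose_k,
    assoc = assoc_config(
      variables = unlist(ac$variables), alpha = ac$alpha,
      control = unlist(ac$control), fss_cutoff = ac$fss_cutoff,
      tertile_basis = ac$tertile_basis
    ),
    out_dir = out_dir, seed = mf$seed, make_plots = isTRUE(cfg$make_plots)
  )
  run_pipeline(config)
}

#' @export
print.run_artifacts <- function(x, ...) {
  cat("Pipeline run:", x$out_dir, "\n")
  cat(sprintf(
    "  n = %d, chosen k = %d (silhouette-optimal k = %d)\n",
    nrow(x$cohort), attr(x$keval, "chosen_k"), attr(x$keval, "optimal_k")
  ))
  invisible(x)
}
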