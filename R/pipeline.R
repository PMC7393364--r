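#' Superset split: multi-class labels to a binary diagnostic problem
#'
#' Maps an instance to 1 iff its subclass belongs to `superset_a` (the
#' "diseased" superset); everything else maps to 0.  The subclasses play the
#' role of hidden subtypes the downstream clustering tries to recover.
#'
#' @param y_subclass subclass label vector.
#' @param superset_a non-empty proper subset of the observed labels.
#' @return integer vector of binary labels.
#' @export
split_supersets <- function(y_subclass, superset_a) {
  if (inherits(y_subclass, "labeled_dataset")) y_subclass <- y_subclass$y_subclass
  obs <- unique(y_subclass)
  if (length(superset_a) == 0L) stop("superset_a must be non-empty")
  missing_lab <- setdiff(superset_a, obs)
  if (length(missing_lab) > 0L)
    stop("superset_a labels never observed: ", paste(missing_lab, collapse = ", "))
  if (length(setdiff(obs, superset_a)) == 0L)
    stop("superset_a covers all observed labels: binary split is degenerate")
  as.integer(y_subclass %in% superset_a)
}

#' Inverse-frequency balancing weights
#'
#' Weight of an instance of binary class c is proportional to `1 / count(c)`,
#' normalized so that the two classes carry equal total weight and the
#' weights sum to n.  Used as bootstrap sampling weights in
#' [train_random_forest()], which is equivalent in expectation to resampling
#' inversely proportional to class frequencies.
#'
#' @param y_binary binary labels in `{0, 1}`, both classes present.
#' @return numeric weight per instance.
#' @export
inverse_frequency_weights <- function(y_binary) {
  y <- as.integer(y_binary)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary in {0, 1}")
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 == 0L || n1 == 0L) stop("both classes must be present")
  n <- n0 + n1
  ifelse(y == 1L, n / (2 * n1), n / (2 * n0))
}

#' Configuration of the benchmark protocol
#'
#' @param superset_a subclass labels forming the positive superset.
#' @param balance `"none"` or `"inverse_frequency"` bootstrap balancing.
#' @param reducers subset of `c("none", "pca", "isomap", "tsne")`.
#' @param k_clusters number of clusters for the agglomerative step, or
#'   `"auto"` for `length(superset_a)` (the ground-truth subtype count of
#'   the evaluated superset; the total subclass count when
#'   `evaluate = "all"`).
#' @param seeds integer master seeds; the protocol runs once per seed and
#'   reports the per-cell mean.  Each master seed fans out into independent
#'   forest / reducer / holdout streams, recorded in the report.
#' @param evaluate `"superset_a"` (default) restricts the clustering
#'   evaluation to positive-superset instances; `"all"` evaluates every
#'   instance against all subclasses.
#' @param holdout fraction in `[0, 1)` of instances excluded from forest
#'   training (the protocol default trains and explains on all instances;
#'   a positive holdout gives the honest variant).
#' @param forest list of [train_random_forest()] settings (`n_trees`,
#'   `mtry`, `min_leaf`, `max_depth`, optionally a fixed `seed` overriding
#'   the derived stream).
#' @param reducer_params list of reducer settings passed to [reduce_dim()]:
#'   `isomap_k`, `tsne_perplexity`, `tsne_eta`, `tsne_n_iter`.
#' @param metric_reference `"ground_truth"` computes the validity indices
#'   (Davies-Bouldin, Calinski-Harabasz, silhouette) against the true
#'   subclass labels, treating them as structural measures of the
#'   representation; `"clusters"` computes them against the agglomerative
#'   partition instead.  AMI always compares the agglomerative partition
#'   with ground truth.
#' @param verbose log stage progress and wall times.
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(superset_a,
                            balance = c("none", "inverse_frequency"),
                            reducers = c("none", "pca", "isomap", "tsne"),
                            k_clusters = "auto",
                            seeds = c(0L, 1L, 2L),
                            evaluate = c("superset_a", "all"),
                            holdout = 0,
                            forest = list(),
                            reducer_params = list(),
                            metric_reference = c("ground_truth", "clusters"),
                            verbose = FALSE) {
  balance <- match.arg(balance)
  evaluate <- match.arg(evaluate)
  metric_reference <- match.arg(metric_reference)
  reducers <- match.arg(reducers, c("none", "pca", "isomap", "tsne"),
                        several.ok = TRUE)
  if (length(superset_a) == 0L) stop("superset_a must be non-empty")
  if (holdout < 0 || holdout >= 1) stop("holdout must be in [0, 1)")
  forest <- utils::modifyList(
    list(n_trees = 100L, mtry = NULL, min_leaf = 1L, max_depth = NULL,
         seed = NULL), forest)
  reducer_params <- utils::modifyList(
    list(isomap_k = 5L, tsne_perplexity = 30, tsne_eta = 200,
         tsne_n_iter = 1000L), reducer_params)
  structure(list(superset_a = superset_a, balance = balance,
                 reducers = reducers, k_clusters = k_clusters,
                 seeds = as.integer(seeds), evaluate = evaluate,
                 holdout = holdout, forest = forest,
                 reducer_params = reducer_params,
                 metric_reference = metric_reference, verbose = verbose),
            class = "protocol_config")
}

.stage <- function(name, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
  })
  if (verbose)
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the explanation-space benchmark protocol
#'
#' Per master seed: (1) build binary superset labels; (2) compute balancing
#' weights if configured; (3) train the forest on the binary task; (4)
#' compute Shapley explanations for all instances; (5) restrict evaluation
#' to positive-superset instances (default); (6) for each space (feature,
#' explanation) and each configured reducer, embed, cluster with
#' [ward_agglomerative()], and score with the validity indices and AMI
#' against the ground-truth subclasses; (7) average the per-seed grids.
#'
#' @param data a [labeled_dataset()].
#' @param config a [protocol_config()].
#' @return an object of class `benchmark_report`: `grid` (mean metric per
#'   space x reducer cell), `per_seed` (long data frame of every replicate),
#'   `embeddings` (2-D coordinates plus subclass labels from the last seed,
#'   for scatter plots), `config`, and a `provenance` block (config hash,
#'   dataset fingerprint, seed fan-out, versions).
#' @export
run_benchmark <- function(data, config) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(config, "protocol_config"))
  X <- data$X
  y <- data$y_subclass
  verbose <- isTRUE(config$verbose)
  if (verbose) message("config: ", paste(utils::capture.output(utils::str(
    config[c("superset_a", "balance", "reducers", "k_clusters", "seeds")],
    give.attr = FALSE)), collapse = " "))

  yb <- .stage("superset_split", verbose, split_supersets(y, config$superset_a))
  w <- if (config$balance == "inverse_frequency")
    .stage("balance", verbose, inverse_frequency_weights(yb)) else NULL

  eval_idx <- if (config$evaluate == "superset_a") which(yb == 1L) else seq_along(yb)
  k <- if (identical(config$k_clusters, "auto")) {
    if (config$evaluate == "superset_a") length(config$superset_a)
    else length(unique(y))
  } else as.integer(config$k_clusters)
  if (length(eval_idx) < k)
    stop("fewer evaluated instances (", length(eval_idx), ") than clusters (", k, ")")
  y_eval <- y[eval_idx]

  per_seed <- list()
  embeddings <- list()
  seed_streams <- list()
  for (ms in config$seeds) {
    streams <- with_preserved_seed(ms, sample.int(.Machine$integer.max - 1L, 3L))
    names(streams) <- c("forest", "reducer", "holdout")
    seed_streams[[as.character(ms)]] <- streams
    forest_seed <- if (!is.null(config$forest$seed)) config$forest$seed else streams[["forest"]]

    train_idx <- seq_along(yb)
    if (config$holdout > 0) {
      train_idx <- with_preserved_seed(streams[["holdout"]],
        sort(sample.int(length(yb), round((1 - config$holdout) * length(yb)))))
    }
    model <- .stage("train_forest", verbose, train_random_forest(
      X[train_idx, , drop = FALSE], yb[train_idx],
      n_trees = config$forest$n_trees, mtry = config$forest$mtry,
      min_leaf = config$forest$min_leaf, max_depth = config$forest$max_depth,
      sample_weights = if (is.null(w)) NULL else w[train_idx],
      seed = forest_seed))
    em <- .stage("explain", verbose, explain_matrix(model, X))

    spaces <- list(feature = X[eval_idx, , drop = FALSE],
                   explanation = em$phi[eval_idx, , drop = FALSE])
    stopifnot(ncol(spaces$explanation) == ncol(X))
    for (space in names(spaces)) {
      for (reducer in config$reducers) {
        emb <- .stage(paste0("reduce_", space, "_", reducer), verbose,
          reduce_dim(spaces[[space]], method = reducer,
                     seed = streams[["reducer"]],
                     isomap_k = config$reducer_params$isomap_k,
                     tsne_perplexity = config$reducer_params$tsne_perplexity,
                     tsne_eta = config$reducer_params$tsne_eta,
                     tsne_n_iter = config$reducer_params$tsne_n_iter))
        part <- .stage(paste0("cluster_", space, "_", reducer), verbose,
                       ward_agglomerative(emb$coords, k))
        ref <- if (config$metric_reference == "ground_truth") y_eval else part
        cell <- .stage(paste0("score_", space, "_", reducer), verbose,
                       .metric_cell(emb$coords, ref, part))
        per_seed[[length(per_seed) + 1L]] <- data.frame(
          seed = ms, space = space, reducer = reducer,
          davies_bouldin = cell$davies_bouldin,
          calinski_harabasz = cell$calinski_harabasz,
          silhouette = cell$silhouette,
          adjusted_mi = cell$adjusted_mi,
          stringsAsFactors = FALSE)
        if (ms == config$seeds[length(config$seeds)] && ncol(emb$coords) >= 2L) {
          embeddings[[paste(space, reducer, sep = "_")]] <- data.frame(
            instance = eval_idx, space = space, reducer = reducer,
            dim1 = emb$coords[, 1L], dim2 = emb$coords[, 2L],
            subclass = y_eval, cluster = part$labels,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  per_seed <- do.call(rbind, per_seed)

  grid <- do.call(rbind, lapply(split(
    per_seed, list(per_seed$space, per_seed$reducer), drop = TRUE),
    function(d) data.frame(
      space = d$space[1L], reducer = d$reducer[1L],
      davies_bouldin = mean(d$davies_bouldin),
      calinski_harabasz = mean(d$calinski_harabasz),
      silhouette = mean(d$silhouette),
      adjusted_mi = mean(d$adjusted_mi),
      stringsAsFactors = FALSE)))
  grid <- grid[order(match(grid$reducer, config$reducers),
                     match(grid$space, c("feature", "explanation")), method = "radix"), ]
  rownames(grid) <- NULL

  structure(list(
    grid = grid, per_seed = per_seed, embeddings = embeddings,
    config = config,
    provenance = list(
      config_hash = .fingerprint(unclass(config)),
      dataset_fingerprint = .fingerprint(list(X = X, y = y)),
      n_instances = nrow(X), n_features = ncol(X),
      n_evaluated = length(eval_idx), k_clusters = k,
      seed_streams = seed_streams,
      package_version = as.character(utils::packageVersion("explspace")),
      r_version = R.version.string,
      created = format(Sys.time(), tz = "UTC"))),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", length(unique(x$per_seed$seed)), " seed(s), ",
      x$provenance$n_evaluated, " evaluated instances, k = ",
      x$provenance$k_clusters, "\n\n", sep = "")
  print(x$grid, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write benchmark metric tables
#'
#' `write_metrics_csv` writes the mean grid either long
#' (`space, reducer, metric, value`) or wide (one row per reducer x space,
#' one column per metric).  `write_report` writes a directory with
#' `report.json` (grid, per-seed replicates, config, provenance),
#' both metric tables, and one 2-D embedding CSV per grid cell for
#' scatter plots.
#'
#' @param report a [run_benchmark()] report.
#' @param path output file (for `write_metrics_csv`) or directory.
#' @param format `"long"` or `"wide"`.
#' @return the path, invisibly.
#' @export
write_metrics_csv <- function(report, path, format = c("long", "wide")) {
  stopifnot(inherits(report, "benchmark_report"))
  format <- match.arg(format)
  g <- report$grid
  if (format == "long") {
    metrics <- c("davies_bouldin", "calinski_harabasz", "silhouette", "adjusted_mi")
    long <- do.call(rbind, lapply(metrics, function(m) data.frame(
      space = g$space, reducer = g$reducer, metric = m, value = g[[m]],
      stringsAsFactors = FALSE)))
    utils::write.csv(long, path, row.names = FALSE)
  } else {
    utils::write.csv(g, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(report$config)
  jsonlite::write_json(
    list(grid = report$grid, per_seed = report$per_seed, config = cfg,
         provenance = report$provenance),
    file.path(path, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null", dataframe = "rows")
  write_metrics_csv(report, file.path(path, "metrics_long.csv"), "long")
  write_metrics_csv(report, file.path(path, "metrics_wide.csv"), "wide")
  for (nm in names(report$embeddings)) {
    utils::write.csv(report$embeddings[[nm]],
                     file.path(path, paste0("embedding_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}
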