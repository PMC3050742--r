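#' Create random training/test splits
#'
#' Each split holds out \code{test_size} labelled compounds, redrawn until
#' every interaction class has at least one test compound. Compounds with
#' unknown interaction always stay in the training set (they are never
#' queries).
#'
#' @param records Compound data frame.
#' @param n_splits Number of independent splits (default 5).
#' @param test_size Test-set size (default 60).
#' @param seed RNG seed.
#' @return List of splits, each a list with \code{split_index},
#'   \code{train} and \code{test} id vectors.
#' @export
make_splits <- function(records, n_splits = 5, test_size = 60, seed = 1) {
  known <- lengths(records$labels) > 0
  present <- interaction_labels()[vapply(interaction_labels(), function(L)
    any(vapply(records$labels[known], function(v) L %in% v, TRUE)), TRUE)]
  absent <- setdiff(interaction_labels(), present)
  if (length(absent) > 0)
    stop("no labelled compound for class(es): ",
         paste(absent, collapse = ", "))
  if (sum(known) < test_size)
    stop("fewer labelled compounds (", sum(known), ") than test_size (",
         test_size, ")")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  labelled_ids <- records$compound_id[known]
  labs <- records$labels[known]
  lapply(seq_len(n_splits), function(s) {
    for (try in 1:10000) {
      test <- sort(sample(labelled_ids, test_size))
      tl <- labs[match(test, labelled_ids)]
      covered <- vapply(interaction_labels(), function(L)
        any(vapply(tl, function(v) L %in% v, TRUE)), TRUE)
      if (all(covered))
        return(list(split_index = s, test = test,
                    train = setdiff(records$compound_id, test)))
    }
    stop("could not draw a test set covering every class")
  })
}

#' Protocol configuration
#'
#' Defaults mirror the full study protocol: all seven descriptor sets,
#' five random splits with 60-compound test sets, five clustering seeds
#' per split (drawn once per split and reused across descriptor sets),
#' predominance levels 50%/66.6%/75%, minimum cluster sizes 1..5, all
#' three nearest-cluster rules, no threshold and the 0.7 similarity
#' threshold, and both unknown-handling modes. Every field can be narrowed
#' for smaller runs.
#'
#' @param descriptor_sets Subset of [descriptor_sets()].
#' @param n_splits,test_size Split layout (see [make_splits()]).
#' @param n_cluster_seeds Clustering seed compounds per split.
#' @param levels,min_sizes,methods,thresholds,include_unknown Prediction
#'   grid; \code{NA} in \code{thresholds} means no similarity abstention.
#' @param baseline_reps Monte Carlo repetitions of the random baseline.
#' @param n_max_cap Upper bound of the avg-s cluster-count grid; the
#'   effective grid is \code{min(n_max_cap, floor(n_train/2))}.
#' @param partition_similarity Compute the run-by-run partition similarity
#'   matrix.
#' @return Object of class \code{"protocol_config"}.
#' @export
protocol_config <- function(descriptor_sets = moaclust::descriptor_sets(),
                            n_splits = 5, test_size = 60,
                            n_cluster_seeds = 5,
                            levels = c(0.5, 2/3, 0.75),
                            min_sizes = 1:5,
                            methods = c("MOST_SIMILAR_COMPOUND",
                                        "CLUSTER_CENTRE",
                                        "AVERAGE_SIMILARITY"),
                            thresholds = c(NA, 0.7),
                            include_unknown = c(TRUE, FALSE),
                            baseline_reps = 100,
                            n_max_cap = 200,
                            partition_similarity = TRUE) {
  structure(list(descriptor_sets = match.arg(descriptor_sets,
                                             moaclust::descriptor_sets(),
                                             several.ok = TRUE),
                 n_splits = n_splits, test_size = test_size,
                 n_cluster_seeds = n_cluster_seeds, levels = levels,
                 min_sizes = min_sizes, methods = methods,
                 thresholds = thresholds,
                 include_unknown = include_unknown,
                 baseline_reps = baseline_reps, n_max_cap = n_max_cap,
                 partition_similarity = partition_similarity),
            class = "protocol_config")
}

#' Run the full clustering / prediction protocol
#'
#' For every (split, descriptor set, clustering seed) combination: build
#' the training similarity matrix, choose the cluster count from the
#' avg-s curve, partition, annotate, classify every test query under the
#' whole prediction grid, and compute the random baseline. Results are
#' aggregated across the runs of each descriptor set; optionally the
#' pairwise partition similarity of all runs is recorded (cross-split
#' pairs are compared on their shared compounds).
#'
#' @param records Compound data frame (the whole library).
#' @param fingerprints Optional precomputed sparse fingerprints (named by
#'   compound id) for fingerprint-space libraries.
#' @param config A [protocol_config()].
#' @param seed Master RNG seed; splits, clustering-seed draws, and
#'   baseline draws all derive from it.
#' @return Object of class \code{"moa_protocol"}: list with \code{runs}
#'   (per-run cluster sets and curves), \code{predominance},
#'   \code{metrics} (per-run prediction metrics), \code{aggregated}
#'   (mean/sd across runs), \code{baselines}, \code{partition_similarity},
#'   \code{manifest} and \code{warnings}.
#' @export
run_protocol <- function(records, fingerprints = NULL,
                         config = protocol_config(), seed = 1) {
  stopifnot(inherits(config, "protocol_config"))
  splits <- make_splits(records, config$n_splits, config$test_size,
                        seed = seed)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed + 1000003)
  seed_compounds <- lapply(splits, function(sp)
    sample(sp$train, config$n_cluster_seeds))
  need_chem <- any(config$descriptor_sets != "ECFP4") || is.null(fingerprints)
  mols <- NULL
  if (need_chem && !any(is.na(records$smiles)))
    mols <- parse_smiles_batch(records$smiles, records$compound_id)
  runs <- list()
  metrics <- list()
  predominance <- list()
  baselines <- list()
  warns <- character(0)
  manifest <- list()
  for (ds in config$descriptor_sets) {
    desc_full <- describe_library(records, ds, fingerprints = fingerprints,
                                  mols = mols)
    for (sp in splits) {
      tr_idx <- match(sp$train, records$compound_id)
      train_rec <- records[tr_idx, , drop = FALSE]
      desc_train <- .subset_desc(desc_full, sp$train)
      desc_test <- .subset_desc(desc_full, sp$test)
      scaling <- descriptor_scaling(desc_train)
      sim_train <- similarity_matrix(desc_train, scaling)
      qsim <- t(cross_similarity(desc_test, desc_train, scaling))
      n_max <- max(2, min(config$n_max_cap, floor(length(sp$train) / 2)))
      for (si in seq_len(config$n_cluster_seeds)) {
        seed_cpd <- seed_compounds[[sp$split_index]][si]
        run_id <- sprintf("%s|split%d|seed%d", ds, sp$split_index, si)
        curve <- withCallingHandlers(
          choose_cluster_count(sim_train, n_max, seed_cpd),
          warning = function(w) {
            warns <<- c(warns, paste0(run_id, ": ", conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        chosen <- attr(curve, "chosen_n")
        cs <- partition_by_centers(sim_train,
                                   attr(curve, "centers")[seq_len(chosen)],
                                   set_id = ds, seed_index = si)
        runs[[run_id]] <- list(run_id = run_id, descriptor_set = ds,
                               split = sp$split_index, seed_index = si,
                               seed_compound = seed_cpd,
                               curve = curve, cluster_set = cs)
        manifest[[run_id]] <- data.frame(
          run_id = run_id, descriptor_set = ds, split = sp$split_index,
          seed_index = si, seed_compound = seed_cpd, n_clusters = chosen,
          master_seed = seed, stringsAsFactors = FALSE)
        for (mode in config$include_unknown) {
          for (lv in config$levels) {
            predominance[[length(predominance) + 1]] <- cbind(
              run_id = run_id, descriptor_set = ds, split = sp$split_index,
              seed_index = si,
              predominance_summary(cs, records, levels = lv,
                                   min_sizes = config$min_sizes,
                                   include_unknown = mode))
          }
          for (ms in config$min_sizes) {
            for (lv in config$levels) {
              bl_cfg <- prediction_config(method = "CLUSTER_CENTRE",
                                          min_cluster_size = ms, level = lv,
                                          include_unknown = mode)
              bl <- random_baseline(cs, records, sp$test, bl_cfg,
                                    reps = config$baseline_reps,
                                    seed = (seed + 7 * sp$split_index +
                                              13 * si) %% 2147483647)
              baselines[[length(baselines) + 1]] <- data.frame(
                run_id = run_id, descriptor_set = ds,
                split = sp$split_index, seed_index = si,
                include_unknown = mode, level = lv, min_size = ms,
                baseline_analytic = bl$analytic,
                baseline_monte_carlo = bl$monte_carlo,
                stringsAsFactors = FALSE)
              for (method in config$methods) {
                for (th in config$thresholds) {
                  cfg <- prediction_config(method = method,
                                           min_cluster_size = ms,
                                           level = lv,
                                           similarity_threshold = th,
                                           include_unknown = mode)
                  res <- classify_queries(qsim, cs, records, cfg, sim_train)
                  ev <- evaluate_predictions(res)
                  metrics[[length(metrics) + 1]] <- data.frame(
                    run_id = run_id, descriptor_set = ds,
                    split = sp$split_index, seed_index = si,
                    method = method, min_size = ms, level = lv,
                    threshold = th, include_unknown = mode,
                    pct_correct_all = ev$pct_correct_all,
                    pct_correct_predicted = ev$pct_correct_predicted,
                    n_predicted = ev$n_predicted,
                    n_queries = ev$n_queries,
                    stringsAsFactors = FALSE)
                }
              }
            }
          }
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  predominance <- do.call(rbind, predominance)
  baselines <- do.call(rbind, baselines)
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  aggregated <- .aggregate_metrics(metrics)
  psim <- NULL
  if (config$partition_similarity && length(runs) > 1) {
    rn <- names(runs)
    psim <- matrix(1, length(rn), length(rn), dimnames = list(rn, rn))
    for (i in seq_along(rn)) {
      ai <- runs[[i]]$cluster_set$assignment
      for (j in seq_len(i - 1)) {
        aj <- runs[[j]]$cluster_set$assignment
        shared <- intersect(names(ai), names(aj))
        v <- cluster_set_similarity(ai[shared], aj[shared])
        psim[i, j] <- psim[j, i] <- v
      }
    }
  }
  structure(list(runs = runs, metrics = metrics,
                 predominance = predominance, baselines = baselines,
                 aggregated = aggregated, partition_similarity = psim,
                 manifest = manifest, warnings = warns,
                 splits = splits, config = config, seed = seed),
            class = "moa_protocol")
}

.subset_desc <- function(desc, ids) {
  stopifnot(all(ids %in% desc$ids))
  structure(list(set_id = desc$set_id, ids = ids,
                 fp = if (!is.null(desc$fp)) desc$fp[match(ids, desc$ids)],
                 blocks = if (!is.null(desc$blocks))
                   lapply(desc$blocks, function(m) m[ids, , drop = FALSE])),
            class = "descriptor_matrix")
}

.aggregate_metrics <- function(metrics) {
  key <- c("descriptor_set", "method", "min_size", "level", "threshold",
           "include_unknown")
  ## aggregate() drops NA grouping values; encode "no threshold" as -1
  metrics$threshold[is.na(metrics$threshold)] <- -1
  agg_mean <- stats::aggregate(
    metrics[c("pct_correct_all", "pct_correct_predicted", "n_predicted")],
    metrics[key], function(x) mean(x, na.rm = TRUE))
  agg_sd <- stats::aggregate(
    metrics[c("pct_correct_all", "n_predicted")],
    metrics[key], function(x) stats::sd(x, na.rm = TRUE))
  names(agg_sd)[names(agg_sd) == "pct_correct_all"] <- "sd_pct_correct_all"
  names(agg_sd)[names(agg_sd) == "n_predicted"] <- "sd_n_predicted"
  agg <- merge(agg_mean, agg_sd, by = key, sort = TRUE)
  agg$n_runs <- stats::aggregate(metrics$pct_correct_all, metrics[key],
                                 length)$x
  agg <- agg[do.call(order, unname(as.list(agg[key]))), , drop = FALSE]
  agg$threshold[agg$threshold == -1] <- NA
  rownames(agg) <- NULL
  agg
}

#' @export
print.moa_protocol <- function(x, ...) {
  cat("Protocol bundle: ", length(x$runs), " clustering runs (",
      length(unique(x$manifest$descriptor_set)), " descriptor sets x ",
      length(x$splits), " splits x ",
      max(x$manifest$seed_index), " seeds)\n", sep = "")
  cat("  ", nrow(x$metrics), " prediction-metric rows; ",
      length(x$warnings), " run warnings\n", sep = "")
  invisible(x)
}

#' Write the protocol report
#'
#' Serializes a protocol bundle to CSVs: the per-run and aggregated
#' prediction metrics, the predominance summaries, the query counts under
#' the similarity threshold by descriptor set and minimum cluster size,
#' the random baselines, the avg-s curves, the partition-similarity
#' matrix, and a run manifest with every seed.
#'
#' @param bundle A \code{"moa_protocol"}.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "moa_protocol"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    files <<- c(files, path)
  }
  wr(bundle$metrics, "prediction_metrics_by_run.csv")
  wr(bundle$aggregated, "prediction_metrics.csv")
  wr(bundle$predominance, "predominance_summary.csv")
  wr(bundle$baselines, "random_baselines.csv")
  wr(bundle$manifest, "manifest.csv")
  ## threshold query counts (mean n_predicted by descriptor x min size)
  th <- bundle$metrics[!is.na(bundle$metrics$threshold), , drop = FALSE]
  if (nrow(th) > 0) {
    tq <- stats::aggregate(th["n_predicted"],
                           th[c("descriptor_set", "min_size", "threshold")],
                           mean)
    tq <- tq[order(tq$descriptor_set, tq$min_size), ]
    wr(tq, "threshold_query_counts.csv")
  }
  curves <- do.call(rbind, lapply(bundle$runs, function(r)
    data.frame(run_id = r$run_id, n = r$curve$n, avg_s = r$curve$avg_s,
               drop = r$curve$drop, chosen = r$curve$n == attr(r$curve, "chosen_n"),
               stringsAsFactors = FALSE)))
  rownames(curves) <- NULL
  wr(curves, "avg_s_curves.csv")
  if (!is.null(bundle$partition_similarity)) {
    ps <- data.frame(run_id = rownames(bundle$partition_similarity),
                     bundle$partition_similarity, check.names = FALSE)
    wr(ps, "partition_similarity.csv")
  }
  if (length(bundle$warnings) > 0)
    writeLines(bundle$warnings, file.path(outdir, "run_warnings.txt"))
  invisible(files)
}
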