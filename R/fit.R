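#' Cluster a labelled compound library for mechanism-of-action prediction
#'
#' The central fitting function. Computes the descriptor representation of
#' the library, the pairwise similarity matrix, selects cluster
#' representatives by maximal dissimilarity from a seed compound, chooses
#' the cluster count by the biggest avg-s drop (unless fixed), partitions
#' the library, and annotates every cluster with its interaction-label
#' profile. The fitted object classifies new compounds with
#' \code{predict()}.
#'
#' @param records Training compound data frame (see [read_library()]);
#'   unlabelled compounds are allowed and handled by the unknown mode at
#'   prediction time.
#' @param descriptor_set One of [descriptor_sets()].
#' @param fingerprints Optional precomputed sparse fingerprints (named list
#'   by compound id) for fingerprint-space libraries without SMILES.
#' @param seed_compound Id of the MaxMin seed compound; default: first
#'   compound of the library.
#' @param n_max Largest cluster count on the avg-s grid; default
#'   \code{min(200, floor(N/2))} (the protocol's cap of 200 corresponds to
#'   an average of two compounds per cluster on a ~400-compound training
#'   set, and is scaled down with the library).
#' @param n_clusters Fix the cluster count instead of choosing it from the
#'   avg-s curve.
#' @param mols Optional pre-parsed structures (see [describe_library()]).
#' @return Object of class \code{"moa_cluster"} with the descriptor matrix,
#'   frozen scaling, similarity matrix, avg-s curve, cluster set and
#'   per-cluster profiles.
#' @seealso [predict.moa_cluster()], [predominance_summary()]
#' @export
moa_cluster <- function(records, descriptor_set = "ECFP4_PROPERTY",
                        fingerprints = NULL, seed_compound = NULL,
                        n_max = NULL, n_clusters = NULL, mols = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 2)
  descriptor_set <- match.arg(descriptor_set, descriptor_sets())
  desc <- describe_library(records, descriptor_set,
                           fingerprints = fingerprints, mols = mols)
  scaling <- descriptor_scaling(desc)
  sim <- similarity_matrix(desc, scaling)
  if (is.null(seed_compound)) seed_compound <- records$compound_id[1]
  curve <- NULL
  if (is.null(n_clusters)) {
    if (is.null(n_max))
      n_max <- max(2, min(200, floor(nrow(records) / 2)))
    curve <- choose_cluster_count(sim, n_max, seed_compound)
    n_clusters <- attr(curve, "chosen_n")
    centers <- attr(curve, "centers")[seq_len(n_clusters)]
  } else {
    stopifnot(n_clusters >= 1, n_clusters <= nrow(records))
    centers <- select_centers(sim, n_clusters, seed_compound)
  }
  cs <- partition_by_centers(sim, centers, set_id = descriptor_set)
  profiles <- lapply(cs$members, label_profile, records = records,
                     include_unknown = TRUE)
  structure(list(records = records, descriptor_set = descriptor_set,
                 desc = desc, scaling = scaling, sim = sim,
                 seed_compound = seed_compound, avg_s_curve = curve,
                 cluster_set = cs, profiles = profiles),
            class = "moa_cluster")
}

#' @export
print.moa_cluster <- function(x, ...) {
  sizes <- lengths(x$cluster_set$members)
  cat("Maximal-dissimilarity clustering [", x$descriptor_set, "]\n", sep = "")
  cat("  ", nrow(x$records), " compounds, ", x$cluster_set$n_clusters,
      " clusters (", sum(sizes >= 2), " non-singleton)\n", sep = "")
  if (!is.null(x$avg_s_curve))
    cat("  cluster count chosen from the avg-s curve over n = 1..",
        nrow(x$avg_s_curve), "\n", sep = "")
  cat("  seed compound: ", x$seed_compound, "\n", sep = "")
  invisible(x)
}

#' @export
summary.moa_cluster <- function(object, level = 2/3, min_size = 2,
                                include_unknown = TRUE, ...) {
  ps <- predominance_summary(object$cluster_set, object$records,
                             levels = level, min_sizes = min_size,
                             include_unknown = include_unknown)
  sizes <- lengths(object$cluster_set$members)
  out <- list(descriptor_set = object$descriptor_set,
              n_compounds = nrow(object$records),
              n_unknown = sum(lengths(object$records$labels) == 0),
              n_clusters = object$cluster_set$n_clusters,
              n_non_singleton = sum(sizes >= 2),
              avg_s = avg_self_similarity(object$cluster_set, object$sim),
              predominance = ps)
  class(out) <- "summary.moa_cluster"
  out
}

#' @export
print.summary.moa_cluster <- function(x, ...) {
  cat("Maximal-dissimilarity clustering [", x$descriptor_set, "]\n", sep = "")
  cat(sprintf("  %d compounds (%d with unknown interaction)\n",
              x$n_compounds, x$n_unknown))
  cat(sprintf("  %d clusters, %d non-singleton; avg-s = %.3f\n",
              x$n_clusters, x$n_non_singleton, x$avg_s))
  p <- x$predominance
  cat(sprintf("  %.1f%% of the %d clusters of size >= %d have one interaction at >= %.1f%%\n",
              p$pct_clusters_predominant[1], p$n_clusters_eligible[1],
              p$min_size[1], 100 * p$level[1]))
  invisible(x)
}

#' Predict the pathway interaction of query compounds
#'
#' Computes the queries' descriptors under the fitted descriptor set (with
#' the training set's frozen scaling), finds each query's nearest
#' size-eligible cluster by the configured search rule, and transfers the
#' cluster's predominant interaction label, abstaining below the
#' similarity threshold or when no label predominates.
#'
#' @param object A fitted \code{"moa_cluster"}.
#' @param newdata Query compound data frame.
#' @param fingerprints Optional precomputed query fingerprints.
#' @param method,min_size,level,threshold,include_unknown Prediction knobs,
#'   see [prediction_config()].
#' @param ... Unused.
#' @return Data frame from [classify_queries()].
#' @export
predict.moa_cluster <- function(object, newdata, fingerprints = NULL,
                                method = "CLUSTER_CENTRE", min_size = 1,
                                level = 2/3, threshold = NA_real_,
                                include_unknown = TRUE, ...) {
  qdesc <- describe_library(newdata, object$descriptor_set,
                            fingerprints = fingerprints)
  qsim <- t(cross_similarity(qdesc, object$desc, object$scaling))
  cfg <- prediction_config(method = method, min_cluster_size = min_size,
                           level = level, similarity_threshold = threshold,
                           include_unknown = include_unknown)
  ## records for classification: training records + query labels (if any)
  q <- data.frame(compound_id = newdata$compound_id, stringsAsFactors = FALSE)
  q$labels <- if ("labels" %in% names(newdata)) newdata$labels else
    rep(list(character(0)), nrow(newdata))
  tr <- data.frame(compound_id = object$records$compound_id,
                   stringsAsFactors = FALSE)
  tr$labels <- object$records$labels
  allrec <- rbind(tr, q)
  classify_queries(qsim, object$cluster_set, allrec, cfg, object$sim)
}

#' Plot the avg-s model-selection curve
#'
#' Average within-cluster self-similarity against the number of clusters,
#' with the chosen cluster count marked.
#'
#' @param x A fitted \code{"moa_cluster"}.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.moa_cluster <- function(x, ...) {
  if (is.null(x$avg_s_curve))
    stop("model was fitted with a fixed cluster count; no avg-s curve")
  cv <- x$avg_s_curve
  graphics::plot(cv$n, cv$avg_s, type = "l", xlab = "number of clusters n",
                 ylab = "avg-s", ...)
  chosen <- attr(cv, "chosen_n")
  graphics::abline(v = chosen, lty = 2)
  graphics::points(chosen, cv$avg_s[chosen], pch = 19)
  invisible(x)
}
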