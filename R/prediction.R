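#' Prediction configuration
#'
#' Bundles the knobs of nearest-cluster classification: the cluster search
#' rule, the minimum cluster size, the predominance level required to
#' transfer a label, the optional similarity threshold below which no
#' prediction is made, and the unknown-handling mode.
#'
#' @param method One of \code{"MOST_SIMILAR_COMPOUND"} (cluster holding the
#'   single most similar compound), \code{"CLUSTER_CENTRE"} (similarity to
#'   the cluster medoid) or \code{"AVERAGE_SIMILARITY"} (mean similarity to
#'   the cluster members).
#' @param min_cluster_size Only clusters with at least this many members
#'   are searched (1..5 in the protocol; 1 admits singletons).
#' @param level Predominance level required of the nearest cluster.
#' @param similarity_threshold Abstain when the best cluster similarity is
#'   below this value (\code{NA} = no similarity abstention). The
#'   comparison is inclusive: a score equal to the threshold predicts.
#' @param include_unknown Unknown-handling mode; when \code{FALSE},
#'   compounds with unknown interaction are omitted from cluster sizes,
#'   profiles and similarity scoring.
#' @return Object of class \code{"prediction_config"}.
#' @export
prediction_config <- function(method = c("CLUSTER_CENTRE",
                                         "MOST_SIMILAR_COMPOUND",
                                         "AVERAGE_SIMILARITY"),
                              min_cluster_size = 1,
                              level = 2/3,
                              similarity_threshold = NA_real_,
                              include_unknown = TRUE) {
  method <- match.arg(method)
  stopifnot(min_cluster_size >= 1, level > 0, level <= 1,
            is.na(similarity_threshold) ||
              (similarity_threshold >= 0 && similarity_threshold <= 1))
  structure(list(method = method,
                 min_cluster_size = as.integer(min_cluster_size),
                 level = level,
                 similarity_threshold = similarity_threshold,
                 include_unknown = include_unknown),
            class = "prediction_config")
}

## members considered for scoring/annotation under the unknown mode
.mode_members <- function(cs, records, include_unknown) {
  if (include_unknown) return(cs$members)
  lapply(cs$members, function(m) {
    labs <- .labels_of(records, m)
    m[lengths(labs) > 0]
  })
}

## cluster score matrix (clusters x queries) for one search rule
.cluster_scores <- function(qsim, members, sim_train, method) {
  K <- length(members)
  out <- matrix(NA_real_, K, ncol(qsim))
  for (k in seq_len(K)) {
    m <- members[[k]]
    if (length(m) == 0) next
    block <- qsim[m, , drop = FALSE]
    out[k, ] <- switch(method,
      MOST_SIMILAR_COMPOUND = apply(block, 2, max),
      AVERAGE_SIMILARITY = colMeans(block),
      CLUSTER_CENTRE = qsim[cluster_medoid(m, sim_train), ])
  }
  out
}

#' Nearest cluster of a query compound
#'
#' Scores every size-eligible cluster by the configured search rule and
#' returns the best cluster with its score; ties go to the lower cluster
#' index. Returns \code{NULL} when no cluster passes the size filter.
#'
#' @param qsim Named numeric vector: similarity of the query to every
#'   training compound.
#' @param cs A \code{"cluster_set"} over the training compounds.
#' @param records Compound data frame (for the unknown mode).
#' @param cfg A [prediction_config()].
#' @param sim_train Training similarity matrix (needed for the medoid rule).
#' @return List with \code{cluster} (index) and \code{similarity}, or
#'   \code{NULL}.
#' @export
nearest_cluster <- function(qsim, cs, records, cfg, sim_train) {
  members <- .mode_members(cs, records, cfg$include_unknown)
  sizes <- lengths(members)
  elig <- which(sizes >= cfg$min_cluster_size)
  if (length(elig) == 0) return(NULL)
  scores <- .cluster_scores(matrix(qsim[colnames(sim_train)], ncol = 1,
                                   dimnames = list(colnames(sim_train), NULL)),
                            members[elig], sim_train, cfg$method)[, 1]
  best <- which.max(scores)             # ties: lower cluster index
  list(cluster = elig[best], similarity = scores[best])
}

#' Classify query compounds by their nearest cluster
#'
#' Applies the full prediction rule to each query: find the nearest
#' size-eligible cluster, abstain if its similarity is below the threshold
#' or if it has no predominant label at the configured level, otherwise
#' transfer the predominant label.
#'
#' @param qsim_mat Similarity matrix, training compounds x queries
#'   (or queries in columns of a \code{t(cross_similarity(...))}).
#' @param cs A \code{"cluster_set"}.
#' @param records Compound data frame covering training compounds (and the
#'   queries, if their correctness is to be evaluated later).
#' @param cfg A [prediction_config()].
#' @param sim_train Training similarity matrix.
#' @return Data frame, one row per query: \code{query_id},
#'   \code{cluster_index}, \code{similarity}, \code{predicted}
#'   (\code{"ABSTAIN"} or a label), \code{correct} (logical; \code{NA} for
#'   queries without known labels).
#' @export
classify_queries <- function(qsim_mat, cs, records, cfg, sim_train) {
  stopifnot(inherits(cs, "cluster_set"), inherits(cfg, "prediction_config"))
  queries <- colnames(qsim_mat)
  members <- .mode_members(cs, records, cfg$include_unknown)
  sizes <- lengths(members)
  elig <- which(sizes >= cfg$min_cluster_size)
  out <- data.frame(query_id = queries,
                    cluster_index = NA_integer_,
                    similarity = NA_real_,
                    predicted = "ABSTAIN",
                    correct = NA,
                    stringsAsFactors = FALSE)
  if (length(elig) > 0) {
    scores <- .cluster_scores(qsim_mat[colnames(sim_train), , drop = FALSE],
                              members[elig], sim_train, cfg$method)
    best <- apply(scores, 2, which.max)
    best_sim <- scores[cbind(best, seq_along(queries))]
    pred_label <- vapply(elig, function(k) {
      if (sizes[k] == 0) return(NA_character_)
      predominant_label(label_profile(members[[k]], records,
                                      cfg$include_unknown), cfg$level)
    }, "")
    lab <- pred_label[best]
    keep <- !is.na(lab)
    if (!is.na(cfg$similarity_threshold))
      keep <- keep & best_sim >= cfg$similarity_threshold - 1e-12
    out$cluster_index <- elig[best]
    out$similarity <- best_sim
    out$predicted[keep] <- lab[keep]
  }
  qlabs <- tryCatch(.labels_of(records, queries), error = function(e) NULL)
  if (!is.null(qlabs)) {
    known <- lengths(qlabs) > 0
    out$correct[known] <- mapply(function(p, truth)
      p != "ABSTAIN" && p %in% truth,
      out$predicted[known], qlabs[known])
  }
  out
}

#' Evaluate a set of predictions
#'
#' The primary metric counts abstentions as incorrect (percentage correct
#' over all queries, as in the protocol's summary figures); the percentage
#' correct among the queries that received a prediction and the number of
#' predicted queries are reported alongside.
#'
#' @param results Data frame from [classify_queries()]; every query must
#'   have known labels.
#' @param records Compound data frame (unused except for validation;
#'   kept for symmetry).
#' @return List with \code{pct_correct_all}, \code{pct_correct_predicted}
#'   (\code{NA} if everything abstained), \code{n_predicted} and
#'   \code{n_queries}. Percentages are on the 0-100 scale.
#' @export
evaluate_predictions <- function(results, records = NULL) {
  if (nrow(results) == 0) stop("no queries to evaluate")
  if (anyNA(results$correct))
    stop("all queries must have known labels for evaluation")
  predicted <- results$predicted != "ABSTAIN"
  list(pct_correct_all = 100 * mean(results$correct),
       pct_correct_predicted = if (any(predicted))
         100 * mean(results$correct[predicted]) else NA_real_,
       n_predicted = sum(predicted),
       n_queries = nrow(results))
}

#' Random-assignment baseline
#'
#' Assigns each query a cluster drawn uniformly from the size-eligible
#' clusters and applies the same predominance rule, estimating the
#' percentage of correct assignments by Monte Carlo and, alongside,
#' computing the analytic expectation
#' \eqn{100 \sum_L f(L) q(L)} where \eqn{f(L)} is the fraction of eligible
#' clusters whose predominant label is \eqn{L} and \eqn{q(L)} the fraction
#' of queries carrying \eqn{L}.
#'
#' @param cs A \code{"cluster_set"}.
#' @param records Compound data frame.
#' @param query_ids Ids of the (labelled) query compounds.
#' @param cfg A [prediction_config()].
#' @param reps Monte Carlo repetitions (>= 1).
#' @param seed RNG seed for the draws.
#' @return List with \code{analytic}, \code{monte_carlo} (both percentages)
#'   and \code{reps}; zero when no cluster is eligible.
#' @export
random_baseline <- function(cs, records, query_ids, cfg, reps = 100,
                            seed = 1) {
  stopifnot(reps >= 1)
  members <- .mode_members(cs, records, cfg$include_unknown)
  sizes <- lengths(members)
  elig <- which(sizes >= cfg$min_cluster_size)
  if (length(elig) == 0)
    return(list(analytic = 0, monte_carlo = 0, reps = reps))
  pred_label <- vapply(elig, function(k)
    predominant_label(label_profile(members[[k]], records,
                                    cfg$include_unknown), cfg$level), "")
  qlabs <- .labels_of(records, query_ids)
  if (any(lengths(qlabs) == 0))
    stop("query compounds must have known labels")
  f <- vapply(interaction_labels(), function(L)
    mean(!is.na(pred_label) & pred_label == L), 0)
  q <- vapply(interaction_labels(), function(L)
    mean(vapply(qlabs, function(v) L %in% v, TRUE)), 0)
  analytic <- 100 * sum(f * q)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  hits <- 0
  for (r in seq_len(reps)) {
    draw <- pred_label[sample.int(length(elig), length(query_ids),
                                  replace = TRUE)]
    hits <- hits + sum(!is.na(draw) &
                         mapply(function(p, truth) p %in% truth, draw, qlabs))
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(analytic = analytic,
       monte_carlo = 100 * hits / (reps * length(query_ids)),
       reps = reps)
}
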