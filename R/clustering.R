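.check_sim <- function(sim) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim),
            !is.null(rownames(sim)))
  invisible(rownames(sim))
}

#' Select cluster representatives by maximal dissimilarity
#'
#' Greedy MaxMin selection: starting from a seed compound, each subsequent
#' representative is the compound whose maximum similarity to the already
#' chosen representatives is smallest (i.e. the most dissimilar compound).
#' Ties are broken by input order. The greedy sequence is nested: the first
#' \eqn{n} centers of a longer run are the centers of the shorter run.
#'
#' @param sim Symmetric similarity matrix with compound ids as dimnames.
#' @param n_max Number of representatives to select (1..N).
#' @param seed_compound Compound id of the first representative.
#' @return Character vector of center ids in selection order.
#' @export
select_centers <- function(sim, n_max, seed_compound) {
  ids <- .check_sim(sim)
  n <- length(ids)
  if (n_max < 1 || n_max > n)
    stop("n_max must be between 1 and ", n)
  s0 <- match(seed_compound, ids)
  if (is.na(s0)) stop("seed compound not in similarity matrix: ",
                      seed_compound)
  centers <- integer(n_max)
  centers[1] <- s0
  if (n_max > 1) {
    maxsim <- sim[, s0]
    maxsim[s0] <- Inf
    for (k in 2:n_max) {
      nxt <- which.min(maxsim)          # ties: lowest index
      centers[k] <- nxt
      maxsim <- pmax(maxsim, sim[, nxt])
      maxsim[nxt] <- Inf
    }
  }
  ids[centers]
}

#' Partition a library around fixed cluster representatives
#'
#' Every compound joins the representative of maximal similarity; ties go
#' to the earliest representative in selection order, and representatives
#' always belong to their own cluster.
#'
#' @param sim Symmetric similarity matrix with compound ids as dimnames.
#' @param centers Ordered character vector of representative ids.
#' @param set_id Optional descriptor-set tag carried on the result.
#' @param seed_index Optional clustering-seed index carried on the result.
#' @return Object of class \code{"cluster_set"}: list with \code{centers},
#'   named integer \code{assignment} (compound id to cluster index),
#'   \code{members} (list of id vectors) and \code{n_clusters}.
#' @export
partition_by_centers <- function(sim, centers, set_id = NA_character_,
                                 seed_index = NA_integer_) {
  ids <- .check_sim(sim)
  if (length(centers) < 1) stop("centers must be non-empty")
  ci <- match(centers, ids)
  if (anyNA(ci)) stop("center id(s) not in similarity matrix: ",
                      paste(centers[is.na(ci)], collapse = ", "))
  smat <- sim[, ci, drop = FALSE]
  assignment <- max.col(smat, ties.method = "first")
  assignment[ci] <- seq_along(ci)       # centers belong to themselves
  names(assignment) <- ids
  members <- split(ids, factor(assignment, levels = seq_along(ci)))
  names(members) <- NULL
  structure(list(set_id = set_id, seed_index = seed_index,
                 seed_compound = centers[1], centers = centers,
                 assignment = assignment, members = members,
                 n_clusters = length(centers)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$members)
  cat("Cluster set: ", x$n_clusters, " clusters over ",
      length(x$assignment), " compounds (", sum(sizes == 1),
      " singletons)", if (!is.na(x$set_id)) paste0(" [", x$set_id, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Average within-cluster self-similarity (avg-s)
#'
#' Mean over clusters of the mean pairwise within-cluster similarity;
#' a singleton's self-similarity is 1 by convention.
#'
#' @param cs A \code{"cluster_set"} (or a named assignment vector).
#' @param sim Similarity matrix consistent with \code{cs}.
#' @return The avg-s value.
#' @export
avg_self_similarity <- function(cs, sim) {
  assignment <- if (inherits(cs, "cluster_set")) cs$assignment else cs
  ids <- .check_sim(sim)
  stopifnot(all(names(assignment) %in% ids))
  vals <- vapply(split(names(assignment), assignment), function(m) {
    k <- length(m)
    if (k == 1) return(1)
    s <- sim[m, m]
    (sum(s) - k) / (k * (k - 1))
  }, 0)
  mean(vals)
}

#' Choose the cluster count by the biggest avg-s drop
#'
#' Runs one nested MaxMin selection to \code{n_max} centers, computes the
#' avg-s curve for every prefix \eqn{n = 1..n_{max}}, and chooses the
#' \eqn{n \ge 2} with the largest decrease in avg-s between \eqn{n-1} and
#' \eqn{n} clusters (ties: smallest \eqn{n}). If no decrease exists
#' anywhere on the curve, the \eqn{n} with the smallest increase is
#' returned with a warning.
#'
#' @param sim Symmetric similarity matrix with compound ids as dimnames.
#' @param n_max Largest cluster count on the grid (>= 2).
#' @param seed_compound Seed compound id for the MaxMin selection.
#' @return Object of class \code{"avg_s_curve"}: data frame columns
#'   \code{n}, \code{avg_s}, \code{drop}, plus attributes \code{chosen_n},
#'   \code{centers} (full selection order) and \code{seed_compound}.
#' @export
choose_cluster_count <- function(sim, n_max, seed_compound) {
  ids <- .check_sim(sim)
  stopifnot(n_max >= 2)
  centers <- select_centers(sim, n_max, seed_compound)
  ci <- match(centers, ids)
  n <- length(ids)

  ## incremental prefix partitions: track per-compound best (sim, cluster)
  ## and per-cluster pair sums so avg-s costs only the reassigned members
  best <- sim[, ci[1]]
  best[ci[1]] <- Inf
  cl <- rep(1L, n)
  memb <- list(seq_len(n))
  pairsum <- c(sum(sim[ids, ids][lower.tri(sim)]))
  ## (pairsum[1] = sum over unordered pairs of the whole set)
  avg_val <- function(ps, k) if (k <= 1) 1 else ps / (k * (k - 1) / 2)
  avg_s <- numeric(n_max)
  vals <- avg_val(pairsum[1], n)
  avg_s[1] <- vals
  cluster_vals <- c(vals)
  for (k in 2:n_max) {
    ck <- ci[k]
    newsim <- sim[, ck]
    moved <- which(newsim > best)
    moved <- union(moved, ck)           # the center always moves
    ## remove moved members from their old clusters
    for (o in unique(cl[moved])) {
      mo <- moved[cl[moved] == o]
      keep <- setdiff(memb[[o]], mo)
      loss <- sum(sim[mo, keep]) +
        (if (length(mo) > 1) sum(sim[mo, mo][lower.tri(diag(length(mo)))]) else 0)
      pairsum[o] <- pairsum[o] - loss
      memb[[o]] <- keep
      cluster_vals[o] <- avg_val(pairsum[o], length(keep))
    }
    pairsum[k] <- if (length(moved) > 1)
      sum(sim[moved, moved][lower.tri(diag(length(moved)))]) else 0
    memb[[k]] <- moved
    cluster_vals[k] <- avg_val(pairsum[k], length(moved))
    cl[moved] <- k
    best[moved] <- newsim[moved]
    best[ck] <- Inf
    avg_s[k] <- mean(cluster_vals)
  }
  drop <- c(NA, -diff(avg_s))
  cand <- 2:n_max
  chosen <- cand[which.max(drop[cand])]  # ties: smallest n
  if (max(drop[cand]) <= 0)
    warning("avg-s never decreases on the grid; choosing n = ", chosen,
            " (smallest increase)")
  structure(data.frame(n = seq_len(n_max), avg_s = avg_s, drop = drop),
            chosen_n = chosen, centers = centers,
            seed_compound = seed_compound,
            class = c("avg_s_curve", "data.frame"))
}

#' @export
print.avg_s_curve <- function(x, ...) {
  cat("avg-s curve over n = 1..", nrow(x), "; chosen n = ",
      attr(x, "chosen_n"), "\n", sep = "")
  invisible(x)
}

#' Medoid centre of a cluster
#'
#' The member maximizing mean similarity to the other members; a singleton
#' is its own centre; ties go to the earliest member in input order.
#'
#' @param members Character vector of member compound ids.
#' @param sim Similarity matrix covering the members.
#' @return The medoid compound id.
#' @export
cluster_medoid <- function(members, sim) {
  stopifnot(length(members) >= 1)
  if (length(members) == 1) return(members)
  s <- sim[members, members]
  score <- (rowSums(s) - 1) / (length(members) - 1)
  members[which.max(score)]
}

.pair_keys <- function(assignment) {
  ids <- names(assignment)
  pairs <- character(0)
  for (m in split(ids, assignment)) {
    if (length(m) < 2) next
    m <- sort(m)
    cmb <- utils::combn(m, 2)
    pairs <- c(pairs, paste(cmb[1, ], cmb[2, ], sep = "\r"))
  }
  pairs
}

#' Tanimoto similarity of two partitions
#'
#' Pair-counting comparison \eqn{c/(a+b-c)}: \eqn{a} and \eqn{b} are the
#' numbers of compound pairs co-clustered in each partition and \eqn{c} the
#' number co-clustered in both. Two partitions of all singletons (no pairs
#' at all) score 1 by convention.
#'
#' @param p1,p2 \code{"cluster_set"} objects (or named assignment vectors)
#'   over the same compound universe.
#' @return Similarity in \[0, 1\].
#' @export
cluster_set_similarity <- function(p1, p2) {
  a1 <- if (inherits(p1, "cluster_set")) p1$assignment else p1
  a2 <- if (inherits(p2, "cluster_set")) p2$assignment else p2
  if (!setequal(names(a1), names(a2)))
    stop("partitions cover different compound universes")
  a2 <- a2[names(a1)]
  tab <- table(a1, a2)
  n_pairs <- function(x) sum(x * (x - 1) / 2)
  a <- n_pairs(rowSums(tab))
  b <- n_pairs(colSums(tab))
  cc <- n_pairs(tab)
  if (a == 0 && b == 0) return(1)
  cc / (a + b - cc)
}

#' Restrict a partition to a subset of compounds
#'
#' Used to compare partitions of overlapping training sets on their shared
#' compounds. Empty clusters are dropped.
#'
#' @param cs A \code{"cluster_set"} or named assignment vector.
#' @param ids Compound ids to keep.
#' @return Named assignment vector over \code{ids}.
#' @export
restrict_partition <- function(cs, ids) {
  a <- if (inherits(cs, "cluster_set")) cs$assignment else cs
  keep <- intersect(names(a), ids)
  a[keep]
}

#' Serialize a cluster set to CSV
#'
#' Columns \code{compound_id,cluster_index,is_center}.
#'
#' @param cs A \code{"cluster_set"}.
#' @param path Output path.
#' @export
write_cluster_csv <- function(cs, path) {
  df <- data.frame(compound_id = names(cs$assignment),
                   cluster_index = as.integer(cs$assignment),
                   is_center = names(cs$assignment) %in% cs$centers)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
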