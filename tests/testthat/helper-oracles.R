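## Literal re-implementations of the greedy clustering rules, written as
## naive loops, used as independent oracles against the package's
## vectorized/incremental code paths.

oracle_select_centers <- function(sim, n_max, seed_compound) {
  ids <- rownames(sim)
  centers <- seed_compound
  while (length(centers) < n_max) {
    remaining <- setdiff(ids, centers)
    best_id <- NULL
    best_val <- Inf
    for (id in remaining) {            # input order; first win = tie rule
      v <- max(sim[id, centers])
      if (v < best_val) {
        best_val <- v
        best_id <- id
      }
    }
    centers <- c(centers, best_id)
  }
  centers
}

oracle_partition <- function(sim, centers) {
  ids <- rownames(sim)
  assignment <- integer(length(ids))
  names(assignment) <- ids
  for (id in ids) {
    best_k <- NA
    best_val <- -Inf
    for (k in seq_along(centers)) {    # earliest center wins ties
      v <- sim[id, centers[k]]
      if (v > best_val) {
        best_val <- v
        best_k <- k
      }
    }
    assignment[id] <- best_k
  }
  for (k in seq_along(centers)) assignment[centers[k]] <- k
  assignment
}

oracle_avg_s <- function(assignment, sim) {
  vals <- c()
  for (k in unique(assignment)) {
    m <- names(assignment)[assignment == k]
    if (length(m) == 1) {
      vals <- c(vals, 1)
    } else {
      tot <- 0; np <- 0
      for (i in seq_along(m)) for (j in seq_along(m)) if (i < j) {
        tot <- tot + sim[m[i], m[j]]; np <- np + 1
      }
      vals <- c(vals, tot / np)
    }
  }
  mean(vals)
}

## random symmetric similarity matrix; 2-decimal rounding induces ties so
## the tie-break rules get exercised
random_sim_matrix <- function(n) {
  s <- matrix(round(stats::runif(n * n), 2), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(paste0("c", seq_len(n)), paste0("c", seq_len(n)))
  s
}

## build a compound data frame from a named list of label vectors
make_records <- function(labels, smiles = NA_character_) {
  rec <- data.frame(compound_id = names(labels),
                    smiles = rep_len(smiles, length(labels)),
                    stringsAsFactors = FALSE)
  rec$labels <- unname(labels)
  rec
}
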