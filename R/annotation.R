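#' Interaction-label profile of a cluster
#'
#' Counts the interaction labels of a cluster's members. Compounds with
#' more than one interaction increment every one of their labels, so the
#' fractions may sum to more than 1. The denominator is the number of
#' member compounds: all members when unknowns are included, only the
#' labelled members when they are excluded.
#'
#' @param members Character vector of member compound ids (non-empty).
#' @param records Compound data frame with a \code{labels} list column.
#' @param include_unknown Include compounds with unknown interaction in the
#'   denominator (\code{TRUE}) or omit them from the analysis
#'   (\code{FALSE}).
#' @return Object of class \code{"predominance_profile"}: list with
#'   \code{size_total}, \code{size_known}, \code{unknown_count},
#'   \code{label_counts} and \code{fractions} (both named by interaction
#'   class), and the active \code{include_unknown} mode.
#' @export
label_profile <- function(members, records, include_unknown = TRUE) {
  stopifnot(length(members) >= 1)
  labs <- .labels_of(records, members)
  known <- lengths(labs) > 0
  counts <- stats::setNames(integer(length(interaction_labels())),
                            interaction_labels())
  tab <- table(factor(unlist(labs), levels = interaction_labels()))
  counts[names(tab)] <- as.integer(tab)
  denom <- if (include_unknown) length(members) else sum(known)
  fractions <- if (denom > 0) counts / denom else
    stats::setNames(rep(NA_real_, length(counts)), names(counts))
  structure(list(size_total = length(members),
                 size_known = sum(known),
                 unknown_count = sum(!known),
                 label_counts = counts,
                 fractions = fractions,
                 include_unknown = include_unknown),
            class = "predominance_profile")
}

#' @export
print.predominance_profile <- function(x, ...) {
  cat("Cluster profile: ", x$size_total, " compounds (", x$unknown_count,
      " unknown)\n", sep = "")
  f <- x$fractions[x$label_counts > 0]
  if (length(f) > 0)
    for (nm in names(f)) cat(sprintf("  %-26s %d (%.1f%%)\n", nm,
                                     x$label_counts[nm], 100 * f[nm]))
  invisible(x)
}

#' Predominant interaction label of a cluster
#'
#' The unique label whose fraction is maximal and at least \code{level}.
#' Returns \code{NA} when two labels tie for the maximum, when no label
#' reaches the level, or when the profile has no denominator (all members
#' unknown under the exclude-unknown mode). Comparisons use a small
#' absolute tolerance so that an exact 2/3 passes the 66.6% level.
#'
#' @param profile A \code{"predominance_profile"}.
#' @param level Predominance level in (0, 1\], typically 0.5, 2/3 or 0.75.
#' @return Interaction label or \code{NA_character_}.
#' @export
predominant_label <- function(profile, level) {
  stopifnot(inherits(profile, "predominance_profile"))
  f <- profile$fractions
  if (all(is.na(f)) || all(f == 0, na.rm = TRUE)) return(NA_character_)
  mx <- max(f)
  top <- names(f)[f >= mx - 1e-9]
  if (length(top) != 1) return(NA_character_)
  if (mx < level - 1e-9) return(NA_character_)
  top
}

#' Predominance summary of a cluster set
#'
#' For every combination of predominance level and minimum cluster size,
#' the percentage of eligible clusters in which some interaction label
#' reaches the level. Cluster size for the eligibility filter is the total
#' member count when unknowns are included and the labelled member count
#' when they are excluded. Unlabelled clusters (all members unknown) never
#' count as label-predominant; under the include-unknown mode the fraction
#' of unknown-predominant clusters is reported separately.
#'
#' @param cs A \code{"cluster_set"}.
#' @param records Compound data frame.
#' @param levels Predominance levels (default 50%, 66.6%, 75%).
#' @param min_sizes Minimum cluster sizes (default 1:5).
#' @param include_unknown Unknown-handling mode, as in [label_profile()].
#' @return Data frame with columns \code{level}, \code{min_size},
#'   \code{include_unknown}, \code{n_clusters_eligible},
#'   \code{pct_clusters_predominant} (\code{NA} when no cluster passes the
#'   size filter) and \code{pct_unknown_predominant}.
#' @export
predominance_summary <- function(cs, records, levels = c(0.5, 2/3, 0.75),
                                 min_sizes = 1:5, include_unknown = TRUE) {
  stopifnot(inherits(cs, "cluster_set"))
  profiles <- lapply(cs$members, label_profile, records = records,
                     include_unknown = include_unknown)
  sizes <- vapply(profiles, function(p)
    if (include_unknown) p$size_total else p$size_known, 0L)
  max_frac <- vapply(profiles, function(p) {
    f <- p$fractions
    if (all(is.na(f))) NA_real_ else max(f)
  }, 0)
  unk_frac <- vapply(profiles, function(p)
    if (p$size_total > 0) p$unknown_count / p$size_total else NA_real_, 0)
  out <- expand.grid(level = levels, min_size = min_sizes,
                     KEEP.OUT.ATTRS = FALSE)
  out$include_unknown <- include_unknown
  out$n_clusters_eligible <- NA_integer_
  out$pct_clusters_predominant <- NA_real_
  out$pct_unknown_predominant <- NA_real_
  for (r in seq_len(nrow(out))) {
    elig <- which(sizes >= out$min_size[r])
    out$n_clusters_eligible[r] <- length(elig)
    if (length(elig) == 0) next         # undefined, not 0
    hit <- !is.na(max_frac[elig]) & max_frac[elig] >= out$level[r] - 1e-9
    out$pct_clusters_predominant[r] <- 100 * mean(hit)
    if (include_unknown)
      out$pct_unknown_predominant[r] <-
        100 * mean(unk_frac[elig] >= out$level[r] - 1e-9)
  }
  out
}
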