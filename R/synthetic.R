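#' Configuration of the synthetic compound-library generator
#'
#' The defaults reproduce the composition of the study library the method
#' was developed on: 460 compounds, 297 of them with a known interaction
#' at the class frequencies ROS 14, translocation inhibition 7, DNA
#' binding 60, IKK inhibition 138, IkB-degradation inhibition 76,
#' IkB-degradation activation 6, four compounds carrying two labels, and
#' 163 compounds of unknown interaction.
#'
#' Compounds are organized into structurally coherent series (analogue
#' series sharing a scaffold / feature prototype) so the similar-property
#' principle holds by construction; unknown-interaction compounds are
#' unstudied analogues drawn from the same series as labelled compounds.
#'
#' @param class_counts Named integer vector of per-class compound counts
#'   (dual-label compounds count towards both of their classes).
#' @param unknown_count Number of unknown-interaction compounds.
#' @param dual_label_count Number of compounds carrying two labels.
#' @param series_size Number of compounds per analogue series (default 8,
#'   a typical published analogue-series size).
#' @param noise_rate Per-feature flip probability epsilon in \[0, 0.5\]
#'   applied to each series member's prototype (fingerprint-space
#'   generator only).
#' @param prototype_size Features per series prototype (fingerprint-space
#'   generator only).
#' @param rng_seed Integer seed; the whole library is reproducible from it.
#' @return Object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(class_counts = c(ROS = 14,
                                              TRANSLOCATION_INHIBITION = 7,
                                              DNA_BINDING = 60,
                                              IKK_INHIBITION = 138,
                                              IKB_DEG_INHIBITION = 76,
                                              IKB_DEG_ACTIVATION = 6),
                             unknown_count = 163,
                             dual_label_count = 4,
                             series_size = 8,
                             noise_rate = 0.05,
                             prototype_size = 40,
                             rng_seed = 1) {
  class_counts <- unlist(class_counts)     # accept list input (YAML/JSON)
  stopifnot(all(names(class_counts) %in% interaction_labels()),
            all(class_counts >= 0), unknown_count >= 0,
            dual_label_count >= 0,
            noise_rate >= 0, noise_rate <= 0.5,
            prototype_size >= 1)
  if (series_size < 1) stop("series_size must be >= 1")
  if (dual_label_count > 0 && sum(class_counts >= 1) < 2)
    stop("dual-label compounds need at least two non-empty classes")
  structure(list(class_counts = class_counts,
                 unknown_count = as.integer(unknown_count),
                 dual_label_count = as.integer(dual_label_count),
                 series_size = as.integer(series_size),
                 noise_rate = noise_rate,
                 prototype_size = as.integer(prototype_size),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

## shared series bookkeeping: which class each single-label compound is in,
## which series it belongs to, which classes/series the duals and unknowns
## use; everything drawn from the cfg RNG
.plan_library <- function(cfg) {
  counts <- cfg$class_counts[cfg$class_counts > 0]
  classes <- names(counts)
  ## dual-label compounds occupy one slot in each of two classes
  dual_pairs <- list()
  if (cfg$dual_label_count > 0) {
    avail <- counts
    for (d in seq_len(cfg$dual_label_count)) {
      ok <- names(avail)[avail >= 1]
      pick <- sample(ok, 2, prob = avail[ok])
      dual_pairs[[d]] <- pick
      avail[pick] <- avail[pick] - 1
    }
  }
  dual_use <- table(factor(unlist(dual_pairs), levels = classes))
  single <- counts - as.integer(dual_use)
  if (any(single < 0))
    stop("dual_label_count exceeds available class counts")
  ## series per class sized for the full class count
  n_series <- pmax(1L, ceiling(counts / cfg$series_size))
  series_class <- rep(classes, n_series)
  series_index <- unlist(lapply(n_series, seq_len), use.names = FALSE)
  list(classes = classes, single = single, dual_pairs = dual_pairs,
       series_class = series_class, series_index = series_index,
       n_series = n_series)
}

## assign members of one class round-robin over its series
.series_of_members <- function(n_members, n_series) {
  if (n_members == 0) return(integer(0))
  rep(seq_len(n_series), length.out = n_members)
}

#' Generate an abstract fingerprint-space compound library
#'
#' Generates the library directly in sparse fingerprint space, with no
#' chemistry involved: each series has a prototype feature set drawn from
#' its own disjoint feature range, and every member flips each position of
#' the series' feature universe in or out with probability
#' \code{noise_rate}. Dual-label compounds carry the union structure of
#' one series from each of their two classes; unknown-interaction
#' compounds are extra members of randomly chosen labelled series that
#' carry no label.
#'
#' @param cfg A [synthetic_config()].
#' @return List with \code{records} (compound data frame, \code{smiles} is
#'   \code{NA}) and \code{fingerprints} (named list of sorted integer
#'   feature vectors).
#' @export
generate_fp_library <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$rng_seed)
  plan <- .plan_library(cfg)
  U <- 2L * cfg$prototype_size          # per-series feature universe size
  n_series_total <- length(plan$series_class)
  ## per-series prototype membership over its universe
  proto <- lapply(seq_len(n_series_total), function(g) {
    memb <- rep(FALSE, U)
    memb[sample.int(U, cfg$prototype_size)] <- TRUE
    memb
  })
  series_offset <- (seq_len(n_series_total) - 1L) * U
  draw_member <- function(g) {
    flips <- stats::runif(U) < cfg$noise_rate
    memb <- xor(proto[[g]], flips)
    series_offset[g] + which(memb)
  }
  ids <- character(0); labels <- list(); fps <- list(); series_id <- integer(0)
  k <- 0
  ## single-label members
  for (cls in plan$classes) {
    n_m <- plan$single[[cls]]
    gseries <- which(plan$series_class == cls)
    sm <- .series_of_members(n_m, length(gseries))
    for (m in seq_len(n_m)) {
      k <- k + 1
      g <- gseries[sm[m]]
      ids[k] <- sprintf("%s_S%02d_M%03d", cls, sm[m], m)
      labels[[k]] <- cls
      fps[[k]] <- draw_member(g)
      series_id[k] <- g
    }
  }
  ## dual-label members: union structure of one series per class
  for (d in seq_along(plan$dual_pairs)) {
    pair <- plan$dual_pairs[[d]]
    g1 <- which(plan$series_class == pair[1])[1]
    g2 <- which(plan$series_class == pair[2])[1]
    k <- k + 1
    ids[k] <- sprintf("DUAL_%02d", d)
    labels[[k]] <- sort(pair)
    fps[[k]] <- sort(c(draw_member(g1), draw_member(g2)))
    series_id[k] <- g1
  }
  ## unknown-interaction members: unstudied analogues of random series
  if (cfg$unknown_count > 0) {
    gs <- sample.int(n_series_total, cfg$unknown_count, replace = TRUE)
    for (u in seq_len(cfg$unknown_count)) {
      k <- k + 1
      ids[k] <- sprintf("UNK_%03d", u)
      labels[[k]] <- character(0)
      fps[[k]] <- draw_member(gs[u])
      series_id[k] <- gs[u]
    }
  }
  records <- data.frame(compound_id = ids, smiles = NA_character_,
                        stringsAsFactors = FALSE)
  records$labels <- labels
  records$series <- series_id
  names(fps) <- ids
  list(records = records, fingerprints = fps)
}

## scaffold templates with two substitution sites; all combinations with
## the substituent alphabet below yield valid SMILES
.scaffolds <- c(
  "c1cc({R1})ccc1{R2}",                          # disubstituted benzene
  "O=C(c1ccc({R1})cc1)c1ccc({R2})cc1",           # benzophenone
  "c1ccc(-c2ccc({R1})cc2{R2})cc1",               # biphenyl
  "O=c1cc(-c2ccc({R1})cc2)oc2cc({R2})ccc12",     # flavone
  "{R1}c1ccc(C=Cc2ccc({R2})cc2)cc1",             # stilbene
  "O=C({R1})Nc1ccc({R2})cc1",                    # anilide
  "{R1}c1ccnc({R2})n1",                          # pyrimidine
  "{R1}c1ccc2nc({R2})ccc2c1",                    # quinoline
  "O=S(=O)(c1ccc({R1})cc1)N{R2}",                # sulfonamide
  "O=C(O{R1})c1ccc({R2})cc1"                     # benzoate ester
)

.substituents <- c("F", "Cl", "Br", "I", "C", "CC", "CCC", "C(C)C", "O",
                   "OC", "OCC", "N", "NC", "C#N", "C(F)(F)F", "CO",
                   "C(=O)O", "C(=O)N", "S", "SC")

.build_smiles <- function(scaffold, r1, r2) {
  s <- sub("{R1}", r1, scaffold, fixed = TRUE)
  sub("{R2}", r2, s, fixed = TRUE)
}

#' Generate a SMILES compound library of scaffold series
#'
#' Structure-level counterpart of [generate_fp_library()]: each series is
#' a scaffold template with one substitution site fixed (the series'
#' identity) and one varied through a substituent alphabet, so that
#' members of a series are close analogues. Dual-label compounds are the
#' two-fragment union of one member from each of their classes' series;
#' unknowns are further analogues of randomly chosen labelled series.
#' Every generated SMILES parses with [parse_smiles()].
#'
#' @param cfg A [synthetic_config()] (\code{noise_rate} and
#'   \code{prototype_size} are not used at the structure level).
#' @return Compound data frame with columns \code{compound_id},
#'   \code{smiles}, \code{labels} and \code{series}.
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$rng_seed)
  plan <- .plan_library(cfg)
  n_series_total <- length(plan$series_class)
  n_combo <- length(.scaffolds) * length(.substituents)
  if (n_series_total > n_combo)
    stop("not enough scaffold/substituent combinations for ",
         n_series_total, " series; increase series_size or extend the ",
         "substituent alphabet")
  combo <- sample.int(n_combo, n_series_total)   # distinct (scaffold, R2)
  series_scaffold <- .scaffolds[(combo - 1) %/% length(.substituents) + 1]
  series_fixed <- .substituents[(combo - 1) %% length(.substituents) + 1]
  next_member <- rep(0L, n_series_total)
  draw_member <- function(g) {
    next_member[g] <<- next_member[g] + 1L
    if (next_member[g] > length(.substituents))
      stop("substituent alphabet exhausted for series ", g,
           "; use a smaller series_size or extend the alphabet")
    .build_smiles(series_scaffold[g], .substituents[next_member[g]],
                  series_fixed[g])
  }
  ids <- character(0); labels <- list(); smiles <- character(0)
  series_id <- integer(0)
  k <- 0
  for (cls in plan$classes) {
    n_m <- plan$single[[cls]]
    gseries <- which(plan$series_class == cls)
    sm <- .series_of_members(n_m, length(gseries))
    for (m in seq_len(n_m)) {
      k <- k + 1
      g <- gseries[sm[m]]
      ids[k] <- sprintf("%s_S%02d_M%03d", cls, sm[m], m)
      labels[[k]] <- cls
      smiles[k] <- draw_member(g)
      series_id[k] <- g
    }
  }
  for (d in seq_along(plan$dual_pairs)) {
    pair <- plan$dual_pairs[[d]]
    g1 <- which(plan$series_class == pair[1])[1]
    g2 <- which(plan$series_class == pair[2])[1]
    k <- k + 1
    ids[k] <- sprintf("DUAL_%02d", d)
    labels[[k]] <- sort(pair)
    smiles[k] <- paste(draw_member(g1), draw_member(g2), sep = ".")
    series_id[k] <- g1
  }
  if (cfg$unknown_count > 0) {
    gs <- sample.int(n_series_total, cfg$unknown_count, replace = TRUE)
    for (u in seq_len(cfg$unknown_count)) {
      k <- k + 1
      ids[k] <- sprintf("UNK_%03d", u)
      labels[[k]] <- character(0)
      smiles[k] <- draw_member(gs[u])
      series_id[k] <- gs[u]
    }
  }
  records <- data.frame(compound_id = ids, smiles = smiles,
                        stringsAsFactors = FALSE)
  records$labels <- labels
  records$series <- series_id
  records
}
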