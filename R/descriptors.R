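#' The seven descriptor sets
#'
#' Names the seven 2D descriptor sets under which compound libraries are
#' represented: circular fingerprints of diameter 4 (\code{ECFP4}), eight
#' physicochemical property descriptors (\code{PROPERTY}), eigenvalue
#' descriptors of the bond-order adjacency matrix (\code{BCUT}) and of the
#' topological distance matrix (\code{GCUT}), and the three combinations
#' used downstream.
#'
#' @return Character vector of the seven descriptor-set identifiers.
#' @export
descriptor_sets <- function() {
  c("ECFP4", "PROPERTY", "ECFP4_PROPERTY", "BCUT", "GCUT", "BCUT_GCUT",
    "GCUT_PROPERTY")
}

## standard atomic masses and polarizabilities (10^-24 cm^3) for the
## elements realistically present in a 2D organic library
.atomic_mass <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, Si = 28.086, P = 30.974, S = 32.065,
                  Cl = 35.453, Br = 79.904, I = 126.904, Se = 78.971,
                  As = 74.922)
.atomic_number <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, Br = 35, I = 53, Se = 34,
                    As = 33)
.polarizability <- c(H = 0.667, B = 3.03, C = 1.76, N = 1.10, O = 0.802,
                     F = 0.557, Si = 5.38, P = 3.63, S = 2.90, Cl = 2.18,
                     Br = 3.05, I = 5.35, Se = 3.77, As = 4.31)

.lookup_table <- function(tab, elements, what) {
  out <- tab[elements]
  if (anyNA(out))
    stop("no ", what, " tabulated for element(s): ",
         paste(unique(elements[is.na(out)]), collapse = ", "))
  unname(out)
}

## batched OpenBabel property computation (AlogP-type atom-contribution
## logP, molecular weight incl. implicit H, H-bond acceptor/donor counts)
.ob_props <- function(smiles) {
  input <- paste0(paste(smiles, paste0("m", seq_along(smiles))), "\n",
                  collapse = "")
  p <- ChemmineOB::forEachMol("SMILES", input, ChemmineOB::prop_OB,
                              reduce = rbind)
  data.frame(alogp = p$logP, mw = p$MW, hba = p$HBA1, hbd = p$HBD)
}

#' Physicochemical property descriptors
#'
#' The eight-component property vector: AlogP (atom-contribution logP, via
#' OpenBabel), molecular weight (including implicit hydrogens), hydrogen
#' bond acceptor count, hydrogen bond donor count, heavy atom count,
#' rotatable bond count, ring count (cyclomatic) and aromatic ring count.
#'
#' @param mol A \code{"molgraph"} from [parse_smiles()].
#' @return Named numeric vector of length 8, components in the order above.
#' @export
property_descriptors <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  ob <- .ob_props(mol$smiles)
  b <- mol$bonds
  rot <- if (nrow(b) == 0) 0L else
    sum(b$order == 1 & !b$aromatic & !b$in_ring &
        mol$atoms$degree[b$a1] >= 2 & mol$atoms$degree[b$a2] >= 2)
  c(alogp = ob$alogp, mw = ob$mw, hba = ob$hba, hbd = ob$hbd,
    n_atoms = nrow(mol$atoms), n_rotatable = as.numeric(rot),
    n_rings = mol$n_rings, n_aromatic_rings = mol$n_aromatic_rings)
}

## deterministic hash of an integer vector into [0, p); p prime < 2^26 so
## all intermediate products stay exactly representable as doubles
.hash_prime <- 67108859
.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 1000003 + (x %% .hash_prime)) %% .hash_prime
  as.integer(h)
}

#' Circular fingerprint (extended-connectivity, unfolded)
#'
#' Sparse circular fingerprint of the given radius (radius 2 = diameter 4,
#' the ECFP4 analogue). Atom environments are grown iteratively by hashing
#' each atom's previous identifier together with the sorted
#' (bond-type, neighbour identifier) pairs; structurally duplicate
#' environments (identical covered-bond sets) are removed, and identifiers
#' are returned as a sorted set of integers. The identifier space is
#' unfolded, so Tanimoto comparison is collision-free for practical library
#' sizes.
#'
#' @param mol A \code{"molgraph"}.
#' @param radius Number of growth iterations (default 2).
#' @return Sorted integer vector of distinct feature identifiers.
#' @export
circular_fingerprint <- function(mol, radius = 2) {
  stopifnot(inherits(mol, "molgraph"), radius >= 0)
  n <- nrow(mol$atoms)
  a <- mol$atoms
  b <- mol$bonds
  ## bond type code: 1/2/3 by order, 4 when aromatic
  btype <- if (nrow(b) > 0) ifelse(b$aromatic, 4L, as.integer(round(b$order)))
           else integer(0)
  nbrs <- vector("list", n)     # per atom: matrix of (bond idx, other atom)
  for (j in seq_len(nrow(b))) {
    nbrs[[b$a1[j]]] <- rbind(nbrs[[b$a1[j]]], c(j, b$a2[j]))
    nbrs[[b$a2[j]]] <- rbind(nbrs[[b$a2[j]]], c(j, b$a1[j]))
  }
  codes <- vapply(seq_len(n), function(i) .hash_ints(c(
    .lookup_table(.atomic_number, a$element[i], "atomic number"),
    a$degree[i], a$n_h[i], a$charge[i], as.integer(a$aromatic[i]))), 1L)
  env <- rep(list(integer(0)), n)          # covered bond sets
  feats <- codes                           # radius-0 identifiers
  seen_env <- character(0)                 # non-empty bond-set signatures
  r <- 0
  while (r < radius) {
    r <- r + 1
    new_codes <- codes
    new_env <- env
    for (i in seq_len(n)) {
      nb <- nbrs[[i]]
      if (is.null(nb)) next
      ord <- order(btype[nb[, 1]], codes[nb[, 2]])
      pairs <- as.vector(t(cbind(btype[nb[ord, 1]], codes[nb[ord, 2]])))
      new_codes[i] <- .hash_ints(c(r, codes[i], pairs))
      new_env[i] <- list(sort(unique(c(env[[i]], nb[, 1],
                                       unlist(env[nb[, 2]])))))
    }
    for (i in seq_len(n)) {
      if (length(new_env[[i]]) == 0) next                 # isolated atom
      if (identical(new_env[[i]], env[[i]])) next         # stopped growing
      sig <- paste(new_env[[i]], collapse = ",")
      if (sig %in% seen_env) next                         # duplicate env
      seen_env <- c(seen_env, sig)
      feats <- c(feats, new_codes[i])
    }
    codes <- new_codes
    env <- new_env
  }
  sort(unique(feats))
}

#' Tanimoto coefficient of two feature sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; two empty sets are identical by
#' convention and score 1.
#'
#' @param a,b Integer vectors of feature identifiers.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

## PEOE (Gasteiger-Marsili) orbital electronegativity parameters a, b, c
.peoe_params <- list(
  H     = c(7.17, 6.24, -0.56),
  C.3   = c(7.98, 9.18, 1.88),
  C.2   = c(8.79, 9.32, 1.51),
  C.1   = c(10.39, 9.45, 0.73),
  N.3   = c(11.54, 10.82, 1.36),
  N.2   = c(12.87, 11.15, 0.85),
  N.1   = c(15.68, 11.70, -0.27),
  O.3   = c(14.18, 12.92, 1.39),
  O.2   = c(17.07, 13.79, 0.47),
  F     = c(14.66, 13.85, 2.31),
  Cl    = c(11.00, 9.69, 1.35),
  Br    = c(10.08, 8.47, 1.16),
  I     = c(9.90, 7.96, 0.96),
  S.3   = c(10.14, 9.13, 1.38),
  P.3   = c(8.90, 8.24, 0.96)
)

.peoe_key <- function(element, hyb) {
  key <- paste0(element, ".", hyb)
  if (key %in% names(.peoe_params)) return(key)
  if (element %in% names(.peoe_params)) return(element)
  alt <- paste0(element, ".", 3)
  if (alt %in% names(.peoe_params)) return(alt)
  "C.3"  # neutral fallback for untabulated elements
}

#' Gasteiger-type partial charges
#'
#' Partial equalization of orbital electronegativities (PEOE): charge flows
#' along each bond from the less to the more electronegative atom, with the
#' transferred amount damped by \eqn{(1/2)^k} at iteration \eqn{k}. Implicit
#' hydrogens participate in the iteration; the returned charges are those of
#' the heavy atoms.
#'
#' @param mol A \code{"molgraph"}.
#' @param n_iter Number of damping iterations (default 6).
#' @return Numeric vector of partial charges, one per heavy atom.
#' @export
gasteiger_charges <- function(mol, n_iter = 6) {
  stopifnot(inherits(mol, "molgraph"))
  n_heavy <- nrow(mol$atoms)
  a <- mol$atoms
  b <- mol$bonds
  ## hybridization per heavy atom from kekule bond orders
  hyb <- rep(3L, n_heavy)
  if (nrow(b) > 0) {
    for (i in seq_len(n_heavy)) {
      ords <- b$order[b$a1 == i | b$a2 == i]
      if (any(ords >= 3) || sum(ords >= 2) >= 2) hyb[i] <- 1L
      else if (any(ords >= 2) || a$aromatic[i]) hyb[i] <- 2L
    }
  } else hyb[a$aromatic] <- 2L
  ## atom list = heavy atoms + implicit hydrogens
  elements <- a$element
  hybs <- hyb
  edges <- if (nrow(b) > 0) cbind(b$a1, b$a2) else
    matrix(integer(0), ncol = 2)
  q <- as.numeric(a$charge)
  for (i in seq_len(n_heavy)) {
    if (a$n_h[i] > 0) {
      for (k in seq_len(a$n_h[i])) {
        elements <- c(elements, "H")
        hybs <- c(hybs, 3L)
        q <- c(q, 0)
        edges <- rbind(edges, c(i, length(elements)))
      }
    }
  }
  keys <- mapply(.peoe_key, elements, hybs)
  par <- do.call(rbind, .peoe_params[keys])
  chi_plus <- ifelse(elements == "H", 20.02, rowSums(par))
  for (it in seq_len(n_iter)) {
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
    damp <- 0.5^it
    dq <- numeric(length(q))
    if (nrow(edges) > 0) {
      for (e in seq_len(nrow(edges))) {
        i <- edges[e, 1]; j <- edges[e, 2]
        if (chi[i] == chi[j]) next
        lo <- if (chi[i] < chi[j]) i else j
        hi <- if (chi[i] < chi[j]) j else i
        d <- (chi[hi] - chi[lo]) / chi_plus[lo] * damp
        dq[hi] <- dq[hi] - d        # more electronegative atom gains electrons
        dq[lo] <- dq[lo] + d
      }
    }
    q <- q + dq
  }
  q[seq_len(n_heavy)]
}

#' Default diagonal weight schemes for BCUT/GCUT descriptors
#'
#' The canonical triple: standard atomic mass, Gasteiger-type partial
#' charge, and atomic polarizability. Each scheme is a function mapping a
#' \code{"molgraph"} to one weight per heavy atom.
#'
#' @return Named list of weight functions.
#' @export
default_weight_schemes <- function() {
  list(
    mass = function(mol) .lookup_table(.atomic_mass, mol$atoms$element,
                                       "atomic mass"),
    charge = gasteiger_charges,
    polarizability = function(mol) .lookup_table(.polarizability,
                                                 mol$atoms$element,
                                                 "polarizability")
  )
}

.cut_eigen_range <- function(off_diag, weights) {
  m <- off_diag
  diag(m) <- weights
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  c(min(ev), max(ev))
}

#' BCUT eigenvalue descriptors
#'
#' For each weight scheme, builds the heavy-atom adjacency matrix with
#' off-diagonal entries equal to the bond order (aromatic bonds 1.5,
#' non-bonded pairs 0) and the diagonal set to the atom weights, and
#' returns the lowest and highest eigenvalue.
#'
#' @param mol A \code{"molgraph"} with at least one heavy atom.
#' @param weight_schemes Named list of weight functions (see
#'   [default_weight_schemes()]).
#' @return Named numeric vector of 2 x \code{length(weight_schemes)} values,
#'   \code{(min, max)} per scheme.
#' @export
bcut_descriptors <- function(mol, weight_schemes = default_weight_schemes()) {
  stopifnot(inherits(mol, "molgraph"), nrow(mol$atoms) >= 1)
  n <- nrow(mol$atoms)
  A <- matrix(0, n, n)
  b <- mol$bonds
  if (nrow(b) > 0) {
    ord <- ifelse(b$aromatic, 1.5, b$order)
    for (j in seq_len(nrow(b))) {
      A[b$a1[j], b$a2[j]] <- ord[j]
      A[b$a2[j], b$a1[j]] <- ord[j]
    }
  }
  out <- numeric(0)
  for (nm in names(weight_schemes)) {
    rng <- .cut_eigen_range(A, weight_schemes[[nm]](mol))
    out <- c(out, stats::setNames(rng, paste0("bcut_", nm, c("_min", "_max"))))
  }
  out
}

#' GCUT eigenvalue descriptors
#'
#' As [bcut_descriptors()] but with off-diagonal entries equal to the
#' topological (bond-count) graph distance; atoms in different fragments get
#' distance 0 (per-fragment block matrix).
#'
#' @inheritParams bcut_descriptors
#' @return Named numeric vector, \code{(min, max)} eigenvalue per scheme.
#' @export
gcut_descriptors <- function(mol, weight_schemes = default_weight_schemes()) {
  stopifnot(inherits(mol, "molgraph"), nrow(mol$atoms) >= 1)
  n <- nrow(mol$atoms)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(mol$bonds) > 0)
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  D <- igraph::distances(g)
  D[is.infinite(D)] <- 0
  out <- numeric(0)
  for (nm in names(weight_schemes)) {
    rng <- .cut_eigen_range(D, weight_schemes[[nm]](mol))
    out <- c(out, stats::setNames(rng, paste0("gcut_", nm, c("_min", "_max"))))
  }
  out
}

## ---------------------------------------------------------------------------
## Library-level descriptor containers and similarity

.set_uses_fp <- function(set_id) set_id %in% c("ECFP4", "ECFP4_PROPERTY")
.set_blocks <- function(set_id) {
  switch(set_id,
         ECFP4 = character(0),
         PROPERTY = "property",
         ECFP4_PROPERTY = "property",
         BCUT = "bcut",
         GCUT = "gcut",
         BCUT_GCUT = c("bcut", "gcut"),
         GCUT_PROPERTY = c("gcut", "property"),
         stop("unknown descriptor set: ", set_id))
}

#' Compute a descriptor matrix for a compound library
#'
#' Builds the representation of every compound under one descriptor set.
#' For fingerprint-bearing sets, precomputed sparse fingerprints may be
#' supplied (as for abstract fingerprint-space libraries that carry no
#' SMILES); otherwise everything is computed from the parsed structures.
#'
#' @param records Compound data frame (see [read_library()]).
#' @param set_id One of [descriptor_sets()].
#' @param fingerprints Optional named list (by compound id) of integer
#'   feature vectors, used instead of computing [circular_fingerprint()].
#' @param mols Optional pre-parsed list of \code{"molgraph"} objects
#'   (named by compound id), to avoid re-parsing across descriptor sets.
#' @return Object of class \code{"descriptor_matrix"}: list with
#'   \code{set_id}, \code{ids}, sparse \code{fp} list and/or named
#'   continuous \code{blocks} matrices.
#' @export
describe_library <- function(records, set_id, fingerprints = NULL,
                             mols = NULL) {
  set_id <- match.arg(set_id, descriptor_sets())
  ids <- records$compound_id
  need_chem <- length(.set_blocks(set_id)) > 0 ||
    (.set_uses_fp(set_id) && is.null(fingerprints))
  if (need_chem && is.null(mols)) {
    if (any(is.na(records$smiles)))
      stop("descriptor set ", set_id, " needs structures, but the library ",
           "has compounds without SMILES")
    mols <- parse_smiles_batch(records$smiles, ids)
  }
  fp <- NULL
  if (.set_uses_fp(set_id)) {
    if (!is.null(fingerprints)) {
      if (!all(ids %in% names(fingerprints)))
        stop("fingerprints missing for some compound ids")
      fp <- fingerprints[ids]
    } else {
      fp <- lapply(mols[ids], circular_fingerprint)
    }
  }
  blocks <- list()
  for (blk in .set_blocks(set_id)) {
    fun <- switch(blk, property = property_descriptors,
                  bcut = bcut_descriptors, gcut = gcut_descriptors)
    if (blk == "property") {
      ## batch the OpenBabel call, counts from the graphs
      ob <- .ob_props(records$smiles)
      rows <- t(vapply(ids, function(id) {
        mol <- mols[[id]]
        b <- mol$bonds
        rot <- if (nrow(b) == 0) 0 else
          sum(b$order == 1 & !b$aromatic & !b$in_ring &
              mol$atoms$degree[b$a1] >= 2 & mol$atoms$degree[b$a2] >= 2)
        c(n_atoms = nrow(mol$atoms), n_rotatable = rot,
          n_rings = mol$n_rings, n_aromatic_rings = mol$n_aromatic_rings)
      }, numeric(4)))
      m <- cbind(alogp = ob$alogp, mw = ob$mw, hba = ob$hba, hbd = ob$hbd,
                 rows)
    } else {
      m <- t(vapply(ids, function(id) fun(mols[[id]]),
                    fun(mols[[ids[1]]])))
    }
    rownames(m) <- ids
    blocks[[blk]] <- m
  }
  structure(list(set_id = set_id, ids = ids, fp = fp,
                 blocks = if (length(blocks)) blocks else NULL),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("Descriptor matrix [", x$set_id, "]: ", length(x$ids), " compounds",
      if (!is.null(x$fp)) paste0("; ", length(unique(unlist(x$fp))),
                                 " distinct fingerprint features") else "",
      if (!is.null(x$blocks)) paste0("; continuous blocks: ",
                                     paste(names(x$blocks), collapse = ", "))
      else "", "\n", sep = "")
  invisible(x)
}

#' Per-component scaling bounds of a training library
#'
#' Records the min/max of every continuous descriptor component over the
#' training set. These bounds are frozen and reused when scoring query
#' compounds, whose scaled values are clamped to \[0, 1\].
#'
#' @param desc A \code{"descriptor_matrix"} of the training library.
#' @return Object of class \code{"descriptor_scaling"}.
#' @export
descriptor_scaling <- function(desc) {
  stopifnot(inherits(desc, "descriptor_matrix"))
  ranges <- lapply(desc$blocks, function(m)
    list(min = apply(m, 2, min), max = apply(m, 2, max)))
  structure(list(set_id = desc$set_id, ranges = ranges),
            class = "descriptor_scaling")
}

.scale_block <- function(m, rng) {
  span <- rng$max - rng$min
  out <- sweep(m, 2, rng$min, "-")
  for (j in seq_len(ncol(out))) {
    if (span[j] > 0) out[, j] <- out[, j] / span[j]
    else out[, j] <- 0.5   # constant component: no contrast
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

.fp_incidence <- function(fp_list, feature_ids) {
  i <- rep(seq_along(fp_list), lengths(fp_list))
  j <- match(unlist(fp_list), feature_ids)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(fp_list), length(feature_ids)))
}

.tanimoto_cross <- function(fp_a, fp_b) {
  feats <- unique(c(unlist(fp_a), unlist(fp_b)))
  if (length(feats) == 0)
    return(matrix(1, length(fp_a), length(fp_b)))
  A <- .fp_incidence(fp_a, feats)
  B <- .fp_incidence(fp_b, feats)
  inter <- as.matrix(Matrix::tcrossprod(A, B))
  na <- Matrix::rowSums(A)
  nb <- Matrix::rowSums(B)
  un <- outer(na, nb, "+") - inter
  out <- ifelse(un == 0, 1, inter / un)
  out
}

.cont_cross <- function(ma, mb, rng) {
  sa <- .scale_block(ma, rng)
  sb <- .scale_block(mb, rng)
  acc <- matrix(0, nrow(sa), nrow(sb))
  for (j in seq_len(ncol(sa)))
    acc <- acc + abs(outer(sa[, j], sb[, j], "-"))
  1 - acc / ncol(sa)
}

.cross_components <- function(da, db, scaling) {
  stopifnot(da$set_id == db$set_id)
  comps <- list()
  if (!is.null(da$fp)) comps$fp <- .tanimoto_cross(da$fp, db$fp)
  for (blk in names(da$blocks))
    comps[[blk]] <- .cont_cross(da$blocks[[blk]], db$blocks[[blk]],
                                scaling$ranges[[blk]])
  comps
}

#' Pairwise similarity matrix of a library
#'
#' Fingerprint components are compared by the Tanimoto coefficient;
#' continuous components by \eqn{1 -} mean absolute difference after
#' per-component min-max scaling over the training library; combined
#' descriptor sets take the unweighted mean of their component
#' similarities.
#'
#' @param desc A \code{"descriptor_matrix"}.
#' @param scaling Frozen [descriptor_scaling()]; defaults to bounds of
#'   \code{desc} itself (i.e. \code{desc} is the training set).
#' @return Symmetric similarity matrix in \[0, 1\] with unit diagonal,
#'   dimnames = compound ids.
#' @export
similarity_matrix <- function(desc, scaling = descriptor_scaling(desc)) {
  comps <- .cross_components(desc, desc, scaling)
  sim <- Reduce(`+`, comps) / length(comps)
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  dimnames(sim) <- list(desc$ids, desc$ids)
  sim
}

#' Similarity of query compounds to a training library
#'
#' @param query_desc Descriptor matrix of the queries (same set).
#' @param train_desc Descriptor matrix of the training library.
#' @param scaling Frozen training [descriptor_scaling()].
#' @return Matrix (queries x training compounds) of similarities.
#' @export
cross_similarity <- function(query_desc, train_desc,
                             scaling = descriptor_scaling(train_desc)) {
  if (query_desc$set_id != train_desc$set_id)
    stop("descriptor set mismatch: ", query_desc$set_id, " vs ",
         train_desc$set_id)
  comps <- .cross_components(query_desc, train_desc, scaling)
  sim <- Reduce(`+`, comps) / length(comps)
  dimnames(sim) <- list(query_desc$ids, train_desc$ids)
  sim
}

#' Extract one compound's descriptor vector
#'
#' @param desc A \code{"descriptor_matrix"}.
#' @param id Compound id.
#' @return Object of class \code{"descriptor_vector"}.
#' @export
extract_vector <- function(desc, id) {
  k <- match(id, desc$ids)
  if (is.na(k)) stop("compound id not in descriptor matrix: ", id)
  structure(list(set_id = desc$set_id,
                 fp = if (!is.null(desc$fp)) desc$fp[[k]],
                 cont = lapply(desc$blocks, function(m) m[k, ])),
            class = "descriptor_vector")
}

#' Similarity of two descriptor vectors
#'
#' Single-pair form of the similarity used throughout: Tanimoto for
#' fingerprint components, 1 - scaled mean absolute difference for
#' continuous components, unweighted mean across components for combined
#' sets.
#'
#' @param a,b \code{"descriptor_vector"} objects of the same set.
#' @param scaling Frozen training [descriptor_scaling()]; if \code{NULL},
#'   bounds are taken from the two vectors themselves (library scoring
#'   should always pass the training scaling).
#' @return Similarity in \[0, 1\].
#' @export
similarity <- function(a, b, scaling = NULL) {
  stopifnot(inherits(a, "descriptor_vector"), inherits(b, "descriptor_vector"))
  if (a$set_id != b$set_id)
    stop("descriptor set mismatch: ", a$set_id, " vs ", b$set_id)
  comps <- numeric(0)
  if (!is.null(a$fp) || !is.null(b$fp))
    comps <- c(comps, tanimoto(a$fp, b$fp))
  for (blk in names(a$cont)) {
    va <- a$cont[[blk]]; vb <- b$cont[[blk]]
    rng <- if (!is.null(scaling)) scaling$ranges[[blk]] else
      list(min = pmin(va, vb), max = pmax(va, vb))
    sa <- .scale_block(rbind(va), rng)
    sb <- .scale_block(rbind(vb), rng)
    comps <- c(comps, 1 - mean(abs(sa - sb)))
  }
  mean(comps)
}

#' Export a descriptor matrix to CSV
#'
#' Continuous components only (one row per compound, named columns).
#'
#' @param desc A \code{"descriptor_matrix"} with continuous blocks.
#' @param path Output path.
#' @export
write_descriptor_csv <- function(desc, path) {
  if (is.null(desc$blocks))
    stop("descriptor set ", desc$set_id, " has no continuous components")
  m <- do.call(cbind, desc$blocks)
  df <- data.frame(compound_id = desc$ids, m, row.names = NULL,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export sparse fingerprints
#'
#' One line per compound: \code{compound_id<TAB>sorted feature ids}
#' (space-separated).
#'
#' @param desc A \code{"descriptor_matrix"} with a fingerprint component.
#' @param path Output path.
#' @export
write_fingerprints <- function(desc, path) {
  if (is.null(desc$fp))
    stop("descriptor set ", desc$set_id, " has no fingerprint component")
  lines <- vapply(seq_along(desc$ids), function(i)
    paste0(desc$ids[i], "\t", paste(sort(desc$fp[[i]]), collapse = " ")), "")
  writeLines(lines, path)
  invisible(path)
}
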