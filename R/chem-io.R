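#' Interaction classes of the NF-kB pathway
#'
#' The six interaction classes used to label compounds: interaction via
#' reactive oxygen species (possible at any point of the pathway), inhibition
#' of IKK activation, inhibition or activation of IkB degradation /
#' phosphorylation, inhibition of nuclear translocation, and interference
#' with DNA binding.
#'
#' @return Character vector of the six class names.
#' @export
interaction_labels <- function() {
  c("ROS", "IKK_INHIBITION", "IKB_DEG_INHIBITION", "IKB_DEG_ACTIVATION",
    "TRANSLOCATION_INHIBITION", "DNA_BINDING")
}

#' Pathway point addressed by each interaction class
#'
#' Maps every interaction class to the step of the simplified NF-kB cascade
#' at which it acts: IKK activation (1), IkB degradation/phosphorylation (2),
#' nuclear translocation (3), DNA binding (4). ROS-mediated interactions can
#' occur at any point and are tagged \code{"any"}.
#'
#' @return Named character vector keyed by interaction class.
#' @export
pathway_points <- function() {
  c(ROS = "any", IKK_INHIBITION = "1", IKB_DEG_INHIBITION = "2",
    IKB_DEG_ACTIVATION = "2", TRANSLOCATION_INHIBITION = "3",
    DNA_BINDING = "4")
}

## default valences used for implicit-hydrogen assignment (heavy atoms only
## are kept in the graph); multiple entries = allowed hypervalent states
.allowed_valences <- list(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5), S = c(2, 4, 6),
  Cl = 1, Br = 1, I = 1, Se = c(2, 4, 6), As = c(3, 5)
)

.mdl_charge <- function(code) {
  # MDL ctab atom-line charge codes
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2,
           `7` = -3)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0
  unname(out)
}

## split OpenBabel SDF output into per-record line lists keyed by title
.split_sdf_records <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  starts <- c(1, utils::head(ends, -1) + 1)
  recs <- Map(function(s, e) lines[s:(e - 1)], starts, ends)
  stats::setNames(recs, vapply(recs, `[`, "", 1))
}

## split OpenBabel MOL2 output into per-record line lists keyed by name
.split_mol2_records <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  starts <- which(lines == "@<TRIPOS>MOLECULE")
  ends <- c(utils::head(starts, -1) + diff(starts) - 1, length(lines))
  recs <- Map(function(s, e) lines[s:e], starts, ends)
  stats::setNames(recs, vapply(recs, `[`, "", 2))
}

## parse one V2000 ctab record (OpenBabel output): atoms, kekule bond
## orders, formal charges
.parse_ctab <- function(rl) {
  counts <- rl[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atom_lines <- rl[4 + seq_len(na)]
  element <- trimws(substr(atom_lines, 32, 34))
  charge <- .mdl_charge(trimws(substr(atom_lines, 37, 39)))
  if (nb > 0) {
    bond_lines <- rl[4 + na + seq_len(nb)]
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    order <- as.numeric(substr(bond_lines, 7, 9))
  } else {
    a1 <- a2 <- integer(0); order <- numeric(0)
  }
  ## M  CHG lines supersede atom-line charge codes
  chg_lines <- grep("^M  CHG", rl, value = TRUE)
  if (length(chg_lines) > 0) {
    charge <- rep(0L, na)
    for (cl in chg_lines) {
      tok <- strsplit(trimws(cl), "[[:space:]]+")[[1]]
      vals <- as.integer(tok[-(1:3)])
      idx <- vals[seq(1, length(vals), by = 2)]
      chg <- vals[seq(2, length(vals), by = 2)]
      charge[idx] <- chg
    }
  }
  list(element = element, charge = charge,
       bonds = data.frame(a1 = a1, a2 = a2, order = order))
}

## parse one MOL2 record: aromatic atom/bond flags and OpenBabel's own
## Gasteiger partial charges (kept for cross-checks)
.parse_mol2 <- function(rl) {
  atom_at <- which(rl == "@<TRIPOS>ATOM")
  bond_at <- which(rl == "@<TRIPOS>BOND")
  counts <- strsplit(trimws(rl[3]), "[[:space:]]+")[[1]]
  na <- as.integer(counts[1]); nb <- as.integer(counts[2])
  atom_tok <- strsplit(trimws(rl[atom_at + seq_len(na)]), "[[:space:]]+")
  type <- vapply(atom_tok, `[`, "", 6)
  pcharge <- suppressWarnings(as.numeric(vapply(atom_tok, function(t)
    t[length(t)], "")))
  arom_atom <- grepl("\\.ar$", type)
  arom_pair <- character(0)
  if (nb > 0 && length(bond_at) == 1) {
    bond_tok <- strsplit(trimws(rl[bond_at + seq_len(nb)]), "[[:space:]]+")
    b1 <- as.integer(vapply(bond_tok, `[`, "", 2))
    b2 <- as.integer(vapply(bond_tok, `[`, "", 3))
    btype <- vapply(bond_tok, `[`, "", 4)
    arom_pair <- paste(pmin(b1, b2), pmax(b1, b2))[btype == "ar"]
  }
  list(arom_atom = arom_atom, arom_pair = arom_pair, pcharge = pcharge)
}

## Build the internal molecular-graph record from parsed ctab + mol2 info.
.molgraph_build <- function(ct, m2, smiles = NA_character_) {
  n <- length(ct$element)
  element <- ct$element
  charge <- ct$charge
  bonds <- ct$bonds
  bonds$aromatic <- paste(pmin(bonds$a1, bonds$a2),
                          pmax(bonds$a1, bonds$a2)) %in% m2$arom_pair
  aromatic_atom <- m2$arom_atom

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0)
    g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  comp <- igraph::components(g)
  n_rings <- nrow(bonds) - n + comp$no

  ## in-ring bonds = non-bridges
  bonds$in_ring <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    br <- igraph::bridges(g)
    bonds$in_ring[-as.integer(br)] <- TRUE
    if (length(br) == 0) bonds$in_ring <- rep(TRUE, nrow(bonds))
  }
  in_ring_atom <- rep(FALSE, n)
  in_ring_atom[c(bonds$a1[bonds$in_ring], bonds$a2[bonds$in_ring])] <- TRUE

  ## aromatic ring count = cyclomatic number of the aromatic subgraph
  n_aromatic_rings <- 0L
  if (any(bonds$aromatic)) {
    ga <- igraph::subgraph_from_edges(
      g, which(bonds$aromatic), delete.vertices = TRUE)
    n_aromatic_rings <- igraph::ecount(ga) - igraph::vcount(ga) +
      igraph::components(ga)$no
  }

  degree <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  ordsum <- numeric(n)
  if (nrow(bonds) > 0) {
    for (j in seq_len(nrow(bonds))) {
      ordsum[bonds$a1[j]] <- ordsum[bonds$a1[j]] + bonds$order[j]
      ordsum[bonds$a2[j]] <- ordsum[bonds$a2[j]] + bonds$order[j]
    }
  }

  ## implicit hydrogens from allowed valences (charge-adjusted)
  n_h <- integer(n)
  for (i in seq_len(n)) {
    av <- .allowed_valences[[element[i]]]
    if (is.null(av)) { n_h[i] <- 0L; next }
    av <- av + charge[i]
    ok <- av[av >= ordsum[i]]
    n_h[i] <- if (length(ok) == 0) 0L else as.integer(min(ok) - ordsum[i])
  }

  atoms <- data.frame(element = element, aromatic = aromatic_atom,
                      charge = charge, n_h = n_h, degree = degree,
                      in_ring = in_ring_atom, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, bonds = bonds,
                 n_rings = n_rings, n_aromatic_rings = n_aromatic_rings,
                 n_fragments = comp$no, fragment = comp$membership,
                 ob_charges = m2$pcharge, smiles = smiles),
            class = "molgraph")
}

#' Parse a SMILES string into a molecular graph
#'
#' Parses via OpenBabel (through \pkg{ChemmineOB}), keeping
#' heavy atoms only: hydrogens stay implicit and are recorded as per-atom
#' counts. Aromaticity and rings are perceived; formal charges are retained.
#'
#' @param smiles A single SMILES string.
#' @return An object of class \code{"molgraph"}: a list with elements
#'   \code{atoms} (element, aromatic flag, formal charge, implicit H count,
#'   heavy degree), \code{bonds} (atom indices, order, aromatic and in-ring
#'   flags), \code{rings} (smallest-ring atom index sets), ring counts and
#'   fragment membership.
#' @examples
#' \donttest{
#' m <- parse_smiles("c1ccccc1")
#' nrow(m$atoms)   # 6
#' }
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (is.na(smiles) || !nzchar(smiles))
    stop("parse_smiles: empty SMILES string")
  parse_smiles_batch(smiles)[[1]]
}

#' Parse a vector of SMILES strings
#'
#' Batch version of [parse_smiles()]. Invalid strings raise an error naming
#' the offending SMILES.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional names for the result.
#' @return A list of \code{"molgraph"} objects.
#' @export
parse_smiles_batch <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  bad <- is.na(smiles) | !nzchar(smiles)
  if (any(bad)) stop("parse_smiles: empty SMILES at position(s) ",
                     paste(which(bad), collapse = ", "))
  nm <- if (is.null(ids)) paste0("mol", seq_along(smiles)) else ids
  ## internal whitespace-free titles keep record alignment unambiguous
  key <- paste0("q", seq_along(smiles))
  input <- paste0(paste(smiles, key), "\n", collapse = "")
  sdf_txt <- ChemmineOB::convertFormat("SMILES", "SDF", input)
  mol2_txt <- ChemmineOB::convertFormat("SMILES", "MOL2", input)
  sdf_recs <- .split_sdf_records(sdf_txt)
  mol2_recs <- .split_mol2_records(mol2_txt)
  missing <- !(key %in% names(sdf_recs)) | !(key %in% names(mol2_recs))
  if (any(missing)) {
    i <- which(missing)[1]
    stop("parse_smiles: cannot parse SMILES '", smiles[i], "'",
         if (!is.null(ids)) paste0(" (", ids[i], ")") else "")
  }
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles))
    out[[i]] <- .molgraph_build(.parse_ctab(sdf_recs[[key[i]]]),
                                .parse_mol2(mol2_recs[[key[i]]]),
                                smiles[i])
  names(out) <- nm
  out
}

#' @export
print.molgraph <- function(x, ...) {
  cat("Molecular graph:", nrow(x$atoms), "heavy atoms,", nrow(x$bonds),
      "bonds,", x$n_rings, "rings",
      if (x$n_fragments > 1) paste0("(", x$n_fragments, " fragments)") else "",
      "\n")
  invisible(x)
}

.check_labels <- function(labels) {
  bad <- setdiff(unique(unlist(labels)), interaction_labels())
  if (length(bad) > 0)
    stop("unknown interaction label(s): ", paste(bad, collapse = ", "),
         "; valid classes are ", paste(interaction_labels(), collapse = ", "))
  invisible(TRUE)
}

#' Read a compound-interaction label table
#'
#' Reads a CSV with header \code{compound_id,interaction}, one row per label;
#' compounds with more than one interaction have multiple rows.
#'
#' @param path Path to the labels CSV.
#' @return Data frame with columns \code{compound_id} and \code{interaction}.
#' @export
read_labels <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "interaction") %in% names(tab)))
    stop("labels file must have columns compound_id,interaction")
  .check_labels(tab$interaction)
  tab
}

#' Read a compound library
#'
#' Reads a SMILES file (one record per line, \code{SMILES<whitespace>ID})
#' and, optionally, an interaction-label CSV. Compounds absent from the label
#' file get an empty label set, meaning their interaction is unknown.
#'
#' @param smiles_path Path to the \code{.smi} file.
#' @param labels_path Optional path to the labels CSV
#'   (\code{compound_id,interaction}).
#' @return Data frame with columns \code{compound_id}, \code{smiles} and the
#'   list column \code{labels} (character vector of interaction classes per
#'   compound; length zero = unknown), in file order.
#' @export
read_library <- function(smiles_path, labels_path = NULL) {
  lines <- readLines(smiles_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  smi <- vapply(parts, `[`, "", 1)
  ids <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
  if (anyNA(ids)) stop("read_library: missing compound id on line(s) ",
                       paste(which(is.na(ids)), collapse = ", "))
  if (anyDuplicated(ids))
    stop("read_library: duplicate compound_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records <- data.frame(compound_id = ids, smiles = smi,
                        stringsAsFactors = FALSE)
  records$labels <- rep(list(character(0)), nrow(records))
  if (!is.null(labels_path)) {
    tab <- read_labels(labels_path)
    missing <- setdiff(tab$compound_id, ids)
    if (length(missing) > 0)
      stop("read_library: label rows reference unknown compound(s): ",
           paste(missing, collapse = ", "))
    lab <- split(tab$interaction, tab$compound_id)
    hit <- match(names(lab), records$compound_id)
    records$labels[hit] <- lapply(lab, function(v) sort(unique(v)))
  }
  records
}

#' Read a compound library from an SDF file
#'
#' V2000 SDF reader; compound ids come from the title line or, if
#' \code{id_field} is given, from that named data field.
#'
#' @param sdf_path Path to the SDF file.
#' @param id_field Optional name of the SDF property holding the compound id.
#' @param labels_path Optional labels CSV as in [read_library()].
#' @return Data frame as returned by [read_library()].
#' @export
read_sdf_library <- function(sdf_path, id_field = NULL, labels_path = NULL) {
  txt <- paste0(paste(readLines(sdf_path, warn = FALSE), collapse = "\n"),
                "\n")
  recs <- .split_sdf_records(txt)
  if (is.null(id_field)) {
    ids <- vapply(recs, function(rl) trimws(rl[1]), "")
  } else {
    ids <- vapply(seq_along(recs), function(i) {
      rl <- recs[[i]]
      at <- grep(paste0("^>\\s*<", id_field, ">"), rl)
      if (length(at) == 0)
        stop("read_sdf_library: field '", id_field, "' absent from record ", i)
      trimws(rl[at[1] + 1])
    }, "")
  }
  if (anyDuplicated(ids))
    stop("read_sdf_library: duplicate compound_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  smi_out <- ChemmineOB::convertFormat("SDF", "SMILES", txt)
  smi <- vapply(strsplit(strsplit(smi_out, "\n")[[1]], "\t"), `[`, "", 1)
  if (length(smi) != length(ids))
    stop("read_sdf_library: ", length(ids) - length(smi),
         " record(s) could not be converted")
  records <- data.frame(compound_id = ids, smiles = smi,
                        stringsAsFactors = FALSE)
  records$labels <- rep(list(character(0)), nrow(records))
  if (!is.null(labels_path)) {
    tab <- read_labels(labels_path)
    missing <- setdiff(tab$compound_id, ids)
    if (length(missing) > 0)
      stop("read_sdf_library: label rows reference unknown compound(s): ",
           paste(missing, collapse = ", "))
    lab <- split(tab$interaction, tab$compound_id)
    hit <- match(names(lab), records$compound_id)
    records$labels[hit] <- lapply(lab, function(v) sort(unique(v)))
  }
  records
}

#' Write a tabular result to CSV
#'
#' Deterministic column order (as given), UTF-8, header row. List columns
#' (such as \code{labels}) are serialized as \code{";"}-joined strings.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_records_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out))
    if (is.list(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(v) paste(v, collapse = ";"), "")
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

## labels of one compound id (helper used throughout annotation/prediction)
.labels_of <- function(records, ids) {
  hit <- match(ids, records$compound_id)
  if (anyNA(hit))
    stop("compound id(s) absent from records: ",
         paste(ids[is.na(hit)], collapse = ", "))
  records$labels[hit]
}
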