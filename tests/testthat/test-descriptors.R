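test_that("property descriptors count what they should", {
  p <- property_descriptors(parse_smiles("C"))
  expect_equal(unname(p[c("n_atoms", "hba", "hbd", "n_rotatable",
                          "n_rings", "n_aromatic_rings")]),
               c(1, 0, 0, 0, 0, 0))

  b <- property_descriptors(parse_smiles("c1ccccc1"))
  expect_equal(unname(b[c("n_rings", "n_aromatic_rings", "hba", "hbd")]),
               c(1, 1, 0, 0))

  e <- property_descriptors(parse_smiles("CCO"))
  expect_equal(unname(e[c("hba", "hbd", "n_rotatable")]), c(1, 1, 0))
  ## MW = 2 C + 6 H + 1 O from the standard atomic mass table
  expect_equal(unname(e["mw"]), 2 * 12.011 + 6 * 1.008 + 15.999,
               tolerance = 1e-3)

  ## fused and biaryl ring counting
  expect_equal(unname(property_descriptors(
    parse_smiles("c1ccc2ccccc2c1"))[c("n_rings", "n_aromatic_rings")]),
    c(2, 2))
  bip <- property_descriptors(parse_smiles("c1ccc(-c2ccccc2)cc1"))
  expect_equal(unname(bip[c("n_rings", "n_aromatic_rings", "n_rotatable")]),
               c(2, 2, 1))
})

test_that("circular fingerprints are canonical and deduplicated", {
  expect_identical(circular_fingerprint(parse_smiles("CCO")),
                   circular_fingerprint(parse_smiles("OCC")))
  ## all radius expansions of a single atom collapse to one feature
  expect_length(circular_fingerprint(parse_smiles("C")), 1)
  ## ethanol: 3 atom features + 3 distinct grown environments
  expect_length(circular_fingerprint(parse_smiles("CCO")), 6)
  ## identity similarity
  fp <- circular_fingerprint(parse_smiles("CC(=O)Oc1ccccc1C(=O)O"))
  expect_equal(tanimoto(fp, fp), 1)
  ## radius 0 = atom-type features only
  fp0 <- circular_fingerprint(parse_smiles("CCO"), radius = 0)
  expect_length(fp0, 3)
})

test_that("tanimoto follows the set formula with the empty convention", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(integer(0), integer(0)), 1)
  expect_equal(tanimoto(c(1, 2), integer(0)), 0)
})

test_that("BCUT/GCUT reproduce closed-form eigenvalues", {
  w <- list(w = function(mol) rep(5, nrow(mol$atoms)))
  two <- parse_smiles("CC")
  expect_equal(unname(bcut_descriptors(two, w)), c(4, 6), tolerance = 1e-9)
  path3 <- parse_smiles("CCC")
  expect_equal(unname(bcut_descriptors(path3, w)),
               c(5 - sqrt(2), 5 + sqrt(2)), tolerance = 1e-9)
  ## distance matrix [[0,1,2],[1,0,1],[2,1,0]] has eigenvalues {-2, 1±√3}
  expect_equal(unname(gcut_descriptors(path3, w)),
               c(5 - 2, 5 + 1 + sqrt(3)), tolerance = 1e-9)
  ## single atom: both reduce to the weight itself
  one <- parse_smiles("C")
  expect_equal(unname(bcut_descriptors(one, w)), c(5, 5))
  expect_equal(unname(gcut_descriptors(one, w)), c(5, 5))
  ## 1- and 2-atom molecules: BCUT == GCUT under equal weights
  expect_equal(bcut_descriptors(two, w), gcut_descriptors(two, w),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("eigen-descriptors are invariant to atom reordering", {
  pairs <- list(c("CCO", "OCC"), c("c1ccccc1O", "Oc1ccccc1"),
                c("CC(C)=O", "O=C(C)C"))
  for (p in pairs) {
    a <- parse_smiles(p[1]); b <- parse_smiles(p[2])
    expect_equal(sort(bcut_descriptors(a)), sort(bcut_descriptors(b)),
                 tolerance = 1e-8, ignore_attr = TRUE, info = p[1])
    expect_equal(sort(gcut_descriptors(a)), sort(gcut_descriptors(b)),
                 tolerance = 1e-8, ignore_attr = TRUE, info = p[1])
  }
})

test_that("PEOE charges agree in rank with OpenBabel's Gasteiger charges", {
  ## independent reference: OpenBabel computes its own Gasteiger charges
  ## in MOL2 output (implicit hydrogens folded differently, so ranks and
  ## signs are compared, not values)
  for (s in c("CCO", "CC(=O)O", "c1ccccc1O", "CCN", "CC(=O)Nc1ccccc1")) {
    m <- parse_smiles(s)
    q <- gasteiger_charges(m)
    expect_gte(stats::cor(q, m$ob_charges, method = "spearman"), 0.7)
    ## the most negative atom is the same element in both schemes
    ## (the reference can tie between equivalent atoms, so indices may differ)
    expect_equal(m$atoms$element[which.min(q)],
                 m$atoms$element[which.min(m$ob_charges)], info = s)
  }
})

test_that("similarity follows the component rules", {
  ## fingerprint + property fusion: mean of 0.4 and 0.8 is 0.6
  a <- structure(list(set_id = "ECFP4_PROPERTY", fp = c(1, 2),
                      cont = list(property = c(x = 0, y = 0))),
                 class = "descriptor_vector")
  b <- structure(list(set_id = "ECFP4_PROPERTY", fp = c(1, 2, 3, 4, 5),
                      cont = list(property = c(x = 0.2, y = 0.2))),
                 class = "descriptor_vector")
  scl <- structure(list(set_id = "ECFP4_PROPERTY",
                        ranges = list(property = list(min = c(x = 0, y = 0),
                                                      max = c(x = 1, y = 1)))),
                   class = "descriptor_scaling")
  expect_equal(tanimoto(a$fp, b$fp), 0.4)
  expect_equal(similarity(a, b, scl), 0.6)
  ## identity
  expect_equal(similarity(a, a, scl), 1)
  ## set mismatch is an error
  c2 <- a; c2$set_id <- "ECFP4"
  expect_error(similarity(a, c2, scl), "mismatch")
  ## out-of-range query values clamp to [0, 1]
  d <- b; d$cont$property <- c(x = 50, y = -50)
  expect_gte(similarity(a, d, scl), 0)
  expect_lte(similarity(a, d, scl), 1)
})

test_that("library similarity matrices are valid and honour frozen scaling", {
  rec <- make_records(stats::setNames(rep(list("ROS"), 6), paste0("m", 1:6)),
                      smiles = c("CCO", "CCCO", "c1ccccc1", "c1ccccc1O",
                                 "CC(=O)O", "CCN"))
  for (set_id in c("PROPERTY", "ECFP4", "ECFP4_PROPERTY", "BCUT_GCUT")) {
    desc <- describe_library(rec, set_id)
    s <- similarity_matrix(desc)
    expect_true(all(s >= 0 & s <= 1), info = set_id)
    expect_equal(unname(diag(s)), rep(1, 6), info = set_id)
    expect_equal(s, t(s), info = set_id)
  }
  ## cross-similarity with frozen training scaling stays bounded even for
  ## queries outside the training descriptor ranges
  tr <- rec[1:4, ]; qu <- rec[5:6, ]
  desc_tr <- describe_library(tr, "PROPERTY")
  scl <- descriptor_scaling(desc_tr)
  cs <- cross_similarity(describe_library(qu, "PROPERTY"), desc_tr, scl)
  expect_true(all(cs >= 0 & cs <= 1))
  expect_equal(dim(cs), c(2, 4))
})

test_that("descriptor exports round-trip", {
  rec <- make_records(list(m1 = "ROS", m2 = character(0)),
                      smiles = c("CCO", "CCC"))
  dir <- withr::local_tempdir()
  desc <- describe_library(rec, "ECFP4_PROPERTY")
  p1 <- file.path(dir, "desc.csv")
  write_descriptor_csv(desc, p1)
  tab <- utils::read.csv(p1)
  expect_equal(tab$compound_id, c("m1", "m2"))
  expect_true("mw" %in% names(tab))
  p2 <- file.path(dir, "fp.tsv")
  write_fingerprints(desc, p2)
  lines <- strsplit(readLines(p2), "\t")
  expect_equal(vapply(lines, `[`, "", 1), c("m1", "m2"))
  got <- as.integer(strsplit(lines[[1]][2], " ")[[1]])
  expect_identical(got, desc$fp[[1]])
})
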