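rec3 <- make_records(list(a = "IKK_INHIBITION", b = "IKK_INHIBITION",
                          c = character(0)))
rec_multi <- make_records(list(a = c("ROS", "IKK_INHIBITION"),
                               b = "IKK_INHIBITION"))

test_that("label profiles count multi-label compounds into every class", {
  p <- label_profile(c("a", "b", "c"), rec3, include_unknown = TRUE)
  expect_equal(p$size_total, 3)
  expect_equal(p$size_known, 2)
  expect_equal(p$unknown_count, 1)
  expect_equal(unname(p$fractions["IKK_INHIBITION"]), 2 / 3)

  px <- label_profile(c("a", "b", "c"), rec3, include_unknown = FALSE)
  expect_equal(unname(px$fractions["IKK_INHIBITION"]), 1)

  pm <- label_profile(c("a", "b"), rec_multi, include_unknown = FALSE)
  expect_equal(unname(pm$fractions["IKK_INHIBITION"]), 1)
  expect_equal(unname(pm$fractions["ROS"]), 0.5)
  ## fractions may sum above 1 with multi-label members
  expect_gt(sum(pm$fractions), 1)
  ## label counts exceed size_known iff multi-label members present
  expect_gt(sum(pm$label_counts), pm$size_known)
  expect_equal(sum(label_profile(c("a", "b"), rec3)$label_counts), 2)

  expect_error(label_profile(c("a", "zz"), rec3), "zz")
})

test_that("excluding unknowns never decreases a label fraction", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    labs <- lapply(seq_len(n), function(i)
      sample(interaction_labels(), sample(0:2, 1)))
    names(labs) <- paste0("m", seq_len(n))
    rec <- make_records(labs)
    pin <- label_profile(names(labs), rec, include_unknown = TRUE)
    pout <- label_profile(names(labs), rec, include_unknown = FALSE)
    if (pout$size_known > 0)
      expect_true(all(pout$fractions >= pin$fractions - 1e-12))
  }
})

test_that("predominant labels respect level, ties and degenerate profiles", {
  p <- label_profile(c("a", "b", "c"), rec3, include_unknown = TRUE)
  ## exact 2/3 passes the 66.6% level (inclusive boundary)
  expect_equal(predominant_label(p, 2 / 3), "IKK_INHIBITION")
  expect_equal(predominant_label(p, 0.666), "IKK_INHIBITION")
  expect_true(is.na(predominant_label(p, 0.75)))

  tie <- make_records(list(a = "IKK_INHIBITION", b = "DNA_BINDING"))
  pt <- label_profile(c("a", "b"), tie)
  expect_true(is.na(predominant_label(pt, 0.5)))     # tied maxima

  unk <- make_records(list(a = character(0), b = character(0)))
  pu <- label_profile(c("a", "b"), unk, include_unknown = FALSE)
  expect_true(is.na(predominant_label(pu, 0.5)))     # no denominator
})

test_that("predominance summaries report eligible-cluster percentages", {
  rec <- make_records(list(a = "IKK_INHIBITION", b = "IKK_INHIBITION",
                           c = "DNA_BINDING", d = "DNA_BINDING"))
  s <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  s[1:3, 1:3] <- 0.8; diag(s) <- 1
  cs <- partition_by_centers(s, c("a", "d"))   # {a,b,c} and {d}
  sm <- predominance_summary(cs, rec, levels = 2 / 3, min_sizes = c(1, 2),
                             include_unknown = TRUE)
  ## min size 2: only {a,b,c} eligible, IKK at 2/3 qualifies
  expect_equal(sm$pct_clusters_predominant[sm$min_size == 2], 100)
  ## min size 1: the singleton {d} is trivially 100% its own label
  expect_equal(sm$pct_clusters_predominant[sm$min_size == 1], 100)
  expect_equal(sm$n_clusters_eligible, c(2L, 1L))

  ## all clusters pure single-label: 100% at every level
  pure <- make_records(list(a = "ROS", b = "ROS", c = "DNA_BINDING",
                            d = "DNA_BINDING"))
  s2 <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  s2[1:2, 1:2] <- 0.9; s2[3:4, 3:4] <- 0.9; diag(s2) <- 1
  cs_pure <- partition_by_centers(s2, c("a", "c"))
  smp <- predominance_summary(cs_pure, pure)
  expect_true(all(smp$pct_clusters_predominant == 100 |
                    is.na(smp$pct_clusters_predominant)))

  ## empty size filter: undefined marker, not 0
  sm5 <- predominance_summary(cs, rec, levels = 0.5, min_sizes = 5)
  expect_true(is.na(sm5$pct_clusters_predominant))
  expect_equal(sm5$n_clusters_eligible, 0L)
})

test_that("predominance percentages are non-increasing in level", {
  set.seed(5)
  lib <- generate_fp_library(small_fp_config())
  desc <- describe_library(lib$records, "ECFP4",
                           fingerprints = lib$fingerprints)
  s <- similarity_matrix(desc)
  curve <- suppressWarnings(choose_cluster_count(s, 30, lib$records$compound_id[1]))
  cs <- partition_by_centers(
    s, attr(curve, "centers")[seq_len(attr(curve, "chosen_n"))])
  for (mode in c(TRUE, FALSE)) {
    sm <- predominance_summary(cs, lib$records, include_unknown = mode)
    for (ms in unique(sm$min_size)) {
      v <- sm$pct_clusters_predominant[sm$min_size == ms][order(
        sm$level[sm$min_size == ms])]
      v <- v[!is.na(v)]
      expect_true(all(diff(v) <= 1e-9), info = paste("mode", mode, "ms", ms))
    }
  }
})
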