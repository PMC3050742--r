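test_that("MaxMin center selection follows the greedy rule", {
  s <- fixture_sim4()
  expect_equal(select_centers(s, 1, "A"), "A")
  expect_equal(select_centers(s, 2, "A"), c("A", "C"))
  expect_length(select_centers(s, 4, "A"), 4)
  expect_setequal(select_centers(s, 4, "A"), LETTERS[1:4])
  expect_error(select_centers(s, 5, "A"), "between 1 and")
  expect_error(select_centers(s, 2, "Z"), "Z")
})

test_that("partitioning assigns by maximal similarity with stable ties", {
  s <- fixture_sim4()
  cs <- partition_by_centers(s, c("A", "C"))
  expect_equal(unname(cs$assignment), c(1, 1, 2, 2))
  ## all compounds as centers: all singletons
  cs_all <- partition_by_centers(s, LETTERS[1:4])
  expect_equal(lengths(cs_all$members), rep(1, 4))
  ## equal similarity to both centers joins the earlier one
  tie <- matrix(c(1, .5, .5, .5, 1, .2, .5, .2, 1), 3, 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  cst <- partition_by_centers(tie, c("y", "z"))
  expect_equal(unname(cst$assignment["x"]), 1)
  ## centers always belong to their own cluster
  expect_equal(unname(cst$assignment[c("y", "z")]), c(1, 2))
})

test_that("avg-s matches the pairwise definition", {
  s <- fixture_sim4()
  expect_equal(avg_self_similarity(partition_by_centers(s, LETTERS[1:4]), s), 1)
  expect_equal(avg_self_similarity(partition_by_centers(s, c("A", "C")), s),
               0.85)
  expect_equal(avg_self_similarity(partition_by_centers(s, "A"), s),
               mean(c(.9, .2, .3, .25, .35, .8)))
})

test_that("greedy selection and partitioning match the brute-force oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    s <- random_sim_matrix(n)
    seed_cpd <- sample(rownames(s), 1)
    k <- sample(seq_len(n), 1)
    centers <- select_centers(s, k, seed_cpd)
    expect_identical(centers, oracle_select_centers(s, k, seed_cpd))
    cs <- partition_by_centers(s, centers)
    expect_identical(cs$assignment, oracle_partition(s, centers))
  }
})

test_that("greedy centers are nested across n", {
  set.seed(7)
  for (rep in 1:25) {
    s <- random_sim_matrix(10)
    full <- select_centers(s, 10, "c3")
    for (k in 1:9)
      expect_identical(select_centers(s, k, "c3"), full[1:k])
  }
})

test_that("the avg-s curve matches direct recomputation and the drop rule", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    s <- random_sim_matrix(n)
    curve <- suppressWarnings(choose_cluster_count(s, n, rownames(s)[1]))
    centers <- attr(curve, "centers")
    ## incremental prefix avg-s equals the direct computation at every n
    for (k in seq_len(n)) {
      direct <- oracle_avg_s(oracle_partition(s, centers[1:k]), s)
      expect_equal(curve$avg_s[k], direct, tolerance = 1e-12)
    }
    ## chosen n is the argmax of the drop, smallest n on ties
    drops <- c(NA, -diff(curve$avg_s))
    expect_equal(attr(curve, "chosen_n"),
                 (2:n)[which.max(drops[2:n])])
  }
})

test_that("a curve with no decrease warns and falls back to smallest increase", {
  ## block-diagonal two-group matrix: refinement only increases avg-s
  s <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  s[1:2, 1:2] <- 0.9; s[3:4, 3:4] <- 0.9; diag(s) <- 1
  expect_warning(curve <- choose_cluster_count(s, 4, "A"),
                 "never decreases")
  expect_true(all(diff(curve$avg_s) >= 0))
})

test_that("cluster medoids maximize mean similarity with stable ties", {
  s <- fixture_sim4()
  expect_equal(cluster_medoid("A", s), "A")
  expect_equal(cluster_medoid(c("A", "B"), s), "A")   # symmetric pair: first
  ## {C,D,A}: mean sims C=.5, D=.55, A=.25
  expect_equal(cluster_medoid(c("C", "D", "A"), s), "D")
})

test_that("partition similarity follows the pair-counting formula", {
  p1 <- stats::setNames(c(1, 1, 2, 2), paste0("m", 1:4))
  expect_equal(cluster_set_similarity(p1, p1), 1)
  p2 <- stats::setNames(c(1, 2, 1, 2), paste0("m", 1:4))
  expect_equal(cluster_set_similarity(p1, p2), 0)
  q1 <- stats::setNames(c(1, 1, 2), paste0("m", 1:3))
  q2 <- stats::setNames(c(1, 1, 1), paste0("m", 1:3))
  expect_equal(cluster_set_similarity(q1, q2), 1 / 3)
  expect_equal(cluster_set_similarity(q2, q1), 1 / 3)  # symmetry
  ## all singletons on both sides: 1 by convention
  s1 <- stats::setNames(1:3, paste0("m", 1:3))
  expect_equal(cluster_set_similarity(s1, s1), 1)
  expect_error(cluster_set_similarity(p1, q1), "universe")
})

test_that("partition restriction keeps labels of the shared compounds", {
  p <- stats::setNames(c(1, 1, 2, 3), paste0("m", 1:4))
  r <- restrict_partition(p, c("m2", "m4"))
  expect_equal(r, stats::setNames(c(1, 3), c("m2", "m4")))
})

test_that("cluster CSV serialization records centers", {
  s <- fixture_sim4()
  cs <- partition_by_centers(s, c("A", "C"))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cl.csv")
  write_cluster_csv(cs, p)
  tab <- utils::read.csv(p)
  expect_equal(tab$cluster_index, c(1, 1, 2, 2))
  expect_equal(tab$is_center, c(TRUE, FALSE, TRUE, FALSE))
})
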