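## five-compound training world with two clusters {t1,t2} and {t3,t4},
## used throughout the nearest-cluster tests
pred_fixture <- function() {
  ids <- paste0("t", 1:4)
  s <- matrix(0.1, 4, 4, dimnames = list(ids, ids))
  s[1:2, 1:2] <- 0.9; s[3:4, 3:4] <- 0.9; diag(s) <- 1
  rec <- make_records(list(t1 = "IKK_INHIBITION", t2 = "IKK_INHIBITION",
                           t3 = "DNA_BINDING", t4 = "DNA_BINDING",
                           q1 = "IKK_INHIBITION"))
  cs <- partition_by_centers(s, c("t1", "t3"))
  list(sim = s, records = rec, cs = cs)
}

test_that("nearest-cluster search honours each rule and the size filter", {
  fx <- pred_fixture()
  qsim <- stats::setNames(c(0.9, 0.1, 0.6, 0.6), paste0("t", 1:4))
  cfg_msc <- prediction_config("MOST_SIMILAR_COMPOUND")
  nc <- nearest_cluster(qsim, fx$cs, fx$records, cfg_msc, fx$sim)
  expect_equal(nc$cluster, 1)
  expect_equal(nc$similarity, 0.9)
  cfg_avg <- prediction_config("AVERAGE_SIMILARITY")
  nc2 <- nearest_cluster(qsim, fx$cs, fx$records, cfg_avg, fx$sim)
  expect_equal(nc2$cluster, 2)          # 0.6 beats (0.9+0.1)/2
  expect_equal(nc2$similarity, 0.6)
  ## singleton-only world: min size 2 leaves nothing eligible
  s1 <- diag(2); dimnames(s1) <- list(c("t1", "t3"), c("t1", "t3"))
  css <- partition_by_centers(s1, c("t1", "t3"))
  cfg2 <- prediction_config(min_cluster_size = 2)
  expect_null(nearest_cluster(qsim[c("t1", "t3")], css, fx$records, cfg2, s1))
  ## single eligible cluster is returned
  cfg1 <- prediction_config(min_cluster_size = 2, level = 0.5)
  s3 <- fx$sim[1:3, 1:3]
  cs3 <- partition_by_centers(s3, c("t1", "t3"))
  nc3 <- nearest_cluster(qsim[1:3], cs3, fx$records, cfg1, s3)
  expect_equal(nc3$cluster, 1)
})

test_that("classification abstains below the threshold and on tied labels", {
  fx <- pred_fixture()
  qsim <- matrix(c(0.65, 0.65, 0.1, 0.1), 4, 1,
                 dimnames = list(paste0("t", 1:4), "q1"))
  base <- list(method = "MOST_SIMILAR_COMPOUND", min_size = 1, level = 2/3)
  ## similarity 0.65 under threshold 0.7: abstain
  cfg <- prediction_config("MOST_SIMILAR_COMPOUND",
                           similarity_threshold = 0.7)
  r <- classify_queries(qsim, fx$cs, fx$records, cfg, fx$sim)
  expect_equal(r$predicted, "ABSTAIN")
  expect_false(r$correct)
  ## a score equal to the threshold predicts (inclusive comparison)
  qsim2 <- qsim; qsim2[1:2, 1] <- 0.7
  r2 <- classify_queries(qsim2, fx$cs, fx$records, cfg, fx$sim)
  expect_equal(r2$predicted, "IKK_INHIBITION")
  expect_true(r2$correct)
  ## no threshold: 100% IKK cluster at level 2/3 transfers its label
  cfg3 <- prediction_config("MOST_SIMILAR_COMPOUND")
  r3 <- classify_queries(qsim, fx$cs, fx$records, cfg3, fx$sim)
  expect_equal(r3$predicted, "IKK_INHIBITION")
  ## tied predominant labels: abstain
  tie_rec <- make_records(list(t1 = "IKK_INHIBITION", t2 = "DNA_BINDING",
                               t3 = "DNA_BINDING", t4 = "DNA_BINDING",
                               q1 = "IKK_INHIBITION"))
  cfg4 <- prediction_config("MOST_SIMILAR_COMPOUND", level = 0.5)
  r4 <- classify_queries(qsim, fx$cs, tie_rec, cfg4, fx$sim)
  expect_equal(r4$predicted, "ABSTAIN")
})

test_that("evaluation separates the all-query and predicted-only metrics", {
  res <- data.frame(query_id = c("q1", "q2", "q3"),
                    cluster_index = c(1, 2, NA),
                    similarity = c(.9, .8, NA),
                    predicted = c("ROS", "DNA_BINDING", "ABSTAIN"),
                    correct = c(TRUE, FALSE, FALSE))
  ev <- evaluate_predictions(res)
  expect_equal(ev$pct_correct_all, 100 / 3)
  expect_equal(ev$pct_correct_predicted, 50)
  expect_equal(ev$n_predicted, 2)
  ## multi-label truth counts a hit on either label
  fx <- pred_fixture()
  rec <- fx$records
  rec$labels[rec$compound_id == "q1"] <- list(c("ROS", "IKK_INHIBITION"))
  qsim <- matrix(c(0.9, 0.9, 0.1, 0.1), 4, 1,
                 dimnames = list(paste0("t", 1:4), "q1"))
  r <- classify_queries(qsim, fx$cs, rec, prediction_config(), fx$sim)
  expect_equal(r$predicted, "IKK_INHIBITION")
  expect_true(r$correct)
  ## all abstained: undefined marker for the predicted-only metric
  resa <- res; resa$predicted <- "ABSTAIN"; resa$correct <- FALSE
  eva <- evaluate_predictions(resa)
  expect_equal(eva$pct_correct_all, 0)
  expect_true(is.na(eva$pct_correct_predicted))
  expect_error(evaluate_predictions(res[0, ]), "no queries")
})

test_that("the random baseline matches its analytic expectation", {
  fx <- pred_fixture()
  ## one eligible cluster, 100% IKK, all queries IKK: certainty
  rec1 <- make_records(list(t1 = "IKK_INHIBITION", t2 = "IKK_INHIBITION",
                            q1 = "IKK_INHIBITION"))
  s1 <- fx$sim[1:2, 1:2]
  cs1 <- partition_by_centers(s1, "t1")
  cfg <- prediction_config(level = 0.5)
  bl1 <- random_baseline(cs1, rec1, "q1", cfg, reps = 50, seed = 2)
  expect_equal(bl1$analytic, 100)
  expect_equal(bl1$monte_carlo, 100)
  ## two pure clusters, all queries IKK: expectation 50%
  bl2 <- random_baseline(fx$cs, fx$records, "q1", cfg, reps = 10000, seed = 2)
  expect_equal(bl2$analytic, 50)
  ## Monte Carlo within 3 binomial standard errors of the expectation
  se <- sqrt(0.5 * 0.5 / 10000) * 100
  expect_lt(abs(bl2$monte_carlo - bl2$analytic), 3 * se)
  ## no eligible clusters: zero
  cfg5 <- prediction_config(min_cluster_size = 5)
  bl3 <- random_baseline(fx$cs, fx$records, "q1", cfg5, reps = 10, seed = 2)
  expect_equal(bl3$analytic, 0)
})

test_that("prediction counts are monotone in size filter and threshold", {
  lib <- generate_fp_library(small_fp_config(rng_seed = 31))
  sp <- make_splits(lib$records, n_splits = 1, test_size = 20, seed = 4)[[1]]
  tr <- lib$records[match(sp$train, lib$records$compound_id), ]
  te <- lib$records[match(sp$test, lib$records$compound_id), ]
  fit <- suppressWarnings(
    moa_cluster(tr, "ECFP4", fingerprints = lib$fingerprints))
  ## n_predicted non-increasing in min_cluster_size
  for (mode in c(TRUE, FALSE)) {
    np <- vapply(1:5, function(ms) {
      r <- predict(fit, te, fingerprints = lib$fingerprints,
                   min_size = ms, level = 0.5, include_unknown = mode)
      sum(r$predicted != "ABSTAIN")
    }, 0)
    expect_true(all(diff(np) <= 0), info = paste("mode", mode))
  }
  ## n_predicted non-increasing in similarity threshold
  np_th <- vapply(c(NA, 0.3, 0.5, 0.7, 0.9), function(th) {
    r <- predict(fit, te, fingerprints = lib$fingerprints,
                 min_size = 1, level = 0.5, threshold = th)
    sum(r$predicted != "ABSTAIN")
  }, 0)
  expect_true(all(diff(np_th) <= 0))
  ## threshold absent, level -> 0, min size 1, single-labelled clusters:
  ## every query predicted
  r_all <- predict(fit, te, fingerprints = lib$fingerprints,
                   min_size = 1, level = 1e-9, include_unknown = FALSE)
  pure <- all(vapply(fit$cluster_set$members, function(m) {
    labs <- unique(unlist(fit$records$labels[match(m, fit$records$compound_id)]))
    length(labs) <= 1
  }, TRUE))
  if (pure) expect_true(all(r_all$predicted != "ABSTAIN"))
})
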