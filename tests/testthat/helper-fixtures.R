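## the worked 4-compound similarity matrix used across clustering tests
fixture_sim4 <- function() {
  s <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  s["A", "B"] <- s["B", "A"] <- 0.9
  s["A", "C"] <- s["C", "A"] <- 0.2
  s["A", "D"] <- s["D", "A"] <- 0.3
  s["B", "C"] <- s["C", "B"] <- 0.25
  s["B", "D"] <- s["D", "B"] <- 0.35
  s["C", "D"] <- s["D", "C"] <- 0.8
  s
}

## small synthetic configuration used by fit/pipeline tests (scaled-down
## class counts keep the default test run fast)
small_fp_config <- function(rng_seed = 20, noise_rate = 0.05) {
  synthetic_config(class_counts = c(ROS = 6, TRANSLOCATION_INHIBITION = 4,
                                    DNA_BINDING = 16, IKK_INHIBITION = 30,
                                    IKB_DEG_INHIBITION = 18,
                                    IKB_DEG_ACTIVATION = 4),
                   unknown_count = 30, dual_label_count = 2,
                   series_size = 6, noise_rate = noise_rate,
                   rng_seed = rng_seed)
}

write_smi_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "lib.smi")
  writeLines(lines, path)
  path
}
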