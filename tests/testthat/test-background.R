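neg_matrix <- function(neg_values) {
  # one sample per value so the pooled negatives are exactly neg_values
  cs <- tiny_codeset()
  n <- length(neg_values)
  mat <- matrix(100, 7, n, dimnames = list(cs$gene_id, sprintf("s%d", 1:n)))
  mat["NEG_A", ] <- neg_values
  mat["NEG_B", ] <- neg_values
  tiny_counts(mat, cs, "positive_normalized")
}

test_that("negative-control threshold is mean + k*SD of pooled values", {
  # pooled {17, 25, 33}: mean 25, SD 8 -> 49 at k = 3
  cs <- tiny_codeset()
  mat <- matrix(100, 7, 3, dimnames = list(cs$gene_id, c("s1", "s2", "s3")))
  mat["NEG_A", ] <- c(17, 25, 33)
  mat["NEG_B", ] <- c(17, 25, 33)
  cm <- tiny_counts(mat, cs, "positive_normalized")
  model <- negative_control_threshold(cm, k = 3)
  # both probes identical: pooled mean 25, pooled SD sd(rep(c(17,25,33),2))
  expect_equal(model$neg_mean, 25)
  expect_equal(model$threshold, 25 + 3 * sd(rep(c(17, 25, 33), each = 2)))
  # with a single negative probe the pooled values are exactly the triple
  cs1 <- codeset(data.frame(gene_id = c("g1", "POS_A", "NEG_A"),
                            probe_class = c("target", "positive", "negative"),
                            spike_fmol = c(NA, 1, NA)))
  m1 <- matrix(c(5, 100, 17, 5, 100, 25, 5, 100, 33), nrow = 3,
               dimnames = list(cs1$gene_id, c("s1", "s2", "s3")))
  cm1 <- count_matrix(m1, cs1, data.frame(sample_id = c("s1", "s2", "s3")),
                      "positive_normalized")
  expect_equal(negative_control_threshold(cm1, k = 3)$threshold, 49)
  expect_equal(negative_control_threshold(cm1, k = 0)$threshold, 25)
})

test_that("constant negative counts give threshold = constant for any k", {
  cm <- neg_matrix(c(20, 20, 20))
  for (k in c(0, 1, 3, 10)) {
    expect_equal(negative_control_threshold(cm, k = k)$threshold, 20)
  }
})

test_that("background modeling rejects raw counts and undefined SD", {
  cs <- tiny_codeset()
  mat <- matrix(10, 7, 1, dimnames = list(cs$gene_id, "s1"))
  expect_error(
    negative_control_threshold(tiny_counts(mat, cs, "raw")),
    class = "state_error")
})

test_that("deletion-calibrated threshold follows the max residual plus k SD", {
  panel <- deletion_panel()
  expect_equal(deletion_threshold(panel, k = 4)$threshold, 349)  # 137 + 4*53
  expect_equal(deletion_threshold(panel, k = 4,
                                  rounding = "ceil_to_50")$threshold, 350)
  expect_equal(deletion_threshold(panel, k = 4,
                                  rounding = "ceil_to_100")$threshold, 400)
  expect_equal(deletion_threshold(panel, k = 4)$calibrating_gene, "ins-6")
  one <- data.frame(gene_id = "x", deletion_mean = 100, deletion_sd = 0)
  expect_equal(deletion_threshold(one, k = 4)$threshold, 100)
  expect_error(deletion_threshold(panel[0, ]), class = "model_error")
})

test_that("detection uses strict inequality against the threshold", {
  cs <- tiny_codeset()
  model <- fixed_threshold(400, scope = "L1")
  mat <- matrix(c(31, 1500, 400, 5000, 5000, 10, 10), ncol = 1,
                dimnames = list(cs$gene_id, "s1"))
  cm <- tiny_counts(mat, cs, "positive_normalized")
  calls <- call_detection(cm, model)
  expect_false(calls$calls["g1", "L1"])   # residual-level counts: 31 < 400
  expect_true(calls$calls["g2", "L1"])    # wild-type level: 1500 > 400
  expect_false(calls$calls["g3", "L1"])   # exactly at threshold: not detected
})

test_that("thresholds are nondecreasing and detections nonincreasing in k", {
  set.seed(31)
  cm <- random_count_matrix(40, 6, state = "positive_normalized")
  prev_threshold <- -Inf
  prev_detected <- Inf
  for (k in 0:6) {
    model <- negative_control_threshold(cm, k = k)
    expect_gte(model$threshold, prev_threshold)
    detected <- sum(call_detection(cm, model)$calls)
    expect_lte(detected, prev_detected)
    prev_threshold <- model$threshold
    prev_detected <- detected
  }
})

test_that("raising a probe's counts never flips it from detected to undetected", {
  set.seed(32)
  cm <- random_count_matrix(30, 5, state = "positive_normalized")
  model <- negative_control_threshold(cm, k = 2)
  before <- call_detection(cm, model)$calls[, 1]
  for (probe in sample(rownames(cm$counts), 10)) {
    bumped <- cm
    bumped$counts[probe, ] <- bumped$counts[probe, ] + 500
    after <- call_detection(bumped, model)$calls[, 1]
    expect_true(all(after[before]))
    expect_true(after[[probe]])
  }
})

test_that("detection_summary equals a brute-force recount on random matrices", {
  set.seed(33)
  for (rep in 1:5) {
    n_probes <- sample(10:100, 1)
    n_samples <- sample(2:10, 1)
    cm <- random_count_matrix(n_probes, n_samples,
                              state = "positive_normalized")
    thr <- stats::runif(1, 0, 400)
    calls <- call_detection(cm, fixed_threshold(thr, scope = "all"))
    tab <- detection_summary(calls, cm$codeset)
    for (cc in c("positive", "negative", "target")) {
      ids <- class_probes(cm$codeset, cc)
      brute <- 0L
      for (g in ids) {
        if (mean(cm$counts[g, ]) > thr) brute <- brute + 1L
      }
      expect_identical(tab$all[tab$probe_class == cc], brute)
      expect_identical(tab$n_probes[tab$probe_class == cc], length(ids))
    }
  }
})

test_that("all-zero counts with a zero threshold detect nothing", {
  cs <- tiny_codeset()
  mat <- matrix(0, 7, 2, dimnames = list(cs$gene_id, c("s1", "s2")))
  cm <- tiny_counts(mat, cs, "positive_normalized")
  tab <- detection_summary(
    call_detection(cm, fixed_threshold(0, scope = "all")), cs)
  expect_equal(tab$all, c(0L, 0L, 0L))
})

test_that("negatives are undetected under their own mean+3SD model and detected targets rise with RNA mass", {
  cfg <- synthetic_config(seed = 5)
  cm <- simulate_titration(cfg, masses = c(0, 0.1, 1, 10), n_replicates = 3)
  norm <- normalize_positive_controls(cm)$counts
  masses <- unique(norm$samples$rna_mass)
  groups <- lapply(masses, function(m) {
    norm$samples$sample_id[norm$samples$rna_mass == m]
  })
  names(groups) <- sprintf("m%g", masses)
  models <- lapply(names(groups), function(g) {
    negative_control_threshold(norm, samples = groups[[g]], k = 3, scope = g)
  })
  names(models) <- names(groups)
  calls <- call_detection(norm, models, groups = groups)
  tab <- detection_summary(calls, norm$codeset)
  neg_row <- as.integer(tab[tab$probe_class == "negative", names(groups)])
  expect_true(all(neg_row == 0L))
  target_row <- as.integer(tab[tab$probe_class == "target", names(groups)])
  expect_true(all(diff(target_row) >= 0))
  expect_lt(target_row[1], 5)       # no-RNA control detects (almost) nothing
  expect_gt(target_row[4], 35)      # nearly all targets at the highest mass
})
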