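test_that("standard curve recovers exact log-linear spike response", {
  fit <- fit_standard_curve(c(10, 100, 1000), c(0.1, 1, 10))
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # counts = 100 * fmol exactly, arbitrary ladder
  fmol <- 0.1 * 2^(0:9)
  fit2 <- fit_standard_curve(100 * fmol, fmol)
  expect_equal(fit2$slope, 1, tolerance = 1e-9)
  expect_equal(fit2$intercept, 2, tolerance = 1e-9)
})

test_that("standard curve rejects degenerate inputs and excludes zeros", {
  expect_error(fit_standard_curve(c(10, 20), c(1, 1)), class = "fit_error")
  expect_warning(
    fit <- fit_standard_curve(c(0, 100, 1000), c(0.1, 1, 10)),
    "excluded")
  expect_equal(fit$n_points, 2)
  expect_error(
    suppressWarnings(fit_standard_curve(c(0, 0, 1000), c(0.1, 1, 10))),
    class = "fit_error")
})

test_that("standard curves from different mass conditions agree", {
  cfg <- synthetic_config(seed = 13)
  cs <- simulate_codeset(cfg)
  pos <- class_probes(cs, "positive")
  fmol <- cs$spike_fmol[match(pos, cs$gene_id)]
  fits <- lapply(c(0.1, 10), function(m) {
    cm <- simulate_hybridization(cfg, m, n_replicates = 3)
    norm <- normalize_positive_controls(cm)$counts
    fit_standard_curve(rowMeans(norm$counts[pos, ]), fmol)
  })
  se <- sqrt(sum(vapply(fits, function(f) {
    summary(f$fit)$coefficients[2, 2]^2
  }, 0)))
  expect_lt(abs(fits[[1]]$slope - fits[[2]]$slope), 3 * se)
})

test_that("replicate CV matches hand arithmetic and flags zero means", {
  cs <- tiny_codeset()
  mat <- matrix(c(90, 90, 0, 50, 50, 5, 5,
                  100, 100, 0, 50, 50, 5, 5,
                  110, 110, 0, 50, 50, 5, 5),
                nrow = 7, dimnames = list(cs$gene_id, c("r1", "r2", "r3")))
  cm <- tiny_counts(mat, cs, "positive_normalized")
  cv <- replicate_cv(cm, groups = rep("grp", 3))
  expect_equal(cv$per_gene_cv["g1", "grp"], 10)   # SD 10, mean 100
  expect_equal(cv$per_gene_cv["g2", "grp"], 10)
  expect_true(is.na(cv$per_gene_cv["g3", "grp"]))
  expect_true(cv$undefined["g3", "grp"])
  expect_equal(unname(cv$median_cv["grp"]), 10)   # zero-mean gene excluded
  # identical replicates: all CVs zero
  m2 <- mat[, c(1, 1, 1)]
  colnames(m2) <- c("a", "b", "c")
  same <- tiny_counts(m2, cs, "positive_normalized")
  cv0 <- replicate_cv(same, rep("grp", 3))
  expect_equal(unname(cv0$median_cv["grp"]), 0)
})

test_that("CV is invariant to rescaling a group's counts", {
  set.seed(41)
  cm <- random_count_matrix(30, 6, state = "positive_normalized")
  groups <- rep(c("a", "b"), each = 3)
  base <- replicate_cv(cm, groups)
  scaled <- cm
  scaled$counts[, groups == "b"] <- scaled$counts[, groups == "b"] * 7.3
  res <- replicate_cv(scaled, groups)
  expect_equal(res$per_gene_cv, base$per_gene_cv, tolerance = 1e-12)
})

test_that("Poisson replicates at mean 1000 give median CV near 1/sqrt(1000)", {
  set.seed(42)
  n_genes <- 120
  n_reps <- 60
  cs <- codeset(data.frame(
    gene_id = c(sprintf("t%03d", 1:n_genes), "POS_A", "NEG_A"),
    probe_class = c(rep("target", n_genes), "positive", "negative"),
    spike_fmol = c(rep(NA, n_genes), 1, NA)))
  mat <- rbind(matrix(rpois(n_genes * n_reps, 1000), n_genes, n_reps),
               matrix(1000, 2, n_reps))
  dimnames(mat) <- list(cs$gene_id, sprintf("r%02d", 1:n_reps))
  cm <- count_matrix(mat, cs, data.frame(sample_id = colnames(mat)),
                     "positive_normalized")
  cv <- replicate_cv(cm, rep("grp", n_reps))
  expect_equal(unname(cv$median_cv["grp"]), 100 / sqrt(1000),
               tolerance = 0.12)
})

test_that("replicate groups of size 1 are rejected by name", {
  cm <- random_count_matrix(10, 3, state = "positive_normalized")
  err <- expect_error(replicate_cv(cm, c("a", "a", "lonely")),
                      class = "validation_error")
  expect_match(conditionMessage(err), "lonely")
})

test_that("titration summary reports exact fold-ratios for proportional counts", {
  cs <- tiny_codeset()
  mat <- rbind(c(24, 24, 240, 240), c(24, 24, 240, 240), c(24, 24, 240, 240),
               c(50, 50, 50, 50), c(50, 50, 50, 50),
               c(4, 4, 4, 4), c(4, 4, 4, 4))
  dimnames(mat) <- list(cs$gene_id, sprintf("s%d", 1:4))
  meta <- data.frame(sample_id = sprintf("s%d", 1:4),
                     rna_mass = c(0.1, 0.1, 1, 1))
  cm <- count_matrix(mat, cs, meta, "positive_normalized")
  ts <- titration_summary(cm)
  expect_equal(ts$fold("target", 1, 0.1), 10)
  expect_equal(ts$table["target", "0.1"], 24)
  expect_equal(ts$table["negative", "1"], 4)
  expect_equal(ts$table["sum_counts", "1"], sum(mat[, 3]))
})

test_that("synthetic titration reproduces linear mass scaling and background doubling", {
  cfg <- synthetic_config(seed = 17)
  cm <- simulate_titration(cfg, masses = c(0.1, 1, 10), n_replicates = 3)
  ts <- titration_summary(normalize_positive_controls(cm)$counts)
  expect_equal(ts$fold("target", 1, 0.1), 10, tolerance = 0.2)
  expect_equal(ts$fold("negative", 10, 1), 2, tolerance = 0.25)
})

test_that("group averages equal brute-force recomputation per cell", {
  set.seed(43)
  for (rep in 1:3) {
    cm <- random_count_matrix(sample(5:50, 1), 9)
    groups <- sample(c("x", "y", "z"), 9, replace = TRUE)
    groups[1:3] <- c("x", "y", "z")
    prof <- group_average(cm, groups)
    for (g in unique(groups)) {
      for (gene in rownames(cm$counts)) {
        vals <- cm$counts[gene, groups == g]
        expect_equal(prof$mean[gene, g], mean(vals))
        expect_equal(prof$sd[gene, g],
                     if (length(vals) > 1) sd(vals) else 0)
      }
      expect_equal(unname(prof$n[g]), sum(groups == g))
    }
  }
})

test_that("the platform-comparison design yields 18 group columns from 53 samples", {
  # 18 biological-replicate groups, all but one of size 3
  sizes <- c(rep(3, 17), 2)
  groups <- rep(sprintf("grp%02d", 1:18), times = sizes)
  set.seed(44)
  cs <- tiny_codeset()
  mat <- matrix(rpois(7 * 53, 100), 7, 53,
                dimnames = list(cs$gene_id, sprintf("s%02d", 1:53)))
  cm <- tiny_counts(mat, cs)
  prof <- group_average(cm, groups)
  expect_equal(ncol(prof$mean), 18)
  expect_equal(sum(prof$n), 53)
})

test_that("concordance of a profile with itself or a rescaling is exactly 1", {
  set.seed(45)
  means <- matrix(10^runif(60, 1, 4), 20, 3,
                  dimnames = list(sprintf("g%02d", 1:20), c("A", "B", "C")))
  expect_equal(platform_concordance(means, means)$r, 1)
  expect_equal(platform_concordance(means, means * 37.5)$r, 1)
})

test_that("concordance respects exclusions, scale and alignment errors", {
  set.seed(46)
  means <- matrix(10^runif(30, 1, 4), 10, 3,
                  dimnames = list(sprintf("g%02d", 1:10), c("A", "B", "C")))
  other <- means * exp(rnorm(30, 0, 0.3))
  # wreck two genes on one platform; excluding them must raise r
  other[c("g01", "g02"), ] <- rev(other[c("g01", "g02"), ])
  r_all <- platform_concordance(means, other)$r
  r_excl <- platform_concordance(means, other,
                                 exclude = c("g01", "g02"))$r
  expect_gt(r_excl, r_all)
  res <- platform_concordance(means, other, exclude = c("g01", "g02"))
  expect_equal(res$n_pairs, 24)
  expect_error(
    platform_concordance(means, other[, c("A", "B"), drop = FALSE]),
    class = "alignment_error")
  withzero <- other
  withzero["g03", "A"] <- 0
  expect_warning(res0 <- platform_concordance(means, withzero),
                 "nonpositive")
  expect_equal(res0$dropped_nonpositive, 1)
})

test_that("noisy re-measurements attenuate correlation to the analytic value", {
  set.seed(47)
  n <- 600
  signal <- rnorm(n, 2, 0.5)     # log10 ground truth across gene-groups
  noise_sd <- 0.15
  a <- matrix(10^(signal + rnorm(n, 0, noise_sd)), n, 1,
              dimnames = list(sprintf("g%03d", 1:n), "grp"))
  b <- matrix(10^(signal + rnorm(n, 0, noise_sd)), n, 1,
              dimnames = list(sprintf("g%03d", 1:n), "grp"))
  r <- platform_concordance(a, b)$r
  expected <- 0.5^2 / (0.5^2 + noise_sd^2)
  expect_equal(r, expected, tolerance = 0.05)
})
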