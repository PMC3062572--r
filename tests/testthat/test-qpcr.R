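test_that("a perfect doubling dilution series gives slope -3.3219 and E = 2", {
  copies <- 10^(0:4)
  cts <- 38 + (-1 / log10(2)) * log10(copies)
  curve <- fit_qpcr_curve(cts, copies)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(curve$efficiency, 2, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1, tolerance = 1e-9)
})

test_that("the constructed 3-point series fits slope -3.32 and E near 2", {
  curve <- fit_qpcr_curve(c(30, 26.68, 23.36), c(1e2, 1e3, 1e4))
  expect_equal(curve$slope, -3.32, tolerance = 1e-9)
  expect_equal(curve$efficiency, 2, tolerance = 0.005)
  expect_equal(curve$r_squared, 1, tolerance = 1e-9)
  expect_equal(curve$intercept, 30 + 2 * 3.32, tolerance = 1e-9)
})

test_that("degenerate dilution series are rejected", {
  expect_error(fit_qpcr_curve(c(30, 27), c(1e2, 1e3)), class = "fit_error")
  expect_error(fit_qpcr_curve(c(30, 29, 28), c(100, 200, 400)),
               class = "fit_error")          # span < 2 log10
  expect_error(fit_qpcr_curve(c(23, 27, 30), c(1e2, 1e3, 1e4)),
               class = "curve_quality_error") # Ct rising with copies
})

test_that("Ct-to-copies inverts the curve on the fitted range", {
  copies <- 10^(0:5)
  curve <- fit_qpcr_curve(36 - 3.3219 * log10(copies), copies)
  expect_equal(ct_to_copies(curve$intercept, curve), 1, tolerance = 1e-9)
  expect_equal(ct_to_copies(curve$intercept + curve$slope, curve), 10,
               tolerance = 1e-9)
  for (c0 in c(1, 50, 1e3, 1e5)) {
    expect_equal(ct_to_copies(qpcr_predict_ct(curve, c0), curve), c0,
                 tolerance = 1e-9)
  }
  expect_warning(ct_to_copies(curve$intercept + 5, curve), "extrapolation")
})

test_that("reference normalization divides by the per-sample geometric mean", {
  meas <- data.frame(
    gene_id = rep(c("target_x", "rpl-12", "rpl-19"), 2),
    sample_id = rep(c("s1", "s2"), each = 3),
    copies = c(1000, 100, 400,    # s1: geo mean of refs = 200
               1000, 100, 100))   # s2: geo mean of refs = 100
  res <- reference_normalize(meas, c("rpl-12", "rpl-19"))
  factors <- attr(res, "reference_factors")
  expect_equal(unname(factors), c(200, 100) / 150)
  expect_equal(mean(factors), 1)
  got <- res$normalized_abundance[res$gene_id == "target_x"]
  expect_equal(got, c(1000 / (200 / 150), 1000 / (100 / 150)))
})

test_that("reference normalization cancels a per-sample global scale", {
  meas <- data.frame(
    gene_id = rep(c("a", "b", "rpl-12", "rpl-19"), 3),
    sample_id = rep(c("s1", "s2", "s3"), each = 4),
    copies = c(10, 80, 100, 400,
               10, 80, 100, 400,
               10, 80, 100, 400))
  doubled <- meas
  doubled$copies[doubled$sample_id == "s2"] <-
    2 * doubled$copies[doubled$sample_id == "s2"]
  base <- reference_normalize(meas, c("rpl-12", "rpl-19"))
  pert <- reference_normalize(doubled, c("rpl-12", "rpl-19"))
  # within-sample relative abundances are exactly invariant
  ratio_base <- with(base, normalized_abundance[gene_id == "a" & sample_id == "s2"] /
                       normalized_abundance[gene_id == "b" & sample_id == "s2"])
  ratio_pert <- with(pert, normalized_abundance[gene_id == "a" & sample_id == "s2"] /
                       normalized_abundance[gene_id == "b" & sample_id == "s2"])
  expect_equal(ratio_pert, ratio_base)
  # and sample s2's profile matches the others up to the shared rescale
  a_vals <- pert$normalized_abundance[pert$gene_id == "a"]
  expect_equal(a_vals[2] / a_vals[1], 1, tolerance = 1e-9)
})

test_that("identical profile shapes in different units correlate perfectly", {
  stages <- c("embryo", "L1_arrest", "12h", "24h")
  counts <- matrix(c(10, 100, 50, 20), 1, 4,
                   dimnames = list("g", stages))
  qpcr <- counts * 0.003   # copy numbers, incommensurate units
  res <- platform_profile_compare(qpcr, counts)
  expect_equal(res$correlation, 1)
  expect_equal(res$discordant_stages, "")
})

test_that("a flat profile against a varying one is flagged, not scored", {
  stages <- c("embryo", "L1_arrest", "12h", "24h")
  flat <- matrix(5, 1, 4, dimnames = list("g", stages))
  vary <- matrix(c(10, 100, 50, 20), 1, 4, dimnames = list("g", stages))
  res <- platform_profile_compare(flat, vary)
  expect_true(res$zero_variance)
  expect_true(is.na(res$correlation))
  # the 10x stage on one platform vs 1x on the other is discordant
  expect_match(res$discordant_stages, "L1_arrest")
  expect_error(platform_profile_compare(flat[, 1:2, drop = FALSE],
                                        vary[, 1:2, drop = FALSE]),
               class = "validation_error")
})

test_that("simulated qPCR round-trips planted curves and stage profiles", {
  cfg <- synthetic_config(seed = 61, qpcr_ct_noise = 0)
  profiles <- default_stage_profiles(cfg)
  sim <- simulate_qpcr(cfg, genes = c("sod-3", "ins-1"),
                       stage_profiles = profiles$abundances)
  # fitted curves recover the planted efficiency
  for (g in c("sod-3", "rpl-12")) {
    dil <- sim$dilutions[sim$dilutions$gene_id == g, ]
    curve <- fit_qpcr_curve(dil$ct, dil$copies)
    expect_equal(curve$efficiency, cfg$qpcr_efficiency, tolerance = 1e-6)
    expect_equal(curve$slope,
                 sim$curves$slope[sim$curves$gene_id == g],
                 tolerance = 1e-6)
  }
  # Ct -> copies -> reference normalization recovers the planted shape
  curves <- lapply(split(sim$dilutions, sim$dilutions$gene_id), function(d) {
    fit_qpcr_curve(d$ct, d$copies)
  })
  meas <- sim$measurements
  meas$copies <- suppressWarnings(vapply(seq_len(nrow(meas)), function(i) {
    ct_to_copies(meas$ct[i], curves[[meas$gene_id[i]]])
  }, 0))
  norm <- reference_normalize(meas, sim$reference_genes)
  sod <- norm[norm$gene_id == "sod-3", ]
  prof <- tapply(sod$normalized_abundance, sod$stage, mean)
  planted <- profiles$abundances["sod-3", names(prof)]
  expect_equal(prof / mean(prof), planted / mean(planted),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("qPCR and count platforms agree on simulated shared ground truth", {
  cfg <- synthetic_config(seed = 62)
  profiles <- default_stage_profiles(cfg)
  lc <- simulate_life_cycle(cfg, stage_profiles = profiles)
  n2 <- normalize_target_sum(
    normalize_positive_controls(lc$counts)$counts)$counts
  count_prof <- stage_profile(n2)
  sim <- simulate_qpcr(cfg, genes = c("sod-3", "ins-7"),
                       stage_profiles = profiles$abundances)
  curves <- lapply(split(sim$dilutions, sim$dilutions$gene_id), function(d) {
    fit_qpcr_curve(d$ct, d$copies)
  })
  meas <- sim$measurements
  meas$copies <- suppressWarnings(vapply(seq_len(nrow(meas)), function(i) {
    ct_to_copies(meas$ct[i], curves[[meas$gene_id[i]]])
  }, 0))
  norm <- reference_normalize(meas, sim$reference_genes)
  qpcr_means <- do.call(rbind, lapply(c("sod-3", "ins-7"), function(g) {
    sub <- norm[norm$gene_id == g, ]
    tapply(sub$normalized_abundance, sub$stage, mean)[life_cycle_stages()]
  }))
  rownames(qpcr_means) <- c("sod-3", "ins-7")
  colnames(qpcr_means) <- life_cycle_stages()
  res <- platform_profile_compare(qpcr_means, count_prof)
  expect_true(all(res$correlation > 0.9))
})
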