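#' Configuration for the synthetic data generator
#'
#' The generator emulates the statistical structure of a digital
#' barcode-count hybridization assay so that every pipeline stage can be
#' tested against known ground truth:
#'
#' * target probes: expected count `a_g * m * u + b(m)` for per-gene
#'   abundance `a_g` (expected counts per microgram), RNA mass `m`
#'   (micrograms) and a lognormal efficiency factor `u` with mean 1 and CV
#'   `replicate_noise_cv`, drawn independently per probe and replicate —
#'   counts linear in RNA mass;
#' * positive controls: `spike_count_per_fmol * fmol + b(m)`, independent
#'   of `m` (the spike-ins are part of the code set, not the sample);
#' * negative controls: `b(m)` alone;
#' * nonspecific background `b(m)`: flat at `b0` up to 1 ug, doubling by
#'   10 ug, log-linear in between (`b(m) = b0 * 2^log10(m)` for
#'   1 < m <= 10); background exists even with no RNA (`b(0) = b0`), so
#'   target probes behave like negative controls at `m = 0`;
#' * observed counts are Poisson draws around these expectations
#'   (Poisson-lognormal compound noise: Poisson molecule counting plus a
#'   multiplicative hybridization-efficiency factor, which reproduces the
#'   CV floor seen at high counts that pure Poisson noise cannot).
#'
#' Default sizes mirror the insulin-like code set (43 targets, 10 positive
#' spike-ins on a 2-fold ladder from 0.1 fmol, 8 negatives). Default rates
#' are calibrated to a typical titration of that code set: mean target
#' abundance ~2240 counts/ug, background `b0` = 24 counts, 550 counts/fmol
#' (so the mean positive-control count is ~5628 and the 0.1 fmol spike sits
#' at ~55 counts, near the detection boundary), technical CV 8%. Biological
#' replicates add a second lognormal factor with CV `bio_noise_cv`.
#' Deletion strains retain a residual fraction `residual_crosshyb` of the
#' deleted gene's own specific signal (cross-hybridization within the gene
#' family scales with the wild-type expression level).
#'
#' @param n_targets,n_positives,n_negatives probe-class sizes.
#' @param target_abundances optional named vector of per-gene abundances
#'   `a_g` (counts/ug); by default drawn log-uniformly over three decades
#'   (seeded) and scaled to `mean_abundance`.
#' @param mean_abundance mean of the default abundance draw, counts/ug.
#' @param spike_fmols spike-in amounts, fmol (length `n_positives`).
#' @param spike_count_per_fmol counts per fmol of spiked transcript.
#' @param b0 baseline background, counts.
#' @param replicate_noise_cv technical lognormal CV `tau`.
#' @param bio_noise_cv additional biological-replicate lognormal CV.
#' @param residual_crosshyb residual fraction `rho` in [0, 1) for deletion
#'   strains.
#' @param qpcr_efficiency planted qPCR amplification efficiency in (1, 2.2].
#' @param qpcr_ct_noise SD of Gaussian Ct noise, cycles.
#' @param qpcr_scale copies per count-unit of abundance in a qPCR reaction.
#' @param qpcr_sample_cv lognormal CV of the per-sample cDNA-preparation
#'   factor (removed by reference-gene normalization).
#' @param seed integer seed; identical config + seed give bit-identical
#'   simulated data.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_targets = 43, n_positives = 10,
                             n_negatives = 8, target_abundances = NULL,
                             mean_abundance = 2240,
                             spike_fmols = 0.1 * 2^(0:(n_positives - 1)),
                             spike_count_per_fmol = 550, b0 = 24,
                             replicate_noise_cv = 0.08, bio_noise_cv = 0.15,
                             residual_crosshyb = 0.05,
                             qpcr_efficiency = 2, qpcr_ct_noise = 0.1,
                             qpcr_scale = 1, qpcr_sample_cv = 0.25,
                             seed = 1) {
  stopifnot(n_targets >= 1, n_positives >= 1, n_negatives >= 1,
            length(spike_fmols) == n_positives, all(spike_fmols > 0),
            spike_count_per_fmol > 0, b0 > 0, replicate_noise_cv >= 0,
            bio_noise_cv >= 0, mean_abundance > 0,
            residual_crosshyb >= 0, residual_crosshyb < 1,
            qpcr_efficiency > 1, qpcr_efficiency <= 2.2,
            qpcr_ct_noise >= 0, qpcr_scale > 0, qpcr_sample_cv >= 0)
  seed <- as.integer(seed)
  gene_ids <- target_gene_ids(n_targets)
  if (is.null(target_abundances)) {
    set.seed(derive_seed(seed, 1L))
    raw <- 10^stats::runif(n_targets, 0.5, 3.5)
    target_abundances <- stats::setNames(raw * mean_abundance / mean(raw),
                                         gene_ids)
  } else {
    stopifnot(length(target_abundances) == n_targets,
              all(target_abundances > 0))
    if (is.null(names(target_abundances))) {
      names(target_abundances) <- gene_ids
    }
    gene_ids <- names(target_abundances)
  }
  structure(list(
    n_targets = n_targets, n_positives = n_positives,
    n_negatives = n_negatives, target_abundances = target_abundances,
    spike_fmols = spike_fmols, spike_count_per_fmol = spike_count_per_fmol,
    b0 = b0, replicate_noise_cv = replicate_noise_cv,
    bio_noise_cv = bio_noise_cv, residual_crosshyb = residual_crosshyb,
    qpcr_efficiency = qpcr_efficiency, qpcr_ct_noise = qpcr_ct_noise,
    qpcr_scale = qpcr_scale, qpcr_sample_cv = qpcr_sample_cv,
    seed = seed), class = "synthetic_config")
}

#' @noRd
target_gene_ids <- function(n_targets) {
  if (n_targets == 43) {
    c(sprintf("ins-%d", 1:40), "daf-2", "daf-16", "sod-3")
  } else {
    sprintf("target_%02d", seq_len(n_targets))
  }
}

#' Expected nonspecific background at a given RNA mass
#'
#' @param config a [synthetic_config].
#' @param mass RNA mass, micrograms (>= 0).
#' @return expected background counts `b(m)`.
#' @export
background_rate <- function(config, mass) {
  stopifnot(inherits(config, "synthetic_config"), all(mass >= 0))
  ifelse(mass <= 1, config$b0,
         config$b0 * 2^pmin(log10(pmax(mass, 1)), 1))
}

#' Simulate a code set
#'
#' @param config a [synthetic_config].
#' @return a [codeset] with `n_targets + n_positives + n_negatives` probes.
#' @export
simulate_codeset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- c(names(config$target_abundances),
           sprintf("POS_%02d", seq_len(config$n_positives)),
           sprintf("NEG_%02d", seq_len(config$n_negatives)))
  classes <- c(rep("target", config$n_targets),
               rep("positive", config$n_positives),
               rep("negative", config$n_negatives))
  fmol <- c(rep(NA_real_, config$n_targets), config$spike_fmols,
            rep(NA_real_, config$n_negatives))
  flags <- rep(NA_character_, length(ids))
  flags[ids == "ins-13"] <- "reports expression of acdh-2"
  codeset(data.frame(gene_id = ids, probe_class = classes,
                     spike_fmol = fmol, specificity_flag = flags,
                     stringsAsFactors = FALSE))
}

#' @noRd
expected_lambda <- function(config, mass, u) {
  # u: per-target-probe efficiency factors for one replicate
  b <- background_rate(config, mass)
  c(config$target_abundances * mass * u + b,
    config$spike_count_per_fmol * config$spike_fmols + b,
    rep(b, config$n_negatives))
}

#' Simulate one hybridization condition
#'
#' Draws `n_replicates` technical replicates at RNA mass `mass` from the
#' generative model described in [synthetic_config()].
#'
#' @param config a [synthetic_config].
#' @param mass RNA mass in micrograms (0 = no-RNA control).
#' @param n_replicates number of replicates.
#' @param stream RNG stream index; the default separates masses so a
#'   titration built mass-by-mass is reproducible as a whole.
#' @param condition condition label stored in the sample metadata.
#' @param strain strain label.
#' @param biological if TRUE, replicates also receive the biological
#'   lognormal factor (`bio_noise_cv`) on their specific signal.
#' @return a raw [count_matrix].
#' @export
simulate_hybridization <- function(config, mass, n_replicates = 3,
                                   stream = NULL, condition = NULL,
                                   strain = "wildtype", biological = FALSE) {
  stopifnot(inherits(config, "synthetic_config"), n_replicates >= 1)
  if (mass < 0) abort("RNA mass must be >= 0", "validation_error")
  stream <- stream %||% (1000L + as.integer(round(mass * 100)))
  set.seed(derive_seed(config$seed, stream))
  cs <- simulate_codeset(config)
  counts <- vapply(seq_len(n_replicates), function(r) {
    u <- rlnorm_cv(config$n_targets, config$replicate_noise_cv)
    if (biological) u <- u * rlnorm_cv(config$n_targets, config$bio_noise_cv)
    stats::rpois(nrow(cs), expected_lambda(config, mass, u))
  }, numeric(nrow(cs)))
  rownames(counts) <- cs$gene_id
  condition <- condition %||% sprintf("mass_%g", mass)
  samples <- data.frame(
    sample_id = sprintf("%s_rep%d", condition, seq_len(n_replicates)),
    rna_mass = mass, condition = condition,
    replicate = seq_len(n_replicates), strain = strain,
    stringsAsFactors = FALSE)
  count_matrix(counts, cs, samples, "raw")
}

#' Simulate an RNA input-mass titration
#'
#' One call per mass via [simulate_hybridization()] (each on its own RNG
#' stream), combined into a single raw [count_matrix]. The default masses
#' reproduce a no-RNA / 0.1 / 1 / 10 ug technical titration with 3
#' replicates per mass.
#'
#' @param config a [synthetic_config].
#' @param masses RNA masses in micrograms.
#' @param n_replicates replicates per mass.
#' @return a raw [count_matrix] with `length(masses) * n_replicates`
#'   samples.
#' @export
simulate_titration <- function(config, masses = c(0, 0.1, 1, 10),
                               n_replicates = 3) {
  parts <- lapply(masses, function(m) {
    simulate_hybridization(config, m, n_replicates)
  })
  do.call(combine_counts, parts)
}

#' Simulate a deletion strain
#'
#' Identical to the wild-type hybridization on the same RNG stream except
#' that the deleted gene's specific signal is replaced by the residual
#' cross-hybridization fraction `rho`: its expected count becomes
#' `rho * a_g * m * u + b(m)`. All other probes are bit-identical to the
#' wild-type run, so wild-type vs deletion differences are confined to the
#' deleted gene.
#'
#' @param config a [synthetic_config].
#' @param gene target gene id to delete.
#' @param mass RNA mass, micrograms.
#' @param n_replicates number of replicates.
#' @param stream RNG stream (must match the wild-type run for paired
#'   comparisons).
#' @return a raw [count_matrix] with `strain = "<gene>_deletion"`.
#' @export
simulate_deletion_strain <- function(config, gene, mass, n_replicates = 3,
                                     stream = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!gene %in% names(config$target_abundances)) {
    abort(sprintf("'%s' is not a target gene of this code set", gene),
          "validation_error")
  }
  wt <- simulate_hybridization(config, mass, n_replicates, stream = stream)
  stream <- stream %||% (1000L + as.integer(round(mass * 100)))
  # re-draw only the deleted gene's row on its own stream
  set.seed(derive_seed(config$seed, stream + 7L))
  u <- rlnorm_cv(n_replicates, config$replicate_noise_cv)
  lambda <- config$residual_crosshyb * config$target_abundances[[gene]] *
    mass * u + background_rate(config, mass)
  counts <- wt$counts
  counts[gene, ] <- stats::rpois(n_replicates, lambda)
  samples <- wt$samples
  samples$strain <- sprintf("%s_deletion", gene)
  samples$sample_id <- sprintf("%s_%s", samples$strain, samples$sample_id)
  colnames(counts) <- samples$sample_id
  count_matrix(counts, wt$codeset, samples, "raw")
}

#' Default planted life-cycle stage profiles
#'
#' Builds gene x stage ground-truth abundances (counts/ug at the reference
#' efficiency) planting every pattern class the classifier knows: a
#' sod-3-like gene 10x up in L1 arrest and 30x up in dauer relative to
#' developing larvae; embryo-specific, adult-enriched, arrest-enriched and
#' larval-peaking genes with 12-fold on/off contrast; genes below
#' background; and broadly expressed genes at varied flat levels. Designed
#' so that each planted gene unambiguously satisfies exactly one
#' classification rule at `F_min = 3`.
#'
#' @param config a [synthetic_config].
#' @return list with `abundances` (genes x 8 stages matrix) and `labels`
#'   (data frame `gene_id`, `label` of planted ground truth).
#' @export
default_stage_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- names(config$target_abundances)
  n <- length(genes)
  stages <- life_cycle_stages()
  ab <- matrix(0, n, length(stages), dimnames = list(genes, stages))
  labels <- rep("broadly_expressed", n)

  # proportions of each planted class, scaled to the code-set size
  n_embryo <- max(1, round(0.09 * n))
  n_adult <- max(1, round(0.05 * n))
  n_arrest <- max(1, round(0.14 * n))
  n_larval <- max(1, round(0.19 * n))
  n_below <- max(1, round(0.07 * n))
  has_sod3 <- "sod-3" %in% genes
  idx <- setdiff(seq_len(n), which(genes == "sod-3"))
  take <- function(k) {
    got <- idx[seq_len(min(k, length(idx)))]
    idx <<- setdiff(idx, got)
    got
  }
  if (has_sod3) {
    i <- which(genes == "sod-3")
    ab[i, ] <- 200
    ab[i, "L1_arrest"] <- 2000   # 10x developing larvae
    ab[i, "dauer"] <- 6000       # 30x developing larvae
    labels[i] <- "arrest_enriched"
  }
  for (i in take(n_embryo)) {
    ab[i, "embryo"] <- 1200
    labels[i] <- "embryo_specific"
  }
  for (i in take(n_adult)) {
    ab[i, "60h"] <- 1200
    labels[i] <- "adult_enriched"
  }
  for (i in take(n_arrest)) {
    ab[i, ] <- 100
    ab[i, c("L1_arrest", "dauer")] <- 1200
    labels[i] <- "arrest_enriched"
  }
  larval <- larval_stages()
  larval_idx <- take(n_larval)
  for (k in seq_along(larval_idx)) {
    i <- larval_idx[k]
    peak <- larval[((k - 1) %% 4) + 1]
    ab[i, ] <- 50
    ab[i, larval] <- 150
    ab[i, peak] <- 1800
    labels[i] <- "larval_peaking"
  }
  for (i in take(n_below)) {
    ab[i, ] <- 1
    labels[i] <- "below_background"
  }
  # broadly expressed genes carry most of the target content, keeping
  # per-stage target totals near-constant (the premise of target-sum
  # normalization)
  set.seed(derive_seed(config$seed, 2L))
  flat <- 10^stats::runif(length(idx), log10(2000), log10(20000))
  for (k in seq_along(idx)) {
    ab[idx[k], ] <- flat[k]
  }
  list(abundances = ab,
       labels = data.frame(gene_id = genes, label = labels,
                           stringsAsFactors = FALSE))
}

#' Simulate a life-cycle experiment
#'
#' Eight stages x `n_replicates` biological replicates at a fixed 3 ug RNA
#' input, with each gene's abundance taken from `stage_profiles` instead of
#' the flat titration abundances. Biological replicates carry both the
#' technical and the biological lognormal factors. Ground-truth pattern
#' labels are returned alongside the counts.
#'
#' @param config a [synthetic_config].
#' @param stage_profiles optional list as returned by
#'   [default_stage_profiles()] (or a plain genes x stages abundance
#'   matrix, in which case no truth labels are attached).
#' @param n_replicates biological replicates per stage (default 3).
#' @param mass RNA mass per hybridization, micrograms (default 3).
#' @return list with `counts` (raw [count_matrix], `condition` = stage) and
#'   `truth` (planted label data frame, or NULL).
#' @export
simulate_life_cycle <- function(config, stage_profiles = NULL,
                                n_replicates = 3, mass = 3) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(stage_profiles)) stage_profiles <- default_stage_profiles(config)
  if (is.matrix(stage_profiles)) {
    stage_profiles <- list(abundances = stage_profiles, labels = NULL)
  }
  ab <- stage_profiles$abundances
  stopifnot(identical(rownames(ab), names(config$target_abundances)))
  if (any(ab < 0)) abort("stage abundances must be >= 0", "validation_error")
  cs <- simulate_codeset(config)
  stages <- colnames(ab)
  b <- background_rate(config, mass)
  pos_lambda <- config$spike_count_per_fmol * config$spike_fmols + b
  parts <- lapply(seq_along(stages), function(s) {
    set.seed(derive_seed(config$seed, 3000L + s))
    counts <- vapply(seq_len(n_replicates), function(r) {
      u <- rlnorm_cv(config$n_targets, config$replicate_noise_cv) *
        rlnorm_cv(config$n_targets, config$bio_noise_cv)
      lambda <- c(ab[, s] * mass * u + b, pos_lambda,
                  rep(b, config$n_negatives))
      stats::rpois(nrow(cs), lambda)
    }, numeric(nrow(cs)))
    rownames(counts) <- cs$gene_id
    samples <- data.frame(
      sample_id = sprintf("%s_rep%d", stages[s], seq_len(n_replicates)),
      rna_mass = mass, condition = stages[s],
      replicate = seq_len(n_replicates), strain = "wildtype",
      stringsAsFactors = FALSE)
    count_matrix(counts, cs, samples, "raw")
  })
  list(counts = do.call(combine_counts, parts),
       truth = stage_profiles$labels)
}

#' Simulate qPCR measurements and dilution series
#'
#' Emulates cross-validation of the count platform by qPCR: per-gene
#' genomic-DNA dilution series (for standard-curve fitting) and per-sample
#' Ct measurements whose underlying copy numbers are proportional to the
#' same stage abundances used for the count simulation, multiplied by a
#' per-sample cDNA-preparation factor that reference-gene normalization
#' must remove. Reference genes (`rpl-12`, `rpl-19`) have constant
#' abundance across stages. `Ct = intercept + slope * log10(copies) +
#' Gaussian noise` with `slope = -1/log10(E)`.
#'
#' @param config a [synthetic_config].
#' @param genes target genes to assay (must be rows of `stage_profiles`).
#' @param stage_profiles genes x stages abundance matrix (counts/ug), e.g.
#'   `default_stage_profiles(config)$abundances`.
#' @param n_replicates biological replicates per stage.
#' @param dilution_copies copy numbers of the gDNA dilution series.
#' @param reference_abundance abundance of the two reference genes.
#' @return list with `dilutions` (gene_id, copies, ct), `measurements`
#'   (gene_id, sample_id, stage, replicate, ct), `curves` (planted slope /
#'   intercept per gene) and `reference_genes`.
#' @export
simulate_qpcr <- function(config, genes, stage_profiles, n_replicates = 3,
                          dilution_copies = 10^(2:6),
                          reference_abundance = 5000) {
  stopifnot(inherits(config, "synthetic_config"),
            all(genes %in% rownames(stage_profiles)))
  stages <- colnames(stage_profiles)
  refs <- c("rpl-12", "rpl-19")
  all_genes <- c(genes, refs)
  slope <- -1 / log10(config$qpcr_efficiency)
  set.seed(derive_seed(config$seed, 4000L))
  intercepts <- stats::setNames(stats::runif(length(all_genes), 34, 38),
                                all_genes)
  abundance <- rbind(stage_profiles[genes, , drop = FALSE],
                     matrix(reference_abundance, 2, length(stages),
                            dimnames = list(refs, stages)))
  # per-sample global cDNA-preparation factor
  n_samples <- length(stages) * n_replicates
  prep <- rlnorm_cv(n_samples, config$qpcr_sample_cv)
  sample_grid <- expand.grid(replicate = seq_len(n_replicates),
                             stage = stages, stringsAsFactors = FALSE)
  sample_grid$sample_id <- sprintf("%s_rep%d", sample_grid$stage,
                                   sample_grid$replicate)
  measurements <- do.call(rbind, lapply(seq_len(nrow(sample_grid)), function(i) {
    s <- sample_grid$stage[i]
    copies <- pmax(abundance[, s] * config$qpcr_scale * prep[i], 1e-6)
    ct <- intercepts[all_genes] + slope * log10(copies) +
      stats::rnorm(length(all_genes), 0, config$qpcr_ct_noise)
    data.frame(gene_id = all_genes, sample_id = sample_grid$sample_id[i],
               stage = s, replicate = sample_grid$replicate[i], ct = ct,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  dilutions <- do.call(rbind, lapply(all_genes, function(g) {
    data.frame(gene_id = g, copies = dilution_copies,
               ct = intercepts[[g]] + slope * log10(dilution_copies) +
                 stats::rnorm(length(dilution_copies), 0,
                              config$qpcr_ct_noise),
               stringsAsFactors = FALSE)
  }))
  list(dilutions = dilutions, measurements = measurements,
       curves = data.frame(gene_id = all_genes, slope = slope,
                           intercept = unname(intercepts[all_genes]),
                           efficiency = config$qpcr_efficiency,
                           stringsAsFactors = FALSE),
       reference_genes = refs)
}
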