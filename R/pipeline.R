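#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills defaults, and validates strictly:
#' unknown keys at any level are rejected (not ignored) with an error
#' listing every offending key, so typos cannot silently disable a stage.
#'
#' Recognized keys:
#' * `seed` (integer), `outdir` (output directory)
#' * `input`: `codeset`, `counts`, `metadata` (paths), `norm_state`
#'   declared for the counts file (default `"raw"`)
#' * `simulate`: `preset` (`"titration"`, `"lifecycle"` or `"deletion"`),
#'   `masses`, `n_replicates`, `gene` (deletion preset)
#' * `normalization`: ordered subset of `"positive"`, `"target_sum"`
#' * `background`: `method` (`"negctrl"`, `"deletion"`, `"fixed"`), `k`,
#'   `rounding`, `threshold` (fixed), `group_by` (metadata column defining
#'   per-scope thresholds; default `"condition"`)
#' * `detection`: `enabled`, `statistic` (`"group_mean"` / `"per_sample"`)
#' * `profile`: `enabled`, `stages` (metadata column), `stage_order`
#' * `classify`: `enabled`, `min_fold`, `threshold`
#'
#' Exactly one of `input` and `simulate` must be given.
#'
#' @param path path to a YAML config file.
#' @return a validated `pipeline_config` list with defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file '%s' does not exist", path), "io_error")
  }
  raw <- yaml::read_yaml(path)
  validate_config(raw, dir = dirname(normalizePath(path)))
}

#' @noRd
config_schema <- function() {
  list(
    seed = NULL, outdir = NULL,
    input = c("codeset", "counts", "metadata", "norm_state"),
    simulate = c("preset", "masses", "n_replicates", "gene"),
    normalization = NULL,
    background = c("method", "k", "rounding", "threshold", "group_by"),
    detection = c("enabled", "statistic"),
    profile = c("enabled", "stages", "stage_order"),
    classify = c("enabled", "min_fold", "threshold"))
}

#' Validate a pipeline configuration list
#'
#' @param raw a named list (as from [yaml::read_yaml()]).
#' @param dir directory against which relative input paths are resolved.
#' @return a `pipeline_config`.
#' @export
validate_config <- function(raw, dir = ".") {
  schema <- config_schema()
  offending <- setdiff(names(raw), names(schema))
  for (section in intersect(names(raw), names(schema))) {
    allowed <- schema[[section]]
    if (!is.null(allowed) && is.list(raw[[section]])) {
      bad <- setdiff(names(raw[[section]]), allowed)
      offending <- c(offending, sprintf("%s.%s", section, bad))
    }
  }
  if (length(offending) > 0) {
    abort(sprintf("unknown config key(s): %s",
                  paste(offending, collapse = ", ")),
          "config_error", keys = offending)
  }
  if (!is.null(raw$input) && !is.null(raw$simulate)) {
    abort("config must set either 'input' or 'simulate', not both",
          "config_error")
  }
  if (is.null(raw$input) && is.null(raw$simulate)) {
    abort("config must set one of 'input' or 'simulate'", "config_error")
  }
  cfg <- list(
    seed = as.integer(raw$seed %||% 1L),
    outdir = raw$outdir %||% "inscount_results",
    input = raw$input,
    simulate = raw$simulate,
    normalization = raw$normalization %||% c("positive", "target_sum"),
    background = utils::modifyList(
      list(method = "negctrl", k = 3, rounding = "none",
           group_by = "condition"),
      raw$background %||% list()),
    detection = utils::modifyList(
      list(enabled = TRUE, statistic = "group_mean"),
      raw$detection %||% list()),
    profile = utils::modifyList(
      list(enabled = TRUE, stages = "condition"),
      raw$profile %||% list()),
    classify = utils::modifyList(
      list(enabled = TRUE, min_fold = 3),
      raw$classify %||% list()))
  if (!all(cfg$normalization %in% c("positive", "target_sum"))) {
    abort("normalization steps must be among: positive, target_sum",
          "config_error")
  }
  if (identical(cfg$normalization, "target_sum")) {
    abort("target_sum normalization requires the positive step first",
          "config_error")
  }
  if (!cfg$background$method %in% c("negctrl", "fixed")) {
    abort("pipeline background method must be 'negctrl' or 'fixed' (deletion thresholds are computed from deletion summaries via deletion_threshold())",
          "config_error")
  }
  if (cfg$background$method == "fixed" && is.null(cfg$background$threshold)) {
    abort("fixed background method requires background.threshold",
          "config_error")
  }
  if (!is.null(cfg$simulate)) {
    cfg$simulate$preset <- match.arg(cfg$simulate$preset,
                                     c("titration", "lifecycle", "deletion"))
    cfg$simulate$n_replicates <- cfg$simulate$n_replicates %||% 3L
  }
  if (!is.null(cfg$input)) {
    for (key in c("codeset", "counts")) {
      if (is.null(cfg$input[[key]])) {
        abort(sprintf("input.%s is required", key), "config_error")
      }
      p <- cfg$input[[key]]
      if (!file.exists(p) && file.exists(file.path(dir, p))) {
        cfg$input[[key]] <- file.path(dir, p)
      }
      if (!file.exists(cfg$input[[key]])) {
        abort(sprintf("input file does not exist: %s", p), "config_error")
      }
    }
    if (!is.null(cfg$input$metadata) && !file.exists(cfg$input$metadata)) {
      if (file.exists(file.path(dir, cfg$input$metadata))) {
        cfg$input$metadata <- file.path(dir, cfg$input$metadata)
      } else {
        abort(sprintf("input file does not exist: %s", cfg$input$metadata),
              "config_error")
      }
    }
    cfg$input$norm_state <- cfg$input$norm_state %||% "raw"
  }
  structure(cfg, class = "pipeline_config")
}

#' Serialize an effective pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full quantification pipeline
#'
#' Composes the stages in assay order — acquire counts (simulated preset or
#' files), positive-control normalization, optional target-sum
#' normalization, background modeling, detection calling, stage profiling
#' and pattern classification — writing every result table plus a JSON run
#' manifest (parameters, package version, seed, input checksums, records
#' in/out per stage) to `config$outdir`. Identical config and inputs give
#' byte-identical result tables.
#'
#' @param config a `pipeline_config` from [load_config()] /
#'   [validate_config()].
#' @param quiet suppress stage-boundary log messages.
#' @return (invisibly) a list with the normalized counts, normalization
#'   results, background models, detection calls and summary, profile,
#'   labels, truth (simulated runs) and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[inscount] ", fmt), ...))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "inscount",
                   version = as.character(utils::packageVersion("inscount")),
                   config = unclass(config), stages = list())
  truth <- NULL

  # --- acquire counts -----------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- synthetic_config(seed = config$seed)
    counts <- switch(config$simulate$preset,
      titration = simulate_titration(
        sim_cfg, masses = unlist(config$simulate$masses %||% c(0, 0.1, 1, 10)),
        n_replicates = config$simulate$n_replicates),
      lifecycle = {
        lc <- simulate_life_cycle(sim_cfg,
                                  n_replicates = config$simulate$n_replicates)
        truth <- lc$truth
        lc$counts
      },
      deletion = simulate_deletion_strain(
        sim_cfg, gene = config$simulate$gene %||% "ins-4", mass = 3,
        n_replicates = config$simulate$n_replicates))
    if (!is.null(truth)) {
      write_table(truth, file.path(config$outdir, "truth_labels.tsv"))
    }
  } else {
    cs <- read_codeset(config$input$codeset)
    meta <- if (!is.null(config$input$metadata)) {
      read_sample_meta(config$input$metadata)
    } else NULL
    counts <- read_counts(config$input$counts, cs, samples = meta,
                          norm_state = config$input$norm_state)
    manifest$input_checksums <- as.list(tools::md5sum(unlist(
      config$input[c("codeset", "counts", "metadata")], use.names = TRUE)))
  }
  log_msg("input: %d probes x %d samples (%s)", nrow(counts$counts),
          ncol(counts$counts), counts$norm_state)
  manifest$stages$input <- list(probes = nrow(counts$counts),
                                samples = ncol(counts$counts),
                                norm_state = counts$norm_state)

  # --- normalization ------------------------------------------------------
  norm_results <- list()
  if ("positive" %in% config$normalization && counts$norm_state == "raw") {
    step <- normalize_positive_controls(counts)
    counts <- step$counts
    norm_results$positive <- step$normalization
    write_table(data.frame(sample_id = names(step$normalization$factors),
                           factor = unname(step$normalization$factors)),
                file.path(config$outdir, "factors_positive.tsv"))
    log_msg("positive-control normalization: reference %.4g",
            step$normalization$reference_value)
  }
  if ("target_sum" %in% config$normalization &&
      counts$norm_state == "positive_normalized") {
    step <- normalize_target_sum(counts)
    counts <- step$counts
    norm_results$target_sum <- step$normalization
    write_table(data.frame(sample_id = names(step$normalization$factors),
                           factor = unname(step$normalization$factors)),
                file.path(config$outdir, "factors_target_sum.tsv"))
    log_msg("target-sum normalization: reference %.4g",
            step$normalization$reference_value)
  }
  write_table(counts, file.path(config$outdir, "normalized_counts.tsv"))
  manifest$stages$normalization <- list(steps = config$normalization,
                                        final_state = counts$norm_state)

  # --- background + detection --------------------------------------------
  groups_col <- config$background$group_by
  group_labels <- unique(counts$samples[[groups_col]])
  groups <- lapply(group_labels, function(g) {
    counts$samples$sample_id[counts$samples[[groups_col]] == g]
  })
  names(groups) <- group_labels
  models <- lapply(group_labels, function(g) {
    if (config$background$method == "fixed") {
      fixed_threshold(config$background$threshold, scope = g)
    } else {
      negative_control_threshold(counts, samples = groups[[g]],
                                 k = config$background$k, scope = g)
    }
  })
  names(models) <- group_labels
  thresholds <- vapply(models, `[[`, 0, "threshold")
  write_table(data.frame(scope = group_labels, threshold = thresholds,
                         method = vapply(models, `[[`, "", "method")),
              file.path(config$outdir, "background_thresholds.tsv"))
  manifest$stages$background <- list(method = config$background$method,
                                     k = config$background$k,
                                     thresholds = as.list(thresholds))
  log_msg("background: %d scope(s), thresholds %s",
          length(models), paste(signif(thresholds, 4), collapse = ", "))

  detection <- NULL
  if (isTRUE(config$detection$enabled)) {
    calls <- call_detection(counts, models, groups = groups,
                            statistic = config$detection$statistic)
    summary_tab <- detection_summary(calls, counts$codeset)
    calls_df <- data.frame(gene_id = rownames(calls$calls),
                           calls$calls * 1L, check.names = FALSE)
    write_table(calls_df, file.path(config$outdir, "detection_calls.tsv"))
    write_table(summary_tab, file.path(config$outdir, "detection_summary.tsv"))
    detection <- list(calls = calls, summary = summary_tab)
    manifest$stages$detection <- list(statistic = config$detection$statistic,
                                      scopes = length(group_labels))
    log_msg("detection: %d probes x %d scope(s)", nrow(calls$calls),
            ncol(calls$calls))
  } else {
    manifest$stages$detection <- list(skipped = TRUE)
    log_msg("detection: skipped")
  }

  # --- profiling + classification ----------------------------------------
  profile <- NULL
  labels <- NULL
  if (isTRUE(config$profile$enabled)) {
    stage_order <- config$profile$stage_order
    stages <- counts$samples[[config$profile$stages]]
    if (is.null(stage_order) &&
        !all(unique(stages) %in% life_cycle_stages())) {
      stage_order <- unique(stages)
    }
    profile <- stage_profile(counts, stages = config$profile$stages,
                             stage_order = stage_order)
    write_table(profile, file.path(config$outdir, "stage_profile.tsv"))
    manifest$stages$profile <- list(genes = nrow(profile$mean),
                                    stages = colnames(profile$mean))
    log_msg("profile: %d genes x %d stages", nrow(profile$mean),
            ncol(profile$mean))
    if (isTRUE(config$classify$enabled) &&
        all(life_cycle_stages() %in% colnames(profile$mean))) {
      threshold <- config$classify$threshold %||% max(thresholds)
      labels <- classify_patterns(profile, threshold = threshold,
                                  min_fold = config$classify$min_fold)
      write_table(labels, file.path(config$outdir, "pattern_labels.tsv"))
      manifest$stages$classify <- list(threshold = threshold,
                                       min_fold = config$classify$min_fold,
                                       labels = as.list(table(labels$label)))
      log_msg("classification: %d genes labelled (T=%.4g, F_min=%g)",
              nrow(labels), threshold, config$classify$min_fold)
    }
  }

  save_config(config, file.path(config$outdir, "effective_config.yaml"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(counts = counts, normalization = norm_results,
                 background = models, detection = detection,
                 profile = profile, labels = labels, truth = truth,
                 manifest = manifest))
}
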