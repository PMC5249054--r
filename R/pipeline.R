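#' Pipeline configuration
#'
#' One structured object holding every tunable of the end-to-end
#' pipeline, with documented defaults. Round-trips through YAML
#' ([write_config()] / [read_config()]) unchanged.
#'
#' @param mode `"reference"` runs the packaged cohort through
#'   classification (verification mode) and statistics; `"simulate"`
#'   draws a synthetic cohort first; `"volumes"` reads image volumes
#'   from `input_paths` and runs segmentation + morphometry before the
#'   same downstream stages.
#' @param input_paths Character vector of volume paths (`mode =
#'   "volumes"`), one per sample.
#' @param spacing_um Voxel spacing, um.
#' @param threshold_method,threshold_value Segmentation threshold
#'   (`"otsu"` or `"fixed"` + value).
#' @param min_voxels Minimum object size kept, voxels.
#' @param smoothing_sigma Gaussian pre-smoothing for surface
#'   estimation, voxels.
#' @param rules A [classification_rules()].
#' @param bonferroni_m Chi-square family size.
#' @param alpha Significance level.
#' @param cohort A [cohort_spec()] (`mode = "simulate"`).
#' @param seed Integer seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("reference", "simulate", "volumes"),
                            input_paths = character(0),
                            spacing_um = 9,
                            threshold_method = "otsu",
                            threshold_value = NULL,
                            min_voxels = 1L,
                            smoothing_sigma = 1,
                            rules = classification_rules(),
                            bonferroni_m = 4,
                            alpha = 0.05,
                            cohort = cohort_spec(),
                            seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, input_paths = input_paths,
                 spacing_um = spacing_um,
                 threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_voxels = as.integer(min_voxels),
                 smoothing_sigma = smoothing_sigma, rules = rules,
                 bonferroni_m = bonferroni_m, alpha = alpha,
                 cohort = cohort, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config` returns the restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  # yaml sequences lose vector names; write named vectors as maps
  namedok <- function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  x$rules <- lapply(unclass(x$rules), namedok)
  x$cohort <- lapply(unclass(x$cohort), namedok)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  devec <- function(v) if (is.list(v)) unlist(v) else v
  x$input_paths <- as.character(unlist(x$input_paths))
  do.call(pipeline_config, c(
    x[setdiff(names(x), c("rules", "cohort"))],
    list(rules = do.call(classification_rules, lapply(x$rules, devec)),
         cohort = do.call(cohort_spec, lapply(x$cohort, devec)))))
}

#' Run the full analysis pipeline
#'
#' Stages (per `config$mode`): acquire per-sample morphometry (packaged
#' cohort, simulation, or segmentation + measurement of input volumes),
#' classify morphology, build presence tables, and run the statistical
#' battery. Every threshold actually applied is echoed to the log.
#' Deterministic given the configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param output_dir If non-NULL, CSV results (`samples.csv`,
#'   `flags.csv`, `stats_tests.csv`, `group_summaries.csv`,
#'   `pipeline.log`) are written there.
#' @return List: `samples` (per-sample records with flags), `objects`
#'   (per-object table, where the mode produces one), `stats`
#'   (see [cohort_statistics()]), `verification` (reference mode:
#'   computed vs printed flags), `log` (character vector).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("mode=%s seed=%d", config$mode, config$seed)
  r <- config$rules
  say("rules: fl d_cube<%g SMI in [%g,%g]; fp d_cube<%g sd>%g; ch d>%g sd>%g",
      r$fl_max_d_cube, r$fl_smi_range[1], r$fl_smi_range[2],
      r$fp_max_d_cube, r$fp_min_sd_smi, r$ch_min_d, r$ch_min_sd_smi)

  objects <- NULL
  verification <- NULL

  if (config$mode == "reference") {
    samples <- reference_cohort()
    say("reference cohort: %d samples, %d excluded", nrow(samples),
        sum(samples$excluded))
  } else if (config$mode == "simulate") {
    sim <- make_cohort(config$cohort, seed = config$seed)
    samples <- sim$samples
    objects <- sim$objects
    say("simulated cohort: %d samples / %d objects", nrow(samples),
        nrow(objects))
  } else {
    if (!length(config$input_paths)) stop("volumes mode needs input_paths")
    rows <- list(); objs <- list()
    for (i in seq_along(config$input_paths)) {
      p <- config$input_paths[i]
      vol <- suppressWarnings(read_volume(p, config$spacing_um))
      bm <- threshold_volume(vol, config$threshold_method,
                             config$threshold_value, verbose = FALSE)
      say("sample %d (%s): threshold=%g", i, basename(p), bm$threshold)
      lab <- filter_objects(label_components(bm), config$min_voxels)
      say("sample %d: %d object(s) >= %d voxel(s)", i, lab$n_objects,
          config$min_voxels)
      om <- measure_objects(lab, sigma = config$smoothing_sigma)
      if (nrow(om)) { om$sample_id <- i; objs[[i]] <- om }
      rows[[i]] <- aggregate_sample(om, sample_id = i)
    }
    samples <- do.call(rbind, rows)
    objects <- if (length(objs)) do.call(rbind, objs) else NULL
  }

  eligible <- !samples$excluded & samples$n_objects >= 1L
  flags <- do.call(rbind, lapply(which(eligible), function(i)
    cbind(sample_id = samples$sample_id[i],
          classify_sample(samples[i, ], r))))
  say("classified %d sample(s); %d excluded", sum(eligible),
      sum(!eligible))

  if (config$mode == "reference") {
    printed <- samples[eligible, c("sample_id", "fl", "fp", "ch", "ns")]
    m <- merge(printed, flags, by = "sample_id",
               suffixes = c("_printed", "_recomputed"))
    m$concordant <- m$fl_printed == m$fl_recomputed &
      m$fp_printed == m$fp_recomputed & m$ch_printed == m$ch_recomputed &
      m$ns_printed == m$ns_recomputed
    verification <- m
    say("verification: %d/%d samples concordant with the printed flags",
        sum(m$concordant), nrow(m))
    # statistics run on the *printed* flags: verification never
    # overwrites the published categorization
    classified <- samples
  } else {
    classified <- merge(samples[, setdiff(names(samples),
                                          c("fl", "fp", "ch", "ns"))],
                        flags, by = "sample_id", all.x = TRUE)
    for (f in c("fl", "fp", "ch")) classified[[f]][is.na(classified[[f]])] <- FALSE
    classified$ns[is.na(classified$ns)] <- TRUE
  }

  stats <- NULL
  if ("group" %in% names(classified) && !anyNA(classified$group)) {
    stats <- cohort_statistics(classified, config$bonferroni_m,
                               config$alpha)
    for (i in seq_len(nrow(stats$chisq)))
      say("chisq %s: X2=%.3f p=%.4f p_adj=%.4f", stats$chisq$flag[i],
          stats$chisq$statistic[i], stats$chisq$p_value[i],
          stats$chisq$p_adjusted[i])
  } else {
    say("no histologic groups attached; skipping group statistics")
  }

  out <- list(samples = classified, objects = objects, flags = flags,
              stats = stats, verification = verification, log = log)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(classified, file.path(output_dir, "samples.csv"),
                     row.names = FALSE)
    utils::write.csv(flags, file.path(output_dir, "flags.csv"),
                     row.names = FALSE)
    if (!is.null(stats)) {
      tests <- rbind(
        data.frame(test = "kruskal_wallis", term = stats$kruskal$field,
                   statistic = stats$kruskal$statistic,
                   df = stats$kruskal$df, p_value = stats$kruskal$p_value,
                   p_adjusted = NA_real_),
        data.frame(test = "chi_square", term = stats$chisq$flag,
                   statistic = stats$chisq$statistic, df = stats$chisq$df,
                   p_value = stats$chisq$p_value,
                   p_adjusted = stats$chisq$p_adjusted))
      utils::write.csv(tests, file.path(output_dir, "stats_tests.csv"),
                       row.names = FALSE)
      utils::write.csv(stats$summaries,
                       file.path(output_dir, "group_summaries.csv"),
                       row.names = FALSE)
    }
    if (!is.null(objects))
      utils::write.csv(objects, file.path(output_dir, "objects.csv"),
                       row.names = FALSE)
    writeLines(log, file.path(output_dir, "pipeline.log"))
  }
  out
}
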