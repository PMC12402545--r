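#' Default pipeline configuration
#'
#' @param n_pd,n_et simulated group sizes.
#' @param seed pipeline seed.
#' @param pd,et named lists of [sim_config()] overrides per group.
#' @param n_baseline baseline sites for NRMS.
#' @param keep_raw also write the raw-trace container into the report
#'   directory.
#' @return A nested list understood by [run_pipeline()].
#' @export
pipeline_config <- function(n_pd = 20, n_et = 20, seed = 7,
                            pd = list(), et = list(),
                            n_baseline = 5, keep_raw = FALSE) {
  list(seed = seed,
       simulate = list(n_pd = n_pd, n_et = n_et, pd = pd, et = et),
       n_baseline = n_baseline, keep_raw = keep_raw)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$simulate) && is.null(cfg$input))
    stop("config must name either a 'simulate' block or an 'input' container")
  if (!is.null(cfg$simulate)) {
    n_pd <- cfg$simulate$n_pd %||% 0
    n_et <- cfg$simulate$n_et %||% 0
    if (n_pd < 1 || n_et < 1)
      stop("config validation: zero trajectories requested")
  }
  if (is.null(cfg$seed)) stop("config must set a seed")
  invisible(cfg)
}

#' Run the full MER analysis pipeline
#'
#' End-to-end composition: simulate (or ingest) a cohort, featurize every
#' trajectory, decode the STN boundaries, compute per-trajectory metrics and
#' depth-normalized group averages, and run the group comparisons. All flat
#' outputs are CSV; a markdown report and a log (with the config hash and
#' seed) are written to `out_dir`. The run is deterministic under the
#' configured seed.
#'
#' @param config a list as from [pipeline_config()], or the path of a YAML
#'   file with the same structure (`simulate:` block or `input:` container
#'   path, plus `seed:`).
#' @param out_dir report directory (created).
#' @return Invisibly, a list with the metric table, comparisons, group
#'   averages and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  t0 <- Sys.time()
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  if (is.null(cfg_path)) {
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(config, cfg_path)
  }
  logline("config: %s (md5 %s)", cfg_path, unname(tools::md5sum(cfg_path)))
  logline("seed: %d", config$seed)

  stage <- "simulate"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      cfg_pd <- do.call(pd_config, config$simulate$pd %||% list())
      cfg_et <- do.call(et_config, config$simulate$et %||% list())
      cohort <- simulate_cohort(config$simulate$n_pd, config$simulate$n_et,
                                cfg_pd, cfg_et, seed = config$seed)
    } else {
      cohort <- read_container(config$input)
    }
    logline("simulate/ingest: %d trajectories", length(cohort$trajectories))

    stage <- "features"
    nb <- config$n_baseline %||% 5
    profiles <- featurize_cohort(cohort, n_baseline = nb)
    write_features_csv(profiles, file.path(out_dir, "features.csv"))

    stage <- "segment"
    warns <- character(0)
    segs <- lapply(profiles, function(p)
      withCallingHandlers(segment_profile(p), warning = function(w) {
        warns <<- c(warns, sprintf("%s: %s", p$id, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }))
    write_segmentations_csv(segs, cohort$ids, file.path(out_dir, "segmentations.csv"))

    stage <- "analyze"
    metrics <- cohort_metrics(profiles, segs, groups = cohort$groups)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    ok <- !vapply(segs, `[[`, logical(1), "degenerate")
    nprofiles <- mapply(function(p, s) {
      withCallingHandlers(normalize_depths(p, s), warning = function(w) {
        warns <<- c(warns, sprintf("%s: %s", p$id, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    }, profiles[ok], segs[ok], SIMPLIFY = FALSE)
    groups_ok <- cohort$groups[ok]
    avgs <- lapply(split(nprofiles, groups_ok), group_average)
    for (g in names(avgs)) {
      write.csv(data.frame(x = avgs[[g]]$grid, nrms = avgs[[g]]$nrms,
                           n = avgs[[g]]$n),
                file.path(out_dir, sprintf("nrms_profile_%s.csv", g)),
                row.names = FALSE)
      sp <- avgs[[g]]$spectrogram
      colnames(sp) <- sprintf("f%.3f", avgs[[g]]$freqs)
      write.csv(cbind(data.frame(x = avgs[[g]]$grid), sp),
                file.path(out_dir, sprintf("spectrogram_%s.csv", g)),
                row.names = FALSE)
    }

    stage <- "compare"
    comparisons <- rbind(
      compare_groups(metrics$beta_ratio[metrics$group == "PD"],
                     metrics$beta_ratio[metrics$group == "ET"],
                     test = "mann_whitney_u", metric = "beta_ratio"),
      compare_groups(metrics$mean_beta_power[metrics$group == "PD"],
                     metrics$mean_beta_power[metrics$group == "ET"],
                     test = "mann_whitney_u", metric = "mean_beta_power"),
      do.call(rbind, lapply(c("nrms_peak", "nrms_auc", "stn_length",
                              "dlor_length", "percent_dlor"), function(m)
        compare_groups(metrics[[m]][metrics$group == "PD"],
                       metrics[[m]][metrics$group == "ET"], metric = m))),
      multiband_compare(metrics))
    write.csv(as.data.frame(comparisons),
              file.path(out_dir, "comparisons.csv"), row.names = FALSE)

    if (isTRUE(config$keep_raw) && !is.null(cohort$trajectories))
      write_container(file.path(out_dir, "cohort"), cohort, features = profiles)

    write_report_md(file.path(out_dir, "report.md"), metrics, comparisons, warns)
    logline("warnings: %d", length(warns))
    for (w in warns) logline("  %s", w)
    logline("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
    list(metrics = metrics, comparisons = comparisons, averages = avgs,
         segmentations = segs, warnings = warns, out_dir = out_dir)
  }, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  invisible(res)
}

# Markdown cohort report: group summaries (mean +/- SEM and median +/- SD,
# both labelled) and the comparison table.
write_report_md <- function(path, metrics, comparisons, warns) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) cat(sprintf(...), "\n", sep = "", file = con)
  w("# MER cohort comparison report")
  w("")
  tab <- table(metrics$group)
  w("Groups: %s", paste(sprintf("%s (n = %d)", names(tab), tab), collapse = ", "))
  w("")
  w("## Per-group metric summaries")
  w("")
  w("| metric | group | mean +/- SEM | median +/- SD |")
  w("|---|---|---|---|")
  mcols <- setdiff(names(metrics), c("id", "group"))
  for (m in mcols) for (g in names(tab)) {
    v <- metrics[[m]][metrics$group == g]
    w("| %s | %s | %.3g +/- %.2g | %.3g +/- %.2g |",
      m, g, mean(v), sd(v) / sqrt(length(v)), median(v), sd(v))
  }
  w("")
  w("## Group comparisons")
  w("")
  w("| metric | test | statistic | p | significant | Bonferroni |")
  w("|---|---|---|---|---|---|")
  cd <- as.data.frame(comparisons)
  for (i in seq_len(nrow(cd))) {
    r <- cd[i, ]
    w("| %s | %s | %.4g | %.3g | %s | %s |", r$metric, r$test, r$statistic,
      r$p_value, ifelse(isTRUE(r$significant), "yes", "no"),
      if (is.na(r$adjusted_alpha)) "-" else
        sprintf("alpha=%.4g: %s", r$adjusted_alpha,
                ifelse(isTRUE(r$significant_adjusted), "yes", "no")))
  }
  if (length(warns)) {
    w("")
    w("## Warnings")
    w("")
    for (x in warns) w("- %s", x)
  }
  invisible(path)
}
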