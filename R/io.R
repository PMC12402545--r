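CONTAINER_SCHEMA <- "mer-cohort/1"

#' Write a cohort to a trajectory container
#'
#' The container is a directory holding a JSON manifest (schema tag, trajectory
#' index, group labels, seed and generator-config snapshots), one trace blob
#' per trajectory (`<id>.rds`: depths, sampling rate and raw traces), a
#' `ground_truth.csv` sidecar when ground truth is available, and optionally a
#' `features.csv` table that can be read back without touching the raw traces.
#' Flat tables are CSV throughout so they are directly consumable.
#'
#' @param path container directory (created if absent).
#' @param cohort a `mer_cohort`, or a list of `mer_trajectory` objects.
#' @param features optional list of `mer_profile` objects to store as the
#'   derived feature table.
#' @return `path`, invisibly.
#' @export
write_container <- function(path, cohort, features = NULL) {
  trajs <- if (inherits(cohort, "mer_cohort")) cohort$trajectories else cohort
  if (!length(trajs)) stop("no trajectories to write")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(trajs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("trajectory ids must be unique")
  for (tr in trajs) {
    if (is.null(tr$sites[[1]]$sampling_rate)) stop("schema violation: missing sampling_rate")
    d <- vapply(tr$sites, `[[`, numeric(1), "depth")
    if (any(diff(d) >= 0)) stop("schema violation: depths must be strictly decreasing")
    saveRDS(list(id = tr$id,
                 depths = d,
                 sampling_rate = tr$sites[[1]]$sampling_rate,
                 duration = tr$sites[[1]]$duration,
                 traces = lapply(tr$sites, `[[`, "samples"),
                 metadata = tr$metadata),
            file.path(path, paste0(tr$id, ".rds")))
  }
  man <- list(schema = CONTAINER_SCHEMA, ids = ids,
              groups = vapply(trajs, function(t)
                as.character(t$metadata$group %||% NA), character(1)),
              seed = if (inherits(cohort, "mer_cohort")) cohort$seed else NULL,
              configs = if (inherits(cohort, "mer_cohort"))
                lapply(cohort$configs, unclass) else NULL)
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (inherits(cohort, "mer_cohort") && length(cohort$ground_truth)) {
    gt <- do.call(rbind, lapply(seq_along(ids), function(i) {
      g <- cohort$ground_truth[[i]]
      data.frame(id = ids[i], entry = g$entry_depth,
                 dlor_exit = g$dlor_exit_depth, exit = g$exit_depth,
                 group = cohort$groups[i])
    }))
    write.csv(gt, file.path(path, "ground_truth.csv"), row.names = FALSE)
  }
  if (!is.null(features))
    write_features_csv(features, file.path(path, "features.csv"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a trajectory container
#'
#' @param path container directory written by [write_container()].
#' @param load_traces read the raw trace blobs (`FALSE` loads only metadata,
#'   ground truth and any stored derived feature table).
#' @return A `mer_cohort` (with `NULL` trajectories when
#'   `load_traces = FALSE`); stored features are attached as `$features`,
#'   ground truth as parallel `mer_ground_truth` stubs.
#' @export
read_container <- function(path, load_traces = TRUE) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a trajectory container: missing manifest.json")
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(man$schema) || !identical(man$schema, CONTAINER_SCHEMA))
    stop(sprintf("unknown container schema tag '%s' (expected '%s')",
                 man$schema %||% "<none>", CONTAINER_SCHEMA))
  ids <- man$ids
  trajs <- NULL
  if (load_traces) {
    trajs <- lapply(ids, function(id) {
      blob <- readRDS(file.path(path, paste0(id, ".rds")))
      if (is.null(blob$sampling_rate)) stop("corrupt trajectory blob: no sampling_rate")
      sites <- lapply(seq_along(blob$depths), function(i)
        structure(list(depth = blob$depths[i], sampling_rate = blob$sampling_rate,
                       duration = blob$duration, samples = blob$traces[[i]]),
                  class = "mer_site"))
      structure(list(id = blob$id, sites = sites, metadata = blob$metadata),
                class = "mer_trajectory")
    })
  }
  gt <- NULL
  gtf <- file.path(path, "ground_truth.csv")
  if (file.exists(gtf)) {
    g <- read.csv(gtf)
    gt <- lapply(seq_len(nrow(g)), function(i)
      structure(list(entry_depth = g$entry[i], dlor_exit_depth = g$dlor_exit[i],
                     exit_depth = g$exit[i], depths = NULL, state = NULL),
                class = "mer_ground_truth"))
  }
  out <- structure(list(trajectories = trajs, ground_truth = gt,
                        groups = man$groups, ids = ids, seed = man$seed,
                        configs = man$configs),
                   class = "mer_cohort")
  ff <- file.path(path, "features.csv")
  if (file.exists(ff)) out$features <- read.csv(ff)
  out
}

#' Write per-site feature tables as CSV
#'
#' One row per site: trajectory id, depth, rms, nrms, and one column per band
#' fraction.
#'
#' @param profiles list of `mer_profile` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(profiles, path) {
  tab <- do.call(rbind, lapply(profiles, function(p)
    cbind(data.frame(id = p$id), p$sites)))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write segmentations as CSV
#'
#' @param segs list of `mer_segmentation` objects.
#' @param ids trajectory ids.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segmentations_csv <- function(segs, ids, path) {
  tab <- do.call(rbind, lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    data.frame(id = ids[i], entry = s$entry_depth, dlor_exit = s$dlor_exit_depth,
               exit = s$exit_depth, source = s$source, degenerate = s$degenerate)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
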