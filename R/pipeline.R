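#' Subject-level pipeline configuration
#'
#' Defaults are the stated method parameters: detection threshold 60 on the
#' uniformized scale (WM median anchored at 1000), one voxel of mask
#' erosion, in-plane 8-neighbour local-contrast neighbourhood.
#'
#' @param threshold PVS detection threshold on the local-difference map.
#' @param neighborhood a [neighborhood_spec()].
#' @param erosion_iterations erosion passes applied to the WM mask.
#' @param erosion_mode `"3d6"` or `"2d4"` (see [erode_mask()]).
#' @param target_level WM median after uniformization.
#' @param denoise logical; apply adaptive denoising before registration.
#' @param registration a [register_settings()] list.
#' @param transform optional known [rigid_transform()] bypassing
#'   registration.
#' @param wm_fallback logical; allow intensity-clustering WM segmentation
#'   when no mask is supplied.
#' @param compute_ratio_map logical; also compute the T1/T2 QC ratio map.
#' @param slice_axis optional explicit slice axis.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = 60,
                            neighborhood = neighborhood_spec(),
                            erosion_iterations = 1L,
                            erosion_mode = "3d6",
                            target_level = 1000,
                            denoise = TRUE,
                            registration = register_settings(),
                            transform = NULL,
                            wm_fallback = FALSE,
                            compute_ratio_map = FALSE,
                            slice_axis = NULL) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  structure(list(threshold = threshold, neighborhood = neighborhood,
                 erosion_iterations = as.integer(erosion_iterations),
                 erosion_mode = erosion_mode, target_level = target_level,
                 denoise = denoise, registration = registration,
                 transform = transform, wm_fallback = wm_fallback,
                 compute_ratio_map = compute_ratio_map,
                 slice_axis = slice_axis),
            class = "pipeline_config")
}

provenance_entry <- function(stage, settings) {
  list(stage = stage, settings = settings,
       version = as.character(utils::packageVersion("wmpvs")))
}

#' Run the full subject-level quantification pipeline
#'
#' Executes the stages in their stated order: adaptive denoising (native
#' space), rigid T2-to-T1 registration, white-matter mask (supplied or
#' fallback) eroded by one voxel, white-matter intensity uniformization of
#' the registered T2, local intensity-difference mapping, thresholding,
#' per-slice clustering, grading and summary. Fully deterministic for a
#' fixed configuration.
#'
#' @param t1,t2 `pvs_volume`s (T2 in native space; it is registered onto
#'   the T1 grid).
#' @param wm_mask optional `pvs_mask` on the T1 grid; when `NULL`,
#'   `config$wm_fallback` must be `TRUE`.
#' @param config a [pipeline_config()].
#' @return list of class `pvs_subject`: `result` (a `pvs_result`),
#'   `pvs_mask`, `eroded_wm`, `t2_uniform`, `transform`, `ratio_map`
#'   (optional), `provenance`.
#' @export
run_subject <- function(t1, t2, wm_mask = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  prov <- list()
  log_stage <- function(stage, settings)
    prov[[length(prov) + 1L]] <<- provenance_entry(stage, settings)

  if (config$denoise) {
    t1 <- denoise_adaptive(t1)
    t2 <- denoise_adaptive(t2)
    log_stage("denoise_adaptive",
              list(patch_radius = 1, search_radius = 5, h_factor = 1.0,
                   space = "native, before resampling"))
  }

  reg <- rigid_register(t2, t1, settings = config$registration,
                        transform = config$transform)
  t2r <- reg$resampled
  log_stage("rigid_register",
            list(metric = "normalized mutual information",
                 bypassed = !is.null(config$transform),
                 rotation = reg$transform$rotation,
                 translation = reg$transform$translation,
                 interpolation = "trilinear"))

  if (is.null(wm_mask)) {
    if (!config$wm_fallback)
      stop("no white-matter mask supplied and `wm_fallback` is disabled",
           call. = FALSE)
    wm_mask <- segment_wm_fallback(t1)
    log_stage("segment_wm_fallback", list(classes = 3))
  } else {
    check_congruent(t1, wm_mask)
    log_stage("wm_mask", list(source = "supplied"))
  }

  eroded <- erode_mask(wm_mask, iterations = config$erosion_iterations,
                       mode = config$erosion_mode)
  log_stage("erode_mask", list(iterations = config$erosion_iterations,
                               mode = config$erosion_mode))

  t2u <- uniformize_wm(t2r, wm_mask, target_level = config$target_level)
  log_stage("uniformize_wm", list(target_level = config$target_level))

  ratio <- NULL
  if (config$compute_ratio_map) {
    ratio <- compute_epc(t1, t2u, mask = eroded)
    log_stage("compute_epc", list(definition = "T1 / T2"))
  }

  dm <- neighborhood_difference_map(t2u, eroded, config$neighborhood)
  log_stage("neighborhood_difference_map",
            list(type = config$neighborhood$type,
                 radius = config$neighborhood$radius,
                 include_outside_mask =
                   config$neighborhood$include_outside_mask))

  pvs <- detect_pvs_voxels(dm, threshold = config$threshold)
  log_stage("detect_pvs_voxels", list(threshold = config$threshold,
                                      rule = "strictly greater"))

  res <- summarize_pvs(pvs, eroded, threshold = config$threshold,
                       slice_axis = config$slice_axis)
  log_stage("summarize_pvs", list(slice_axis = res$clusters$slice_axis))

  structure(list(result = res, pvs_mask = pvs, eroded_wm = eroded,
                 t2_uniform = t2u, transform = reg$transform,
                 ratio_map = ratio, provenance = prov),
            class = "pvs_subject")
}

#' @export
print.pvs_subject <- function(x, ...) {
  print(x$result)
  invisible(x)
}

#' Write the subject JSON report
#'
#' @param subject a `pvs_subject` from [run_subject()].
#' @param path output JSON path.
#' @param subject_id identifier recorded in the report.
#' @param timestamp logical; include a timestamp (disable for byte-stable
#'   re-runs).
#' @return `path` invisibly.
#' @export
write_subject_report <- function(subject, path, subject_id = "subject",
                                 timestamp = TRUE) {
  r <- subject$result
  payload <- list(subject_id = subject_id,
                  threshold = r$threshold_used,
                  neighborhood = subject$provenance[[
                    which(vapply(subject$provenance, `[[`, "", "stage") ==
                            "neighborhood_difference_map")[1]]]$settings,
                  pvs_voxel_count = r$pvs_voxel_count,
                  wm_voxel_count = r$wm_voxel_count,
                  normalized_volume = r$normalized_volume,
                  per_slice_counts = r$per_slice_cluster_counts,
                  max_slice_count = r$max_slice_count,
                  grade = r$grade,
                  enlargement_flag = r$enlargement,
                  provenance = subject$provenance)
  if (timestamp) payload$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Merge per-subject quantifications into a cohort table and analyse
#'
#' Joins `pvs_result`s to the cohort covariate table by subject id, then
#' builds the comparison report.
#'
#' @param subject_results named list of `pvs_result` (or `pvs_subject`)
#'   objects; names are subject ids.
#' @param cohort data.frame with an `id` column (plus group/sex covariates).
#' @param ... passed to [build_report()].
#' @return list with `table` (merged data.frame) and `report`
#'   (`pvs_report`).
#' @export
run_cohort <- function(subject_results, cohort, ...) {
  ids <- names(subject_results)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("`subject_results` must be a named list keyed by subject id",
         call. = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate subject id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(cohort$id))
    stop("duplicate id(s) in cohort table", call. = FALSE)
  unmatched <- setdiff(ids, cohort$id)
  if (length(unmatched))
    stop(sprintf("id(s) not in cohort table: %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  getres <- function(x) if (inherits(x, "pvs_subject")) x$result else x
  add <- data.frame(id = ids,
                    pvs_volume_voxels = vapply(subject_results, function(x)
                      getres(x)$pvs_voxel_count, numeric(1)),
                    wm_voxel_count = vapply(subject_results, function(x)
                      getres(x)$wm_voxel_count, numeric(1)),
                    normalized_volume = vapply(subject_results, function(x)
                      getres(x)$normalized_volume, numeric(1)),
                    max_slice_count = vapply(subject_results, function(x)
                      getres(x)$max_slice_count, numeric(1)),
                    pvs_grade = vapply(subject_results, function(x)
                      getres(x)$grade, integer(1)),
                    stringsAsFactors = FALSE)
  drop <- intersect(setdiff(names(add), "id"), names(cohort))
  merged <- merge(cohort[, setdiff(names(cohort), drop), drop = FALSE], add,
                  by = "id", all.x = TRUE, sort = TRUE)
  list(table = merged, report = build_report(merged, ...))
}
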