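# Pipeline orchestration: generate -> filter -> score -> fit -> null ->
# compare, with on-disk CSV artifacts per stage so each stage can be re-run
# and tested in isolation, plus a YAML run manifest with seeds, row counts,
# timings and file checksums.

#' Configure a full pipeline run
#'
#' @param generator A [generator_config()].
#' @param viewshed List with `area_m2` and `aspect_ratio` for the camera
#'   viewsheds (homogeneous across cameras).
#' @param nullmodel List with `areas_m2` (vector; default 650, 300 and 150),
#'   `aspect_ratio`, `n_values`, `replicates` and `boundary` for the null
#'   curves.
#' @param analysis List with `ci_level_person`, `ci_level_frame`, `n_bins`,
#'   and logical `winsorize`.
#' @param output_dir Directory for all artifacts (created if needed).
#' @param log_level `"debug"`, `"info"`, `"warn"` or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            viewshed = list(area_m2 = 650,
                                            aspect_ratio = 2),
                            nullmodel = list(areas_m2 = c(650, 300, 150),
                                             aspect_ratio = 2,
                                             n_values = 2:40,
                                             replicates = 10000,
                                             boundary = "plain"),
                            analysis = list(ci_level_person = 0.9995,
                                            ci_level_frame = 0.995,
                                            n_bins = 20,
                                            winsorize = TRUE),
                            output_dir = "crowdprox-output",
                            log_level = "info") {
  stopifnot(inherits(generator, "generator_config"))
  if (!log_level %in% names(log_levels)) {
    stop("unknown log_level: ", log_level, call. = FALSE)
  }
  structure(
    list(generator = generator, viewshed = viewshed, nullmodel = nullmodel,
         analysis = analysis, output_dir = output_dir,
         log_level = log_level),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] structure; the `generator`
#' section mirrors [generator_config()] field names exactly.  Omitted
#' fields take their defaults, and every value passes through the
#' constructors' validation.
#'
#' @param path Path to a YAML file.
#' @param seed Optional integer overriding `generator$seed`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator %||% list()
  if (!is.null(gen_args$crowd_range)) {
    gen_args$crowd_range <- unlist(gen_args$crowd_range)
  }
  if (!is.null(gen_args$group_size_dist)) {
    gen_args$group_size_dist <- unlist(gen_args$group_size_dist)
  }
  if (!is.null(gen_args$within_group_spacing_m)) {
    gen_args$within_group_spacing_m <- unlist(gen_args$within_group_spacing_m)
  }
  if (!is.null(seed)) gen_args$seed <- as.integer(seed)
  args <- list(generator = do.call(generator_config, gen_args))
  for (f in c("viewshed", "nullmodel", "analysis")) {
    if (!is.null(raw[[f]])) {
      merged <- formals(pipeline_config)[[f]]
      merged <- eval(merged)
      merged[names(raw[[f]])] <- raw[[f]]
      if (!is.null(merged$n_values)) merged$n_values <- unlist(merged$n_values)
      if (!is.null(merged$areas_m2)) merged$areas_m2 <- unlist(merged$areas_m2)
      args[[f]] <- merged
    }
  }
  if (!is.null(raw$output_dir)) args$output_dir <- raw$output_dir
  if (!is.null(raw$log_level)) args$log_level <- raw$log_level
  do.call(pipeline_config, args)
}

write_stage_csv <- function(tab, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  path
}

#' Generate the detection table artifact
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the detection tibble, the artifact `path`
#'   and a `manifest` entry (seed, rows, md5).
#' @export
run_generate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$output_dir, mode = 2L) != 0L) {
    stop("output_dir is not writable: ", config$output_dir, call. = FALSE)
  }
  gen <- config$generator
  vs <- default_viewsheds(gen$n_cameras,
                          area_m2 = config$viewshed$area_m2,
                          aspect_ratio = config$viewshed$aspect_ratio)
  t0 <- proc.time()[["elapsed"]]
  detections <- generate_dataset(gen, vs)
  path <- write_stage_csv(
    detections[, detection_cols], config$output_dir, "detections.csv")
  pipe_log("info", sprintf("generated %d detections in %d frames",
                           nrow(detections),
                           gen$n_cameras * gen$frames_per_camera),
           config$log_level)
  invisible(list(
    detections = detections, path = path,
    manifest = list(seed = gen$seed, rows = nrow(detections),
                    seconds = round(proc.time()[["elapsed"]] - t0, 2),
                    md5 = unname(tools::md5sum(path)))
  ))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: scene generation; the fewer-than-2-persons frame
#' filter; person- and frame-level proximity scoring; the pooled person-
#' level models (main clustered LPM, camera-fixed-effects variant,
#' stricter >= 2-contact outcome, winsorized-predictor variant); pooled and
#' per-camera binned series; pooled and per-camera frame-level OLS; null
#' curves for each configured area; and the observed-vs-null comparison.
#' All tables are written as CSV under `output_dir`, figures as PDF (and
#' PNG where the device is available) with their data always also in CSV,
#' and a `manifest.yaml` records seeds, row counts, timings and MD5
#' checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`detections`,
#'   `persons`, `frames`, `fits`, `per_camera`, `binned`, `null_curves`,
#'   `comparison`, `manifest`).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  lvl <- config$log_level
  manifest <- list(
    package_version = as.character(utils::packageVersion("crowdprox")),
    seed = config$generator$seed,
    stages = list(), files = list()
  )
  out_dir <- config$output_dir
  timer <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, secs = round(proc.time()[["elapsed"]] - t0, 2))
  }
  stage <- function(name, rows, secs) {
    manifest$stages[[name]] <<- list(rows = rows, seconds = secs)
    pipe_log("info", sprintf("stage %-12s rows=%d (%.2fs)", name, rows, secs),
             lvl)
  }

  gen <- timer(run_generate(config))
  detections <- gen$val$detections
  stage("generate", nrow(detections), gen$secs)

  flt <- timer(suppressMessages(filter_frames(detections)))
  filtered <- flt$val
  write_stage_csv(filtered[, detection_cols], out_dir,
                  "detections_filtered.csv")
  stage("filter", nrow(filtered), flt$secs)
  pipe_log("info", sprintf("dropped %d underpopulated frame(s)",
                           attr(filtered, "frames_dropped")), lvl)

  sc <- timer(score_dataset(filtered, config$generator$threshold_m))
  persons <- sc$val$persons
  frames <- sc$val$frames
  if (nrow(persons) != nrow(filtered)) {
    stop("row-count conservation violated at the scoring stage",
         call. = FALSE)
  }
  write_stage_csv(persons, out_dir, "person_outcomes.csv")
  write_stage_csv(frames, out_dir, "frame_summaries.csv")
  stage("score", nrow(persons), sc$secs)

  an <- config$analysis
  ft <- timer({
    main <- fit_lpm_clustered(persons, "violation",
                              ci_level = an$ci_level_person)
    fe <- fit_lpm_clustered(persons, "violation",
                            ci_level = an$ci_level_person,
                            fixed_effects = "camera")
    v2 <- fit_lpm_clustered(persons, "violation2",
                            ci_level = an$ci_level_person)
    fits <- list(main = main, camera_fe = fe, violation2 = v2)
    if (isTRUE(an$winsorize)) {
      wz <- winsorize_upper(persons$n_present)
      pw <- persons
      pw$n_present_winsorized <- wz$values
      fits$winsorized <- fit_lpm_clustered(
        pw, "violation", predictor = "n_present_winsorized",
        ci_level = an$ci_level_person)
      attr(fits$winsorized, "winsor") <- wz
    }
    frame_fit <- fit_frame_ols(frames, ci_level = an$ci_level_frame)
    list(fits = fits, frame_fit = frame_fit)
  })
  fits_tab <- dplyr::bind_rows(
    lapply(names(ft$val$fits), function(nm) {
      f <- ft$val$fits[[nm]]
      tibble::tibble(model = nm, outcome = f$outcome_name,
                     fixed_effects = f$fixed_effects, slope = f$slope,
                     se = f$se_cluster, ci_level = f$ci_level,
                     ci_low = f$ci_low, ci_high = f$ci_high,
                     n = f$n_obs, clusters = f$n_clusters,
                     r_squared = NA_real_)
    })
  )
  ff <- ft$val$frame_fit
  fits_tab <- dplyr::bind_rows(
    fits_tab,
    tibble::tibble(model = "frame_ols", outcome = ff$outcome_name,
                   fixed_effects = "none", slope = ff$slope, se = ff$se,
                   ci_level = ff$ci_level, ci_low = ff$ci_low,
                   ci_high = ff$ci_high, n = ff$n_frames,
                   clusters = NA_integer_, r_squared = ff$r_squared))
  write_stage_csv(fits_tab, out_dir, "fits.csv")
  stage("fit", nrow(fits_tab), ft$secs)

  bn <- timer({
    pooled_person <- binscatter(persons$n_present, persons$violation,
                                n_bins = min(an$n_bins,
                                             length(unique(persons$n_present))))
    pooled_frame <- binscatter(frames$n_present, frames$n_violators,
                               n_bins = min(an$n_bins,
                                            length(unique(frames$n_present))))
    per_cam <- dplyr::bind_rows(lapply(
      unique(persons$camera_id), function(cam) {
        p <- persons[persons$camera_id == cam, ]
        nb <- min(10L, length(unique(p$n_present)))
        dplyr::mutate(as_tibble_binned(
          binscatter(p$n_present, p$violation, n_bins = nb)),
          camera_id = cam, .before = 1L)
      }))
    list(person = pooled_person, frame = pooled_frame, per_camera = per_cam)
  })
  write_stage_csv(as_tibble_binned(bn$val$person), out_dir,
                  "binscatter_person.csv")
  write_stage_csv(as_tibble_binned(bn$val$frame), out_dir,
                  "binscatter_frame.csv")
  write_stage_csv(bn$val$per_camera, out_dir, "binscatter_per_camera.csv")
  stage("binscatter", bn$val$person$n_obs, bn$secs)

  pc <- timer(suppressMessages(
    fit_per_camera(persons, frames,
                   ci_level_person = an$ci_level_person,
                   ci_level_frame = an$ci_level_frame)))
  write_stage_csv(pc$val, out_dir, "fits_per_camera.csv")
  stage("per_camera", nrow(pc$val), pc$secs)

  nm <- config$nullmodel
  nl <- timer(dplyr::bind_rows(lapply(nm$areas_m2, function(a) {
    simulate_random_placement(null_model_config(
      area_m2 = a, aspect_ratio = nm$aspect_ratio,
      threshold_m = config$generator$threshold_m,
      n_values = nm$n_values, replicates = nm$replicates,
      seed = child_seed(config$generator$seed, round(a), stream = 3L),
      boundary = nm$boundary))
  })))
  write_stage_csv(nl$val, out_dir, "null_curves.csv")
  stage("null", nrow(nl$val), nl$secs)

  cp <- timer(suppressMessages(compare_observed_to_null(frames, nl$val)))
  write_stage_csv(cp$val, out_dir, "observed_vs_null.csv")
  stage("compare", nrow(cp$val), cp$secs)

  fg <- timer(render_figures(bn$val$person, frames, ft$val$frame_fit,
                             cp$val, out_dir))
  stage("figures", length(fg$val), fg$secs)

  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(detections = detections, filtered = filtered,
                 persons = persons, frames = frames,
                 fits = ft$val$fits, frame_fit = ft$val$frame_fit,
                 fits_table = fits_tab, per_camera = pc$val,
                 binned = bn$val, null_curves = nl$val,
                 comparison = cp$val, manifest = manifest))
}
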