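# End-to-end orchestration: simulate -> rigid -> deform -> analyze as one
# reproducible run driven by a serialisable configuration, plus cohort
# aggregation. A YAML/JSON-serialisable config and a provenance sidecar make
# every output reconstructible from the archived configuration alone.

#' Run configuration
#'
#' Describes one case: either a phantom simulation (give `phantom`) or real
#' inputs (give the `paths`). The configuration is fully serialisable and is
#' archived verbatim next to the outputs.
#'
#' @param output_dir directory for the case artifacts (created if needed).
#' @param phantom a [phantom_spec] for simulation runs, or `NULL`.
#' @param fixed_path,moving_path scalar volume files (ignored for
#'   simulation runs).
#' @param fixed_structure_paths,moving_structure_paths named vectors of mask
#'   files (see [read_structures()]).
#' @param control a [registration_control].
#' @param seed integer seed for simulation runs (overrides the phantom
#'   spec's seed when given).
#' @param case_id label used in file names and the provenance record.
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir, phantom = NULL, fixed_path = NULL,
                       moving_path = NULL, fixed_structure_paths = NULL,
                       moving_structure_paths = NULL,
                       control = registration_control(), seed = NULL,
                       case_id = "case") {
  if (is.null(phantom) && (is.null(fixed_path) || is.null(moving_path) ||
                           is.null(fixed_structure_paths) ||
                           is.null(moving_structure_paths)))
    stop("run_config: provide either `phantom` or all four input paths",
         call. = FALSE)
  if (!is.null(phantom) && !is.null(seed)) phantom$seed <- as.integer(seed)
  structure(list(output_dir = output_dir, phantom = phantom,
                 fixed_path = fixed_path, moving_path = moving_path,
                 fixed_structure_paths = fixed_structure_paths,
                 moving_structure_paths = moving_structure_paths,
                 control = control, case_id = case_id),
            class = "run_config")
}

config_as_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  strip(unclass(config))
}

# stable content checksum of the serialised config (polynomial hash of the
# JSON bytes, kept within 31-bit integer range)
config_checksum <- function(config) {
  txt <- jsonlite::toJSON(config_as_list(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run one case end to end
#'
#' Executes all stages in order (simulate or load, rigid alignment,
#' deformable registration, motion analysis), writes the declared artifacts
#' (field, trace, summary CSV, provenance JSON, and the simulated volumes
#' for phantom runs) and returns the fit. Deterministic: identical
#' config + seed reproduce identical outputs.
#'
#' @param config a [run_config].
#' @param write_volumes also write the simulated NIfTI volumes and masks
#'   (phantom runs only).
#' @return The `meniscus_motion` fit, invisibly, with attribute
#'   `"artifacts"` naming the written files.
#' @export
run_case <- function(config, write_volumes = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, code) {
    s <- Sys.time()
    out <- tryCatch(force(code), error = function(e)
      stop("run_case: stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    out
  }
  truth <- NULL
  if (!is.null(config$phantom)) {
    case <- stage("simulate", generate_case(config$phantom))
    fixed <- case$reference$volume
    fixed_structures <- case$reference$structures
    moving <- case$moving$volume
    moving_structures <- case$moving$structures
    truth <- list(rigid = case$truth_rigid, field = case$truth_field)
  } else {
    fixed <- stage("load_fixed", read_volume(config$fixed_path))
    moving <- stage("load_moving", read_volume(config$moving_path))
    fixed_structures <- stage("load_fixed_structures",
                              read_structures(config$fixed_structure_paths,
                                              fixed))
    moving_structures <- stage("load_moving_structures",
                               read_structures(config$moving_structure_paths,
                                               moving))
  }
  fit <- stage("register", fit_meniscus_motion(fixed, moving, fixed_structures,
                                               moving_structures,
                                               control = config$control))
  paths <- c(
    summary = file.path(config$output_dir,
                        paste0(config$case_id, "_summary.csv")),
    trace = file.path(config$output_dir, paste0(config$case_id, "_trace.csv")),
    field = file.path(config$output_dir,
                      paste0(config$case_id, "_field.nii.gz")),
    provenance = file.path(config$output_dir,
                           paste0(config$case_id, "_provenance.json")))
  stage("write", {
    write_summary(fit$summary, paths[["summary"]])
    write.csv(fit$trace, paths[["trace"]], row.names = FALSE)
    write_field(fit$field, paths[["field"]])
    if (write_volumes && !is.null(config$phantom)) {
      write_volume(fixed, file.path(config$output_dir,
                                    paste0(config$case_id, "_fixed.nii.gz")))
      write_volume(moving, file.path(config$output_dir,
                                     paste0(config$case_id, "_moving.nii.gz")))
      write_structures(fixed_structures,
                       file.path(config$output_dir,
                                 paste0(config$case_id, "_fixed_structures")))
      write_structures(moving_structures,
                       file.path(config$output_dir,
                                 paste0(config$case_id, "_moving_structures")))
    }
  })
  {
    prov <- list(case_id = config$case_id,
                 config = config_as_list(config),
                 config_checksum = config_checksum(config),
                 truth = if (!is.null(truth)) list(
                   rigid_rotation_deg = truth$rigid$rotation,
                   rigid_translation_mm = truth$rigid$translation),
                 rigid_estimate = list(rotation_deg = fit$rigid$rotation,
                                       translation_mm = fit$rigid$translation,
                                       center_mm = fit$rigid$center),
                 stage_seconds = timings,
                 r_version = R.version.string,
                 package_version = as.character(
                   utils::packageVersion("menisci")),
                 finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(prov, paths[["provenance"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  attr(fit, "artifacts") <- paths
  attr(fit, "truth") <- truth
  invisible(fit)
}

#' Run a cohort of cases and aggregate
#'
#' Runs each configuration with [run_case()]; failed cases are reported,
#' excluded from aggregation and counted in the output attributes. Writes
#' the across-case mean and SD per meniscus x scope cell.
#'
#' @param configs list of [run_config]s.
#' @param output_csv optional path for the cohort CSV.
#' @return The cohort table from [aggregate_cohort()], with attributes
#'   `n_failed` and `per_case` (list of per-case summaries).
#' @export
run_cohort <- function(configs, output_csv = NULL) {
  stopifnot(length(configs) >= 1)
  fits <- lapply(configs, function(cfg) {
    tryCatch(run_case(cfg), error = function(e) {
      warning("run_cohort: case '", cfg$case_id, "' failed and was excluded: ",
              conditionMessage(e))
      NULL
    })
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("run_cohort: all cases failed", call. = FALSE)
  summaries <- lapply(fits[ok], function(f) f$summary)
  tab <- aggregate_cohort(summaries)
  if (!is.null(output_csv)) {
    hdr <- paste0("# cohort of ", sum(ok), " case(s); failed_cases=",
                  sum(!ok))
    con <- file(output_csv, "w")
    writeLines(hdr, con)
    write.csv(tab, con, row.names = FALSE)
    close(con)
  }
  attr(tab, "n_failed") <- sum(!ok)
  attr(tab, "per_case") <- summaries
  tab
}

#' Serialise / restore a run configuration as YAML
#'
#' @param config a [run_config].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ctl <- do.call(registration_control, raw$control %||% list())
  ph <- if (!is.null(raw$phantom)) {
    raw$phantom$meniscal_motion <- lapply(raw$phantom$meniscal_motion, unlist)
    do.call(phantom_spec, raw$phantom)
  }
  run_config(output_dir = raw$output_dir, phantom = ph,
             fixed_path = raw$fixed_path, moving_path = raw$moving_path,
             fixed_structure_paths = unlist(raw$fixed_structure_paths),
             moving_structure_paths = unlist(raw$moving_structure_paths),
             control = ctl, case_id = raw$case_id %||% "case")
}
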