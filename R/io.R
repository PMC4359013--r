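#' Read a NIfTI-1 volume as a plain array
#'
#' Thin wrapper over RNifti that returns the voxel data as a base array with
#' the grid metadata attached, failing fast on malformed files.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return Numeric array (3D or 4D) with attributes `"pixdim"` and
#'   `"description"`.
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "failed to read NIfTI file %s: %s", path,
                    conditionMessage(e)), call. = FALSE))
  out <- array(as.numeric(img), dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  attr(out, "description") <- RNifti::niftiHeader(img)$descrip
  out
}

#' Write a volume to NIfTI-1
#'
#' @param volume 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param description Free-text header description, conventionally the map's
#'   units (e.g. `"R1 [s^-1]"`). Truncated to the 79 bytes NIfTI allows.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path, description = "") {
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume) %||%
                                 length(volume)))
  img <- RNifti::asNifti(img,
                         list(descrip = substr(description, 1, 79)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write all phantom volumes to a directory
#'
#' One NIfTI file per map (`r1.nii.gz`, `pd.nii.gz`, `mt_sat.nii.gz`,
#' `r2s.nii.gz`, `b1_rel.nii.gz`, `class_labels.nii.gz`, plus one
#' `prob_<class>.nii.gz` per tissue class), with units in the header
#' description.
#'
#' @param phantom A `"phantom_volumes"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_volumes"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_volume(phantom$r1, file.path(dir, "r1.nii.gz"), "R1 [s^-1]"),
    write_volume(phantom$pd, file.path(dir, "pd.nii.gz"), "PD [a.u.]"),
    write_volume(phantom$mt_sat, file.path(dir, "mt_sat.nii.gz"),
                 "MT saturation [p.u.]"),
    write_volume(phantom$r2s, file.path(dir, "r2s.nii.gz"), "R2* [s^-1]"),
    write_volume(phantom$b1_rel, file.path(dir, "b1_rel.nii.gz"),
                 "relative B1+ [1]"),
    write_volume(phantom$class_labels, file.path(dir, "class_labels.nii.gz"),
                 paste(attr(phantom$class_labels, "levels"), collapse = ","))
  )
  for (nm in names(phantom$tissue_probs)) {
    paths <- c(paths, write_volume(
      phantom$tissue_probs[[nm]],
      file.path(dir, sprintf("prob_%s.nii.gz", nm)),
      sprintf("tissue probability: %s", nm)))
  }
  invisible(paths)
}

#' Read and write flat key-value run configuration files
#'
#' The configuration format is flat `key = value` text with units embedded in
#' key names (e.g. `noise_sd_au`, `tr_pdw_ms`). Values are parsed as numeric
#' vectors when possible (comma-separated), otherwise kept as strings.
#'
#' @param path File path.
#' @return For `read_run_config`, a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such config file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L)
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' @rdname read_run_config
#' @param config Named list of scalar/vector values.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(config[[k]], collapse = ", "))
  }, "")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Run the full single-subject pipeline
#'
#' Phantom generation, FLASH simulation, quantitative-map estimation and the
#' masked linear relaxometry fit, in order, with every intermediate map
#' written to `out_dir` along with a JSON report carrying the coefficients,
#' Pearson correlation, per-class residual summaries and full provenance
#' (seed, noise level, grid, thresholds), sufficient to re-execute the run
#' exactly.
#'
#' @param out_dir Output directory; created if needed.
#' @param spec A `"phantom_spec"` (default: [default_brain_spec()] with
#'   `seed`).
#' @param acq Acquisition parameters.
#' @param noise_sd Acquisition noise SD, a.u.
#' @param seed Integer seed (used for the phantom when `spec` is `NULL`, and
#'   always for the noise draws).
#' @param gmwm_threshold,csf_threshold Mask thresholds.
#' @param terms Model terms after the intercept (`c("mt", "r2s")` or `"mt"`
#'   for the iron-ablated variant).
#' @param echo_handling Passed to [fit_mpm_maps()].
#' @param write_maps Write NIfTI intermediates (default `TRUE`); the JSON
#'   report is always written.
#' @return The `"relax_fit"`, invisibly, with attribute `"report_path"`.
#' @export
run_subject_pipeline <- function(out_dir, spec = NULL,
                                 acq = default_acquisition(), noise_sd = 0,
                                 seed = 1L, gmwm_threshold = 0.5,
                                 csf_threshold = 0.5,
                                 terms = c("mt", "r2s"),
                                 echo_handling = "average",
                                 write_maps = TRUE) {
  stage <- "phantom"
  result <- tryCatch({
    if (is.null(spec)) spec <- default_brain_spec(seed = seed)
    phantom <- make_phantom(spec)

    stage <- "flash simulation"
    series <- simulate_mpm(phantom, acq, noise_sd = noise_sd, seed = seed)

    stage <- "map estimation"
    maps <- fit_mpm_maps(series, acq, b1_rel = phantom$b1_rel,
                         echo_handling = echo_handling)

    stage <- "model fit"
    fit <- relax_fit(maps$r1, maps$mt_sat, maps$r2s,
                     tissue_probs = phantom$tissue_probs,
                     gmwm_threshold = gmwm_threshold,
                     csf_threshold = csf_threshold,
                     terms = terms, class_labels = phantom$class_labels)

    stage <- "output"
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (write_maps) {
      write_phantom(phantom, file.path(out_dir, "phantom"))
      write_volume(maps$r1, file.path(out_dir, "r1.nii.gz"), "R1 [s^-1]")
      write_volume(maps$pd, file.path(out_dir, "pd.nii.gz"), "PD [a.u.]")
      write_volume(maps$mt_sat, file.path(out_dir, "mt_sat.nii.gz"),
                   "MT saturation [p.u.]")
      write_volume(maps$r2s, file.path(out_dir, "r2s.nii.gz"), "R2* [s^-1]")
      write_volume(maps$mtr, file.path(out_dir, "mtr.nii.gz"), "MTR [p.u.]")
      write_volume(predict(fit), file.path(out_dir, "r1_synthetic.nii.gz"),
                   "synthetic R1 [s^-1]")
      write_volume(residuals(fit, "map"),
                   file.path(out_dir, "residuals.nii.gz"),
                   "R1 residual [s^-1]")
    }

    report <- list(
      package_version = as.character(utils::packageVersion("relaxometry")),
      seed = seed, noise_sd_au = noise_sd,
      grid_shape = spec$grid_shape,
      gmwm_threshold = gmwm_threshold, csf_threshold = csf_threshold,
      terms = fit$terms,
      echo_handling = echo_handling,
      n_voxels = fit$n, n_dropped = fit$design$n_dropped,
      coefficients = as.list(fit$coefficients),
      pearson = fit$pearson,
      free_water_t1_s = if ("unity" %in% names(fit$coefficients) &&
                            fit$coefficients[["unity"]] > 0)
        free_water_t1(fit) else NULL,
      residual_pct = as.list(fit$report$residual_pct),
      per_class = fit$report$per_class
    )
    report_path <- file.path(out_dir, "fit_report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    attr(fit, "report_path") <- report_path
    fit
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
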