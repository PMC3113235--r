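#' Scenario serialisation
#'
#' Scenario configurations round-trip through a nested key/value YAML
#' document. `write_scenario()`/`read_scenario()` preserve every parameter
#' block, the variant switches and the isoform specs.
#'
#' @param cfg a `vegf_scenario`.
#' @param path file path (`.yaml`).
#' @export
write_scenario <- function(cfg, path) {
  validate_scenario(cfg)
  ser_iso <- function(s) {
    out <- unclass(s)
    out$Kd_H <- if (is.infinite(out$Kd_H)) "Inf" else out$Kd_H
    out
  }
  doc <- list(
    label = cfg$label,
    variant = cfg$variant,
    sprout = cfg$sprout,
    allow_V189_R2 = cfg$allow_V189_R2,
    geometry = unclass(cfg$geometry),
    transport = unclass(cfg$transport),
    isoform = ser_iso(cfg$isoform),
    cleaved_isoform = ser_iso(cfg$cleaved_isoform),
    receptors = if (!is.null(cfg$receptors)) unclass(cfg$receptors),
    interstitial = unclass(cfg$interstitial),
    drive = lapply(unclass(cfg$drive), function(x)
      if (is.numeric(x) && anyNA(x)) "NA" else x)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  req <- c("variant", "geometry", "transport", "isoform", "cleaved_isoform",
           "interstitial", "drive")
  missing_fields <- setdiff(req, names(doc))
  if (length(missing_fields)) {
    stop("invalid scenario file `", path, "`: missing fields:\n",
         paste0("  - ", missing_fields, collapse = "\n"), call. = FALSE)
  }
  de_iso <- function(x) {
    x$Kd_H <- if (identical(x$Kd_H, "Inf")) Inf else as.numeric(x$Kd_H)
    do.call(isoform_spec, x[setdiff(names(x), "kon_H")])
  }
  num <- function(x) if (identical(x, "NA")) NA_real_ else as.numeric(x)
  drive <- doc$drive
  cfg <- structure(list(
    geometry = do.call(geometry_params, doc$geometry),
    transport = do.call(transport_params, doc$transport),
    isoform = de_iso(doc$isoform),
    cleaved_isoform = de_iso(doc$cleaved_isoform),
    receptors = if (!is.null(doc$receptors))
      do.call(receptor_params, doc$receptors),
    interstitial = do.call(interstitial_params, doc$interstitial),
    drive = boundary_drive(V0 = num(drive$V0), g0 = num(drive$g0),
                           q = num(drive$q), k_clear = num(drive$k_clear),
                           mode = drive$mode),
    variant = doc$variant,
    sprout = isTRUE(doc$sprout),
    allow_V189_R2 = isTRUE(doc$allow_V189_R2),
    label = doc$label %||% "scenario"
  ), class = "vegf_scenario")
  validate_scenario(cfg)
  cfg
}

#' Apply `key=value` overrides to a scenario
#'
#' Keys use dotted paths into the configuration, e.g.
#' `interstitial.H_total_ref=0` or `drive.q=5.27e-5`.
#'
#' @param cfg a `vegf_scenario`.
#' @param overrides character vector of `key=value` strings.
#' @export
apply_overrides <- function(cfg, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("override must be key=value: ", ov, call. = FALSE)
    path <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(kv[2]))
    if (is.na(val) && !identical(kv[2], "NA")) val <- kv[2]
    expr <- sprintf("cfg%s <- val",
                    paste0(sprintf("[['%s']]", path), collapse = ""))
    eval(parse(text = expr))
  }
  validate_scenario(cfg)
  cfg
}

#' Execute a full run and write its outputs
#'
#' Runs calibration if the drive lacks `q`/`k_clear`, solves to steady
#' state, and writes the field table, surface table, metrics summary and a
#' JSON run manifest to `outdir`.
#'
#' @param config a `vegf_scenario`, a figure tag accepted by
#'   [build_figure_scenario()], or a path to a scenario YAML file.
#' @param outdir output directory (created if needed).
#' @param overrides character vector of `key=value` dotted-path overrides.
#' @param settings a [solver_settings()].
#' @param isoform passed to [build_figure_scenario()] for tag configs.
#' @param dz,dr optional mesh overrides (axial spacing and the radial
#'   spacing next to the sprout, um).
#' @return the run manifest (list), invisibly.
#' @export
cmd_run <- function(config, outdir = ".", overrides = character(),
                    settings = solver_settings(), isoform = "VEGF165",
                    dz = 8, dr = 8) {
  t0 <- Sys.time()
  cfg <- if (inherits(config, "vegf_scenario")) {
    config
  } else if (file.exists(config)) {
    read_scenario(config)
  } else {
    build_figure_scenario(config, isoform = isoform)
  }
  if (inherits(cfg, "sweep_spec")) {
    stop("tag resolves to a sweep; use cmd_sweep()", call. = FALSE)
  }
  if (length(overrides)) cfg <- apply_overrides(cfg, overrides)
  grid <- if (dz != 8 || dr != 8) {
    build_grid(cfg$geometry, dz = dz, dr_fine = dr, dr_coarse = 8,
               sprout = cfg$sprout)
  }
  if (!is.finite(cfg$drive$q) || !is.finite(cfg$drive$k_clear)) {
    cal <- calibrate_neumann(cfg, settings = settings, grid = grid)
    cfg$drive$q <- cal$q
    cfg$drive$k_clear <- cal$k_clear
  }
  cfg$drive$mode <- "neumann_stage"
  res <- solve_steady(cfg, settings = settings, grid = grid)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(field = "field.tsv", surface = "surface.tsv",
             metrics = "metrics.tsv", manifest = "manifest.json")
  utils::write.table(tidy(res), file.path(outdir, files["field"]),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(surface_table(res), file.path(outdir, files["surface"]),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  metrics <- tidy(tip_metrics(res))
  utils::write.table(metrics, file.path(outdir, files["metrics"]),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg_file <- file.path(outdir, "scenario.yaml")
  write_scenario(cfg, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("vegfgrad")),
    label = cfg$label,
    config = "scenario.yaml",
    settings = unclass(settings),
    convergence = list(steps = res$steps, final_delta = res$final_delta,
                       closure = attr(res$flux_balance, "closure")),
    timing_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(outdir, files["manifest"]),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Execute a parameter sweep and write its outputs
#'
#' @param spec a `sweep_spec`, or one of the sweep tags of
#'   [build_figure_scenario()] ("fig7B", "fig7C", "fig8").
#' @param outdir output directory.
#' @param with_receptor_map also compute [receptor_binding_map()].
#' @param settings a [solver_settings()].
#' @return the run manifest, invisibly.
#' @export
cmd_sweep <- function(spec, outdir = ".", with_receptor_map = FALSE,
                      settings = solver_settings(dt_max = 1e5)) {
  t0 <- Sys.time()
  if (is.character(spec)) {
    if (identical(spec, "fig8")) with_receptor_map <- TRUE
    spec <- build_figure_scenario(spec)
  }
  stopifnot(inherits(spec, "sweep_spec"))
  sw <- run_sweep(spec, settings = settings)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  long <- tidyr::pivot_longer(
    sw$points, cols = -c("axis", "Kd", "k_P", "converged"),
    names_to = "metric", values_to = "value")
  utils::write.table(long, file.path(outdir, "sweep.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sw$classification,
                     file.path(outdir, "classification.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  outputs <- list(sweep = "sweep.tsv", classification = "classification.tsv")
  if (with_receptor_map) {
    rm_ <- receptor_binding_map(sw, spec$receptors %||% receptor_params())
    utils::write.table(rm_$curves, file.path(outdir, "receptor_map.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    outputs$receptor_map <- "receptor_map.tsv"
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("vegfgrad")),
    variant = spec$variant,
    n_points = nrow(sw$points),
    n_converged = sum(sw$points$converged),
    timing_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Emit the preset scenario configurations
#'
#' Writes the YAML configuration for every figure-level condition to a
#' directory (the sweep tags are emitted as their defining parameters).
#'
#' @param outdir target directory.
#' @return paths written, invisibly.
#' @export
cmd_fixtures <- function(outdir = "fixtures") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (tag in c("fig3", "fig3_noHSPG")) {
    p <- file.path(outdir, paste0(tag, ".yaml"))
    write_scenario(build_figure_scenario(tag), p)
    paths <- c(paths, p)
  }
  for (tag in c("fig4A", "fig4B", "fig4C", "fig4D", "fig5_iso", "fig6_iso")) {
    for (iso in c("VEGF121", "VEGF165", "VEGF189")) {
      p <- file.path(outdir, sprintf("%s_%s.yaml", tag, iso))
      write_scenario(build_figure_scenario(tag, isoform = iso), p)
      paths <- c(paths, p)
    }
  }
  for (tag in c("fig7B", "fig7C", "fig8")) {
    sp <- build_figure_scenario(tag)
    p <- file.path(outdir, paste0(tag, "_sweep.yaml"))
    yaml::write_yaml(list(variant = sp$variant, Kd_grid = format(sp$Kd_grid),
                          kP_grid = sp$kP_grid, kP_fixed = sp$kP_fixed,
                          Kd_fixed = sp$Kd_fixed,
                          receptors = !is.null(sp$receptors)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
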