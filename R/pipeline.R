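#' Pipeline run configuration
#'
#' Collects every tunable of the analysis in one round-trippable list.
#' The defaults are the study's own constants: pre season 1--25 October,
#' early season 27 October -- 23 November (opening 27 October), late
#' season 24 November -- 15 December; error-ellipse thresholds 2000 m^2
#' (daytime) and 1000 m^2 (roost); at least 10 relocations per seasonal
#' home range; 11-relocation moving windows (half-width 5); 5000
#' posterior draws; 1000 bootstrap iterations with 999 permutations per
#' inner PERMANOVA.
#'
#' @param ... overrides of any default field.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(
    season_pre = c("10-01", "10-25"),
    season_early = c("10-27", "11-23"),
    season_late = c("11-24", "12-15"),
    opening = "10-27",
    ellipse_daytime_max = 2000,
    ellipse_roost_max = 1000,
    min_fixes = 10,
    window_half_width = 5,
    n_draws = 5000,
    n_boot = 1000,
    n_perm = 999,
    distance = "euclidean_std",
    pressure_offset = 0.001,
    n_cells_seasonal = 200,
    n_cells_window = 60,
    survival_days = 49,
    seed = 1,
    log_level = "info")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file.
#' @export
write_config <- function(cfg, path) {
  x <- cfg
  class(x) <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @param cfg a \code{run_config}.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# tiny polynomial rolling hash of the config for the manifest
# (double arithmetic mod 2^31 stays exact well within 2^53)
config_hash <- function(cfg) {
  x <- cfg; class(x) <- NULL
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[riskspace] %s", paste0(...)))
}

#' Run the full space-use analysis pipeline
#'
#' \code{mode = "simulate"} first generates a synthetic dataset (from
#' \code{truth}) and writes it to \code{data_dir}; \code{mode =
#' "analyze"} reads an existing dataset from \code{data_dir}. Either way
#' the pipeline then runs, in order: bearing-set triangulation (QC
#' product), relocation precision filtering, daily hunting pressure and
#' the risk mixed model, seasonal home ranges and center shifts, moving
#' windows with pressure attribution and steps, the space-use mixed-model
#' suite, the three bootstrapped roost PERMANOVAs, and the survival
#' summaries. All result tables are written to \code{out_dir} together
#' with a run manifest (config hash, seed, row counts, stage timings).
#' Input files are validated before any computation; outputs are written
#' atomically (temp file + rename).
#'
#' @param cfg a \code{\link{run_config}}.
#' @param mode \code{"simulate"} or \code{"analyze"}.
#' @param data_dir dataset directory.
#' @param out_dir results directory.
#' @param truth \code{\link{simulation_truth}} used in simulate mode.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg = run_config(),
                         mode = c("simulate", "analyze"),
                         data_dir, out_dir,
                         truth = simulation_truth(seed = cfg$seed)) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(mode = mode, config_hash = config_hash(cfg),
                   seed = cfg$seed, stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      rows = if (is.data.frame(val)) nrow(val) else NA)
    log_msg(cfg, name, " done")
    val
  }
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    tmp <- paste0(path, ".tmp")
    write_table_csv(x, tmp)
    file.rename(tmp, path)
    manifest$outputs[[name]] <<- nrow(x)
  }

  if (mode == "simulate") {
    ds <- t_stage("simulate", simulate_dataset(truth))
    write_dataset(ds, data_dir)
  } else {
    need <- c("relocations.csv", "cameras.csv", "fates.csv",
              "sites.geojson")
    for (f in need) if (!file.exists(file.path(data_dir, f)))
      stop("analyze mode: required input missing: ", file.path(data_dir, f))
  }
  relocations <- read_relocations_csv(file.path(data_dir, "relocations.csv"))
  cameras <- read_cameras_csv(file.path(data_dir, "cameras.csv"))
  fates <- read_fates_csv(file.path(data_dir, "fates.csv"))
  sites <- read_sites_geojson(file.path(data_dir, "sites.geojson"))
  veg <- if (file.exists(file.path(data_dir, "vegetation.csv")))
    read_vegetation_csv(file.path(data_dir, "vegetation.csv")) else NULL
  bearings <- if (file.exists(file.path(data_dir, "bearings.csv")))
    read_bearings_csv(file.path(data_dir, "bearings.csv")) else NULL

  if (!is.null(bearings)) {
    tri <- t_stage("triangulate", triangulate_sets(bearings))
    emit(tri, "triangulated.csv")
  }
  relocations <- t_stage("filter", filter_relocations(
    relocations, cfg$ellipse_daytime_max, cfg$ellipse_roost_max))

  pressure <- t_stage("pressure", daily_pressure(cameras, sites))
  emit(pressure[, setdiff(names(pressure), "polygon")], "pressure.csv")

  risk_fit <- tryCatch(
    t_stage("risk_model",
            fit_risk_model(pressure, n_draws = cfg$n_draws,
                           seed = cfg$seed)$summary),
    error = function(e) { log_msg(cfg, "risk model skipped: ",
                                  conditionMessage(e)); NULL })

  hr <- t_stage("seasonal_home_ranges", seasonal_home_ranges(
    relocations, min_fixes = cfg$min_fixes,
    n_cells = cfg$n_cells_seasonal))
  emit(hr, "home_ranges.csv")
  shifts <- t_stage("seasonal_shifts", seasonal_shifts(hr))
  emit(shifts, "shifts.csv")

  windows <- t_stage("windows", build_windows(
    relocations, half_width = cfg$window_half_width,
    n_cells = cfg$n_cells_window, sites = sites))
  windows <- t_stage("pressure_attribution",
                     assign_site_and_pressure(windows, sites, pressure))
  emit(windows, "windows.csv")
  steps <- t_stage("window_steps", window_steps(windows))
  emit(steps, "window_steps.csv")

  set.seed(cfg$seed)
  fits <- space_use_model_suite(hr, shifts, windows, steps,
                                n_draws = cfg$n_draws,
                                pressure_offset = cfg$pressure_offset)
  model_results <- coef_table(fits)
  if (!is.null(risk_fit))
    model_results <- rbind(cbind(model = "risk", risk_fit), model_results)
  emit(model_results, "model_results.csv")
  manifest$stages[["model_suite"]] <- list(rows = nrow(model_results))

  if (!is.null(veg)) {
    perm <- lapply(c("pre", "within", "nonuse"), function(m) {
      r <- tryCatch(
        subsample_bootstrap(veg, model = m, n_iter = cfg$n_boot,
                            n_perm = cfg$n_perm, seed = cfg$seed,
                            distance = cfg$distance),
        error = function(e) { log_msg(cfg, "permanova ", m, " skipped: ",
                                      conditionMessage(e)); NULL })
      if (!is.null(r)) cbind(model = m, as.data.frame(r)) else NULL
    })
    perm <- do.call(rbind, perm)
    if (!is.null(perm)) emit(perm, "permanova_results.csv")
    manifest$stages[["permanova"]] <- list(
      rows = if (is.null(perm)) 0 else nrow(perm))
  }

  curves <- t_stage("survival", survival_curves(
    fates, days = 0:cfg$survival_days))
  emit(curves, "survival_curves.csv")
  emit(early_mortality_table(fates), "mortality_table.csv")

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
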