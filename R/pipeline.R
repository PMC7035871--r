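# Pipeline orchestration: simulate/ingest -> (classify) -> buffers ->
# grassiness -> isotopes -> permutation report, with a declarative config,
# per-stage logging/timing and a JSON provenance sidecar. Stages are
# skippable when their outputs are supplied pre-computed (e.g. deposited
# %C4 values and buffer coverages).

#' Merge samples, grassiness and diet estimates into an analysis table
#'
#' @param samples data frame with \code{sample_id}, \code{locality_id},
#'   \code{interval}, \code{season}, and either \code{pct_c4} (pre-computed)
#'   or \code{d13C}.
#' @param grass output of \code{\link{grassiness_table}} (\code{sample_id},
#'   \code{radius_m}, \code{grassiness}).
#' @param diet optional output of \code{\link{estimate_diet}}; required when
#'   \code{samples} lacks \code{pct_c4}.
#' @param profiles optional long profile table carrying
#'   \code{valid_fraction}; samples with any radius below
#'   \code{min_valid_fraction} are excluded (and listed in the
#'   \code{"excluded"} attribute).
#' @param min_valid_fraction minimum buffer coverage to keep a sample
#'   (default 0.5).
#' @return wide analysis table: one row per specimen with
#'   \code{grassiness_<r>km} columns.
#' @export
build_analysis_table <- function(samples, grass, diet = NULL,
                                 profiles = NULL,
                                 min_valid_fraction = 0.5) {
  need <- c("sample_id", "locality_id", "interval", "season")
  stop_if(!all(need %in% names(samples)), "samples missing columns: ",
          paste(setdiff(need, names(samples)), collapse = ", "))
  tab <- samples[, intersect(c(need, "pct_c4", "d13C"), names(samples))]
  if (!"pct_c4" %in% names(tab)) {
    stop_if(is.null(diet), "samples lack pct_c4 and no diet estimates given")
    tab <- merge(tab, diet[, c("sample_id", "pct_c4")], by = "sample_id")
  }
  excluded <- character(0)
  if (!is.null(profiles)) {
    vf <- unique(profiles[, c("sample_id", "radius_m", "valid_fraction")])
    bad <- unique(vf$sample_id[vf$valid_fraction < min_valid_fraction])
    excluded <- as.character(bad)
    grass <- grass[!grass$sample_id %in% bad, , drop = FALSE]
    tab <- tab[!tab$sample_id %in% bad, , drop = FALSE]
  }
  wide <- stats::reshape(grass, idvar = "sample_id", timevar = "radius_m",
                         direction = "wide")
  names(wide) <- sub("^grassiness\\.(\\d+)$", "\\1", names(wide))
  rcols <- setdiff(names(wide), "sample_id")
  names(wide)[match(rcols, names(wide))] <-
    grassiness_column(as.numeric(rcols))
  out <- merge(tab, wide, by = "sample_id")
  attr(out, "excluded") <- excluded
  out
}

#' Read a pipeline run configuration
#'
#' YAML file with sections: \code{output_dir}, \code{radii_m},
#' \code{min_valid_fraction}, and either a \code{simulate} block (landscape
#' + diet generator settings) or an \code{inputs} block (\code{landcover}
#' .asc path, \code{samples} CSV path), plus optional \code{classify}
#' (senescent/flushed band files, training points CSV), \code{mixing}
#' (endmembers, epsilon) and \code{permutation} (iterations, seed, scheme,
#' cl, alpha) blocks.
#'
#' @param path YAML file path.
#' @return config list, validated by \code{\link{run_pipeline}}.
#' @export
read_run_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: ", path)
  yaml::read_yaml(path)
}

validate_config <- function(config) {
  stop_if(is.null(config$output_dir), "config field missing: output_dir")
  stop_if(is.null(config$simulate) && is.null(config$inputs) &&
            is.null(config$classify),
          "config needs one of: simulate, inputs, classify")
  for (f in c("landcover", "samples")) {
    p <- config$inputs[[f]]
    stop_if(!is.null(p) && !file.exists(p),
            "config field inputs$", f, ": file not found: ", p)
  }
  if (!is.null(config$classify)) {
    for (f in c("senescent", "flushed")) {
      p <- config$classify[[f]]
      stop_if(is.null(p), "config field classify$", f, " missing")
      miss <- p[!file.exists(p)]
      stop_if(length(miss) > 0, "config field classify$", f,
              ": file not found: ", paste(miss, collapse = ", "))
    }
    stop_if(is.null(config$classify$points) ||
              !file.exists(config$classify$points),
            "config field classify$points: file not found")
  }
  radii <- config$radii_m %||% c(2000, 4000, 8000, 12000)
  stop_if(any(radii <= 0) || anyDuplicated(radii) > 0,
          "config field radii_m: radii must be positive and unique")
  invisible(TRUE)
}

#' Run the full diet-landscape analysis pipeline
#'
#' @param config a config list (see \code{\link{read_run_config}}) or a
#'   YAML path.
#' @param quiet suppress console logging.
#' @return (invisibly) list with the analysis objects and output paths.
#'   Artefacts written to \code{output_dir}: \code{landcover.asc},
#'   \code{samples.csv}, \code{profiles.csv}, \code{grassiness.csv},
#'   \code{diet.csv} (unless the isotope stage was skipped),
#'   \code{report_summaries.csv}, \code{report_comparisons.csv},
#'   \code{accuracy.csv} (when validating a classification) and
#'   \code{run_metadata.json}.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  timings <- list(); notes <- character(0)
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(line, "\n", file = log_path, append = TRUE)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    log("stage ", name, " ...")
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  scheme <- savanna_scheme()
  radii <- config$radii_m %||% c(2000, 4000, 8000, 12000)

  # --- land cover ---------------------------------------------------------
  accuracy <- NULL
  if (!is.null(config$classify)) {
    cls <- stage("classify", {
      sen <- read_stack(config$classify$senescent)
      flu <- read_stack(config$classify$flushed)
      comp <- build_composite(sen, flu)
      pts <- utils::read.csv(config$classify$points)
      if (!"role" %in% names(pts)) pts <- allocate_roles(pts)
      clf <- train_classifier(comp, pts,
                              ntree = config$classify$ntree %||% 500,
                              seed = config$classify$seed %||% 1)
      r <- classify_raster(comp, clf)
      cm <- confusion_matrix(r, pts, scheme)
      acc <- accuracy_summary(cm)
      acc_df <- data.frame(class = c("overall", names(acc$users)),
                           users_pct = c(NA, round_half_up(acc$users)),
                           producers_pct =
                             c(NA, round_half_up(acc$producers)),
                           overall_pct = c(round_half_up(acc$overall),
                                           rep(NA, length(acc$users))))
      utils::write.csv(acc_df, file.path(out_dir, "accuracy.csv"),
                       row.names = FALSE)
      list(raster = r, accuracy = acc_df)
    })
    lc <- cls$raster
    accuracy <- cls$accuracy
  } else if (!is.null(config$simulate)) {
    lc <- stage("simulate_landscape", {
      ls_spec <- do.call(landscape_spec, config$simulate$landscape %||% list())
      generate_landscape(ls_spec, scheme)
    })
  } else {
    lc <- stage("read_landcover", read_lc_raster(config$inputs$landcover))
  }
  write_lc_raster(lc, file.path(out_dir, "landcover.asc"))

  # --- samples ------------------------------------------------------------
  samples <- if (!is.null(config$simulate)) {
    stage("simulate_samples", {
      dspec <- do.call(diet_model_spec, config$simulate$diet %||% list())
      generate_samples(lc, scheme, dspec)
    })
  } else {
    stage("read_samples", utils::read.csv(config$inputs$samples))
  }
  utils::write.csv(samples, file.path(out_dir, "samples.csv"),
                   row.names = FALSE)

  # --- buffers + grassiness ----------------------------------------------
  profiles <- stage("buffers", extract_all(lc, samples, radii, scheme))
  utils::write.csv(profiles, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE)
  grass <- stage("grassiness",
                 grassiness_table(profiles, scheme,
                                  renormalise =
                                    isTRUE(config$grassiness_renormalise)))
  utils::write.csv(grass, file.path(out_dir, "grassiness.csv"),
                   row.names = FALSE)

  # --- isotopes (skippable when %C4 is deposited) -------------------------
  diet <- NULL
  if ("pct_c4" %in% names(samples)) {
    notes <- c(notes, "isotope stage skipped: pre-computed pct_c4 supplied")
    log("stage isotopes skipped (pre-computed pct_c4)")
  } else {
    diet <- stage("isotopes", {
      mp <- do.call(mixing_params, config$mixing %||% list())
      estimate_diet(samples, mp)
    })
    utils::write.csv(diet, file.path(out_dir, "diet.csv"), row.names = FALSE)
  }

  # --- permutation regression --------------------------------------------
  perm <- config$permutation %||% list()
  records <- stage("merge", build_analysis_table(
    samples, grass, diet, profiles,
    min_valid_fraction = config$min_valid_fraction %||% 0.5))
  report <- stage("permtest", permutation_report(
    records, radii_km = radii / 1000,
    iterations = perm$iterations %||% 1000, seed = perm$seed %||% 1,
    scheme = perm$scheme %||% "one_per_unit", cl = perm$cl %||% "sem",
    alpha = perm$alpha %||% 0.05))
  utils::write.csv(report$summaries,
                   file.path(out_dir, "report_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons,
                   file.path(out_dir, "report_comparisons.csv"),
                   row.names = FALSE)
  if (isTRUE(config$qc_plot)) {
    grDevices::png(file.path(out_dir, "qc_diet_vs_grassiness.png"),
                   width = 800, height = 600)
    plot_diet_grassiness(records, radius_km = (radii / 1000)[
      min(2, length(radii))])
    grDevices::dev.off()
  }

  # --- provenance sidecar -------------------------------------------------
  cfg_json <- file.path(out_dir, "config_resolved.json")
  jsonlite::write_json(config, cfg_json, auto_unbox = TRUE, null = "null")
  meta <- list(
    package_version = as.character(utils::packageVersion("grazescape")),
    r_version = R.version.string,
    config_md5 = unname(tools::md5sum(cfg_json)),
    buffer_membership_rule = "pixel centre within Euclidean radius",
    radii_m = radii,
    permutation = list(iterations = perm$iterations %||% 1000,
                       seed = perm$seed %||% 1,
                       scheme = perm$scheme %||% "one_per_unit",
                       cl = perm$cl %||% "sem",
                       alpha = perm$alpha %||% 0.05),
    stage_seconds = timings, notes = notes,
    excluded_samples = attr(records, "excluded"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log("done")
  invisible(list(landcover = lc, samples = samples, profiles = profiles,
                 grassiness = grass, diet = diet, records = records,
                 report = report, accuracy = accuracy,
                 output_dir = out_dir))
}

#' QC scatter of %C4 intake against grassiness, by season
#'
#' @param records analysis table from \code{\link{build_analysis_table}}.
#' @param radius_km which radius column to plot.
#' @export
plot_diet_grassiness <- function(records, radius_km = 4) {
  col <- grassiness_column(radius_km * 1000)
  stop_if(!col %in% names(records), "no column ", col, " in records")
  dry <- records$season == "dry"
  graphics::plot(records[[col]], records$pct_c4,
                 pch = ifelse(dry, 16, 2),
                 col = ifelse(dry, "black", "grey50"),
                 xlab = sprintf("Grassiness index (%g km buffer)", radius_km),
                 ylab = "%C4 in diet")
  for (ssn in c("dry", "wet")) {
    i <- records$season == ssn
    if (sum(i) >= 3 && stats::var(records[[col]][i]) > 0) {
      fit <- ols_fit(records[[col]][i], records$pct_c4[i])
      graphics::abline(fit$a, fit$b,
                       col = if (ssn == "dry") "black" else "grey50")
    }
  }
  graphics::legend("topleft", legend = c("dry", "wet"), pch = c(16, 2),
                   col = c("black", "grey50"), bty = "n")
}
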