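# End-to-end orchestration: simulate -> quantify -> date -> analyze.
# Every stage reads and writes plain CSV so each is independently
# re-runnable; a JSON manifest records the config snapshot, seed and
# per-stage record counts. Outputs carry no timestamps, so identical
# config + seed give byte-identical files.

config_schema <- function() {
  list(
    seed = 1L,
    output_dir = "microfire-run",
    stages = list(simulate = TRUE, quantify = TRUE, agemodel = TRUE,
                  analyze = TRUE),
    core = list(),       # overrides for core_sim_params()
    imaging = list(enabled = FALSE, n_fields = 2L),  # + imaging_sim_params overrides
    detection = list(),  # overrides for detection_config()
    paths = list(phase_table = NULL, samples = NULL,
                 control_points = NULL),
    analysis = list(ellipse_level = 0.95, trend_window = NULL,
                    pool_hs_with_gs = FALSE)
  )
}

check_unknown_keys <- function(x, allowed, where, errors) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    errors <- c(errors, sprintf("unknown key%s in %s: %s",
                                if (length(extra) > 1) "s" else "", where,
                                paste(extra, collapse = ", ")))
  }
  errors
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML/JSON file path or a plain list, fills defaults,
#' cross-checks fields (domain errors such as a non-positive dilution are
#' caught here, before any stage runs) and rejects unknown keys. All
#' schema violations are collected and reported together, not
#' first-failure.
#'
#' @param config path to a YAML or JSON config file, or a named list.
#' @return A validated `run_config` object with all defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    ext <- tolower(tools::file_ext(config))
    config <- if (ext == "json") jsonlite::read_json(config,
                                                     simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  schema <- config_schema()
  errors <- character(0)
  errors <- check_unknown_keys(config, names(schema), "config", errors)
  for (sect in c("stages", "paths", "analysis")) {
    if (!is.null(config[[sect]])) {
      errors <- check_unknown_keys(config[[sect]], names(schema[[sect]]),
                                   sect, errors)
    }
  }
  if (!is.null(config$imaging)) {
    errors <- check_unknown_keys(
      config$imaging,
      union(names(schema$imaging), names(formals(imaging_sim_params))),
      "imaging", errors)
  }
  if (!is.null(config$core)) {
    errors <- check_unknown_keys(
      config$core,
      setdiff(names(formals(core_sim_params)), "phase_spec"),
      "core", errors)
    if (!is.null(config$core$meta)) {
      errors <- check_unknown_keys(
        config$core$meta, setdiff(names(formals(sample_meta)),
                                  c("sample_id", "depth")),
        "core$meta", errors)
    }
  }
  if (!is.null(config$detection)) {
    errors <- check_unknown_keys(config$detection,
                                 names(formals(detection_config)),
                                 "detection", errors)
  }
  cfg <- modifyList(schema, config[intersect(names(config), names(schema))])
  if (!is.null(config$seed)) {
    if (!is.numeric(config$seed) || length(config$seed) != 1L ||
        config$seed != round(config$seed)) {
      errors <- c(errors, "seed: must be a single integer")
    } else {
      cfg$seed <- as.integer(config$seed)
    }
  }
  # domain checks routed through the constructors, reported not thrown
  if (isTRUE(cfg$stages$simulate)) {
    core_args <- cfg$core
    core_args$seed <- NULL
    meta_err <- FALSE
    if (!is.null(core_args$meta)) {
      res <- tryCatch(do.call(sample_meta,
                              c(list(sample_id = "template", depth = 0),
                                core_args$meta)),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        errors <- c(errors, paste0("core$meta: ", res))
        meta_err <- TRUE
      } else core_args$meta <- res
    }
    if (!meta_err) {
      res <- tryCatch(do.call(core_sim_params,
                              c(core_args, list(seed = cfg$seed))),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) errors <- c(errors, paste0("core: ", res))
      else cfg$core_params <- res
    }
  }
  res <- tryCatch(do.call(detection_config, cfg$detection),
                  error = function(e) conditionMessage(e))
  if (is.character(res)) errors <- c(errors, paste0("detection: ", res))
  else cfg$detection_params <- res
  if (isTRUE(cfg$imaging$enabled)) {
    im <- cfg$imaging
    im$enabled <- NULL
    im$seed <- NULL
    n_fields <- im$n_fields %||% 2L
    im$n_fields <- NULL
    res <- tryCatch(do.call(imaging_sim_params,
                            c(im, list(seed = cfg$seed))),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) errors <- c(errors, paste0("imaging: ", res))
    else {
      cfg$imaging_params <- res
      cfg$imaging$n_fields <- as.integer(n_fields)
    }
  }
  for (p in c("phase_table", "samples", "control_points")) {
    path <- cfg$paths[[p]]
    if (!is.null(path) && !file.exists(path)) {
      errors <- c(errors, sprintf("paths$%s: file not found: %s", p, path))
    }
  }
  if (!isTRUE(cfg$stages$simulate) && is.null(cfg$paths$samples)) {
    errors <- c(errors,
                "paths$samples is required when the simulate stage is off")
  }
  if (length(errors)) {
    stop("invalid run config:\n", paste0("  - ", errors, collapse = "\n"),
         call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

write_table <- function(df, dir, name, manifest) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  manifest$files[[name]] <- list(rows = nrow(df),
                                 md5 = unname(tools::md5sum(path)))
  manifest
}

#' Run the microcharcoal pipeline end to end
#'
#' Executes the enabled stages in order:
#'
#' * `simulate`: generate a synthetic core (and, when imaging is enabled,
#'   synthetic micrograph fields with ground truth);
#' * `quantify`: convert charcoal pixel counts to CCsurf records (and run
#'   the particle detector over any simulated fields, writing the
#'   per-particle audit table);
#' * `agemodel`: build the age-depth model, date every record and compute
#'   sedimentation rates;
#' * `analyze`: phase summaries, the logarithmic fuel-fire fit on phase
#'   means, per-phase confidence ellipses, sedimentation-rate
#'   independence checks and the long-term trend.
#'
#' All outputs are CSV files under `output_dir`, plus `manifest.json`
#' recording the config snapshot, seed, package version, per-stage record
#' counts and file checksums. A failing stage aborts the run, names
#' itself in the error, and leaves a `RUN_FAILED.txt` marker next to any
#' partial outputs.
#'
#' @param config a `run_config` from [validate_config()], or anything
#'   [validate_config()] accepts.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "microfire",
    version = as.character(utils::packageVersion("microfire")),
    seed = cfg$seed,
    stages_run = character(0),
    counts = list(),
    files = list())
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      writeLines(sprintf("run failed in stage '%s': %s", name,
                         conditionMessage(e)),
                 file.path(cfg$output_dir, "RUN_FAILED.txt"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  core <- NULL; samples <- NULL; control_points <- NULL; phases <- NULL

  if (isTRUE(cfg$stages$simulate)) {
    stage("simulate", {
      core <- generate_core_record(cfg$core_params)
      samples <- core$samples
      control_points <- core$control_points
      phases <- core$phases
      manifest <- write_table(samples, cfg$output_dir, "samples.csv",
                              manifest)
      manifest <- write_table(control_points, cfg$output_dir,
                              "control_points.csv", manifest)
      manifest <- write_table(as.data.frame(phases), cfg$output_dir,
                              "phases.csv", manifest)
      if (!is.null(cfg$imaging_params)) {
        img_dir <- file.path(cfg$output_dir, "micrographs")
        dir.create(img_dir, showWarnings = FALSE)
        gt <- list()
        for (k in seq_len(cfg$imaging$n_fields)) {
          p <- cfg$imaging_params
          p$seed <- derive_seed(cfg$seed, k)
          sim <- generate_micrograph(p)
          write_micrograph(sim$field,
                           file.path(img_dir, sprintf("field_%02d.png", k)))
          sim$particles$field <- sprintf("field_%02d", k)
          gt[[k]] <- sim$particles
        }
        manifest <- write_table(do.call(rbind, gt), cfg$output_dir,
                                "micrograph_ground_truth.csv", manifest)
      }
      manifest$counts$simulate <- nrow(samples)
      manifest$stages_run <- c(manifest$stages_run, "simulate")
    })
  } else {
    samples <- read.csv(cfg$paths$samples)
    if (!is.null(cfg$paths$control_points)) {
      control_points <- read.csv(cfg$paths$control_points)
    }
  }
  if (!is.null(cfg$paths$phase_table)) {
    phases <- phase_table(read.csv(cfg$paths$phase_table))
  }

  records <- NULL
  if (isTRUE(cfg$stages$quantify)) {
    stage("quantify", {
      need <- c("charcoal_pixels_P", "Sp_um2", "Sr_um2", "D", "W_g",
                "Ss_um2")
      miss <- setdiff(need, names(samples))
      if (length(miss)) {
        stop("samples table lacks columns: ", paste(miss, collapse = ", "))
      }
      cc <- mapply(function(P, Sp, Sr, D, W, Ss)
        compute_ccsurf(P, Sp, Sr, D, W, Ss),
        samples$charcoal_pixels_P, samples$Sp_um2, samples$Sr_um2,
        samples$D, samples$W_g, samples$Ss_um2)
      records <- data.frame(sample_id = samples$sample_id,
                            depth = samples$depth,
                            charcoal_pixels_P = samples$charcoal_pixels_P,
                            ccsurf = cc)
      if (!is.null(samples$biomass)) records$biomass <- samples$biomass
      manifest <- write_table(records, cfg$output_dir,
                              "ccsurf_records.csv", manifest)
      if (!is.null(cfg$imaging_params)) {
        img_dir <- file.path(cfg$output_dir, "micrographs")
        audits <- list()
        for (k in seq_len(cfg$imaging$n_fields)) {
          f <- read_micrograph(
            file.path(img_dir, sprintf("field_%02d.png", k)),
            pixel_area = cfg$imaging_params$pixel_area)
          det <- classify_particles(
            label_particles(binarize(f, cfg$detection_params),
                            cfg$detection_params, f),
            cfg$detection_params)
          attr(det, "labels") <- NULL
          det <- cbind(field = sprintf("field_%02d", k),
                       as.data.frame(det))
          audits[[k]] <- det
        }
        manifest <- write_table(do.call(rbind, audits), cfg$output_dir,
                                "particle_audit.csv", manifest)
      }
      manifest$counts$quantify <- nrow(records)
      manifest$stages_run <- c(manifest$stages_run, "quantify")
    })
  } else if (!is.null(samples$ccsurf)) {
    records <- samples[, intersect(c("sample_id", "depth", "ccsurf",
                                     "biomass", "charcoal_pixels_P"),
                                   names(samples))]
  }

  if (isTRUE(cfg$stages$agemodel)) {
    stage("agemodel", {
      if (is.null(control_points)) {
        stop("no control points available (simulate them or supply paths$control_points)")
      }
      model <- build_age_model(control_points)
      records$age <- depth_to_age(model, records$depth)
      sed <- sedimentation_rate(model, depths = records$depth)
      records$sed_rate_cm_per_kyr <- attr(sed, "sample_rates")
      manifest <- write_table(records, cfg$output_dir,
                              "ccsurf_records_dated.csv", manifest)
      manifest <- write_table(sed, cfg$output_dir,
                              "sedimentation_rates.csv", manifest)
      res <- sampling_resolution(sort(records$age))
      manifest$counts$agemodel <- nrow(records)
      manifest$resolution_yr <- res
      manifest$stages_run <- c(manifest$stages_run, "agemodel")
    })
  }

  if (isTRUE(cfg$stages$analyze)) {
    stage("analyze", {
      if (is.null(phases)) {
        stop("no phase table available (simulate one or supply paths$phase_table)")
      }
      if (is.null(records$age)) {
        stop("records are undated; enable the agemodel stage")
      }
      summ <- phase_summaries(records, phases)
      if (isTRUE(cfg$analysis$pool_hs_with_gs)) {
        summ$phase_class[summ$phase_class == "HS"] <- "GS"
      }
      manifest <- write_table(summ, cfg$output_dir, "phase_summaries.csv",
                              manifest)
      ok <- summ$n >= 1 & !is.na(summ$mean_biomass) & summ$mean_biomass > 0
      fit <- log_fit(summ$mean_biomass[ok], summ$mean_ccsurf[ok])
      fit_df <- data.frame(level = "phase_means", alpha = fit$alpha,
                           beta = fit$beta, se_beta = fit$se_beta,
                           b = fit$b, p_value = fit$p_value, n = fit$n)
      manifest <- write_table(fit_df, cfg$output_dir, "fit_results.csv",
                              manifest)
      lab <- assign_phase(records$age, phases)
      ell <- list()
      for (ph in summ$label[summ$n >= 3]) {
        sel <- !is.na(lab) & lab == ph & !is.na(records$biomass)
        e <- tryCatch(confidence_ellipse(records$biomass[sel],
                                         records$ccsurf[sel],
                                         level = cfg$analysis$ellipse_level),
                      error = function(e) NULL)
        if (!is.null(e)) {
          ell[[ph]] <- data.frame(
            label = ph, n = e$n, center_biomass = e$center[1],
            center_ccsurf = e$center[2], semi_major = e$semi_axes[1],
            semi_minor = e$semi_axes[2], orientation_rad = e$orientation,
            level = e$level)
        }
      }
      if (length(ell)) {
        manifest <- write_table(do.call(rbind, ell), cfg$output_dir,
                                "ellipses.csv", manifest)
      }
      indep <- independence_check(records$ccsurf,
                                  records$sed_rate_cm_per_kyr,
                                  ages = records$age, phases = phases)
      indep_df <- data.frame(
        level = c("samples", "phase_means"),
        r = c(indep$overall$r, indep$phase_level$r),
        p_value = c(indep$overall$p_value, indep$phase_level$p_value),
        n = c(indep$overall$n, indep$phase_level$n))
      manifest <- write_table(indep_df, cfg$output_dir,
                              "independence.csv", manifest)
      window <- cfg$analysis$trend_window %||% range(records$age)
      trend <- long_term_trend(records, window)
      trend_df <- data.frame(slope = trend$slope, se = trend$se,
                             p_value = trend$p_value, n = trend$n,
                             window_young = window[1],
                             window_old = window[2])
      manifest <- write_table(trend_df, cfg$output_dir, "trend.csv",
                              manifest)
      manifest$counts$analyze <- nrow(summ)
      manifest$stages_run <- c(manifest$stages_run, "analyze")
    })
  }

  snapshot <- cfg
  snapshot$core_params$meta <- unclass(snapshot$core_params$meta)
  snapshot$core_params <- if (!is.null(snapshot$core_params))
    unclass(snapshot$core_params)
  snapshot$detection_params <- unclass(snapshot$detection_params)
  snapshot$imaging_params <- if (!is.null(snapshot$imaging_params))
    unclass(snapshot$imaging_params)
  manifest$config <- unclass(snapshot)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
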