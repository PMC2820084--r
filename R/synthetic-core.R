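# Synthetic core records with known phase structure and fuel-fire
# coupling. Emulates a last-glacial deep-sea record: depth-indexed
# samples dated by a handful of control points, alternating Greenland
# Interstadial/Stadial phases, a pollen-derived biomass index that is
# high in interstadials and low in stadials, and a fire proxy coupled
# logarithmically to biomass with additive noise. The sedimentation rate
# is generated independently of the fire proxy, so independence checks
# have a true null to calibrate against.

#' Build an alternating GI/GS phase specification
#'
#' Deterministic default sequence of climatic phases: interstadials and
#' stadials alternate (GI 1.75 kyr, GS 1.25 kyr by default, the
#' millennial Dansgaard-Oeschger tempo) and every `hs_every`-th stadial
#' is an extended Heinrich Stadial.
#'
#' @param age_range c(young, old) in kyr cal BP to cover.
#' @param gi_duration,gs_duration,hs_duration phase durations, kyr.
#' @param hs_every every n-th stadial becomes a Heinrich Stadial
#'   (default 4).
#' @return Data frame (`phase_class`, `duration`, `label`) ordered young
#'   to old, suitable for [generate_phase_sequence()].
#' @export
default_phase_spec <- function(age_range = c(10, 70), gi_duration = 1.75,
                               gs_duration = 1.25, hs_duration = 2.5,
                               hs_every = 4L) {
  assert_range(age_range, "age_range")
  span <- diff(age_range)
  cls <- character(0); dur <- numeric(0)
  total <- 0; stadial_i <- 0L
  while (total < span) {
    cls <- c(cls, "GI"); dur <- c(dur, gi_duration)
    stadial_i <- stadial_i + 1L
    if (stadial_i %% hs_every == 0L) {
      cls <- c(cls, "HS"); dur <- c(dur, hs_duration)
    } else {
      cls <- c(cls, "GS"); dur <- c(dur, gs_duration)
    }
    total <- sum(dur)
  }
  counts <- stats::ave(seq_along(cls), cls, FUN = seq_along)
  data.frame(phase_class = cls, duration = dur,
             label = paste(cls, counts))
}

#' Expand a phase specification into a phase table
#'
#' Lays out contiguous, non-overlapping phases from the young end of the
#' record toward the old end: the first spec row is the youngest phase.
#'
#' @param spec data frame with `phase_class` and `duration` (kyr) columns,
#'   optionally `label` (auto-numbered young-to-old when absent).
#' @param start_age young edge of the sequence, kyr cal BP.
#' @return A [phase_table()] (empty for an empty spec).
#' @export
generate_phase_sequence <- function(spec, start_age = 10) {
  stopifnot(is.data.frame(spec))
  assert_scalar_number(start_age, "start_age")
  if (nrow(spec) == 0L) {
    return(phase_table(data.frame(label = character(0),
                                  phase_class = character(0),
                                  age_start = numeric(0),
                                  age_end = numeric(0))))
  }
  if (!all(c("phase_class", "duration") %in% names(spec))) {
    stop("spec needs `phase_class` and `duration` columns", call. = FALSE)
  }
  if (any(spec$duration <= 0)) {
    stop("phase durations must be positive", call. = FALSE)
  }
  if (is.null(spec$label)) {
    counts <- stats::ave(seq_len(nrow(spec)), spec$phase_class,
                         FUN = seq_along)
    spec$label <- paste(spec$phase_class, counts)
  }
  edges <- start_age + cumsum(c(0, spec$duration))
  phase_table(data.frame(label = spec$label,
                         phase_class = spec$phase_class,
                         age_start = edges[-1L],
                         age_end = edges[-length(edges)]))
}

#' Parameters for the synthetic core generator
#'
#' Defaults emulate a last-glacial marine record: samples every 10 cm
#' between 420 and 2000 cm, dated by 10 control points spanning 10-70 kyr
#' cal BP; the biomass index averages 40% in interstadials and 8% in
#' stadials; the fire proxy follows
#' `ccsurf = alpha + beta * ln(biomass) + noise`, floored at zero.
#'
#' @param depth_range c(top, bottom) sampled depths, cm.
#' @param sampling_step sampling interval, cm.
#' @param n_control_points number of dated control points (>= 2).
#' @param age_range c(young, old) kyr cal BP spanned by the control
#'   points.
#' @param phase_spec phase specification data frame (see
#'   [default_phase_spec()]); must cover `age_range`.
#' @param biomass_GI_mean,biomass_GS_mean phase-class biomass means,
#'   percent (Heinrich Stadials use the GS mean).
#' @param biomass_noise_sd per-sample biomass noise SD, percent; values
#'   are truncated into \[0.1, 100\] before the log-coupling is applied.
#'   The default (2%, a quarter of the stadial mean) keeps the Gaussian
#'   draw essentially inside the index's support, so truncation stays
#'   negligible and the log-coupling remains identifiable.
#' @param coupling_alpha intercept of the fuel-fire coupling, um^2 g^-1.
#' @param coupling_beta slope per ln-unit of biomass percent, um^2 g^-1.
#' @param ccsurf_noise_sd additive CCsurf noise SD, um^2 g^-1 (the result
#'   is floored at 0).
#' @param meta a [sample_meta()]-style list of measurement constants
#'   applied to every sample (default: W = 0.2 g, D = 0.1, 47 mm filter).
#' @param pixel_area Sp used to derive the implied charcoal pixel count,
#'   um^2.
#' @param seed integer master seed.
#' @return Object of class `core_sim_params`.
#' @export
core_sim_params <- function(depth_range = c(420, 2000),
                            sampling_step = 10,
                            n_control_points = 10,
                            age_range = c(10, 70),
                            phase_spec = default_phase_spec(age_range),
                            biomass_GI_mean = 40,
                            biomass_GS_mean = 8,
                            biomass_noise_sd = 2,
                            coupling_alpha = 1e5,
                            coupling_beta = 5e4,
                            ccsurf_noise_sd = 3e4,
                            meta = sample_meta("template", depth = 0),
                            pixel_area = 0.25,
                            seed = 1L) {
  assert_range(depth_range, "depth_range")
  assert_scalar_number(sampling_step, "sampling_step", positive = TRUE)
  n_control_points <- assert_count(n_control_points, "n_control_points",
                                   min = 2L)
  assert_range(age_range, "age_range")
  if (age_range[1] <= 0) stop("ages must be positive (kyr cal BP)",
                              call. = FALSE)
  assert_scalar_number(biomass_GI_mean, "biomass_GI_mean", positive = TRUE)
  assert_scalar_number(biomass_GS_mean, "biomass_GS_mean", positive = TRUE)
  if (biomass_GI_mean > 100 || biomass_GS_mean > 100) {
    stop("biomass means are percentages and must be <= 100", call. = FALSE)
  }
  assert_scalar_number(biomass_noise_sd, "biomass_noise_sd")
  assert_scalar_number(ccsurf_noise_sd, "ccsurf_noise_sd")
  if (biomass_noise_sd < 0 || ccsurf_noise_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  assert_scalar_number(coupling_alpha, "coupling_alpha")
  assert_scalar_number(coupling_beta, "coupling_beta")
  assert_scalar_number(pixel_area, "pixel_area", positive = TRUE)
  structure(
    list(depth_range = depth_range, sampling_step = sampling_step,
         n_control_points = n_control_points, age_range = age_range,
         phase_spec = phase_spec, biomass_GI_mean = biomass_GI_mean,
         biomass_GS_mean = biomass_GS_mean,
         biomass_noise_sd = biomass_noise_sd,
         coupling_alpha = coupling_alpha, coupling_beta = coupling_beta,
         ccsurf_noise_sd = ccsurf_noise_sd, meta = meta,
         pixel_area = pixel_area, seed = as.integer(seed)),
    class = "core_sim_params"
  )
}

#' Generate a synthetic core record
#'
#' Produces a depth-indexed sample table with true ages (from a random
#' but reproducible piecewise-linear chronology), phase labels, biomass
#' indices drawn around the phase-class means, a latent CCsurf following
#' the logarithmic fuel-fire coupling, and the implied charcoal pixel
#' count `P` that makes [compute_ccsurf()] reproduce the latent value to
#' within one pixel's worth of area. Control-point ages are jittered
#' independently of everything else, so sedimentation rate carries no
#' information about the fire proxy.
#'
#' @param params a [core_sim_params()] object.
#' @return Object of class `synthetic_core`: list with `samples` (data
#'   frame: `sample_id`, `depth`, `age`, `phase`, `phase_class`,
#'   `biomass`, `ccsurf`, `charcoal_pixels_P`, `sed_rate_cm_per_kyr`,
#'   and the measurement constants `W_g`, `D`, `Sr_um2`, `Ss_um2`,
#'   `Sp_um2`), `control_points`, `phases` (a [phase_table()]),
#'   `age_model` and `params`.
#' @export
generate_core_record <- function(params) {
  stopifnot(inherits(params, "core_sim_params"))
  phases <- generate_phase_sequence(params$phase_spec,
                                    start_age = params$age_range[1])
  old_edge <- max(phases$age_start)
  if (old_edge < params$age_range[2] - 1e-9) {
    stop(sprintf(
      "phase sequence covers only up to %g kyr; interval [%g, %g] kyr is uncovered",
      old_edge, old_edge, params$age_range[2]), call. = FALSE)
  }
  with_seed(params$seed, {
    depths <- seq(params$depth_range[1], params$depth_range[2],
                  by = params$sampling_step)
    n <- length(depths)
    ncp <- params$n_control_points
    cp_depth <- seq(params$depth_range[1], params$depth_range[2],
                    length.out = ncp)
    w <- runif(ncp - 1L, 0.5, 1.5)
    cp_age <- params$age_range[1] +
      diff(params$age_range) * cumsum(c(0, w)) / sum(w)
    control_points <- data.frame(depth = cp_depth, age = cp_age,
                                 source = "synthetic control")
    model <- build_age_model(control_points)
    ages <- depth_to_age(model, depths)
    lab <- assign_phase(ages, phases)
    cls <- phases$phase_class[match(lab, phases$label)]
    mu_b <- ifelse(cls == "GI", params$biomass_GI_mean,
                   params$biomass_GS_mean)
    biomass <- mu_b + rnorm(n, 0, params$biomass_noise_sd)
    biomass <- pmin(100, pmax(0.1, biomass))
    latent <- params$coupling_alpha +
      params$coupling_beta * log(biomass) +
      rnorm(n, 0, params$ccsurf_noise_sd)
    latent <- pmax(0, latent)
    meta <- params$meta
    # pixel count that reproduces the latent concentration
    px_value <- compute_ccsurf(1, Sp = params$pixel_area,
                               Sr = meta$filter_area_Sr, D = meta$dilution_D,
                               W = meta$dry_weight_W,
                               Ss = meta$scanned_area_Ss)
    P <- as.integer(round(latent / px_value))
    sed <- sedimentation_rate(model, depths = depths)
    samples <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      depth = depths, age = ages, phase = lab, phase_class = cls,
      biomass = biomass, ccsurf = latent, charcoal_pixels_P = P,
      sed_rate_cm_per_kyr = attr(sed, "sample_rates"),
      W_g = meta$dry_weight_W, D = meta$dilution_D,
      Sr_um2 = meta$filter_area_Sr, Ss_um2 = meta$scanned_area_Ss,
      Sp_um2 = params$pixel_area)
    structure(list(samples = samples, control_points = control_points,
                   phases = phases, age_model = model, params = params),
              class = "synthetic_core")
  })
}

#' @export
print.synthetic_core <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<synthetic_core: %d samples, %g-%g cm, %.1f-%.1f kyr cal BP, %d phases, %d control points>\n",
    nrow(s), min(s$depth), max(s$depth), min(s$age), max(s$age),
    nrow(x$phases), nrow(x$control_points)))
  invisible(x)
}

#' Write a synthetic core to CSV tables
#'
#' Writes `samples.csv`, `control_points.csv`, `phases.csv` and a JSON
#' snapshot of the generator parameters into `dir`.
#'
#' @param core a `synthetic_core`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic_core <- function(core, dir) {
  stopifnot(inherits(core, "synthetic_core"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(core$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  write.csv(core$control_points, file.path(dir, "control_points.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(core$phases), file.path(dir, "phases.csv"),
            row.names = FALSE)
  p <- core$params
  p$meta <- unclass(p$meta)
  jsonlite::write_json(unclass(p), file.path(dir, "core_sim_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
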