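# Phase-stratified fire-regime statistics.
#
# All statistics are stratified by the millennial-scale climatic phases of
# the last glacial: Greenland Interstadials (GI, warm/wet, high fuel
# load), Greenland Stadials (GS, cold/dry) and Heinrich Stadials (HS,
# extreme stadials marked by ice-rafted debris). A phase table is a set of
# labelled, non-overlapping age intervals on the BP scale (older bound =
# age_start > age_end); it may also declare sedimentary hiatuses whose
# samples are excluded from every statistic.

PHASE_CLASSES <- c("GI", "GS", "HS", "LGM", "HIATUS")

#' Validate a climatic phase table
#'
#' @param phases data frame with columns `label`, `phase_class` (one of
#'   GI, GS, HS, LGM, HIATUS), `age_start` (older bound, kyr cal BP) and
#'   `age_end` (younger bound); `age_start > age_end` on the BP scale.
#'   Non-hiatus intervals must not overlap (hiatuses may overlie phases).
#' @return The validated table (class `phase_table`), sorted young to old.
#' @export
phase_table <- function(phases) {
  stopifnot(is.data.frame(phases))
  need <- c("label", "phase_class", "age_start", "age_end")
  if (!all(need %in% names(phases))) {
    stop("phase table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(phases) == 0L) {
    return(structure(phases[need], class = c("phase_table", "data.frame")))
  }
  bad <- setdiff(unique(phases$phase_class), PHASE_CLASSES)
  if (length(bad)) {
    stop("unknown phase_class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(phases$age_start <= phases$age_end)) {
    i <- which(phases$age_start <= phases$age_end)[1]
    stop(sprintf(
      "phase '%s' has age_start <= age_end; the BP convention requires the older bound first",
      phases$label[i]), call. = FALSE)
  }
  phases <- phases[order(phases$age_end, phases$age_start), need]
  rownames(phases) <- NULL
  real <- phases[phases$phase_class != "HIATUS", ]
  if (nrow(real) > 1L) {
    for (i in seq_len(nrow(real) - 1L)) {
      if (real$age_start[i] > real$age_end[i + 1L] + 1e-12) {
        stop(sprintf("phases '%s' and '%s' overlap",
                     real$label[i], real$label[i + 1L]), call. = FALSE)
      }
    }
  }
  structure(phases, class = c("phase_table", "data.frame"))
}

#' Assign samples to climatic phases
#'
#' Membership is by half-open interval on the BP scale with the older
#' bound inclusive: an age `a` belongs to a phase when
#' `age_end < a <= age_start`. The single youngest phase additionally
#' includes its own young bound, so a record that ends exactly at the
#' young edge of the phase table is not orphaned. Ages inside a declared
#' hiatus, or outside every phase, are unassigned (`NA`).
#'
#' @param age numeric vector of ages, kyr cal BP.
#' @param phases a [phase_table()].
#' @return Character vector of phase labels (`NA` = unassigned).
#' @export
assign_phase <- function(age, phases) {
  phases <- if (inherits(phases, "phase_table")) phases else phase_table(phases)
  out <- rep(NA_character_, length(age))
  if (nrow(phases) == 0L) return(out)
  real <- phases[phases$phase_class != "HIATUS", ]
  if (nrow(real) > 0L) {
    young_edge <- min(real$age_end)
    for (i in seq_len(nrow(real))) {
      hit <- age > real$age_end[i] & age <= real$age_start[i]
      if (real$age_end[i] == young_edge) {
        hit <- hit | age == young_edge
      }
      out[hit] <- real$label[i]
    }
  }
  hia <- phases[phases$phase_class == "HIATUS", ]
  for (i in seq_len(nrow(hia))) {
    out[age > hia$age_end[i] & age <= hia$age_start[i]] <- NA_character_
  }
  out
}

#' Fuel-load biomass index from a pollen spectrum
#'
#' A biomass index is the sum of the pollen percentages of the
#' taxon-groups that represent burnable fuel in a region, with
#' over-represented groups excluded. Two conventions are bundled:
#' `"iberia"` (Ericaceae heathland + open Mediterranean forest) and
#' `"france"` (arboreal pollen with Pinus excluded, because Pinus pollen
#' is over-represented in marine cores).
#'
#' @param spectrum named numeric vector or one-row data frame of
#'   taxon-group percentages (each within \[0, 100\]).
#' @param definition a list with `region`, `include` (character vector of
#'   taxon-group names, non-empty) and optional `exclude`; see
#'   [biomass_definition()].
#' @return The index in percent, capped at 100 (with a warning when the
#'   included groups overlap and sum above 100).
#' @export
biomass_index <- function(spectrum, definition) {
  if (is.data.frame(spectrum)) {
    stopifnot(nrow(spectrum) == 1L)
    spectrum <- unlist(spectrum)
  }
  stopifnot(is.numeric(spectrum), !is.null(names(spectrum)))
  if (any(spectrum < 0 | spectrum > 100)) {
    stop("pollen percentages must be in [0, 100]", call. = FALSE)
  }
  inc <- definition$include
  if (length(inc) == 0L) stop("empty inclusion set", call. = FALSE)
  missing_groups <- setdiff(inc, names(spectrum))
  if (length(missing_groups)) {
    stop("taxon-group(s) missing from spectrum: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  idx <- sum(spectrum[inc])
  if (idx > 100) {
    warning("included groups sum above 100%; index capped at 100",
            call. = FALSE)
    idx <- 100
  }
  idx
}

#' @rdname biomass_index
#' @param region `"iberia"`, `"france"`, or `"custom"`.
#' @param include,exclude taxon-group names for `region = "custom"`.
#' @export
biomass_definition <- function(region = c("iberia", "france", "custom"),
                               include = NULL, exclude = NULL) {
  region <- match.arg(region)
  out <- switch(region,
    iberia = list(region = "iberia",
                  include = c("Ericaceae", "MedForest"),
                  exclude = character(0)),
    france = list(region = "france",
                  include = "AP_noPinus",
                  exclude = "Pinus"),
    custom = list(region = "custom",
                  include = include %||% character(0),
                  exclude = exclude %||% character(0)))
  if (length(out$include) == 0L) {
    stop("a biomass definition needs a non-empty inclusion set",
         call. = FALSE)
  }
  out
}

#' Per-phase summaries of the fire record
#'
#' For every non-hiatus phase in the table: number of samples assigned,
#' mean and sample standard deviation of CCsurf, and the mean biomass
#' index. Phases without samples are reported with `n = 0` and `NA`
#' statistics, never dropped; the SD is `NA` below `n = 2`.
#'
#' @param records data frame with columns `age` (kyr cal BP), `ccsurf`
#'   and optionally `biomass`.
#' @param phases a [phase_table()].
#' @return Data frame with one row per phase: `label`, `phase_class`,
#'   `age_start`, `age_end`, `n`, `mean_ccsurf`, `sd_ccsurf`,
#'   `mean_biomass`.
#' @export
phase_summaries <- function(records, phases) {
  stopifnot(is.data.frame(records),
            all(c("age", "ccsurf") %in% names(records)))
  phases <- if (inherits(phases, "phase_table")) phases else phase_table(phases)
  lab <- assign_phase(records$age, phases)
  real <- phases[phases$phase_class != "HIATUS", , drop = FALSE]
  rows <- lapply(seq_len(nrow(real)), function(i) {
    sel <- !is.na(lab) & lab == real$label[i]
    n <- sum(sel)
    data.frame(
      label = real$label[i], phase_class = real$phase_class[i],
      age_start = real$age_start[i], age_end = real$age_end[i], n = n,
      mean_ccsurf = if (n >= 1) mean(records$ccsurf[sel]) else NA_real_,
      sd_ccsurf = if (n >= 2) sd(records$ccsurf[sel]) else NA_real_,
      mean_biomass = if (n >= 1 && !is.null(records$biomass))
        mean(records$biomass[sel]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Logarithmic fuel-fire fit
#'
#' Least-squares fit of the coupling `ccsurf = alpha + beta * ln(biomass)`
#' between the fire proxy and the fuel-load index. The strength of the
#' coupling is reported as `b`, the Pearson correlation between CCsurf
#' and `ln(biomass)` (so `|b| <= 1`), with a two-sided t-test p-value for
#' zero correlation; the slope `beta` (um^2 g^-1 per ln-unit of biomass
#' percent) and its standard error are reported separately. An exact
#' permutation p-value is available as a cross-check.
#'
#' @param biomass fuel-load index values, percent, all `> 0`.
#' @param ccsurf fire-proxy values, um^2 per g.
#' @param n_perm if `> 0`, also compute a permutation p-value for the
#'   correlation from this many shuffles.
#' @return An object of class `log_fit`: list with `alpha`, `beta`,
#'   `se_beta`, `b` (correlation), `p_value`, `n`, and `p_perm` when
#'   requested.
#' @export
log_fit <- function(biomass, ccsurf, n_perm = 0) {
  stopifnot(length(biomass) == length(ccsurf))
  keep <- complete.cases(biomass, ccsurf)
  biomass <- biomass[keep]; ccsurf <- ccsurf[keep]
  if (length(biomass) < 3L) {
    stop("log_fit needs at least 3 (biomass, ccsurf) pairs", call. = FALSE)
  }
  if (any(biomass <= 0)) {
    stop("biomass values must be positive for the logarithmic fit",
         call. = FALSE)
  }
  lx <- log(biomass)
  if (var(lx) == 0 || var(ccsurf) == 0) {
    stop("degenerate variance: ",
         if (var(lx) == 0) "biomass is constant" else "ccsurf is constant",
         call. = FALSE)
  }
  fit <- lm(ccsurf ~ lx)
  ct <- suppressWarnings(cor.test(ccsurf, lx, method = "pearson"))
  out <- list(alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
              se_beta = unname(coef(summary(fit))[2, 2]),
              b = unname(ct$estimate), p_value = ct$p.value,
              n = length(biomass))
  if (n_perm > 0) {
    obs <- abs(out$b)
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      abs(cor(ccsurf, sample(lx))) >= obs - 1e-12
    }, logical(1)))
    out$p_perm <- (hits + 1) / (n_perm + 1)
  }
  structure(out, class = "log_fit")
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf(
    "<log_fit: ccsurf = %.4g + %.4g * ln(biomass); b = %.3f, p = %.3g, n = %d>\n",
    x$alpha, x$beta, x$b, x$p_value, x$n))
  invisible(x)
}

#' Bivariate confidence ellipse
#'
#' Normal-theory confidence ellipse for a cloud of (biomass, ccsurf)
#' points: centred at the sample mean, axes along the eigenvectors of the
#' sample covariance, squared semi-axis lengths equal to eigenvalue times
#' the chi-square quantile at `level` with 2 degrees of freedom.
#'
#' @param x,y coordinates of the points (at least 3, non-degenerate).
#' @param level confidence level (default 0.95).
#' @return Object of class `confidence_ellipse`: list with `center`,
#'   `semi_axes` (major, minor), `orientation` (radians of the major
#'   axis), `cov`, `level`, `n`.
#' @export
confidence_ellipse <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop("confidence_ellipse needs at least 3 points", call. = FALSE)
  }
  S <- cov(cbind(x, y))
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2] <= 1e-12 * max(e$values[1], 1e-300)) {
    dir <- e$vectors[, 2]
    stop(sprintf(
      "degenerate covariance: no spread along direction (%.3f, %.3f); points are collinear",
      dir[1], dir[2]), call. = FALSE)
  }
  r2 <- qchisq(level, df = 2)
  structure(
    list(center = c(mean(x), mean(y)),
         semi_axes = sqrt(e$values * r2),
         orientation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
         cov = S, level = level, n = length(x)),
    class = "confidence_ellipse")
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf(
    "<%.0f%% confidence ellipse: center (%.4g, %.4g), semi-axes %.4g x %.4g, orientation %.1f deg, n = %d>\n",
    100 * x$level, x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
    180 / pi * x$orientation, x$n))
  invisible(x)
}

#' @rdname confidence_ellipse
#' @param ellipse a `confidence_ellipse`.
#' @param px,py points to test.
#' @return `ellipse_contains()`: logical vector, `TRUE` where the point's
#'   Mahalanobis distance (under the ellipse covariance) is within the
#'   chi-square radius.
#' @export
ellipse_contains <- function(ellipse, px, py) {
  d2 <- mahalanobis(cbind(px, py), ellipse$center, ellipse$cov)
  d2 <= qchisq(ellipse$level, df = 2)
}

#' @rdname confidence_ellipse
#' @param n_points number of polygon points for plotting.
#' @return `ellipse_points()`: two-column matrix tracing the ellipse.
#' @export
ellipse_points <- function(ellipse, n_points = 181) {
  t <- seq(0, 2 * pi, length.out = n_points)
  u <- rbind(ellipse$semi_axes[1] * cos(t), ellipse$semi_axes[2] * sin(t))
  th <- ellipse$orientation
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(t(R %*% u), 2, ellipse$center, "+")
}

#' Sedimentation-rate independence check
#'
#' If CCsurf were driven by sedimentary input or charcoal dilution rather
#' than fire, it would correlate (positively or negatively) with the
#' sedimentation rate. This check computes the Pearson correlation with a
#' two-sided p-value between two aligned series; when a phase table and
#' sample ages are supplied, the same test is repeated on per-phase means
#' (the climatic-event-level control).
#'
#' @param series_a,series_b aligned numeric series (n >= 3).
#' @param ages optional sample ages (kyr cal BP), required for the
#'   phase-level test.
#' @param phases optional [phase_table()].
#' @return A list with `overall` (list `r`, `p_value`, `n`) and, when
#'   phase information is supplied, `phase_level` of the same shape.
#' @export
independence_check <- function(series_a, series_b, ages = NULL,
                               phases = NULL) {
  if (length(series_a) != length(series_b)) {
    stop("series lengths differ", call. = FALSE)
  }
  pearson <- function(a, b) {
    keep <- complete.cases(a, b)
    a <- a[keep]; b <- b[keep]
    if (length(a) < 3L) stop("need at least 3 aligned values", call. = FALSE)
    if (sd(a) == 0 || sd(b) == 0) {
      stop("constant series: correlation undefined", call. = FALSE)
    }
    ct <- cor.test(a, b, method = "pearson")
    list(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
  }
  out <- list(overall = pearson(series_a, series_b))
  if (!is.null(phases) && !is.null(ages)) {
    lab <- assign_phase(ages, phases)
    keep <- !is.na(lab)
    ma <- tapply(series_a[keep], lab[keep], mean)
    mb <- tapply(series_b[keep], lab[keep], mean)
    out$phase_level <- pearson(as.numeric(ma), as.numeric(mb))
  }
  out
}

#' Long-term fire-regime trend
#'
#' Least-squares slope of CCsurf versus age within an age window. Sign
#' convention: the slope is per kyr of age (BP scale), so a positive
#' slope means CCsurf increases with age, i.e. the fire regime decreases
#' toward the present.
#'
#' @param records data frame with columns `age` (kyr cal BP) and `ccsurf`.
#' @param age_window c(young, old) limits in kyr cal BP (inclusive).
#' @return List with `slope` (um^2 g^-1 per kyr), `se`, `p_value`, `n`
#'   and `age_window`.
#' @export
long_term_trend <- function(records, age_window) {
  stopifnot(is.data.frame(records),
            all(c("age", "ccsurf") %in% names(records)))
  assert_range(age_window, "age_window")
  sel <- records$age >= age_window[1] & records$age <= age_window[2] &
    complete.cases(records$age, records$ccsurf)
  if (sum(sel) < 3L) {
    stop(sprintf("fewer than 3 samples in the %g-%g kyr window",
                 age_window[1], age_window[2]), call. = FALSE)
  }
  fit <- lm(ccsurf ~ age, data = records[sel, ])
  sm <- coef(summary(fit))
  list(slope = unname(sm[2, 1]), se = unname(sm[2, 2]),
       p_value = unname(sm[2, 4]), n = sum(sel), age_window = age_window)
}
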