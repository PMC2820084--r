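# Piecewise-linear age-depth modelling.
#
# Deep-sea core chronologies are anchored on a small number of dated
# control points (AMS 14C dates, event correlations). Between control
# points the age-depth relation is taken as linear; ages are expressed in
# kyr cal BP (thousands of calibrated years before present, older =
# larger) and depths in cm below sea floor.

#' Build a piecewise-linear age-depth model
#'
#' Validates and sorts dated control points into a usable chronology.
#' Age must increase strictly with depth (no reversals) and depths must be
#' unique.
#'
#' @param points data frame with columns `depth` (cm), `age` (kyr cal BP)
#'   and optionally `source` (e.g. `"AMS 14C"`, `"event correlation"`).
#' @return An object of class `age_model`: the sorted control-point table.
#' @examples
#' m <- build_age_model(data.frame(depth = c(100, 200), age = c(10, 20)))
#' depth_to_age(m, 150)  # 15
#' @export
build_age_model <- function(points) {
  stopifnot(is.data.frame(points))
  if (!all(c("depth", "age") %in% names(points))) {
    stop("control points need `depth` and `age` columns", call. = FALSE)
  }
  if (nrow(points) < 2L) {
    stop("an age model needs at least 2 control points", call. = FALSE)
  }
  if (any(!is.finite(points$depth)) || any(!is.finite(points$age))) {
    stop("control points must be finite", call. = FALSE)
  }
  if (any(points$depth < 0) || any(points$age <= 0)) {
    stop("depths must be >= 0 and ages > 0", call. = FALSE)
  }
  if (is.null(points$source)) points$source <- NA_character_
  points <- points[order(points$depth), c("depth", "age", "source")]
  rownames(points) <- NULL
  if (anyDuplicated(points$depth)) {
    stop("duplicate control-point depths: ",
         paste(points$depth[duplicated(points$depth)], collapse = ", "),
         call. = FALSE)
  }
  rev <- which(diff(points$age) <= 0)
  if (length(rev)) {
    i <- rev[1]
    stop(sprintf(
      "age reversal between control points (%g cm, %g kyr) and (%g cm, %g kyr)",
      points$depth[i], points$age[i], points$depth[i + 1], points$age[i + 1]),
      call. = FALSE)
  }
  structure(points, class = c("age_model", "data.frame"))
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("<age_model: %d control points, %g-%g cm, %g-%g kyr cal BP>\n",
              nrow(x), min(x$depth), max(x$depth), min(x$age), max(x$age)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Convert depths to ages
#'
#' Linear interpolation between the bracketing control points; exact at
#' control points. Depths outside the dated span are refused unless
#' extrapolation (linear continuation of the end segments) is explicitly
#' enabled.
#'
#' @param model an [build_age_model()] result.
#' @param depth numeric vector of depths, cm.
#' @param extrapolate allow depths outside the control range
#'   (default `FALSE`).
#' @return Ages in kyr cal BP, same length as `depth`.
#' @export
depth_to_age <- function(model, depth, extrapolate = FALSE) {
  stopifnot(inherits(model, "age_model"))
  out_of_range <- depth < min(model$depth) | depth > max(model$depth)
  if (any(out_of_range) && !extrapolate) {
    stop(sprintf(
      "depth %g cm outside the dated span [%g, %g] cm (set extrapolate = TRUE to allow)",
      depth[out_of_range][1], min(model$depth), max(model$depth)),
      call. = FALSE)
  }
  inner <- approx(model$depth, model$age, xout = depth, rule = 1)$y
  if (any(out_of_range)) {
    n <- nrow(model)
    lo_slope <- (model$age[2] - model$age[1]) / (model$depth[2] - model$depth[1])
    hi_slope <- (model$age[n] - model$age[n - 1]) /
      (model$depth[n] - model$depth[n - 1])
    below <- depth < min(model$depth)
    above <- depth > max(model$depth)
    inner[below] <- model$age[1] + (depth[below] - model$depth[1]) * lo_slope
    inner[above] <- model$age[n] + (depth[above] - model$depth[n]) * hi_slope
  }
  inner
}

#' Inverse lookup: age to depth
#'
#' @param model an `age_model`.
#' @param age ages in kyr cal BP within the dated span.
#' @return Depths in cm.
#' @export
age_to_depth <- function(model, age) {
  stopifnot(inherits(model, "age_model"))
  if (any(age < min(model$age) | age > max(model$age))) {
    stop("age outside the dated span", call. = FALSE)
  }
  approx(model$age, model$depth, xout = age, rule = 1)$y
}

#' Sedimentation rates along an age model
#'
#' One rate per control interval (`delta depth / delta age`, cm per kyr);
#' optionally a per-sample rate by locating each sample depth in its
#' control interval.
#'
#' @param model an `age_model`.
#' @param depths optional sample depths (cm) for per-sample lookup.
#' @return Data frame of intervals (`depth_top`, `depth_bottom`,
#'   `age_top`, `age_bottom`, `rate_cm_per_kyr`). When `depths` is given,
#'   the per-sample rates are attached as attribute `"sample_rates"`.
#' @export
sedimentation_rate <- function(model, depths = NULL) {
  stopifnot(inherits(model, "age_model"))
  n <- nrow(model)
  out <- data.frame(
    depth_top = model$depth[-n], depth_bottom = model$depth[-1],
    age_top = model$age[-n], age_bottom = model$age[-1],
    rate_cm_per_kyr = diff(model$depth) / diff(model$age))
  if (!is.null(depths)) {
    if (any(depths < min(model$depth) | depths > max(model$depth))) {
      stop("sample depth outside the dated span", call. = FALSE)
    }
    iv <- findInterval(depths, model$depth, rightmost.closed = TRUE)
    iv[iv == n] <- n - 1L
    attr(out, "sample_rates") <- out$rate_cm_per_kyr[iv]
  }
  out
}

#' Temporal sampling resolution
#'
#' Statistics of the successive age differences of a sampled record,
#' reported in years.
#'
#' @param ages strictly increasing ages in kyr cal BP (at least 2).
#' @return A list with `mean_yr`, `min_yr`, `max_yr` and `n_intervals`.
#' @export
sampling_resolution <- function(ages) {
  if (length(ages) < 2L) {
    stop("need at least two ages", call. = FALSE)
  }
  d <- diff(ages)
  if (any(d <= 0)) {
    stop("ages must be strictly increasing", call. = FALSE)
  }
  list(mean_yr = mean(d) * 1000, min_yr = min(d) * 1000,
       max_yr = max(d) * 1000, n_intervals = length(d))
}
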