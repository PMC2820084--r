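# Microcharcoal detection and the CCsurf proxy.
#
# Charcoal is identified in transmitted light as black, opaque and angular
# with sharp edges; the main confounder is vitrinite (unburnt, eroded
# organic matter) which is also dark but rounded and slightly less opaque.
# The detector thresholds the field, labels connected components, and
# accepts components that are dark enough (opacity screen) and angular
# enough (circularity screen). Accepted pixel counts feed the CCsurf
# concentration: total charcoal surface area per gram of dry sediment.

#' Construct a micrograph field
#'
#' A micrograph field is a rectangular 8-bit grayscale raster with a known
#' physical pixel area, the unit of image analysis.
#'
#' @param raster numeric or integer matrix of intensities in \[0, 255\]
#'   (row 1 is the top of the field).
#' @param pixel_area physical area of one pixel, in square micrometres
#'   (the `Sp` term of the CCsurf equation).
#' @param field_id optional identifier string.
#' @return An object of class `micrograph_field`: a list with elements
#'   `raster`, `pixel_area` and `field_id`.
#' @seealso [process_sample()], [generate_micrograph()]
#' @export
micrograph_field <- function(raster, pixel_area, field_id = "field") {
  if (!is.matrix(raster) || length(raster) == 0L) {
    stop("`raster` must be a non-empty matrix", call. = FALSE)
  }
  if (any(!is.finite(raster)) || min(raster) < 0 || max(raster) > 255) {
    stop("raster intensities must be finite and within [0, 255]", call. = FALSE)
  }
  assert_scalar_number(pixel_area, "pixel_area", positive = TRUE)
  structure(
    list(raster = raster, pixel_area = pixel_area,
         field_id = as.character(field_id)),
    class = "micrograph_field"
  )
}

#' @export
print.micrograph_field <- function(x, ...) {
  cat(sprintf("<micrograph_field '%s': %d x %d px, Sp = %g um^2/px>\n",
              x$field_id, nrow(x$raster), ncol(x$raster), x$pixel_area))
  invisible(x)
}

#' Per-sample measurement metadata
#'
#' The measurement constants of the microcharcoal extraction protocol that
#' convert a charcoal pixel count to a concentration: dry sediment weight
#' `W`, residue dilution `D`, filter area `Sr` and microscope-scanned area
#' `Ss`. Defaults follow the standard protocol: about 0.2 g of dried
#' sediment, a 0.1 dilution of the residue, filtration onto a 47 mm
#' diameter membrane.
#'
#' @param sample_id identifier string.
#' @param depth sample depth in the core, cm.
#' @param dry_weight_W dry sediment weight, g.
#' @param dilution_D dilution factor applied to the residue, in (0, 1].
#' @param filter_area_Sr area of the filter membrane, um^2. Default is a
#'   47 mm diameter circle.
#' @param scanned_area_Ss area scanned by the microscope, um^2; must not
#'   exceed `filter_area_Sr` (only a portion of the membrane is mounted
#'   and scanned). The default is a placeholder: the scanned fraction
#'   depends on the microscope set-up and should be measured per study.
#' @return An object of class `sample_meta` (a named list).
#' @export
sample_meta <- function(sample_id, depth,
                        dry_weight_W = 0.2,
                        dilution_D = 0.1,
                        filter_area_Sr = pi * 23500^2,
                        scanned_area_Ss = 1e8) {
  assert_scalar_number(depth, "depth")
  assert_scalar_number(dry_weight_W, "dry_weight_W", positive = TRUE)
  assert_scalar_number(dilution_D, "dilution_D", positive = TRUE)
  if (dilution_D > 1) stop("`dilution_D` must be in (0, 1]", call. = FALSE)
  assert_scalar_number(filter_area_Sr, "filter_area_Sr", positive = TRUE)
  assert_scalar_number(scanned_area_Ss, "scanned_area_Ss", positive = TRUE)
  if (scanned_area_Ss > filter_area_Sr) {
    stop("`scanned_area_Ss` cannot exceed `filter_area_Sr`: ",
         "the scanned area is a portion of the filter", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), depth = depth,
         dry_weight_W = dry_weight_W, dilution_D = dilution_D,
         filter_area_Sr = filter_area_Sr, scanned_area_Ss = scanned_area_Ss),
    class = "sample_meta"
  )
}

#' Detection configuration
#'
#' Tunable parameters of the charcoal detector. The binarization threshold
#' plays the role of the "best-fit threshold" that is normally calibrated
#' against petrographic inspection of vitrinite; here it is explicit
#' configuration (see [calibrate_threshold()] and [auto_threshold()]).
#'
#' @param binarization_threshold intensity in \[0, 255\]; pixels with
#'   intensity `<=` threshold enter the binary mask.
#' @param opacity_cutoff maximum mean intensity for a particle to count as
#'   opaque charcoal; must not exceed `binarization_threshold`.
#' @param min_particle_pixels components smaller than this are dropped as
#'   noise (default 4).
#' @param max_circularity angularity screen: particles with circularity
#'   above this are rejected as rounded (vitrinite-like). Circularity is
#'   `4*pi*area / perimeter^2` with the perimeter counted as exposed pixel
#'   edges, a convention under which a digitized square scores ~0.785 and
#'   more angular or elongated shapes score lower.
#' @param connectivity 4 or 8 (default 8), pixel adjacency used for
#'   connected components.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(binarization_threshold = 100,
                             opacity_cutoff = 50,
                             min_particle_pixels = 4,
                             max_circularity = 0.9,
                             connectivity = 8) {
  assert_scalar_number(binarization_threshold, "binarization_threshold")
  if (binarization_threshold < 0 || binarization_threshold > 255) {
    stop("`binarization_threshold` must be in [0, 255]", call. = FALSE)
  }
  assert_scalar_number(opacity_cutoff, "opacity_cutoff")
  if (opacity_cutoff > binarization_threshold) {
    stop("`opacity_cutoff` must not exceed `binarization_threshold`",
         call. = FALSE)
  }
  min_particle_pixels <- assert_count(min_particle_pixels,
                                      "min_particle_pixels", min = 1L)
  assert_scalar_number(max_circularity, "max_circularity", positive = TRUE)
  if (max_circularity > 1) {
    stop("`max_circularity` must be in (0, 1]", call. = FALSE)
  }
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  structure(
    list(binarization_threshold = binarization_threshold,
         opacity_cutoff = opacity_cutoff,
         min_particle_pixels = min_particle_pixels,
         max_circularity = max_circularity,
         connectivity = as.integer(connectivity)),
    class = "detection_config"
  )
}

#' Binarize a micrograph field
#'
#' Marks every pixel at least as dark as the binarization threshold, the
#' first step of charcoal identification ("black, opaque").
#'
#' @param field a [micrograph_field()].
#' @param config a [detection_config()], or a bare numeric threshold.
#' @return Logical matrix, `TRUE` exactly where
#'   `intensity <= binarization_threshold`.
#' @export
binarize <- function(field, config = detection_config()) {
  stopifnot(inherits(field, "micrograph_field"))
  threshold <- if (is.numeric(config)) config else config$binarization_threshold
  if (threshold < 0 || threshold > 255) {
    stop("threshold must be within [0, 255]", call. = FALSE)
  }
  field$raster <= threshold
}

# Connected-component labelling under 4- or 8-connectivity.
# Foreground pixels become graph vertices; adjacent foreground pixels are
# joined and components extracted. Labels are renumbered in column-major
# first-appearance order so results are deterministic.
label_mask <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  id <- integer(nr * nc)
  id[idx] <- seq_len(n)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  ev <- integer(0)
  for (o in offs) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= nc
    nidx <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nidx]
    if (any(hit)) {
      ev <- c(ev, rbind(id[idx[ok][hit]], id[nidx[hit]]))
    }
  }
  g <- igraph::make_graph(ev, n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber in order of first appearance along the pixel scan
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  lab[idx] <- relab[memb]
  lab
}

# Exposed-edge perimeter per label: the number of unit pixel edges between
# a component pixel and background (or the image border). Exact and
# convention-stable; a digitized square of side s has perimeter 4*s.
perimeter_by_label <- function(lab) {
  k <- max(lab)
  if (k == 0L) return(numeric(0))
  nr <- nrow(lab); nc <- ncol(lab)
  zc <- matrix(0L, nr, 1L); zr <- matrix(0L, 1L, nc)
  count_exposed <- function(nb) {
    d <- lab[lab > 0L & lab != nb]
    tabulate(d, nbins = k)
  }
  count_exposed(cbind(zc, lab[, -nc, drop = FALSE])) +
    count_exposed(cbind(lab[, -1L, drop = FALSE], zc)) +
    count_exposed(rbind(zr, lab[-nr, , drop = FALSE])) +
    count_exposed(rbind(lab[-1L, , drop = FALSE], zr))
}

# Points (px, py) inside (or on, within tol) the convex polygon hv
# (two-column vertex matrix in hull order, either orientation).
points_in_convex <- function(px, py, hv, tol = 1e-9) {
  n <- nrow(hv)
  jj <- c(seq_len(n)[-1L], 1L)
  # signed polygon area fixes the orientation of the half-plane tests
  area2 <- sum(hv[, 1] * hv[jj, 2] - hv[jj, 1] * hv[, 2])
  s <- if (area2 >= 0) 1 else -1
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- jj[i]
    cr <- (hv[j, 1] - hv[i, 1]) * (py - hv[i, 2]) -
          (hv[j, 2] - hv[i, 2]) * (px - hv[i, 1])
    inside <- inside & (s * cr >= -tol)
  }
  inside
}

# Number of lattice pixels whose centres fall inside (or on) the convex
# hull of the component's pixel centres. Degenerate (collinear) components
# return the pixel count itself, i.e. solidity 1.
hull_pixel_count <- function(r, c) {
  pts <- unique(cbind(r, c))
  if (nrow(pts) < 3L) return(length(r))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) return(length(r))
  hv <- pts[h, , drop = FALSE]
  jj <- c(seq_len(nrow(hv))[-1L], 1L)
  if (abs(sum(hv[, 1] * hv[jj, 2] - hv[jj, 1] * hv[, 2])) < 1e-9) {
    return(length(r))
  }
  grid <- expand.grid(r = min(r):max(r), c = min(c):max(c))
  sum(points_in_convex(grid$r, grid$c, hv))
}

#' Label particles in a binary mask
#'
#' Extracts connected components from a binarized field and computes the
#' per-particle measurements used downstream: pixel count, physical area,
#' mean intensity, circularity and solidity. Components smaller than
#' `min_particle_pixels` are dropped. Particles touching the field edge
#' are kept (no border exclusion).
#'
#' @param mask logical matrix from [binarize()].
#' @param config a [detection_config()].
#' @param field the [micrograph_field()] the mask came from; required for
#'   mean intensities and physical areas. If omitted, `mean_intensity` is
#'   `NA` and areas are in pixels (`pixel_area = 1`).
#' @return A data frame of class `particle_detections`, one row per
#'   particle: `particle_id`, `pixel_count`, `area` (um^2),
#'   `mean_intensity`, `perimeter` (pixel edge units), `circularity`,
#'   `solidity`, and bounding box columns `rmin`, `rmax`, `cmin`, `cmax`.
#'   The integer label raster is attached as attribute `"labels"`.
#' @export
label_particles <- function(mask, config = detection_config(), field = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!is.null(field)) {
    stopifnot(inherits(field, "micrograph_field"))
    if (!identical(dim(mask), dim(field$raster))) {
      stop("mask and field dimensions differ", call. = FALSE)
    }
  }
  lab <- label_mask(mask, config$connectivity)
  if (max(lab) > 0L && config$min_particle_pixels > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= config$min_particle_pixels)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  k <- max(lab)
  sp <- if (is.null(field)) 1 else field$pixel_area
  if (k == 0L) {
    out <- data.frame(particle_id = integer(0), pixel_count = integer(0),
                      area = numeric(0), mean_intensity = numeric(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      solidity = numeric(0), rmin = integer(0),
                      rmax = integer(0), cmin = integer(0), cmax = integer(0))
    attr(out, "labels") <- lab
    class(out) <- c("particle_detections", "data.frame")
    return(out)
  }
  idx <- which(lab > 0L)
  labv <- lab[idx]
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  npx <- tabulate(labv, nbins = k)
  per <- perimeter_by_label(lab)
  mean_int <- if (is.null(field)) rep(NA_real_, k) else {
    as.numeric(tapply(field$raster[idx], labv, mean))
  }
  solidity <- vapply(seq_len(k), function(i) {
    sel <- labv == i
    npx[i] / hull_pixel_count(rr[sel], cc[sel])
  }, numeric(1))
  out <- data.frame(
    particle_id = seq_len(k),
    pixel_count = npx,
    area = npx * sp,
    mean_intensity = mean_int,
    perimeter = per,
    circularity = 4 * pi * npx / per^2,
    solidity = solidity,
    rmin = as.integer(tapply(rr, labv, min)),
    rmax = as.integer(tapply(rr, labv, max)),
    cmin = as.integer(tapply(cc, labv, min)),
    cmax = as.integer(tapply(cc, labv, max))
  )
  attr(out, "labels") <- lab
  class(out) <- c("particle_detections", "data.frame")
  out
}

#' Classify detected particles as charcoal or not
#'
#' A particle is accepted as charcoal when it passes both screens:
#' opaque (`mean_intensity <= opacity_cutoff`) and angular
#' (`circularity <= max_circularity`). Rounded semi-opaque vitrinite
#' fails the opacity screen; both metric values are retained per particle
#' so rejection decisions are auditable.
#'
#' @param detections a `particle_detections` data frame from
#'   [label_particles()] (with non-`NA` mean intensities).
#' @param config a [detection_config()].
#' @return The detections with logical columns `opaque`, `angular` and
#'   `accepted` appended.
#' @export
classify_particles <- function(detections, config = detection_config()) {
  stopifnot(is.data.frame(detections))
  if (nrow(detections) > 0 && anyNA(detections$mean_intensity)) {
    stop("mean_intensity is NA: label particles with the field supplied",
         call. = FALSE)
  }
  detections$opaque <- detections$mean_intensity <= config$opacity_cutoff
  detections$angular <- detections$circularity <= config$max_circularity
  detections$accepted <- detections$opaque & detections$angular
  detections
}

#' @rdname classify_particles
#' @param detection a single detection (one-row data frame or named list
#'   with `mean_intensity` and `circularity`).
#' @return `classify_particle()` returns a single logical flag.
#' @export
classify_particle <- function(detection, config = detection_config()) {
  isTRUE(detection$mean_intensity <= config$opacity_cutoff &&
         detection$circularity <= config$max_circularity)
}

#' Count charcoal pixels
#'
#' The `P` of the CCsurf equation: the total number of pixels belonging to
#' accepted charcoal particles.
#'
#' @param detections classified detections from [classify_particles()].
#' @return Integer pixel count.
#' @export
count_charcoal_pixels <- function(detections) {
  stopifnot(is.data.frame(detections))
  if (nrow(detections) == 0L) return(0L)
  if (is.null(detections$accepted)) {
    stop("detections are not classified: run classify_particles() first",
         call. = FALSE)
  }
  as.integer(sum(detections$pixel_count[detections$accepted]))
}

#' Microcharcoal surface-area concentration (CCsurf)
#'
#' Converts a charcoal pixel count to the concentration of microcharcoal
#' surface area per gram of dry sediment:
#' \deqn{CC_{surf} = \frac{P \, S_p \, S_r}{D \, W \, S_s}}
#' where `P` is the number of pixels identified as charcoal, `Sp` the
#' surface of one pixel, `Sr` the filter area, `D` the dilution factor,
#' `W` the dry sediment weight and `Ss` the area scanned by the
#' microscope. Surface area is used instead of particle counts because
#' taphonomic fragmentation inflates counts but conserves area.
#'
#' @param P charcoal pixel count (vectorized), `>= 0`.
#' @param Sp pixel area, um^2.
#' @param Sr filter area, um^2.
#' @param D dilution factor in (0, 1].
#' @param W dry sediment weight, g.
#' @param Ss scanned area, um^2.
#' @return CCsurf in um^2 per gram, same length as `P`.
#' @examples
#' compute_ccsurf(P = 1000, Sp = 0.25, Sr = 1.735e9,
#'                D = 0.1, W = 0.2, Ss = 1e8)  # 216875
#' @export
compute_ccsurf <- function(P, Sp, Sr, D, W, Ss) {
  if (any(!is.finite(P)) || any(P < 0)) {
    stop("`P` must be a non-negative pixel count", call. = FALSE)
  }
  assert_scalar_number(Sp, "Sp", positive = TRUE)
  assert_scalar_number(Sr, "Sr", positive = TRUE)
  assert_scalar_number(D, "D", positive = TRUE)
  if (D > 1) stop("`D` must be in (0, 1]", call. = FALSE)
  assert_scalar_number(W, "W", positive = TRUE)
  assert_scalar_number(Ss, "Ss", positive = TRUE)
  (P * Sp * Sr) / (D * W * Ss)
}

#' Quantify one sample: field to CCsurf record
#'
#' Runs the full imaging chain on one micrograph field: binarize, label,
#' classify, count charcoal pixels, and convert to CCsurf using the
#' sample's measurement metadata. Per-particle decisions are retained for
#' audit.
#'
#' @param field a [micrograph_field()].
#' @param meta a [sample_meta()].
#' @param config a [detection_config()].
#' @return A list of class `ccsurf_result` with elements `record` (one-row
#'   data frame: `sample_id`, `depth`, `age` (`NA` until a chronology is
#'   applied), `charcoal_pixels_P`, `ccsurf`) and `detections` (the
#'   classified particle table).
#' @export
process_sample <- function(field, meta, config = detection_config()) {
  stopifnot(inherits(field, "micrograph_field"), inherits(meta, "sample_meta"))
  mask <- binarize(field, config)
  det <- label_particles(mask, config, field = field)
  det <- classify_particles(det, config)
  P <- count_charcoal_pixels(det)
  cc <- compute_ccsurf(P, Sp = field$pixel_area,
                       Sr = meta$filter_area_Sr, D = meta$dilution_D,
                       W = meta$dry_weight_W, Ss = meta$scanned_area_Ss)
  record <- data.frame(sample_id = meta$sample_id, depth = meta$depth,
                       age = NA_real_, charcoal_pixels_P = P, ccsurf = cc)
  structure(list(record = record, detections = det), class = "ccsurf_result")
}

#' @export
print.ccsurf_result <- function(x, ...) {
  r <- x$record
  cat(sprintf(
    "<ccsurf_result '%s': P = %d px over %d accepted / %d detected particles, CCsurf = %.4g um^2/g>\n",
    r$sample_id, r$charcoal_pixels_P, sum(x$detections$accepted),
    nrow(x$detections), r$ccsurf))
  invisible(x)
}

#' Automatic threshold initializer (Otsu)
#'
#' Suggests a binarization threshold by maximizing the between-class
#' intensity variance of the field's 256-bin histogram. Useful as a
#' starting point when no petrographic calibration material is available;
#' the returned value should still be reviewed against labelled fixtures
#' (see [calibrate_threshold()]).
#'
#' @param field a [micrograph_field()].
#' @return Integer threshold in \[0, 254\]; pixels `<=` threshold are
#'   foreground under [binarize()].
#' @export
auto_threshold <- function(field) {
  stopifnot(inherits(field, "micrograph_field"))
  h <- tabulate(as.integer(field$raster) + 1L, nbins = 256L)
  p <- h / sum(h)
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  # threshold t: classes {<= t} vs {> t}
  as.integer(which.max(between[1:255]) - 1L)
}

#' Sweep binarization thresholds against labelled ground truth
#'
#' Calibration helper replacing the petrographic best-fit threshold
#' procedure when labelled material is available: for each candidate
#' threshold, runs the detector on every field and compares the recovered
#' charcoal pixel count against ground truth.
#'
#' @param fields list of [micrograph_field()] objects.
#' @param truth_pixels integer vector, true charcoal pixel count per field.
#' @param thresholds candidate thresholds (default `seq(10, 250, by = 10)`).
#' @param config base [detection_config()]; its threshold is overridden at
#'   each sweep point (the opacity cutoff is capped at the threshold).
#' @return Data frame with `threshold`, `total_abs_error` (summed absolute
#'   pixel-count error) and `rel_error`; the attribute `"best"` holds the
#'   threshold with minimal total error.
#' @export
calibrate_threshold <- function(fields, truth_pixels,
                                thresholds = seq(10, 250, by = 10),
                                config = detection_config()) {
  stopifnot(length(fields) == length(truth_pixels), length(fields) > 0)
  err <- vapply(thresholds, function(th) {
    cfg <- detection_config(
      binarization_threshold = th,
      opacity_cutoff = min(config$opacity_cutoff, th),
      min_particle_pixels = config$min_particle_pixels,
      max_circularity = config$max_circularity,
      connectivity = config$connectivity)
    got <- vapply(fields, function(f) {
      det <- classify_particles(label_particles(binarize(f, cfg), cfg, f), cfg)
      as.numeric(count_charcoal_pixels(det))
    }, numeric(1))
    sum(abs(got - truth_pixels))
  }, numeric(1))
  out <- data.frame(threshold = thresholds, total_abs_error = err,
                    rel_error = err / max(sum(truth_pixels), 1))
  attr(out, "best") <- thresholds[which.min(err)]
  out
}
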