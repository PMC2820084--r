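# Synthetic transmitted-light micrographs with known particle ground
# truth. Three particle classes reproduce the classification problem:
#   charcoal  - dark (opaque), angular star-shaped polygons;
#   vitrinite - dark-but-lighter rounded ellipses (the classic false
#               positive: unburnt organic particles eroded from
#               sedimentary basins);
#   debris    - low-contrast translucent blobs near background level.
# Particles are placed without overlap; Gaussian background noise is added
# last. All output is a pure function of the parameter object (seed
# included), so detector tests have exact ground truth.

#' Parameters for the synthetic micrograph generator
#'
#' @param field_shape integer c(rows, cols) of the field in pixels.
#' @param pixel_area physical pixel area Sp, um^2.
#' @param background_level background intensity in \[0, 255\].
#' @param background_noise_sd standard deviation of additive Gaussian
#'   intensity noise (0 disables noise).
#' @param n_charcoal,n_vitrinite,n_debris particle counts per class.
#' @param charcoal_level,vitrinite_level,debris_level rendered mean
#'   intensities; must satisfy
#'   `charcoal_level < vitrinite_level < debris_level <= background_level`.
#' @param charcoal_size_range particle area interval, um^2, for charcoal.
#' @param vitrinite_size_range particle area interval, um^2, for
#'   vitrinite and debris (defaults to `charcoal_size_range`).
#' @param angularity_vertices integer range of polygon vertex counts for
#'   charcoal (default 3 to 8: triangles to octagons, always angular).
#' @param min_separation minimum pixel gap enforced between particles so
#'   that detections stay well separated (default 3).
#' @param seed integer master seed for this field.
#' @return An object of class `imaging_sim_params`.
#' @export
imaging_sim_params <- function(field_shape = c(256L, 256L),
                               pixel_area = 0.25,
                               background_level = 200,
                               background_noise_sd = 5,
                               n_charcoal = 10,
                               n_vitrinite = 5,
                               n_debris = 5,
                               charcoal_level = 15,
                               vitrinite_level = 90,
                               debris_level = 170,
                               charcoal_size_range = c(10, 150),
                               vitrinite_size_range = charcoal_size_range,
                               angularity_vertices = c(3L, 8L),
                               min_separation = 3L,
                               seed = 1L) {
  stopifnot(length(field_shape) == 2L, all(field_shape >= 8))
  assert_scalar_number(pixel_area, "pixel_area", positive = TRUE)
  for (nm in c("background_level", "charcoal_level", "vitrinite_level",
               "debris_level")) {
    v <- get(nm)
    assert_scalar_number(v, nm)
    if (v < 0 || v > 255) stop(sprintf("`%s` must be in [0, 255]", nm),
                               call. = FALSE)
  }
  if (!(charcoal_level < vitrinite_level &&
        vitrinite_level < debris_level &&
        debris_level <= background_level)) {
    stop("intensity levels must satisfy charcoal < vitrinite < debris <= background",
         call. = FALSE)
  }
  assert_scalar_number(background_noise_sd, "background_noise_sd")
  if (background_noise_sd < 0) stop("`background_noise_sd` must be >= 0",
                                    call. = FALSE)
  n_charcoal <- assert_count(n_charcoal, "n_charcoal")
  n_vitrinite <- assert_count(n_vitrinite, "n_vitrinite")
  n_debris <- assert_count(n_debris, "n_debris")
  assert_range(charcoal_size_range, "charcoal_size_range")
  assert_range(vitrinite_size_range, "vitrinite_size_range")
  stopifnot(length(angularity_vertices) == 2L, angularity_vertices[1] >= 3,
            angularity_vertices[2] >= angularity_vertices[1])
  min_separation <- assert_count(min_separation, "min_separation", min = 1L)
  structure(
    list(field_shape = as.integer(field_shape), pixel_area = pixel_area,
         background_level = background_level,
         background_noise_sd = background_noise_sd,
         n_charcoal = n_charcoal, n_vitrinite = n_vitrinite,
         n_debris = n_debris, charcoal_level = charcoal_level,
         vitrinite_level = vitrinite_level, debris_level = debris_level,
         charcoal_size_range = charcoal_size_range,
         vitrinite_size_range = vitrinite_size_range,
         angularity_vertices = as.integer(angularity_vertices),
         min_separation = min_separation, seed = as.integer(seed)),
    class = "imaging_sim_params"
  )
}

# Rasterize a random star-shaped polygon (angular, sharp-edged) with
# n_vertices vertices and roughly target_px pixels. Returns a logical
# matrix mask (local bounding box). A physical particle is a single
# connected blob, so only the largest 8-connected component of the
# rasterization is kept; near-degenerate slivers are re-drawn.
rasterize_polygon <- function(target_px, n_vertices) {
  for (try in 1:50) {
    r_out <- sqrt(target_px / (0.6 * pi))
    ang <- sort(runif(n_vertices, 0, 2 * pi))
    rad <- runif(n_vertices, 0.45 * r_out, r_out)
    vx <- rad * cos(ang)
    vy <- rad * sin(ang)
    ext <- ceiling(max(abs(c(vx, vy)))) + 1L
    g <- expand.grid(x = -ext:ext, y = -ext:ext)
    inside <- point_in_polygon(g$x, g$y, vx, vy)
    if (sum(inside) < 4L) next
    m <- matrix(inside, nrow = 2L * ext + 1L)
    lab <- label_mask(m, 8L)
    sizes <- tabulate(lab[lab > 0L])
    m <- lab == which.max(sizes)
    if (sum(m) >= 4L) {
      return(trim_mask(m))
    }
  }
  stop("failed to rasterize a polygon of the requested size", call. = FALSE)
}

# Even-odd (ray casting) point-in-polygon test; handles non-convex
# star-shaped outlines. Vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

rasterize_ellipse <- function(target_px, elongation) {
  r <- sqrt(target_px / pi)
  a <- r * elongation
  b <- r / elongation
  th <- runif(1, 0, pi)
  ext <- ceiling(max(a, b)) + 1L
  g <- expand.grid(x = -ext:ext, y = -ext:ext)
  xr <- g$x * cos(th) + g$y * sin(th)
  yr <- -g$x * sin(th) + g$y * cos(th)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  if (sum(inside) < 4L) {
    # tiny ellipse: fall back to a 2x2 block
    return(matrix(TRUE, 2L, 2L))
  }
  m <- matrix(inside, nrow = 2L * ext + 1L)
  lab <- label_mask(m, 8L)
  sizes <- tabulate(lab[lab > 0L])
  trim_mask(lab == which.max(sizes))
}

trim_mask <- function(m) {
  rs <- range(which(rowSums(m) > 0))
  cs <- range(which(colSums(m) > 0))
  m[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE]
}

# Dilate a logical mask by `by` pixels (Chebyshev ball) inside a frame of
# the given dimensions at offset (r0, c0). Used to enforce separation.
stamp_dilated <- function(frame, m, r0, c0, by) {
  nr <- nrow(frame); nc <- ncol(frame)
  for (dr in -by:by) for (dc in -by:by) {
    r1 <- r0 + dr; c1 <- c0 + dc
    rlo <- max(1L, r1); rhi <- min(nr, r1 + nrow(m) - 1L)
    clo <- max(1L, c1); chi <- min(nc, c1 + ncol(m) - 1L)
    if (rlo > rhi || clo > chi) next
    rr <- rlo:rhi; cc <- clo:chi
    mr <- rr - r1 + 1L; mc <- cc - c1 + 1L
    frame[rr, cc] <- frame[rr, cc] | m[mr, mc, drop = FALSE]
  }
  frame
}

#' Generate a synthetic micrograph with ground truth
#'
#' Renders the requested number of charcoal (angular polygons at the
#' charcoal intensity level), vitrinite (rounded ellipses) and debris
#' (low-contrast blobs) particles on a uniform background, without
#' overlap, then adds Gaussian background noise and clips to \[0, 255\].
#' Identical parameters (including the seed) give bit-identical output.
#'
#' @param params an [imaging_sim_params()] object.
#' @return A list of class `synthetic_micrograph`:
#'   * `field`: a [micrograph_field()];
#'   * `particles`: ground-truth data frame (`particle_id`, `class_label`,
#'     `pixel_count`, `true_area` um^2, bounding box);
#'   * `labels`: integer raster of ground-truth particle ids (0 =
#'     background).
#' @section Errors:
#' If a particle cannot be placed without overlap after 200 attempts the
#' field is considered too crowded and an error is raised; particles are
#' never silently overlapped.
#' @export
generate_micrograph <- function(params) {
  stopifnot(inherits(params, "imaging_sim_params"))
  with_seed(params$seed, {
    nr <- params$field_shape[1]; nc <- params$field_shape[2]
    raster <- matrix(params$background_level, nr, nc)
    labels <- matrix(0L, nr, nc)
    forbidden <- matrix(FALSE, nr, nc)
    classes <- rep(c("charcoal", "vitrinite", "debris"),
                   times = c(params$n_charcoal, params$n_vitrinite,
                             params$n_debris))
    gt <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      cls <- classes[i]
      placed <- FALSE
      for (attempt in 1:200) {
        m <- switch(cls,
          charcoal = {
            a_um2 <- runif(1, params$charcoal_size_range[1],
                           params$charcoal_size_range[2])
            nv <- sample(params$angularity_vertices[1]:
                           params$angularity_vertices[2], 1L)
            rasterize_polygon(a_um2 / params$pixel_area, nv)
          },
          {
            a_um2 <- runif(1, params$vitrinite_size_range[1],
                           params$vitrinite_size_range[2])
            rasterize_ellipse(a_um2 / params$pixel_area, runif(1, 1.1, 1.8))
          })
        if (nrow(m) > nr - 2L || ncol(m) > nc - 2L) next
        r0 <- sample.int(nr - nrow(m) + 1L, 1L)
        c0 <- sample.int(nc - ncol(m) + 1L, 1L)
        sub <- forbidden[r0:(r0 + nrow(m) - 1L), c0:(c0 + ncol(m) - 1L)]
        if (any(sub & m)) next
        level <- switch(cls, charcoal = params$charcoal_level,
                        vitrinite = params$vitrinite_level,
                        debris = params$debris_level)
        tgt_r <- r0:(r0 + nrow(m) - 1L); tgt_c <- c0:(c0 + ncol(m) - 1L)
        block <- raster[tgt_r, tgt_c]; block[m] <- level
        raster[tgt_r, tgt_c] <- block
        lblock <- labels[tgt_r, tgt_c]; lblock[m] <- i
        labels[tgt_r, tgt_c] <- lblock
        forbidden <- stamp_dilated(forbidden, m, r0, c0,
                                   params$min_separation)
        gt[[i]] <- data.frame(
          particle_id = i, class_label = cls, pixel_count = sum(m),
          true_area = sum(m) * params$pixel_area,
          rmin = r0, rmax = r0 + nrow(m) - 1L,
          cmin = c0, cmax = c0 + ncol(m) - 1L)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(
          "could not place %s particle %d of %d without overlap: field too crowded",
          cls, i, length(classes)), call. = FALSE)
      }
    }
    if (params$background_noise_sd > 0) {
      raster <- raster + rnorm(length(raster), 0, params$background_noise_sd)
    }
    raster <- matrix(pmin(255, pmax(0, round(raster))), nr, nc)
    particles <- if (length(gt)) do.call(rbind, gt) else
      data.frame(particle_id = integer(0), class_label = character(0),
                 pixel_count = integer(0), true_area = numeric(0),
                 rmin = integer(0), rmax = integer(0), cmin = integer(0),
                 cmax = integer(0))
    structure(
      list(field = micrograph_field(raster, params$pixel_area,
                                    field_id = sprintf("sim-%d", params$seed)),
           particles = particles, labels = labels),
      class = "synthetic_micrograph")
  })
}

#' @export
print.synthetic_micrograph <- function(x, ...) {
  tb <- table(x$particles$class_label)
  cat(sprintf("<synthetic_micrograph %d x %d px: %s>\n",
              nrow(x$field$raster), ncol(x$field$raster),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Read and write micrograph rasters
#'
#' 8-bit grayscale I/O via PNG or TIFF, chosen by file extension.
#' Intensities are stored as `value/255` in the file and restored to the
#' \[0, 255\] integer scale on read.
#'
#' @param field a [micrograph_field()].
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return `write_micrograph()` returns `path` invisibly;
#'   `read_micrograph()` returns a [micrograph_field()].
#' @export
write_micrograph <- function(field, path) {
  stopifnot(inherits(field, "micrograph_field"))
  ext <- tolower(tools::file_ext(path))
  img <- field$raster / 255
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_micrograph
#' @param pixel_area physical pixel area Sp, um^2 (not stored in the image
#'   file, so it must be supplied).
#' @param field_id identifier; defaults to the file name.
#' @export
read_micrograph <- function(path, pixel_area,
                            field_id = tools::file_path_sans_ext(basename(path))) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image extension: ", ext, call. = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  micrograph_field(round(img * 255), pixel_area, field_id = field_id)
}
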