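#' Imaging configuration for synthetic microscopy
#'
#' Rendering and noise parameters shared by the synthetic generators. Images
#' are grayscale matrices in `[0, 1]` (written as 16-bit TIFF), indexed
#' `[row = y + 1, col = x + 1]` with 0-based pixel coordinates, x right and
#' y down, pixel centers at integer coordinates.
#'
#' Grey levels mimic bright-field droplet micrographs: mid-grey oil, bright
#' droplet interior, darker rim, darker rod crystals.
#'
#' @param pixel_size_um Pixel size, um per px (> 0).
#' @param image_size Image size in px as `c(width, height)`.
#' @param background_level Oil background grey level.
#' @param interior_level,rim_level,crystal_level Droplet interior, rim and
#'   crystal grey levels.
#' @param rim_width_px Rim annulus thickness, px.
#' @param noise_sd Additive Gaussian noise SD (intensity units, >= 0).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size_um = 0.5, image_size = c(512, 512),
                           background_level = 0.35, interior_level = 0.9,
                           rim_level = 0.7, crystal_level = 0.5,
                           rim_width_px = 1.5, noise_sd = 0.01, seed = 1L) {
  stopifnot(pixel_size_um > 0, length(image_size) == 2, all(image_size >= 16),
            noise_sd >= 0)
  structure(list(pixel_size_um = pixel_size_um,
                 image_size = as.integer(image_size),
                 background_level = background_level,
                 interior_level = interior_level, rim_level = rim_level,
                 crystal_level = crystal_level, rim_width_px = rim_width_px,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "imaging_config")
}

# Block-average a supersampled matrix (ss x ss subsamples per pixel).
block_mean <- function(m, ss) {
  ny <- nrow(m) / ss
  nx <- ncol(m) / ss
  by <- kronecker(diag(ny), matrix(1 / ss, ss, 1))
  bx <- kronecker(diag(nx), matrix(1 / ss, ss, 1))
  t(by) %*% m %*% bx
}

# Render one droplet (disk + rim + rod crystals) into `img` with ss x ss
# anti-aliasing. Center/radius in 0-based px; crystals: data frame with
# center_x_px, center_y_px, half_len_px, half_wid_px, orientation_deg.
render_droplet <- function(img, cx, cy, r_px, crystals, cfg, ss = 3L) {
  x0 <- max(0L, floor(cx - r_px - 2))
  x1 <- min(ncol(img) - 1L, ceiling(cx + r_px + 2))
  y0 <- max(0L, floor(cy - r_px - 2))
  y1 <- min(nrow(img) - 1L, ceiling(cy + r_px + 2))
  xs <- rep(x0:x1, each = ss) + (rep(seq_len(ss), x1 - x0 + 1) - 0.5) / ss - 0.5
  ys <- rep(y0:y1, each = ss) + (rep(seq_len(ss), y1 - y0 + 1) - 0.5) / ss - 0.5
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  d2 <- (gx - cx)^2 + (gy - cy)^2
  inside <- d2 <= r_px^2
  val <- matrix(0, nrow(gx), ncol(gx))
  val[inside] <- cfg$rim_level
  val[d2 <= (r_px - cfg$rim_width_px)^2] <- cfg$interior_level
  if (!is.null(crystals) && nrow(crystals) > 0) {
    for (i in seq_len(nrow(crystals))) {
      th <- crystals$orientation_deg[i] * pi / 180
      rx <- (gx - crystals$center_x_px[i]) * cos(th) +
        (gy - crystals$center_y_px[i]) * sin(th)
      ry <- -(gx - crystals$center_x_px[i]) * sin(th) +
        (gy - crystals$center_y_px[i]) * cos(th)
      in_rod <- abs(rx) <= crystals$half_len_px[i] &
        abs(ry) <= crystals$half_wid_px[i]
      val[in_rod & inside] <- cfg$crystal_level
    }
  }
  # composite only the droplet's own coverage over the existing image
  val[!inside] <- 0
  cov <- block_mean(inside * 1, ss)
  blk <- block_mean(val, ss)
  old <- img[(y0:y1) + 1L, (x0:x1) + 1L]
  img[(y0:y1) + 1L, (x0:x1) + 1L] <- old * (1 - cov) + blk
  img
}

#' Generate a synthetic droplet-field micrograph with ground truth
#'
#' Emulates a micrograph of a monodisperse emulsion loaded with rod-shaped
#' microcrystals: droplet diameters are normal with the configured CV,
#' per-droplet crystal counts are Poisson with mean `lam`, crystal lengths
#' follow the supplied length model, and droplets are placed without overlap
#' by rejection sampling. The ground truth (droplet centers/diameters,
#' per-crystal dimensions and orientations) is returned alongside the
#' rendered image for benchmarking the measurement pipeline.
#'
#' @param n Number of droplets (>= 1).
#' @param mean_diameter_um Mean droplet diameter, um.
#' @param size_cv Droplet diameter CV (fraction); monodisperse generation
#'   corresponds to < 0.04.
#' @param lam Mean crystals per droplet (Poisson).
#' @param length_model List with `mean_um`, `cv` and `aspect` describing the
#'   crystal length distribution (normal, truncated at 0.5 um) and the
#'   length:width aspect.
#' @param imaging An [imaging_config()].
#' @param max_tries_per_droplet Placement retries per droplet before the
#'   field is declared too crowded.
#' @return An object of class `droplet_field`: `image` (matrix), `truth`
#'   (data frame of droplets), `truth_crystals` (data frame of crystals) and
#'   the `imaging` config.
#' @examples
#' fld <- gen_droplet_field(12, 18, lam = 0.5,
#'                          imaging = imaging_config(image_size = c(256, 256),
#'                                                   seed = 7))
#' table(fld$truth$n_crystals)
#' @export
gen_droplet_field <- function(n, mean_diameter_um, size_cv = 0.03, lam = 0.1,
                              length_model = list(mean_um = 3, cv = 0.15,
                                                  aspect = 2.7),
                              imaging = imaging_config(),
                              max_tries_per_droplet = 200) {
  stopifnot(n >= 1, mean_diameter_um > 0, size_cv >= 0, lam >= 0,
            inherits(imaging, "imaging_config"))
  set.seed(imaging$seed)
  px <- imaging$pixel_size_um
  w <- imaging$image_size[1]; h <- imaging$image_size[2]
  diam_um <- rnorm(n, mean_diameter_um, size_cv * mean_diameter_um)
  diam_um <- pmax(diam_um, 0.2 * mean_diameter_um)
  r_px <- diam_um / 2 / px

  # non-overlapping placement, droplets fully inside the frame
  cxs <- cys <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- max_tries_per_droplet * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("field too crowded: could not place ", n, " droplets without overlap")
    }
    i <- placed + 1L
    r <- r_px[i]
    if (2 * r + 4 > min(w, h)) stop("droplet larger than the image")
    cx <- runif(1, r + 2, w - 1 - r - 2)
    cy <- runif(1, r + 2, h - 1 - r - 2)
    if (placed == 0L ||
        all((cxs[1:placed] - cx)^2 + (cys[1:placed] - cy)^2 >
            (r_px[1:placed] + r + 2)^2)) {
      cxs[i] <- cx; cys[i] <- cy; placed <- i
    }
  }

  counts <- stats::rpois(n, lam)
  img <- matrix(imaging$background_level, h, w)
  crys_list <- vector("list", n)
  for (i in seq_len(n)) {
    k <- counts[i]
    crys <- NULL
    if (k > 0) {
      len_um <- pmax(rnorm(k, length_model$mean_um,
                           length_model$cv * length_model$mean_um), 0.5)
      # confine the rod to the droplet interior
      r_int <- r_px[i] - imaging$rim_width_px - 1
      len_um <- pmin(len_um, 2 * r_int * px * 0.9)
      wid_um <- len_um / length_model$aspect
      hl <- len_um / 2 / px; hw <- wid_um / 2 / px
      hd <- sqrt(hl^2 + hw^2)
      rmax <- pmax(r_int - hd, 0)
      # place rods disjointly where possible (bounding-circle rejection)
      ccx <- ccy <- numeric(k)
      for (j in seq_len(k)) {
        for (try in seq_len(30)) {
          rr <- rmax[j] * sqrt(runif(1))
          ang <- runif(1, 0, 2 * pi)
          xj <- cxs[i] + rr * cos(ang); yj <- cys[i] + rr * sin(ang)
          if (j == 1 || all((ccx[1:(j - 1)] - xj)^2 + (ccy[1:(j - 1)] - yj)^2 >
                            (hd[1:(j - 1)] + hd[j] + 1)^2)) break
        }
        ccx[j] <- xj; ccy[j] <- yj
      }
      crys <- data.frame(droplet_id = i, crystal_id = seq_len(k),
                         center_x_px = ccx,
                         center_y_px = ccy,
                         length_um = len_um, width_um = wid_um,
                         orientation_deg = runif(k, 0, 180),
                         half_len_px = hl, half_wid_px = hw)
    }
    crys_list[[i]] <- crys
    img <- render_droplet(img, cxs[i], cys[i], r_px[i], crys, imaging)
  }
  if (imaging$noise_sd > 0) {
    img <- img + matrix(rnorm(h * w, 0, imaging$noise_sd), h, w)
  }
  img <- pmin(pmax(img, 0), 1)

  truth <- data.frame(droplet_id = seq_len(n), center_x_px = cxs,
                      center_y_px = cys, diameter_um = diam_um,
                      n_crystals = counts)
  crystals <- do.call(rbind, crys_list[!vapply(crys_list, is.null, logical(1))])
  if (is.null(crystals)) {
    crystals <- data.frame(droplet_id = integer(0), crystal_id = integer(0),
                           center_x_px = numeric(0), center_y_px = numeric(0),
                           length_um = numeric(0), width_um = numeric(0),
                           orientation_deg = numeric(0))
  } else {
    crystals$half_len_px <- NULL
    crystals$half_wid_px <- NULL
    rownames(crystals) <- NULL
  }
  structure(list(image = img, truth = truth, truth_crystals = crystals,
                 imaging = imaging),
            class = "droplet_field")
}

#' @export
print.droplet_field <- function(x, ...) {
  cat(sprintf("Synthetic droplet field: %d droplets, %d crystals, %d x %d px (%.3g um/px)\n",
              nrow(x$truth), nrow(x$truth_crystals),
              x$imaging$image_size[1], x$imaging$image_size[2],
              x$imaging$pixel_size_um))
  invisible(x)
}

#' Render a mixing simulation as a synthetic image sequence
#'
#' Maps the stored concentration fields of a [run_mixing_sim()] result to
#' pixel intensities (the dye absorbs: higher concentration renders darker,
#' an affine map), adds optional Gaussian noise, and records the noise-free
#' intensity-CV series and its threshold crossing as ground truth. One
#' simulation cell renders as one pixel.
#'
#' @param sim A `mixing_sim` run with `store_fields = TRUE`.
#' @param imaging An [imaging_config()]; `background_level` fills the oil
#'   outside the droplet, `interior_level` is the dye-free intensity and
#'   `crystal_level` the fully dyed intensity.
#' @return An object of class `mixing_frames`: `frames` (list of matrices),
#'   `mask`, `times_ms`, `truth` (noise-free CV series and mixing time) and
#'   the `imaging` config.
#' @export
gen_mixing_frames <- function(sim, imaging = imaging_config(noise_sd = 0)) {
  stopifnot(inherits(sim, "mixing_sim"))
  if (is.null(sim$fields) || length(sim$fields$conc) == 0) {
    stop("simulation was run without store_fields = TRUE")
  }
  set.seed(imaging$seed)
  mask <- sim$mask
  hi <- imaging$interior_level
  lo <- imaging$crystal_level
  truth_cv <- numeric(length(sim$fields$conc))
  frames <- vector("list", length(sim$fields$conc))
  for (i in seq_along(frames)) {
    conc <- sim$fields$conc[[i]]
    f <- matrix(imaging$background_level, nrow(conc), ncol(conc))
    f[mask] <- hi - (hi - lo) * conc[mask]
    truth_cv[i] <- pixel_cv(f, mask)
    if (imaging$noise_sd > 0) {
      f <- f + matrix(rnorm(length(f), 0, imaging$noise_sd), nrow(f))
      f <- pmin(pmax(f, 0), 1)
    }
    frames[[i]] <- f
  }
  thr <- sim$config$threshold
  structure(list(frames = frames, mask = mask, times_ms = sim$fields$times_ms,
                 truth = list(cv = truth_cv,
                              mixing_time_ms = compute_mixing_time(
                                sim$fields$times_ms, truth_cv, thr),
                              threshold = thr),
                 imaging = imaging),
            class = "mixing_frames")
}

#' Generate a synthetic exponential CV trace
#'
#' Analyzer unit-test fixture: an exponentially homogenizing CV series
#' `CV(t) = cv0 * exp(-t / tau)` with optional Gaussian noise. The analytic
#' threshold crossing is `tau * log(cv0 / threshold)` (0 when the trace
#' starts at or below the threshold), returned as `true_mixing_time_ms`.
#'
#' @param cv0 Initial CV.
#' @param tau_ms Homogenization time constant, ms (> 0).
#' @param frame_interval_ms Sampling interval, ms.
#' @param n_frames Number of samples.
#' @param noise_sd SD of additive noise on the CV (>= 0).
#' @param seed Optional integer seed.
#' @param threshold Mixing threshold.
#' @return A [cv_trace()] with an extra element `true_mixing_time_ms`.
#' @export
gen_cv_trace <- function(cv0, tau_ms, frame_interval_ms, n_frames,
                         noise_sd = 0, seed = NULL, threshold = 0.05) {
  stopifnot(cv0 >= 0, tau_ms > 0, frame_interval_ms > 0, n_frames >= 1,
            noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  t_ms <- (seq_len(n_frames) - 1) * frame_interval_ms
  cv <- cv0 * exp(-t_ms / tau_ms)
  if (noise_sd > 0) cv <- pmax(cv + rnorm(n_frames, 0, noise_sd), 0)
  tr <- cv_trace(t_ms, cv, threshold = threshold)
  tr$true_mixing_time_ms <- if (threshold >= cv0) 0 else tau_ms * log(cv0 / threshold)
  tr
}
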