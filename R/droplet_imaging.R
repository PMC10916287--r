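#' Detect and size droplets in a grayscale micrograph
#'
#' Unsupervised, parameter-driven droplet segmentation: global threshold
#' (Otsu by default), hole filling (crystals and interior texture), a
#' distance-transform watershed to split touching droplets, then a
#' circularity filter. Diameter is the equivalent-area circle diameter in
#' micrometres. Circularity is moment-based: equivalent-area diameter over
#' the moment major-axis length (1 for a disk), robust on pixelated rims.
#'
#' @param image Numeric matrix in `[0, 1]`, indexed `[y + 1, x + 1]` (see
#'   [imaging_config()] for the coordinate convention).
#' @param pixel_size_um Pixel size, um/px.
#' @param params Optional list overriding: `min_circularity` (0.8),
#'   `min_diameter_um` (2), `exclude_edge` (TRUE, drop droplets touching the
#'   frame border to avoid truncated diameters), `threshold` (NULL = Otsu, or
#'   a numeric level), `watershed_tolerance` (1).
#' @return Data frame with one row per detection: `droplet_id`,
#'   `center_x_px`, `center_y_px` (0-based), `diameter_um`, `area_px`,
#'   `circularity`; the labelled pixel mask (same orientation as `image`) is
#'   attached as attribute `"labels"`. Deterministic for fixed parameters;
#'   an empty frame gives zero rows.
#' @export
detect_droplets <- function(image, pixel_size_um, params = list()) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  p <- utils::modifyList(list(min_circularity = 0.8, min_diameter_um = 2,
                              exclude_edge = TRUE, threshold = NULL,
                              watershed_tolerance = 1), params)
  thr <- p$threshold
  if (is.null(thr)) {
    # Otsu separates droplets from oil but sits above the half-coverage
    # level of the anti-aliased edge, biasing diameters low; refine to the
    # midpoint between the background and the object edge level
    thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
    bw0 <- image > thr
    if (any(bw0) && any(!bw0)) {
      inner <- EBImage::imageData(EBImage::erode(EBImage::Image(bw0 * 1),
                                                 EBImage::makeBrush(3, "box"))) > 0
      edge <- bw0 & !inner
      if (any(edge)) {
        thr <- (stats::median(image[!bw0]) + stats::median(image[edge])) / 2
      }
    }
  }
  bw <- EBImage::fillHull(EBImage::Image(image > thr))
  if (sum(bw) == 0) return(empty_droplets(image))
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = p$watershed_tolerance, ext = 1)
  lab <- EBImage::imageData(lab)
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  out <- vector("list", length(ids))
  keep_lab <- matrix(0L, nrow(image), ncol(image))
  next_id <- 0L
  h <- nrow(image); w <- ncol(image)
  min_area <- pi * (p$min_diameter_um / pixel_size_um / 2)^2
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE)
    a <- nrow(idx)
    if (a < min_area) next
    ys <- idx[, 1] - 1; xs <- idx[, 2] - 1      # 0-based px
    if (p$exclude_edge &&
        (min(xs) == 0 || min(ys) == 0 || max(xs) == w - 1 || max(ys) == h - 1)) next
    cxm <- mean(xs); cym <- mean(ys)
    # second moments (+ 1/12 px^2 for finite pixel extent)
    sxx <- mean((xs - cxm)^2) + 1 / 12
    syy <- mean((ys - cym)^2) + 1 / 12
    sxy <- mean((xs - cxm) * (ys - cym))
    ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2), symmetric = TRUE,
                only.values = TRUE)$values
    major <- 4 * sqrt(max(ev[1], 0))
    d_eq <- 2 * sqrt(a / pi)
    circ <- if (major > 0) d_eq / major else 0
    if (circ < p$min_circularity) next
    next_id <- next_id + 1L
    keep_lab[idx] <- next_id
    out[[next_id]] <- data.frame(droplet_id = next_id, center_x_px = cxm,
                                 center_y_px = cym,
                                 diameter_um = d_eq * pixel_size_um,
                                 area_px = a, circularity = circ)
  }
  df <- if (next_id == 0) empty_droplets(image) else do.call(rbind, out[seq_len(next_id)])
  rownames(df) <- NULL
  attr(df, "labels") <- keep_lab
  df
}

empty_droplets <- function(image) {
  df <- data.frame(droplet_id = integer(0), center_x_px = numeric(0),
                   center_y_px = numeric(0), diameter_um = numeric(0),
                   area_px = numeric(0), circularity = numeric(0))
  attr(df, "labels") <- matrix(0L, nrow(image), ncol(image))
  df
}

# Minimum-area enclosing rectangle of a pixel set (rotating calipers over
# the convex hull). Returns extents of pixel centers; +1 px converts a
# center-to-center extent to a full pixel extent.
min_area_rect <- function(xs, ys) {
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) == 1) return(list(len = 0, wid = 0, angle = 0))
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[hull, , drop = FALSE]
  if (nrow(hp) == 2) {
    dx <- hp[2, 1] - hp[1, 1]; dy <- hp[2, 2] - hp[1, 2]
    return(list(len = sqrt(dx^2 + dy^2), wid = 0,
                angle = (atan2(dy, dx) * 180 / pi) %% 180))
  }
  best <- list(area = Inf)
  nh <- nrow(hp)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hp[j, 1] - hp[i, 1]; ey <- hp[j, 2] - hp[i, 2]
    L <- sqrt(ex^2 + ey^2)
    if (L == 0) next
    ex <- ex / L; ey <- ey / L
    proj1 <- pts[, 1] * ex + pts[, 2] * ey
    proj2 <- -pts[, 1] * ey + pts[, 2] * ex
    e1 <- max(proj1) - min(proj1)
    e2 <- max(proj2) - min(proj2)
    if (e1 * e2 < best$area) {
      if (e1 >= e2) {
        best <- list(area = e1 * e2, len = e1, wid = e2,
                     angle = (atan2(ey, ex) * 180 / pi) %% 180)
      } else {
        best <- list(area = e1 * e2, len = e2, wid = e1,
                     angle = (atan2(ex, -ey) * 180 / pi) %% 180)
      }
    }
  }
  best
}

#' Measure crystals inside detected droplets
#'
#' Segments the dark rod-shaped crystals within each droplet mask (pixels
#' below a fraction of the droplet's median interior intensity, after
#' eroding the mask to exclude the rim), labels connected objects, discards
#' objects below a minimum area, and measures each by its rotated
#' minimum-area bounding box: length = major extent, width = minor extent,
#' orientation = long-axis angle. Objects outside droplet masks are ignored.
#'
#' @param image The same matrix passed to [detect_droplets()].
#' @param droplets The result of [detect_droplets()] (its `"labels"`
#'   attribute provides the droplet masks).
#' @param pixel_size_um Pixel size, um/px.
#' @param params Optional list overriding: `min_area_px` (4, noise
#'   suppression), `rel_threshold` (0.75 of the droplet median),
#'   `erode_px` (2).
#' @return Data frame: `droplet_id`, `crystal_id`, `length_um`, `width_um`,
#'   `orientation_deg`, `area_px`. Zero rows when no crystals are found.
#' @export
measure_crystals <- function(image, droplets, pixel_size_um, params = list()) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  p <- utils::modifyList(list(min_area_px = 4, rel_threshold = 0.75,
                              erode_px = 2), params)
  labels <- attr(droplets, "labels")
  if (is.null(labels)) stop("droplets must carry a 'labels' attribute (from detect_droplets)")
  empty <- data.frame(droplet_id = integer(0), crystal_id = integer(0),
                      length_um = numeric(0), width_um = numeric(0),
                      orientation_deg = numeric(0), area_px = numeric(0))
  if (nrow(droplets) == 0) return(empty)
  interior <- labels > 0
  if (p$erode_px > 0) {
    brush <- EBImage::makeBrush(2 * p$erode_px + 1, shape = "disc")
    interior <- EBImage::imageData(
      EBImage::erode(EBImage::Image(interior * 1), brush)) > 0
  }
  crystal_mask <- matrix(FALSE, nrow(image), ncol(image))
  for (id in droplets$droplet_id) {
    dmask <- interior & labels == id
    if (!any(dmask)) next
    med <- stats::median(image[dmask])
    crystal_mask[dmask & image < p$rel_threshold * med] <- TRUE
  }
  if (!any(crystal_mask)) return(empty)
  clab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(crystal_mask * 1)))
  out <- list()
  per_droplet_count <- integer(max(droplets$droplet_id))
  for (cid in setdiff(sort(unique(as.vector(clab))), 0)) {
    idx <- which(clab == cid, arr.ind = TRUE)
    if (nrow(idx) < p$min_area_px) next
    ys <- idx[, 1] - 1; xs <- idx[, 2] - 1
    did <- as.integer(names(which.max(table(labels[idx]))))
    rect <- min_area_rect(xs, ys)
    per_droplet_count[did] <- per_droplet_count[did] + 1L
    out[[length(out) + 1L]] <- data.frame(
      droplet_id = did, crystal_id = per_droplet_count[did],
      length_um = (rect$len + 1) * pixel_size_um,
      width_um = (rect$wid + 1) * pixel_size_um,
      orientation_deg = rect$angle, area_px = nrow(idx))
  }
  if (length(out) == 0) return(empty)
  df <- do.call(rbind, out)
  df <- df[order(df$droplet_id, df$crystal_id), ]
  rownames(df) <- NULL
  df
}

#' Summarize a measured droplet/crystal population
#'
#' Population statistics in the form used to characterize an emulsion batch:
#' droplet diameter mean and CV, crystal length mean and CV, the occupancy
#' histogram, and the Poisson mean occupancy estimate (delegating to
#' [fit_lambda()]) with its confidence interval. With fewer than two
#' measured crystals the length CV is undefined and flagged as such rather
#' than reported as 0.
#'
#' @param droplets Data frame from [detect_droplets()] (or a truth table with
#'   columns `droplet_id` and `diameter_um`); at least one droplet.
#' @param crystals Data frame from [measure_crystals()] (or a truth table
#'   with columns `droplet_id` and `length_um`).
#' @param conf_level Confidence level for the lambda interval.
#' @return An object of class `droplet_summary`.
#' @export
summarize_population <- function(droplets, crystals, conf_level = 0.95) {
  if (is.null(droplets) || nrow(droplets) == 0) stop("need at least one droplet")
  occupancy <- vapply(droplets$droplet_id,
                      function(id) sum(crystals$droplet_id == id), numeric(1))
  fit <- fit_lambda(occupancy, conf_level = conf_level)
  d <- droplets$diameter_um
  len <- crystals$length_um
  n_cry <- length(len)
  hist_tab <- as.data.frame(table(crystals_per_droplet = occupancy),
                            stringsAsFactors = FALSE)
  names(hist_tab)[2] <- "count"
  hist_tab$crystals_per_droplet <- as.integer(hist_tab$crystals_per_droplet)
  structure(list(
    n_droplets = nrow(droplets),
    droplet_diameter_mean_um = mean(d),
    droplet_diameter_cv = if (length(d) > 1) stats::sd(d) / mean(d) else NA_real_,
    n_crystals = n_cry,
    crystal_length_mean_um = if (n_cry > 0) mean(len) else NA_real_,
    crystal_length_cv = if (n_cry > 1) stats::sd(len) / mean(len) else NA_real_,
    length_cv_defined = n_cry > 1,
    occupancy_histogram = hist_tab,
    lambda_fit = fit),
    class = "droplet_summary")
}

#' @export
print.droplet_summary <- function(x, ...) {
  cat(sprintf("Population of %d droplets, %d crystals\n", x$n_droplets, x$n_crystals))
  cat(sprintf("  droplet diameter: %.3g um (CV %s)\n", x$droplet_diameter_mean_um,
              if (is.na(x$droplet_diameter_cv)) "undefined"
              else sprintf("%.1f%%", 100 * x$droplet_diameter_cv)))
  if (x$n_crystals > 0) {
    cat(sprintf("  crystal length: %.3g um (CV %s)\n", x$crystal_length_mean_um,
                if (!x$length_cv_defined) "undefined (single crystal)"
                else sprintf("%.1f%%", 100 * x$crystal_length_cv)))
  }
  cat(sprintf("  lambda-hat = %.4g, %.0f%% CI [%.4g, %.4g]\n",
              x$lambda_fit$lambda, 100 * x$lambda_fit$conf_level,
              x$lambda_fit$conf_int[1], x$lambda_fit$conf_int[2]))
  invisible(x)
}
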