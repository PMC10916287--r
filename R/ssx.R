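#' Serial-crystallography image count accounting
#'
#' @param images Detector images collected.
#' @param hits Images containing diffraction.
#' @param indexed Hits indexed to a single lattice.
#' @return An object of class `ssx_counts`; the invariant
#'   `0 <= indexed <= hits <= images` is enforced.
#' @export
ssx_counts <- function(images, hits, indexed) {
  stopifnot(length(images) == 1, length(hits) == 1, length(indexed) == 1,
            images == round(images), hits == round(hits),
            indexed == round(indexed))
  if (!(0 <= indexed && indexed <= hits && hits <= images)) {
    stop("counts must satisfy 0 <= indexed <= hits <= images")
  }
  structure(list(images = as.numeric(images), hits = as.numeric(hits),
                 indexed = as.numeric(indexed)),
            class = "ssx_counts")
}

#' Hit rate and indexing rate from SSX counts
#'
#' `hit_rate = 100 * hits / images`; `indexing_rate = 100 * indexed / hits`,
#' undefined (`NA`) when there are no hits. Values are returned unrounded;
#' the print method shows one decimal place, the usual reporting convention.
#'
#' @param counts An [ssx_counts()] object, or the `images` count if the three
#'   counts are given directly.
#' @param hits,indexed Optional counts when not passing an `ssx_counts`.
#' @return An object of class `ssx_rates` with `hit_rate_pct` and
#'   `indexing_rate_pct`.
#' @examples
#' ssx_rates(ssx_counts(81800, 34032, 29954))  # 41.6% / 88.0%
#' @export
ssx_rates <- function(counts, hits = NULL, indexed = NULL) {
  if (!inherits(counts, "ssx_counts")) counts <- ssx_counts(counts, hits, indexed)
  structure(list(
    counts = counts,
    hit_rate_pct = 100 * counts$hits / counts$images,
    indexing_rate_pct = if (counts$hits == 0) NA_real_
                        else 100 * counts$indexed / counts$hits),
    class = "ssx_rates")
}

#' @export
print.ssx_rates <- function(x, ...) {
  cat(sprintf("SSX rates (%g images, %g hits, %g indexed):\n",
              x$counts$images, x$counts$hits, x$counts$indexed))
  cat(sprintf("  hit rate:      %.1f%%\n", x$hit_rate_pct))
  cat(sprintf("  indexing rate: %s\n",
              if (is.na(x$indexing_rate_pct)) "undefined (no hits)"
              else sprintf("%.1f%%", x$indexing_rate_pct)))
  invisible(x)
}
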