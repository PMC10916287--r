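#' Mean crystals per droplet from crystal density
#'
#' Under random encapsulation the mean occupancy lambda of a droplet is the
#' bulk crystal (or seed) density times the droplet volume.
#'
#' @param density_nl Crystal/seed density in per-nanolitre (>= 0).
#' @param volume_pl Droplet volume in picolitres (>= 0).
#' @return lambda, the mean number of crystals per droplet.
#' @examples
#' lambda_from_density(80, 194)  # ~15.5 crystals per droplet
#' lambda_from_density(7, 0.89)  # ~0.006, deep in the single-occupancy regime
#' @export
lambda_from_density <- function(density_nl, volume_pl) {
  stopifnot(is.numeric(density_nl), is.numeric(volume_pl))
  if (any(density_nl < 0) || any(volume_pl < 0)) {
    stop("density and volume must be non-negative")
  }
  density_nl * volume_pl / 1000
}

#' Poisson occupancy probability
#'
#' Probability that a droplet contains exactly `k` crystals under Poisson
#' loading with mean `lam`. Random encapsulation of dilute particles into
#' monodisperse droplets is Poisson to an excellent approximation.
#'
#' @param lam Mean crystals per droplet (>= 0).
#' @param k Crystal count (non-negative integer, vectorized).
#' @return P(K = k).
#' @export
poisson_pmf <- function(lam, k) {
  stopifnot(is.numeric(lam), length(lam) == 1, lam >= 0)
  if (any(k < 0) || any(k != round(k))) {
    stop("k must be a non-negative integer")
  }
  stats::dpois(k, lambda = lam)
}

#' Fraction of occupied droplets holding exactly one crystal
#'
#' `P(K = 1 | K >= 1) = lam * exp(-lam) / (1 - exp(-lam))` under Poisson
#' loading. Approaches 1 as lambda tends to 0 (the dilute, single-occupancy
#' regime exploited for crystal uniformity) and decreases strictly with
#' lambda. The function requires `lam > 0`; the limit value 1 at lambda = 0
#' is documented rather than silently returned.
#'
#' @param lam Mean crystals per droplet (> 0, vectorized).
#' @return Conditional single-occupancy probability.
#' @examples
#' single_occupancy_fraction(0.1)  # ~0.95
#' @export
single_occupancy_fraction <- function(lam) {
  stopifnot(is.numeric(lam))
  if (any(lam <= 0)) stop("lam must be positive (limit at 0+ is 1)")
  lam * exp(-lam) / (1 - exp(-lam))
}

#' Estimate lambda from per-droplet crystal counts
#'
#' Maximum-likelihood estimate of the Poisson mean occupancy (the sample
#' mean), with a confidence interval. The default interval is the exact
#' Poisson-mean (Garwood) interval built from the chi-square quantiles of the
#' total count, which behaves correctly in the small-count regimes typical of
#' dilute encapsulation (lambda <= 0.1, many empty droplets); a nonparametric
#' bootstrap is available as an alternative.
#'
#' @param counts Either an integer vector of per-droplet crystal counts, or a
#'   two-column data frame / matrix `(crystals_per_droplet, count)` giving an
#'   occupancy histogram.
#' @param conf_level Confidence level, default 0.95.
#' @param method `"garwood"` (exact Poisson-mean interval, default) or
#'   `"bootstrap"`.
#' @param n_boot Bootstrap replicates (used for `method = "bootstrap"`).
#' @param seed Optional integer seed for the bootstrap, for reproducibility.
#' @return An object of class `occupancy_fit` with elements `lambda`,
#'   `conf_int`, `conf_level`, `n`, `total`, `method`.
#' @examples
#' fit_lambda(c(0, 0, 0, 1))          # lambda-hat = 0.25
#' fit_lambda(data.frame(crystals_per_droplet = 0:1, count = c(90, 10)))
#' @export
fit_lambda <- function(counts, conf_level = 0.95,
                       method = c("garwood", "bootstrap"),
                       n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  counts <- expand_occupancy(counts)
  n <- length(counts)
  if (n < 1) stop("need at least one observation")
  total <- sum(counts)
  lam_hat <- total / n
  alpha <- 1 - conf_level
  if (method == "garwood") {
    lo <- if (total == 0) 0 else stats::qchisq(alpha / 2, 2 * total) / 2 / n
    hi <- stats::qchisq(1 - alpha / 2, 2 * total + 2) / 2 / n
  } else {
    if (!is.null(seed)) set.seed(seed)
    boot <- replicate(n_boot, mean(sample(counts, n, replace = TRUE)))
    qs <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  structure(list(lambda = lam_hat, conf_int = c(lo, hi),
                 conf_level = conf_level, n = n, total = total,
                 method = method),
            class = "occupancy_fit")
}

# Accept raw per-droplet counts or a (value, count) histogram.
expand_occupancy <- function(counts) {
  if (is.data.frame(counts) || is.matrix(counts)) {
    if (ncol(counts) != 2) stop("histogram input must have two columns")
    k <- as.numeric(counts[[1]]); m <- as.numeric(counts[[2]])
    if (any(m < 0) || any(m != round(m))) stop("histogram counts must be non-negative integers")
    counts <- rep(k, times = m)
  }
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  counts
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("Poisson occupancy fit: lambda-hat = %.4g (n = %d droplets, %d crystals)\n",
              x$lambda, x$n, x$total))
  cat(sprintf("  %.0f%% CI [%.4g, %.4g] (%s)\n", 100 * x$conf_level,
              x$conf_int[1], x$conf_int[2], x$method))
  if (x$lambda > 0) {
    cat(sprintf("  single-occupancy fraction P(K=1 | K>=1) = %.3f\n",
                single_occupancy_fraction(x$lambda)))
  }
  invisible(x)
}

#' @export
coef.occupancy_fit <- function(object, ...) c(lambda = object$lambda)

#' @export
confint.occupancy_fit <- function(object, parm, level, ...) {
  m <- matrix(object$conf_int, nrow = 1,
              dimnames = list("lambda", c("lower", "upper")))
  m
}

#' Read or write an occupancy histogram CSV
#'
#' The on-disk schema is two columns, `crystals_per_droplet,count`; reading
#' validates the header and integer counts.
#'
#' @param path File path.
#' @param histogram Data frame with columns `crystals_per_droplet` and `count`.
#' @return `read_occupancy_csv` returns the validated data frame.
#' @export
read_occupancy_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("crystals_per_droplet", "count")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("occupancy CSV must have columns: ", paste(need, collapse = ", "))
  }
  expand_occupancy(df[need])  # validation only
  df[need]
}

#' @rdname read_occupancy_csv
#' @export
write_occupancy_csv <- function(histogram, path) {
  stopifnot(all(c("crystals_per_droplet", "count") %in% names(histogram)))
  utils::write.csv(histogram[c("crystals_per_droplet", "count")], path,
                   row.names = FALSE)
  invisible(path)
}
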