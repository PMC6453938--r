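#' Rain-on-snow frequency scenario
#'
#' A scenario is a beta distribution on the probability scale used to warp
#' the empirical ROS distribution: a projection-year ROS value is drawn as
#' `X = Q(U)` with `U ~ Beta(alpha1, alpha2)` and `Q` the empirical quantile
#' function of the observed ROS pool. `Beta(1, 1)` reproduces the historical
#' distribution; right-skewed shapes (`alpha1 > alpha2`) make extreme ROS
#' winters more frequent. Five named presets span very low to very high
#' extreme-winter frequency.
#'
#' @param name one of `"very_low"`, `"low"`, `"medium"`, `"high"`,
#'   `"very_high"`, or `"custom"` (then `alpha1`/`alpha2` are required).
#' @param alpha1,alpha2 beta shape parameters (> 0); override the preset.
#' @return object of class `ros_scenario` with fields `name`, `alpha1`,
#'   `alpha2`.
#' @examples
#' ros_scenario("very_high")          # Beta(4, 1)
#' ros_scenario(alpha1 = 3, alpha2 = 2)
#' @export
ros_scenario <- function(name = "custom", alpha1 = NULL, alpha2 = NULL) {
  presets <- list(very_low  = c(1, 4),
                  low       = c(1, 2),
                  medium    = c(1, 1),
                  high      = c(2, 1),
                  very_high = c(4, 1))
  if (name != "custom") {
    if (!name %in% names(presets)) stop("unknown scenario name: ", name)
    p <- presets[[name]]
    alpha1 <- alpha1 %||% p[1]
    alpha2 <- alpha2 %||% p[2]
  }
  if (is.null(alpha1) || is.null(alpha2))
    stop("custom scenario needs alpha1 and alpha2")
  if (alpha1 <= 0 || alpha2 <= 0) stop("beta shape parameters must be > 0")
  structure(list(name = name, alpha1 = alpha1, alpha2 = alpha2),
            class = "ros_scenario")
}

#' @export
print.ros_scenario <- function(x, ...) {
  cat(sprintf("ROS scenario '%s': Beta(%g, %g), mean U = %.3f\n",
              x$name, x$alpha1, x$alpha2, x$alpha1 / (x$alpha1 + x$alpha2)))
  invisible(x)
}

#' Empirical quantile function of an observed ROS pool
#'
#' Linear interpolation between order statistics at plotting positions
#' `(i - 1)/(n - 1)` (type 7), or a right-continuous step function (type 1).
#' All outputs lie within the range of the pool, so simulated ROS never
#' exceeds historically observed values.
#'
#' @param pool numeric vector of observed ROS values.
#' @param dialect `"linear"` (default) or `"step"`.
#' @return function mapping probabilities in \[0, 1\] to ROS values.
#' @export
ros_quantile_fun <- function(pool, dialect = c("linear", "step")) {
  dialect <- match.arg(dialect)
  if (length(pool) == 0L || anyNA(pool)) stop("pool must be non-empty and complete")
  type <- if (dialect == "linear") 7L else 1L
  function(u) unname(stats::quantile(pool, probs = u, type = type))
}

#' Draw a ROS sequence under a frequency scenario
#'
#' Inverse-transform sampling: independent `U_t ~ Beta(alpha1, alpha2)` per
#' year, mapped through the empirical quantile function of the observed
#' pool. Under the medium scenario (`Beta(1, 1)`) the draws reproduce the
#' historical ROS distribution; skewed shapes shift the frequency of
#' extreme winters while keeping every draw inside the observed range.
#'
#' @param pool numeric vector of observed log-scale ROS values.
#' @param scenario a [ros_scenario()].
#' @param n_years number of winters to draw.
#' @param seed optional integer seed for reproducibility.
#' @param dialect quantile dialect, see [ros_quantile_fun()].
#' @return list of class `ros_sample` with `values` (length `n_years`),
#'   `u` (the beta draws), `scenario` and `seed`.
#' @export
sample_ros <- function(pool, scenario, n_years, seed = NULL,
                       dialect = "linear") {
  stopifnot(inherits(scenario, "ros_scenario"), n_years >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::rbeta(n_years, scenario$alpha1, scenario$alpha2)
  q <- ros_quantile_fun(pool, dialect)
  structure(list(values = q(u), u = u, scenario = scenario,
                 seed = seed), class = "ros_sample")
}

#' Draw winter lengths for projection years
#'
#' Independent normal draws with the observed mean and standard deviation,
#' truncated below at zero by redrawing (a winter length cannot be
#' negative).
#'
#' @param mean,sd observed mean and standard deviation in days (`sd >= 0`).
#' @param n_years number of winters to draw.
#' @param seed optional integer seed.
#' @return numeric vector of `n_years` non-negative winter lengths.
#' @export
sample_winter_length <- function(mean, sd, n_years, seed = NULL) {
  if (sd < 0) stop("sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n_years, mean, sd)
  while (any(neg <- x < 0)) x[neg] <- stats::rnorm(sum(neg), mean, sd)
  x
}
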