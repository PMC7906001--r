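# The speed threshold separating stable from rapid samples is estimated from
# the data itself, per signal, so the classifier needs no user-set cutoff and
# is independent of device units and sampling rate. The scheme is an
# iterative trimmed mean + k*sd rule: start from the threshold implied by all
# speeds, then repeatedly re-estimate the noise distribution from the
# sub-threshold speeds only. On a noise-plus-spikes mixture the iteration
# walks down from the spike-inflated initial value and settles just above the
# noise mode.

#' Estimate a data-driven speed threshold
#'
#' Iterates `theta <- mean(s) + k * sd(s)` over the sub-threshold speeds
#' `s = speed[speed < theta]`, starting from the same rule applied to all
#' speeds, until the update falls below `tolerance` or `max_iter` is reached.
#' `NA` speeds (gap intervals) are ignored.
#'
#' @param vel a [compute_velocity()] result or a numeric vector of speeds in
#'   units/s.
#' @param k multiplier on the noise standard deviation (default 3).
#' @param tolerance convergence tolerance on the threshold update, units/s.
#' @param max_iter maximum number of iterations.
#' @param floor lower bound on the returned threshold, units/s. A degenerate
#'   signal whose speeds are all identical returns the floor with
#'   `converged = TRUE`.
#' @return An object of class `threshold_estimate`: list with `theta`,
#'   `noise_mu`, `noise_sigma` (location/scale of the converged sub-threshold
#'   speeds), `n_iter`, `converged`.
#' @export
estimate_threshold <- function(vel, k = 3, tolerance = 1, max_iter = 50,
                               floor = 1e-6) {
  speeds <- if (inherits(vel, "velocity_series")) vel$speed else as.numeric(vel)
  speeds <- speeds[is.finite(speeds)]
  if (length(speeds) < 10L) {
    stop("need at least 10 finite speed samples to estimate a threshold (got ",
         length(speeds), ")")
  }
  stopifnot(k > 0, tolerance > 0, max_iter >= 1, floor > 0)
  s_all <- stats::sd(speeds)
  if (s_all == 0) {
    return(new_threshold_estimate(theta = floor, noise_mu = mean(speeds),
                                  noise_sigma = 0, n_iter = 0L,
                                  converged = TRUE))
  }
  theta <- mean(speeds) + k * s_all
  mu <- mean(speeds)
  sigma <- s_all
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    sub <- speeds[speeds < theta]
    if (length(sub) < 2L) break
    mu <- mean(sub)
    sigma <- stats::sd(sub)
    theta_new <- mu + k * sigma
    if (abs(theta_new - theta) < tolerance) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
  }
  new_threshold_estimate(theta = max(theta, floor), noise_mu = mu,
                         noise_sigma = sigma, n_iter = iter,
                         converged = converged)
}

new_threshold_estimate <- function(theta, noise_mu, noise_sigma, n_iter,
                                   converged) {
  structure(list(theta = theta, noise_mu = noise_mu,
                 noise_sigma = noise_sigma, n_iter = n_iter,
                 converged = converged),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "<threshold_estimate> theta = %.4g units/s (noise %.4g +- %.4g), %d iter%s\n",
    x$theta, x$noise_mu, x$noise_sigma, x$n_iter,
    if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}
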