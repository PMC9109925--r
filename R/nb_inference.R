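# Negative binomial parameterisation used throughout: mean mu, dispersion
# phi, variance mu + phi * mu^2; stats::*nbinom size = 1/phi.  phi = 0 is
# the Poisson limit and is handled explicitly.

POIS_PHI <- 1e-12  # below this, NB routines switch to the Poisson limit

#' TMM normalization of a read-type count table
#'
#' Trimmed-mean-of-M-values scaling factors computed on the read-type count
#' matrix with the method's published defaults: reference sample chosen by
#' upper-quartile count fraction closest to the across-sample mean, 30% trim
#' on log-ratios (M), 5% trim on average abundance (A), precision weights,
#' zero rows excluded, factors renormalised to geometric mean 1.  The
#' effective library size is N*_j = N_j x f_j and the common pseudo library
#' size N* is the geometric mean of the effective sizes.
#'
#' @param table An \code{sgnb_counts} object with >= 2 samples.
#' @return List of class \code{sgnb_norm}: \code{factors} (named, geometric
#'   mean 1), \code{lib_sizes}, \code{eff_lib_sizes}, \code{common_size}.
#' @export
tmm_normalize <- function(table) {
  stopifnot(inherits(table, "sgnb_counts"))
  if (ncol(table$counts) < 2L) stop("TMM normalization needs >= 2 samples")
  f <- edgeR::calcNormFactors(table$counts, lib.size = table$lib_sizes,
                              method = "TMM")
  eff <- table$lib_sizes * f
  structure(list(factors = stats::setNames(f, colnames(table$counts)),
                 lib_sizes = table$lib_sizes,
                 eff_lib_sizes = eff,
                 common_size = exp(mean(log(eff)))),
            class = "sgnb_norm")
}

#' Conditional log-likelihood of the NB dispersion
#'
#' For counts x_1..x_J observed at a common effective library size, the
#' log-likelihood of the dispersion phi conditional on the sufficient
#' statistic z = sum(x):
#' \deqn{l(\phi) = \sum_j \log\Gamma(x_j + \phi^{-1}) + \log\Gamma(J\phi^{-1})
#'   - \log\Gamma(z + J\phi^{-1}) - J \log\Gamma(\phi^{-1})}
#' The mean parameter cancels, which is what makes maximising this a valid
#' dispersion estimator on quantile-adjusted (equal-size) pseudo counts.
#' Counts may be real-valued (pseudo counts).  At phi = 0 the Poisson/
#' multinomial limit -z log J is returned.
#'
#' @param x Non-negative numeric counts.
#' @param phi Dispersion, >= 0.
#' @return Log-likelihood value (a scalar).
#' @export
cml_loglik <- function(x, phi) {
  if (any(x < 0)) stop("negative count")
  J <- length(x); z <- sum(x)
  if (phi < POIS_PHI) return(-z * log(J))
  r <- 1 / phi
  sum(lgamma(x + r)) + lgamma(J * r) - lgamma(z + J * r) - J * lgamma(r)
}

# mid-P cdf of NB(mu, phi) at integer k: P(X < k) + 0.5 P(X = k)
nb_mid_cdf <- function(k, mu, phi) {
  if (phi < POIS_PHI) {
    ppois(k - 1, lambda = mu) + 0.5 * dpois(k, lambda = mu)
  } else {
    pnbinom(k - 1, mu = mu, size = 1 / phi) +
      0.5 * dnbinom(k, mu = mu, size = 1 / phi)
  }
}

#' Quantile-adjust counts to a common library size
#'
#' Maps each observed count through the mid-quantile of its own NB
#' distribution (mean N*_j theta, dispersion phi) onto the scale of the
#' target distribution (mean N* theta, same phi), inverting the target
#' mid-CDF numerically with linear interpolation between integer support
#' points.  Pseudo counts are real-valued and non-negative; equal input and
#' target sizes give back the input exactly, and a zero count always maps
#' to zero.
#'
#' @param x Non-negative counts, one per sample.
#' @param sizes Effective library sizes N*_j, one per sample.
#' @param target Common library size N*.
#' @param theta Relative expression level (mean = size x theta), >= 0.
#' @param phi Dispersion, >= 0.
#' @return Numeric vector of pseudo counts.
#' @export
quantile_adjust <- function(x, sizes, target, theta, phi) {
  stopifnot(length(x) == length(sizes), target > 0, all(sizes > 0))
  if (theta < 0 || phi < 0) stop("theta and phi must be non-negative")
  if (theta == 0) {
    if (any(x > 0)) stop("theta = 0 with positive counts is inconsistent")
    return(numeric(length(x)))
  }
  mu_t <- target * theta
  out <- numeric(length(x))
  for (j in seq_along(x)) {
    if (x[j] == 0) { out[j] <- 0; next }
    if (sizes[j] == target) { out[j] <- x[j]; next }
    p <- nb_mid_cdf(x[j], mu = sizes[j] * theta, phi = phi)
    out[j] <- invert_mid_cdf(p, mu = mu_t, phi = phi)
  }
  out
}

# invert the target mid-CDF at p with linear interpolation between integers:
# find the smallest integer hi with G(hi) >= p, then interpolate on
# [hi - 1, hi].
invert_mid_cdf <- function(p, mu, phi) {
  G <- function(k) nb_mid_cdf(k, mu, phi)
  if (p <= G(0)) return(0)
  # start near the naive quantile and bracket [lo, hi] with G(lo) < p <= G(hi)
  k <- if (phi < POIS_PHI) stats::qpois(min(p, 1 - 1e-15), lambda = mu)
       else qnbinom(min(p, 1 - 1e-15), mu = mu, size = 1 / phi)
  k <- max(k, 1)
  if (G(k) >= p) {
    hi <- k; lo <- k - 1; step <- 1
    while (lo > 0 && G(lo) >= p) { hi <- lo; lo <- max(0, lo - step); step <- step * 2 }
  } else {
    lo <- k; hi <- k + 1; step <- 1
    while (G(hi) < p) { lo <- hi; hi <- hi + step; step <- step * 2 }
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (G(mid) >= p) hi <- mid else lo <- mid
  }
  g_lo <- G(hi - 1); g_hi <- G(hi)
  if (g_hi == g_lo) return(hi)
  (hi - 1) + (p - g_lo) / (g_hi - g_lo)
}

#' EM estimate of the NB mean parameter theta with offsets
#'
#' The latent-rate formulation: X_j | Theta_j ~ Poisson(N*_j Theta_j) with
#' Theta_j ~ Gamma(shape 1/phi, mean theta).  The E-step takes the posterior
#' mean E[Theta_j | x_j] = (x_j + 1/phi) / (N*_j + 1/(phi theta)); the
#' M-step averages the posterior means.  With equal offsets the fixed point
#' is mean(x)/N* exactly; at phi = 0 the Poisson MLE sum(x)/sum(N*) is
#' returned directly.  Iterated until the relative change in theta drops
#' below \code{tol} or \code{maxit} iterations.
#'
#' @param x Non-negative counts.
#' @param sizes Effective library sizes (offsets) N*_j.
#' @param phi Dispersion, >= 0.
#' @param tol Relative convergence tolerance (default 1e-8).
#' @param maxit Maximum iterations (default 200).
#' @return List: \code{theta}, \code{iterations}, \code{converged}.
#' @export
estimate_theta_em <- function(x, sizes, phi, tol = 1e-8, maxit = 200L) {
  stopifnot(length(x) == length(sizes), all(sizes > 0), phi >= 0)
  if (all(x == 0)) return(list(theta = 0, iterations = 0L, converged = TRUE))
  if (phi < POIS_PHI)
    return(list(theta = sum(x) / sum(sizes), iterations = 0L, converged = TRUE))
  theta <- sum(x) / sum(sizes)
  r <- 1 / phi
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    post <- (x + r) / (sizes + r / theta)
    theta_new <- mean(post)
    if (abs(theta_new - theta) <= tol * max(theta, 1e-12)) {
      theta <- theta_new; converged <- TRUE; break
    }
    theta <- theta_new
  }
  list(theta = theta, iterations = it, converged = converged)
}

#' Quantile-adjusted CML dispersion fit for one read-type group
#'
#' Alternates (i) pooled theta estimation by EM at the current phi,
#' (ii) quantile adjustment of all samples to the common library size N*,
#' (iii) maximisation over phi of the summed per-condition conditional
#' log-likelihoods of the pseudo counts (the dispersion is assumed common
#' across conditions).  The outer loop stops when the relative change in
#' phi-hat falls below \code{tol} or after \code{max_outer} iterations.
#' phi is searched on [\code{phi_min}, \code{phi_max}] by bounded scalar
#' maximisation.  Pseudo counts stay real-valued; the per-condition pseudo
#' sums z0, z1 are rounded (half up) only for the exact test.
#'
#' @param x Counts of one group across all samples (named by sample).
#' @param design An \code{sgnb_design} (0/1 per sample).
#' @param norm An \code{sgnb_norm} from \code{\link{tmm_normalize}}.
#' @param phi_min,phi_max Search bounds for phi (defaults 1e-6, 10).
#' @param tol Outer-loop relative tolerance on phi (default 1e-4).
#' @param max_outer Maximum outer iterations (default 20).
#' @return List of class \code{sgnb_dispfit}: \code{phi}, \code{theta}
#'   (pooled), \code{theta0}, \code{theta1} (per condition), \code{pseudo}
#'   (real-valued pseudo counts), \code{z0}, \code{z1} (rounded pseudo
#'   sums), \code{iterations}, \code{converged}, \code{at_bound}.
#' @export
fit_dispersion <- function(x, design, norm, phi_min = 1e-6, phi_max = 10,
                           tol = 1e-4, max_outer = 20L) {
  stopifnot(inherits(design, "sgnb_design"))
  samp <- names(design)
  x <- x[samp]
  sizes <- norm$eff_lib_sizes[samp]
  target <- norm$common_size
  if (all(x == 0)) {
    return(structure(list(phi = NA_real_, theta = 0, theta0 = 0, theta1 = 0,
                          pseudo = x * 0, z0 = 0, z1 = 0, iterations = 0L,
                          converged = TRUE, at_bound = FALSE,
                          skipped = "all-zero group"),
                     class = "sgnb_dispfit"))
  }
  e0 <- design == 0L; e1 <- design == 1L
  phi <- 0.1
  converged <- FALSE
  pseudo <- x
  for (it in seq_len(max_outer)) {
    theta <- estimate_theta_em(x, sizes, phi)$theta
    pseudo <- quantile_adjust(x, sizes, target, theta, phi)
    obj <- function(ph)
      cml_loglik(pseudo[e0], ph) + cml_loglik(pseudo[e1], ph)
    opt <- optimize(obj, interval = c(phi_min, phi_max), maximum = TRUE,
                    tol = 1e-6)
    phi_new <- opt$maximum
    if (abs(phi_new - phi) / max(phi_new, 1e-4) < tol) {
      phi <- phi_new; converged <- TRUE; break
    }
    phi <- phi_new
  }
  theta <- estimate_theta_em(x, sizes, phi)$theta
  pseudo <- quantile_adjust(x, sizes, target, theta, phi)
  th0 <- estimate_theta_em(x[e0], sizes[e0], phi)$theta
  th1 <- estimate_theta_em(x[e1], sizes[e1], phi)$theta
  structure(list(phi = phi, theta = theta, theta0 = th0, theta1 = th1,
                 pseudo = pseudo,
                 z0 = floor(sum(pseudo[e0]) + 0.5),
                 z1 = floor(sum(pseudo[e1]) + 0.5),
                 iterations = it, converged = converged,
                 at_bound = phi <= phi_min * 1.01 || phi >= phi_max * 0.99,
                 skipped = NULL),
            class = "sgnb_dispfit")
}
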