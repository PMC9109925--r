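test_that("cml_loglik equals the four-term log-gamma expression to 1e-10", {
  for (cs in cml_reference) {
    expect_equal(cml_loglik(cs$x, cs$phi), cs$ll, tolerance = 1e-10)
  }
})

test_that("cml_loglik degenerate cases: single sample, exchangeability, phi -> 0", {
  expect_equal(cml_loglik(17, 0.3), 0)
  expect_equal(cml_loglik(c(42.5), 2.1), 0)
  x <- c(3, 5, 11, 0)
  expect_equal(cml_loglik(x, 0.7), cml_loglik(rev(x), 0.7))
  expect_equal(cml_loglik(x, 0), -sum(x) * log(4))
  expect_error(cml_loglik(c(3, -1), 0.5), "negative")
})

test_that("tmm_normalize matches an independent TMM reimplementation", {
  set.seed(31)
  counts <- matrix(rnbinom(200 * 5, mu = 80, size = 2), 200, 5,
                   dimnames = list(NULL, paste0("s", 1:5)))
  libs <- stats::setNames(colSums(counts) * runif(5, 1, 1.4), paste0("s", 1:5))
  tab <- count_table(counts, gene = paste0("g", 1:200),
                     type = rep("1", 200), lib_sizes = libs)
  norm <- tmm_normalize(tab)
  expect_equal(unname(norm$factors),
               unname(oracle_tmm_factors(counts, libs)), tolerance = 1e-8)
  expect_equal(exp(mean(log(norm$factors))), 1, tolerance = 1e-12)
  expect_equal(norm$eff_lib_sizes, libs * norm$factors)
})

test_that("tmm factors are symmetric for identical samples and undo scaling", {
  counts <- matrix(rep(c(10, 50, 200, 7, 90), 2), ncol = 2,
                   dimnames = list(NULL, c("a", "b")))
  tab <- count_table(counts, gene = paste0("g", 1:5), type = rep("1", 5),
                     lib_sizes = c(a = 1000, b = 1000))
  expect_equal(unname(tmm_normalize(tab)$factors), c(1, 1))

  # sample b doubles every count and the library size: effective expression equal
  counts2 <- cbind(a = c(10, 50, 200, 7, 90), b = 2 * c(10, 50, 200, 7, 90))
  tab2 <- count_table(counts2, gene = paste0("g", 1:5), type = rep("1", 5),
                      lib_sizes = c(a = 1000, b = 2000))
  n2 <- tmm_normalize(tab2)
  expect_equal(n2$eff_lib_sizes[["b"]] / n2$eff_lib_sizes[["a"]], 2,
               tolerance = 1e-6)
  expect_error(tmm_normalize(count_table(counts2[, 1, drop = FALSE],
                                         gene = paste0("g", 1:5),
                                         type = rep("1", 5),
                                         lib_sizes = c(a = 1000))),
               ">= 2 samples")
})

test_that("quantile_adjust is the identity at equal sizes and maps 0 to 0", {
  x <- c(0, 3, 10, 25)
  sizes <- rep(5000, 4)
  expect_equal(quantile_adjust(x, sizes, 5000, theta = 0.002, phi = 0.3), x)
  expect_equal(quantile_adjust(c(0, 0), c(1000, 9000), 3000, 0.01, 0.2),
               c(0, 0))
  expect_error(quantile_adjust(c(1, 0), c(1000, 1000), 1000, 0, 0.1),
               "inconsistent")
})

test_that("quantile_adjust matches brute-force mid-P CDF mapping", {
  cases <- expand.grid(x = c(1, 4, 10, 33), ratio = c(0.5, 2, 1.7),
                       phi = c(0.1, 0.6))
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    target <- 10000
    got <- quantile_adjust(cs$x, cs$ratio * target, target,
                           theta = 0.001, phi = cs$phi)
    want <- oracle_quantile_map(cs$x, cs$ratio * target, target,
                                theta = 0.001, phi = cs$phi)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # the spec case x = 10 at double the target size
  expect_equal(quantile_adjust(10, 2 * 10000, 10000, 0.001, 0.1),
               oracle_quantile_map(10, 20000, 10000, 0.001, 0.1),
               tolerance = 1e-6)
})

test_that("quantile_adjust is monotone in the input count", {
  for (phi in c(0.05, 0.5)) {
    y <- vapply(0:40, function(x)
      quantile_adjust(x, 15000, 10000, 0.001, phi), numeric(1))
    # non-strict at the bottom: small counts can clamp to 0 on the target
    # scale; strictly increasing once off the boundary
    expect_true(all(diff(y) >= 0))
    expect_true(all(diff(y[y > 0]) > 0))
  }
})

test_that("estimate_theta_em has the closed-form fixed point at equal offsets", {
  x <- c(4, 9, 2, 7)
  fit <- estimate_theta_em(x, rep(2000, 4), phi = 0.4)
  expect_equal(fit$theta, mean(x) / 2000, tolerance = 1e-7)
  expect_true(fit$converged)
  expect_equal(estimate_theta_em(c(0, 0, 0), rep(100, 3), 0.2)$theta, 0)
  expect_equal(estimate_theta_em(c(5, 10), c(1000, 2000), 0)$theta, 15 / 3000)
})

test_that("estimate_theta_em maximizes the marginal NB likelihood (grid oracle)", {
  fit <- estimate_theta_em(c(2, 9), c(1000, 3000), phi = 0.2)
  expect_equal(fit$theta, oracle_theta_grid(c(2, 9), c(1000, 3000), 0.2),
               tolerance = 1e-5)
  set.seed(12)
  for (r in 1:5) {
    J <- sample(3:6, 1)
    sizes <- runif(J, 500, 5000)
    x <- rnbinom(J, mu = sizes * 0.004, size = 1 / 0.3)
    if (all(x == 0)) next
    fit <- estimate_theta_em(x, sizes, 0.3)
    expect_equal(fit$theta, oracle_theta_grid(x, sizes, 0.3),
                 tolerance = 1e-4)
  }
})

test_that("EM iterations never decrease the observed-data NB log-likelihood", {
  set.seed(8)
  sizes <- runif(6, 800, 4000)
  x <- rnbinom(6, mu = sizes * 0.002, size = 1 / 0.5)
  ll <- function(th) sum(oracle_nb_logpmf(x, sizes * th, 0.5))
  theta <- sum(x) / sum(sizes)
  prev <- ll(theta)
  for (i in 1:50) {
    post <- (x + 1 / 0.5) / (sizes + 1 / (0.5 * theta))
    theta <- mean(post)
    cur <- ll(theta)
    expect_gte(cur, prev - 1e-9)
    prev <- cur
  }
})

test_that("fit_dispersion keeps raw counts as pseudo counts at equal library sizes", {
  J <- 8
  libs <- stats::setNames(rep(1e5, J), paste0("s", 1:J))
  v <- c(40, 75, 12)  # identical samples: TMM factors all 1
  tab <- count_table(matrix(v, 3, J, dimnames = list(NULL, names(libs))),
                     gene = c("g1", "g1", "g2"), type = c("1", "2", "1"),
                     lib_sizes = libs)
  norm <- tmm_normalize(tab)
  expect_equal(unname(norm$eff_lib_sizes), rep(norm$common_size, J))
  x <- stats::setNames(rep(40, J), names(libs))
  fit <- fit_dispersion(x, two_condition_design(J / 2), norm)
  expect_equal(unname(fit$pseudo), unname(x))
  expect_equal(fit$z0 + fit$z1, sum(x))
})

test_that("fit_dispersion recovers theta and phi from model simulations", {
  set.seed(77)
  J <- 50
  libs <- stats::setNames(round(runif(2 * J, 0.9e6, 1.1e6)),
                          sprintf("s%03d", 1:(2 * J)))
  design <- design_info(stats::setNames(rep(0:1, each = J), names(libs)))
  theta_true <- 5e-4; phi_true <- 0.2
  x <- simulate_counts_model(rep(theta_true, 50), libs, phi_true, seed = 5)
  tab <- count_table(x, gene = sprintf("g%02d", 1:50), type = rep("1", 50),
                     lib_sizes = libs)
  norm <- tmm_normalize(tab)
  fits <- apply(tab$counts, 1, function(row)
    unlist(fit_dispersion(row, design, norm)[c("phi", "theta")]))
  expect_lt(abs(median(fits["phi", ]) - phi_true) / phi_true, 0.25)
  expect_lt(abs(median(fits["theta", ]) - theta_true) / theta_true, 0.05)
})

test_that("fit_dispersion drives phi to the boundary on Poisson data", {
  set.seed(13)
  J <- 50
  libs <- stats::setNames(rep(1e6, 2 * J), sprintf("s%03d", 1:(2 * J)))
  design <- design_info(stats::setNames(rep(0:1, each = J), names(libs)))
  x <- simulate_counts_model(rep(5e-4, 30), libs, phi = 0, seed = 99)
  tab <- count_table(x, gene = sprintf("g%02d", 1:30), type = rep("1", 30),
                     lib_sizes = libs)
  norm <- tmm_normalize(tab)
  phis <- apply(tab$counts, 1, function(row)
    fit_dispersion(row, design, norm)$phi)
  expect_gte(mean(phis < 0.01), 0.9)
})
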