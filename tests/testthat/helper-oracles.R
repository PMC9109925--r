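# Independent brute-force oracles used across the suite.  These deliberately
# avoid the code paths they check: pmfs are computed from the log-gamma
# formula rather than dnbinom, partitions per base rather than via IRanges,
# and optima by grid scan rather than optimize().

# per-base partition of an exon union by membership pattern (genes <= 10 kb)
oracle_flatten <- function(intervals) {
  lo <- min(intervals$start); hi <- max(intervals$end)
  stopifnot(hi - lo <= 10000)
  bases <- lo:hi
  pat <- vapply(bases, function(b)
    paste(as.integer(b >= intervals$start & b <= intervals$end),
          collapse = ""), character(1))
  covered <- pat != strrep("0", nrow(intervals))
  bases <- bases[covered]; pat <- pat[covered]
  brk <- c(TRUE, pat[-1] != pat[-length(pat)] |
             diff(bases) > 1L)
  grp <- cumsum(brk)
  data.frame(start = tapply(bases, grp, min),
             end = tapply(bases, grp, max), row.names = NULL)
}

# NB log pmf from first principles (mean mu, dispersion phi)
oracle_nb_logpmf <- function(a, mu, phi) {
  if (phi == 0) return(a * log(mu) - mu - lgamma(a + 1))
  r <- 1 / phi
  lgamma(a + r) - lgamma(r) - lgamma(a + 1) +
    r * log(r / (r + mu)) + a * log(mu / (r + mu))
}

# exact conditional two-sided p-value by direct enumeration
oracle_exact_p <- function(z0, z1, J0, J1, Nstar, theta, phi) {
  z <- z0 + z1
  a <- 0:z
  lq <- oracle_nb_logpmf(a, J0 * Nstar * theta, phi / J0) +
    oracle_nb_logpmf(z - a, J1 * Nstar * theta, phi / J1)
  q <- exp(lq - max(lq)); q <- q / sum(q)
  sum(q[q <= q[z0 + 1] * (1 + 1e-10)])
}

# mid-P quantile mapping by direct CDF summation and linear scan
oracle_quantile_map <- function(x, size_from, size_to, theta, phi) {
  midcdf <- function(k, mu) {
    if (k == 0) return(0.5 * exp(oracle_nb_logpmf(0, mu, phi)))
    sum(exp(oracle_nb_logpmf(0:(k - 1), mu, phi))) +
      0.5 * exp(oracle_nb_logpmf(k, mu, phi))
  }
  p <- midcdf(x, size_from * theta)
  mu_t <- size_to * theta
  k <- 0
  while (midcdf(k, mu_t) < p) k <- k + 1
  if (k == 0) return(0)
  g0 <- midcdf(k - 1, mu_t); g1 <- midcdf(k, mu_t)
  (k - 1) + (p - g0) / (g1 - g0)
}

# NB mean MLE with offsets by two-stage grid scan
oracle_theta_grid <- function(x, sizes, phi) {
  ll <- function(th) sum(oracle_nb_logpmf(x, sizes * th, phi))
  th0 <- sum(x) / sum(sizes)
  grid <- th0 * seq(0.2, 5, length.out = 2000)
  best <- grid[which.max(vapply(grid, ll, numeric(1)))]
  grid2 <- best * seq(0.995, 1.005, length.out = 2000)
  grid2[which.max(vapply(grid2, ll, numeric(1)))]
}

# straightforward reimplementation of TMM with its published defaults
oracle_tmm_factors <- function(counts, lib.size) {
  uq <- apply(counts, 2, stats::quantile, p = 0.75) / lib.size
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j] / lib.size[j]
    rf <- counts[, ref] / lib.size[ref]
    keep <- obs > 0 & rf > 0
    M <- log2(obs[keep] / rf[keep])
    A <- (log2(obs[keep]) + log2(rf[keep])) / 2
    v <- (lib.size[j] - counts[keep, j]) / (lib.size[j] * counts[keep, j]) +
      (lib.size[ref] - counts[keep, ref]) / (lib.size[ref] * counts[keep, ref])
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    k <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[k] / v[k]) / sum(1 / v[k]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# small deterministic count-table fixture
make_fixture_table <- function(n_genes = 3, n_types = 2, J = 4, seed = 1) {
  set.seed(seed)
  n <- n_genes * n_types
  counts <- matrix(rpois(n * J, 50), n, J,
                   dimnames = list(NULL, paste0("s", seq_len(J))))
  count_table(counts,
              gene = rep(paste0("g", seq_len(n_genes)), each = n_types),
              type = rep(as.character(seq_len(n_types)), n_genes),
              lib_sizes = stats::setNames(colSums(counts) + 1000,
                                          paste0("s", seq_len(J))))
}

two_condition_design <- function(J_per = 2) {
  design_info(stats::setNames(rep(c(0L, 1L), each = J_per),
                              paste0("s", seq_len(2 * J_per))))
}

write_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_exon <- function(gene, start, end, feature = "exon", chrom = "chr1",
                     strand = "+") {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
          chrom, feature, start, end, strand, gene)
}

# Frozen high-precision reference values for the conditional log-likelihood,
# computed term by term with 60-digit arithmetic from the four-log-gamma
# expression.  Inputs mix integer and real-valued (pseudo) counts.
cml_reference <- list(
  list(phi = 4.2212, x = c(49.162, 31, 50.018, 29.288, 50.258, 58.708), ll = -487.4368922306811104428),
  list(phi = 4.2008, x = c(55, 25, 54, 6, 5, 36, 10, 35), ll = -431.7401642165998610013),
  list(phi = 3.7685, x = c(17.307, 17.499, 9.796, 43.922, 47.768, 0.942, 55.976, 55.159), ll = -468.5239529952699650387),
  list(phi = 3.5426, x = c(35, 14, 3, 60, 54, 44, 7, 39), ll = -488.6932598684951708019),
  list(phi = 0.5103, x = c(7.525, 21.776, 28.256), ll = -59.62165285735882921789),
  list(phi = 4.3708, x = c(38, 39, 29, 44, 51), ll = -331.8809140214043288598),
  list(phi = 4.8614, x = c(20.42, 36.288, 12.775, 49.317, 24.028), ll = -226.7624556205529128521),
  list(phi = 3.8025, x = c(13, 56, 46), ll = -116.3306707105930585257),
  list(phi = 0.224, x = c(10.546, 44.955), ll = -29.62856956785791074114),
  list(phi = 4.5426, x = c(6, 53, 24, 42, 15, 60, 40, 49), ll = -578.3826955438987347875),
  list(phi = 1.096, x = c(18.675, 40.176, 8.986, 7.378, 8.325, 2.252), ll = -133.3572176758144148651),
  list(phi = 2.0788, x = c(58, 55), ll = -80.90420454502441178613),
  list(phi = 3.4854, x = c(22.761, 39.926, 15.35, 9.499), ll = -117.1199061092750694893),
  list(phi = 3.4039, x = c(16, 52, 48, 38, 18, 23, 57, 43), ll = -606.1027023220915089407),
  list(phi = 0.2935, x = c(25.671, 30.998, 24.581, 30.285, 9.515, 31.617, 24.828, 50.376), ll = -467.1870350507031562234),
  list(phi = 3.6291, x = c(5, 11, 43, 14), ll = -87.06459592979386389694),
  list(phi = 4.447, x = c(50.288, 28.005, 3.408, 16.86), ll = -118.036867250173714633),
  list(phi = 1.0444, x = c(59, 14, 21, 54), ll = -188.8680007001469720896),
  list(phi = 4.7883, x = c(9.377, 12.523, 36.416, 18.823, 59.894, 11.554), ll = -244.2461987649508238627),
  list(phi = 3.5612, x = c(55, 59, 47, 53, 53), ll = -440.6911652883638356848))
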