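test_that("generate_gene_models is deterministic and respects its ranges", {
  cfg <- sim_config()
  a <- generate_gene_models(30, cfg, seed = 4)
  b <- generate_gene_models(30, cfg, seed = 4)
  expect_identical(a, b)
  for (m in a$genes) {
    E <- length(m$exon_len)
    expect_true(E >= 3 && E <= 10)
    expect_true(all(m$exon_len >= 80 & m$exon_len <= 500))
    expect_true(length(m$isoforms) >= 1 && length(m$isoforms) <= 4)
    for (ch in m$isoforms) {
      expect_true(all(diff(ch) > 0))
      expect_equal(ch[1], 1L)
      expect_equal(ch[length(ch)], E)
    }
  }
})

test_that("base copy numbers have the configured NB moments", {
  set.seed(2)
  k <- rnbinom(1e5, mu = 10, size = 10^2 / (210 - 10))
  se_mean <- sqrt(210 / 1e5)
  expect_lt(abs(mean(k) - 10), 3 * se_mean)
  # SE of the sample variance via the fourth moment
  m4 <- mean((k - mean(k))^4)
  se_var <- sqrt((m4 - var(k)^2) / 1e5)
  expect_lt(abs(var(k) - 210), 3 * se_var)
})

test_that("enumerate_start_positions walks every start exactly once", {
  # one exon of length 150: L - r + 1 = 51 starts of the pure type
  one <- enumerate_start_positions(1L, exon_len = 150L, read_len = 100L)
  expect_equal(one$type, "1")
  expect_equal(one$count, 51L)

  # middle exon shorter than the read: no pure type "2"
  tri <- enumerate_start_positions(c(1L, 2L, 3L),
                                   exon_len = c(150L, 50L, 150L),
                                   read_len = 100L)
  expect_false("2" %in% tri$type)
  expect_true("1-2-3" %in% tri$type)
  expect_equal(sum(tri$count), 150L + 50L + 150L - 100L + 1L)

  expect_equal(nrow(enumerate_start_positions(1L, 80L, 100L)), 0L)
})

test_that("shared sub-chains give identical start counts across isoforms", {
  set.seed(17)
  models <- generate_gene_models(40, sim_config(), seed = 17)
  for (m in models$genes) {
    tsc <- type_start_counts(m, read_len = 100L)
    # l_gih is two-valued: per type, non-zero entries all equal l_g.h
    for (h in seq_len(nrow(tsc$l))) {
      nz <- tsc$l[h, tsc$l[h, ] > 0]
      expect_equal(length(unique(nz)), 1L)
    }
    # conservation: per isoform the counts sum to the usable length
    for (i in seq_along(m$isoforms)) {
      L <- sum(m$exon_len[m$isoforms[[i]]])
      expect_equal(unname(tsc$l_iso[i]), L - 100L + 1L)
    }
  }
})

test_that("ground_truth_groups partitions types by generating-isoform sets", {
  # single isoform: every type in one class
  m1 <- list(gene_id = "g", chrom = "chr1", exon_len = c(200L, 150L, 300L),
             exon_start = c(1L, 1000L, 2000L),
             isoforms = list(c(1L, 2L, 3L)))
  t1 <- ground_truth_groups(type_start_counts(m1))
  expect_equal(length(t1$classes), 1L)

  # skipped exon: types touching exon 2 form their own class
  m2 <- list(gene_id = "g", chrom = "chr1", exon_len = c(300L, 200L, 300L),
             exon_start = c(1L, 1000L, 2000L),
             isoforms = list(c(1L, 2L, 3L), c(1L, 3L)))
  t2 <- ground_truth_groups(type_start_counts(m2))
  with2 <- vapply(t2$classes, function(cl)
    any(grepl("(^|-)2(-|$)", cl)), logical(1))
  for (cl in t2$classes[with2]) {
    expect_true(all(grepl("(^|-)2(-|$)", cl)))
  }
  expect_true(t2$full_rank)
  expect_equal(t2$rank_after, t2$rank_before)
})

test_that("mechanistic read frequencies follow the start-position law", {
  m <- list(gene_id = "g", chrom = "chr1", exon_len = c(250L, 120L, 400L),
            exon_start = c(1L, 2000L, 4000L),
            isoforms = list(c(1L, 2L, 3L)))
  models <- structure(list(genes = list(g = m), config = sim_config()),
                      class = "sgnb_models")
  cfg <- sim_config(n_genes = 1, samples_per_condition = 2,
                    reads_per_gene = 50000)
  design <- design_info(stats::setNames(rep(0:1, each = 2), paste0("s", 1:4)))
  copies <- draw_copy_numbers(models, design, cfg, seed = 23)
  sim <- simulate_reads_mechanistic(models, copies, design, cfg, seed = 24)
  tsc <- type_start_counts(m, read_len = 100L)
  obs <- rowSums(sim$table$counts)
  expect_setequal(sim$table$type, rownames(tsc$l))
  expected <- tsc$l[, 1][sim$table$type] / sum(tsc$l[, 1])
  chi <- stats::chisq.test(obs, p = expected)
  expect_gt(chi$p.value, 0.001)
})

test_that("simulated totals match the reads-per-gene budget", {
  cfg <- sim_config(n_genes = 8, samples_per_condition = 3, de_fraction = 0)
  sim <- simulate_experiment(cfg, seed = 31)
  per_gene <- rowsum(sim$table$counts, sim$table$gene)
  # each gene's per-sample reads are NB around 1000 with c = 5
  expect_true(all(abs(colMeans(per_gene) - 1000) < 1000 * 0.35))
  expect_equal(unname(sim$table$lib_sizes), unname(colSums(sim$table$counts)))
})

test_that("model-based simulator matches NB moments and the Poisson limit", {
  libs <- stats::setNames(rep(1e6, 2), c("a", "b"))
  x <- simulate_counts_model(rep(2e-4, 5000), libs, phi = 0.3, seed = 6)
  mu <- 200
  expect_lt(abs(mean(x) - mu), 3 * sqrt((mu + 0.3 * mu^2) / 10000))
  v <- var(as.vector(x))
  expect_lt(abs(v - (mu + 0.3 * mu^2)) / (mu + 0.3 * mu^2), 0.1)
  xp <- simulate_counts_model(rep(2e-4, 5000), libs, phi = 0, seed = 7)
  vp <- var(as.vector(xp))
  expect_lt(abs(vp - mu) / mu, 0.05)
})

test_that("simulators are deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 3, samples_per_condition = 2)
  a <- simulate_experiment(cfg, seed = 12)
  b <- simulate_experiment(cfg, seed = 12)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$copies, b$copies)
})

test_that("the switch preset realizes equal totals with swapped isoform levels", {
  sw <- make_switch_gene()
  L <- vapply(sw$isoforms, function(ch) sum(sw$exon_len[ch]), numeric(1))
  expect_equal(L[1], L[2])
  expect_equal(sw$k0, rev(sw$k1))
  expect_equal(sum(sw$k0 * L), sum(sw$k1 * L))
  # theta = P k: composition changes, total stays put
  tsc <- type_start_counts(sw)
  th0 <- tsc$P %*% (sw$k0 * tsc$l_iso)
  th1 <- tsc$P %*% (sw$k1 * tsc$l_iso)
  expect_false(isTRUE(all.equal(th0, th1)))
  expect_true(ground_truth_groups(tsc)$full_rank)
})
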