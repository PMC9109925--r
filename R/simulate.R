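# Mechanistic single-end RNA-seq simulator and brute-force ground-truth
# oracles.  The simulator mimics the fragment-and-sequence process: isoform
# copy numbers are drawn NB, each sample's reads per isoform are NB around
# the copy-proportional expectation, fragments get a Normal length, and the
# leftmost read_len bases of each fragment become the read.

#' Simulation configuration
#'
#' Defaults reproduce the reference study conditions: isoform copy numbers
#' NB with mean 10 and variance 210, fragment length Normal(250, 25)
#' truncated to [read_len, transcript length], read length 100 bp, 1000
#' expected reads per gene, per-transcript NB dispersion constant c (small
#' 5, large 30; reads per isoform ~ NB(mean, size = mean / c)), ~30% DE
#' genes with per-isoform log2 fold changes Normal(0, 1).
#'
#' @param n_genes Number of genes.
#' @param samples_per_condition Samples in each of the two conditions.
#' @param copy_mean,copy_var NB moments of the base isoform copy number.
#' @param frag_mean,frag_sd Fragment length distribution (bp).
#' @param read_len Read length (bp).
#' @param reads_per_gene Expected reads per gene per sample.
#' @param dispersion_const Per-transcript dispersion constant c.
#' @param de_fraction Fraction of genes that are differentially expressed.
#' @param lfc_mean,lfc_sd Normal parameters of per-isoform log2 fold changes.
#' @return List of class \code{sgnb_sim_config}.
#' @export
sim_config <- function(n_genes = 10L, samples_per_condition = 20L,
                       copy_mean = 10, copy_var = 210,
                       frag_mean = 250, frag_sd = 25,
                       read_len = 100L, reads_per_gene = 1000L,
                       dispersion_const = 5, de_fraction = 0.30,
                       lfc_mean = 0, lfc_sd = 1) {
  stopifnot(copy_var > copy_mean, read_len >= 1, reads_per_gene >= 1,
            samples_per_condition >= 2, dispersion_const > 0)
  structure(as.list(environment()), class = "sgnb_sim_config")
}

#' Generate random gene models (flat exons + isoform structures)
#'
#' Per gene: 3-10 flat exons with lengths uniform on 80-500 bp, separated by
#' introns, and 1-4 distinct isoforms, each a random increasing subset of
#' the exons that always contains the terminal (first and last) exons.
#' Deterministic given the seed.
#'
#' @param n_genes Number of genes.
#' @param config An \code{sgnb_sim_config}.
#' @param seed Integer seed.
#' @return List of class \code{sgnb_models}: per-gene list with
#'   \code{gene_id}, \code{chrom}, \code{exon_len}, \code{exon_start}
#'   (genomic), \code{isoforms} (list of integer chains).
#' @export
generate_gene_models <- function(n_genes, config = sim_config(), seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  pos <- 10000L
  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    E <- sample(3:10, 1L)
    len <- sample(80:500, E, replace = TRUE)
    intron <- sample(200:2000, E, replace = TRUE)
    start <- integer(E)
    p <- pos
    for (e in seq_len(E)) { start[e] <- p; p <- p + len[e] + intron[e] }
    pos <- p + 10000L
    n_iso <- sample(1:4, 1L)
    iso <- list()
    guard <- 0L
    while (length(iso) < n_iso && guard < 50L) {
      guard <- guard + 1L
      mid <- if (E > 2L) which(runif(E - 2L) < 0.5) + 1L else integer(0)
      chain <- sort(unique(c(1L, mid, E)))
      if (!any(vapply(iso, identical, logical(1), chain))) {
        iso[[length(iso) + 1L]] <- chain
      }
    }
    genes[[g]] <- list(gene_id = sprintf("gene%03d", g), chrom = "chr1",
                       exon_len = len, exon_start = start, isoforms = iso)
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  structure(list(genes = genes, config = config), class = "sgnb_models")
}

#' Construct the two-isoform switch gene
#'
#' Four exons; isoform A uses exons (1, 2, 4) and isoform B exons (1, 3, 4),
#' with exons 2 and 3 of equal length so the two isoforms have identical
#' lengths.  With expected copies (10, 50) in condition 0 and (50, 10) in
#' condition 1 the gene's total isoform size is unchanged across conditions
#' while the isoform-wise expression switches -- invisible to a gene-level
#' total-count test.
#'
#' @param gene_id Gene identifier.
#' @param at Genomic start offset.
#' @return A single gene model (same shape as elements of
#'   \code{\link{generate_gene_models}}), with fixed copies \code{k0},
#'   \code{k1} attached.
#' @export
make_switch_gene <- function(gene_id = "switch", at = 1e6L) {
  len <- c(200L, 300L, 300L, 200L)
  intron <- c(500L, 1500L, 500L, 0L)
  start <- at + c(0L, cumsum(len + intron))[1:4]
  list(gene_id = gene_id, chrom = "chr1", exon_len = len, exon_start = start,
       isoforms = list(c(1L, 2L, 4L), c(1L, 3L, 4L)),
       k0 = c(10, 50), k1 = c(50, 10))
}

#' Flat annotation of generated gene models
#'
#' @param models An \code{sgnb_models}.
#' @return Flat annotation \code{data.frame} (see
#'   \code{\link{flatten_annotation}}).
#' @export
models_to_flat <- function(models) {
  do.call(rbind, lapply(models$genes, function(m) {
    data.frame(gene_id = m$gene_id, exon_id = seq_along(m$exon_len),
               chrom = m$chrom, start = m$exon_start,
               end = m$exon_start + m$exon_len - 1L, strand = "+",
               stringsAsFactors = FALSE)
  }))
}

#' Enumerate read-start positions per read type on one isoform
#'
#' Brute-force walk over every start position 1..(L - read_len + 1) of the
#' isoform's transcript; the chain of exons covered by the read is its
#' type.  The counts l_gih are exact and sum to the usable transcript
#' length L - read_len + 1.
#'
#' @param chain Integer vector, the isoform's exon chain.
#' @param exon_len Integer vector of all the gene's flat-exon lengths.
#' @param read_len Read length.
#' @return \code{data.frame} with columns \code{type}, \code{count}; empty
#'   when the transcript is shorter than the read.
#' @export
enumerate_start_positions <- function(chain, exon_len, read_len) {
  stopifnot(read_len >= 1)
  le <- exon_len[chain]
  L <- sum(le)
  if (L < read_len)
    return(data.frame(type = character(0), count = integer(0)))
  cum <- cumsum(le)
  s <- seq_len(L - read_len + 1L)
  f <- findInterval(s - 1L, cum) + 1L
  l <- findInterval(s + read_len - 2L, cum) + 1L
  key <- paste(f, l)
  tab <- table(key)
  fl <- strsplit(names(tab), " ", fixed = TRUE)
  data.frame(
    type = vapply(fl, function(p)
      chain_label(chain[as.integer(p[1]):as.integer(p[2])]), character(1)),
    count = as.integer(tab), stringsAsFactors = FALSE)
}

#' Per-gene type-start counts and the matrix P_g
#'
#' Runs \code{\link{enumerate_start_positions}} for every isoform and
#' assembles l_gih (starts of type h on isoform i), the usable lengths
#' l_gi., and the types-by-isoforms probability matrix P_g with entries
#' p_gih = l_gih / l_gi..
#'
#' @param model One gene model.
#' @param read_len Read length.
#' @return List of class \code{sgnb_tsc}: \code{types}, \code{l} (types x
#'   isoforms count matrix), \code{l_iso} (usable length per isoform),
#'   \code{P} (types x isoforms).
#' @export
type_start_counts <- function(model, read_len = 100L) {
  per <- lapply(model$isoforms, enumerate_start_positions,
                exon_len = model$exon_len, read_len = read_len)
  types <- unique(unlist(lapply(per, `[[`, "type")))
  types <- types[chain_order(types)]
  l <- matrix(0L, length(types), length(per),
              dimnames = list(types, NULL))
  for (i in seq_along(per)) {
    l[match(per[[i]]$type, types), i] <- per[[i]]$count
  }
  l_iso <- colSums(l)
  P <- sweep(l, 2L, pmax(l_iso, 1L), "/")
  structure(list(types = types, l = l, l_iso = l_iso, P = P),
            class = "sgnb_tsc")
}

#' Ground-truth always-showing-together classes and rank report
#'
#' Partitions a gene's read types by their generating-isoform sets (the
#' brute-force definition of "always showing together") and reports the
#' column rank of P_g before and after summing the rows of each class.
#'
#' @param tsc An \code{sgnb_tsc} from \code{\link{type_start_counts}}.
#' @return List: \code{classes} (list of character vectors of types),
#'   \code{rank_before}, \code{rank_after}, \code{full_rank} (whether the
#'   original P_g has full column rank).
#' @export
ground_truth_groups <- function(tsc) {
  pat <- apply(tsc$l > 0, 1L, paste, collapse = "")
  classes <- split(rownames(tsc$l), pat)
  names(classes) <- NULL
  classes <- lapply(classes, function(x) x[chain_order(x)])
  merged <- rowsum(tsc$P, pat)
  rb <- qr(tsc$P)$rank
  ra <- qr(merged)$rank
  list(classes = classes, rank_before = rb, rank_after = ra,
       full_rank = rb == ncol(tsc$P))
}

#' Draw per-sample isoform read counts
#'
#' Base copy numbers k_gi ~ NB(mean copy_mean, variance copy_var) per
#' isoform (unless the gene model carries fixed \code{k0}/\code{k1}).  A
#' gene is DE with probability \code{de_fraction}; its isoforms' condition-1
#' copies are scaled by 2^lfc with lfc ~ Normal(lfc_mean, lfc_sd).  The
#' expected reads for isoform i in sample j are
#' reads_per_gene x k_i^(e(j)) L_i / sum_i' k0_i' L_i' (baseline-anchored so
#' fold changes move the gene total), and the realised reads are
#' NB(mean, size = mean / c), the per-transcript dispersion convention.
#'
#' @param models An \code{sgnb_models}.
#' @param design An \code{sgnb_design}.
#' @param config An \code{sgnb_sim_config}.
#' @param seed Integer seed.
#' @return List of class \code{sgnb_copies}: per gene, \code{k0}, \code{k1},
#'   \code{lfc}, \code{de}, and \code{reads} (isoforms x samples integer
#'   matrix).
#' @export
draw_copy_numbers <- function(models, design, config = models$config,
                              seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  size_k <- config$copy_mean^2 / (config$copy_var - config$copy_mean)
  J <- length(design)
  out <- lapply(models$genes, function(m) {
    I <- length(m$isoforms)
    L <- vapply(m$isoforms, function(ch) sum(m$exon_len[ch]), numeric(1))
    if (!is.null(m$k0)) {
      k0 <- m$k0; k1 <- m$k1; de <- TRUE; lfc <- log2(pmax(k1, 1e-9) / pmax(k0, 1e-9))
    } else {
      k0 <- rnbinom(I, mu = config$copy_mean, size = size_k)
      de <- runif(1) < config$de_fraction
      lfc <- if (de) rnorm(I, config$lfc_mean, config$lfc_sd) else numeric(I)
      k1 <- k0 * 2^lfc
    }
    base_total <- sum(k0 * L)
    reads <- matrix(0L, I, J, dimnames = list(NULL, names(design)))
    if (base_total > 0) {
      for (j in seq_len(J)) {
        k <- if (design[j] == 0L) k0 else k1
        mu <- config$reads_per_gene * k * L / base_total
        pos <- mu > 0
        reads[pos, j] <- rnbinom(sum(pos), mu = mu[pos],
                                 size = mu[pos] / config$dispersion_const)
      }
    }
    list(k0 = k0, k1 = k1, lfc = lfc, de = de, reads = reads)
  })
  structure(out, class = "sgnb_copies")
}

#' Simulate reads mechanistically and tally read types
#'
#' For every isoform and sample, draws the realised number of reads (from
#' \code{\link{draw_copy_numbers}}), gives each read a fragment of length
#' Normal(frag_mean, frag_sd) truncated to [read_len, transcript length], a
#' uniform fragment start, and sequences the leftmost read_len bases; the
#' covered exon chain (the same walk as
#' \code{\link{enumerate_start_positions}}) is the read's type.  The
#' returned table is the simulator's own truth tally; optionally the reads
#' are also written as pre-aligned SAM records, one file per sample, so the
#' alignment-facing code path can be exercised end to end.
#'
#' @param models An \code{sgnb_models}.
#' @param copies An \code{sgnb_copies}.
#' @param design An \code{sgnb_design}.
#' @param config An \code{sgnb_sim_config}.
#' @param seed Integer seed.
#' @param sam_dir Optional directory; when given, per-sample SAM files
#'   \code{<sample>.sam} are written and their paths returned.
#' @return List: \code{table} (an \code{sgnb_counts}), \code{truth}
#'   (data.frame gene_id, type, isoform-generated tally identical to the
#'   table rows), \code{sam_files} (or NULL).
#' @export
simulate_reads_mechanistic <- function(models, copies, design,
                                       config = models$config, seed = 1L,
                                       sam_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- length(design)
  samp <- names(design)
  rows_gene <- character(0); rows_type <- character(0)
  count_blocks <- list()
  sam_records <- if (!is.null(sam_dir)) vector("list", 0L) else NULL
  rl <- config$read_len
  for (g in names(models$genes)) {
    m <- models$genes[[g]]
    cp <- copies[[g]]
    # possible (first, last) exon-position pairs per isoform -> type labels
    gene_counts <- NULL
    gene_types <- character(0)
    acc <- new.env(parent = emptyenv())
    for (i in seq_along(m$isoforms)) {
      chain <- m$isoforms[[i]]
      le <- m$exon_len[chain]
      L <- sum(le)
      if (L < rl) next
      cum <- cumsum(le)
      n_j <- cp$reads[i, ]
      tot <- sum(n_j)
      if (tot == 0L) next
      # the read is the leftmost rl bases of its fragment, so the fragment
      # length (Normal(frag_mean, frag_sd), truncated below at rl) never
      # changes which bases are read: any position with room for a read can
      # start one, and read starts are uniform over the usable length --
      # the sampling law the read-type model assumes
      s <- 1L + floor(runif(tot) * (L - rl + 1))
      f <- findInterval(s - 1L, cum) + 1L
      l <- findInterval(s + rl - 2L, cum) + 1L
      K <- length(chain)
      pairkey <- (f - 1L) * K + l
      jidx <- rep(seq_len(J), n_j)
      combo <- (jidx - 1L) * (K * K) + pairkey
      tab <- tabulate(combo, nbins = J * K * K)
      dim(tab) <- c(K * K, J)
      used <- which(rowSums(tab) > 0L)
      for (u in used) {
        ff <- (u - 1L) %/% K + 1L
        ll <- (u - 1L) %% K + 1L
        lbl <- chain_label(chain[ff:ll])
        prev <- if (exists(lbl, envir = acc, inherits = FALSE))
          get(lbl, envir = acc) else numeric(J)
        assign(lbl, prev + tab[u, ], envir = acc)
      }
      if (!is.null(sam_dir)) {
        sam_records[[length(sam_records) + 1L]] <-
          sam_lines_for_reads(m, chain, s, jidx, rl, g, i)
      }
    }
    gene_types <- ls(acc)
    if (length(gene_types) == 0L) next
    gene_counts <- t(vapply(gene_types, get, numeric(J), envir = acc))
    ord <- chain_order(gene_types)
    count_blocks[[g]] <- gene_counts[ord, , drop = FALSE]
    rows_gene <- c(rows_gene, rep(g, length(gene_types)))
    rows_type <- c(rows_type, gene_types[ord])
  }
  counts <- do.call(rbind, count_blocks)
  colnames(counts) <- samp
  lib_sizes <- colSums(counts)
  table <- count_table(counts, rows_gene, rows_type, lib_sizes)
  sam_files <- NULL
  if (!is.null(sam_dir)) {
    sam_files <- write_sim_sam(sam_records, models, samp, sam_dir, rl)
  }
  list(table = table,
       truth = data.frame(gene_id = rows_gene, type = rows_type,
                          stringsAsFactors = FALSE),
       sam_files = sam_files)
}

# transcript interval -> genomic blocks and SAM fields for simulated reads
sam_lines_for_reads <- function(m, chain, starts, jidx, read_len, gene, iso) {
  le <- m$exon_len[chain]
  cum <- c(0L, cumsum(le))
  recs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    s <- starts[r]; e <- s + read_len - 1L
    f <- findInterval(s - 1L, cum[-1L]) + 1L
    l <- findInterval(e - 1L, cum[-1L]) + 1L
    cigar <- character(0)
    pos0 <- NA_integer_
    for (k in f:l) {
      exon <- chain[k]
      a <- max(s, cum[k] + 1L); b <- min(e, cum[k + 1L])
      gstart <- m$exon_start[exon] + (a - cum[k] - 1L)
      gend <- m$exon_start[exon] + (b - cum[k] - 1L)
      if (is.na(pos0)) pos0 <- gstart
      else {
        prev_exon <- chain[k - 1L]
        gap <- gstart - (m$exon_start[prev_exon] + m$exon_len[prev_exon])
        cigar <- c(cigar, paste0(gap, "N"))
      }
      cigar <- c(cigar, paste0(gend - gstart + 1L, "M"))
    }
    recs[[r]] <- c(j = jidx[r], pos = pos0,
                   cigar = paste(cigar, collapse = ""))
  }
  data.frame(j = vapply(recs, function(x) as.integer(x[["j"]]), integer(1)),
             chrom = m$chrom,
             pos = vapply(recs, function(x) as.integer(x[["pos"]]), integer(1)),
             cigar = vapply(recs, function(x) x[["cigar"]], character(1)),
             gene = gene, iso = iso, stringsAsFactors = FALSE)
}

write_sim_sam <- function(sam_records, models, samples, dir, read_len) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all <- do.call(rbind, sam_records)
  chrom_end <- max(vapply(models$genes, function(m)
    max(m$exon_start + m$exon_len), numeric(1))) + 1000
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", models$genes[[1]]$chrom,
                     "\tLN:", format(chrom_end, scientific = FALSE)))
  files <- character(0)
  seq_str <- strrep("A", read_len)
  qual <- strrep("I", read_len)
  for (j in seq_along(samples)) {
    sub <- all[all$j == j, , drop = FALSE]
    path <- file.path(dir, paste0(samples[j], ".sam"))
    lines <- header
    if (nrow(sub) > 0L) {
      lines <- c(lines, sprintf(
        "r%s_%d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
        sub$gene, seq_len(nrow(sub)), sub$chrom, sub$pos, sub$cigar,
        seq_str, qual))
    }
    writeLines(lines, path)
    files[samples[j]] <- path
  }
  files
}

#' Model-based NB count simulation (fast path)
#'
#' Samples X_hj ~ NB(N_j theta_h, phi) directly at the read-type level --
#' the marginal model the estimators assume -- for estimator recovery
#' tests.  phi = 0 samples Poisson.
#'
#' @param theta Vector of per-type relative expression levels.
#' @param lib_sizes Named per-sample library sizes.
#' @param phi Dispersion, >= 0.
#' @param seed Integer seed.
#' @return Numeric matrix, types x samples.
#' @export
simulate_counts_model <- function(theta, lib_sizes, phi, seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  H <- length(theta); J <- length(lib_sizes)
  mu <- outer(theta, lib_sizes)
  x <- if (phi < POIS_PHI) rpois(H * J, mu) else
    rnbinom(H * J, mu = mu, size = 1 / phi)
  matrix(x, H, J, dimnames = list(names(theta), names(lib_sizes)))
}

#' Assemble a complete simulated experiment
#'
#' Convenience wrapper: generate (or accept) gene models, draw copies,
#' simulate reads mechanistically, and return everything the pipeline
#' needs.  When \code{switch_gene} is TRUE the last gene is replaced by the
#' two-isoform switch gene of \code{\link{make_switch_gene}}.
#'
#' @param config An \code{sgnb_sim_config}.
#' @param seed Integer seed.
#' @param switch_gene Include the isoform-switch gene?
#' @param models Optional pre-built \code{sgnb_models}.
#' @param sam_dir Optional SAM output directory.
#' @return List: \code{models}, \code{design}, \code{copies}, \code{table},
#'   \code{truth}, \code{flat}, \code{sam_files}, \code{switch_id}.
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1L,
                                switch_gene = FALSE, models = NULL,
                                sam_dir = NULL) {
  set.seed(seed)
  if (is.null(models)) {
    models <- generate_gene_models(config$n_genes, config, seed = NULL)
    if (switch_gene) {
      sw <- make_switch_gene("gene_switch",
                             at = 2e6L)
      models$genes[[length(models$genes)]] <- NULL
      models$genes[[sw$gene_id]] <- sw
      # the switch design: one DE gene, all background genes null
      config$de_fraction <- 0
    }
  }
  J <- config$samples_per_condition
  design <- design_info(stats::setNames(rep(c(0L, 1L), each = J),
                                        sprintf("s%02d", seq_len(2L * J))))
  copies <- draw_copy_numbers(models, design, config, seed = NULL)
  sim <- simulate_reads_mechanistic(models, copies, design, config,
                                    seed = NULL, sam_dir = sam_dir)
  list(models = models, design = design, copies = copies,
       table = sim$table, truth = sim$truth, flat = models_to_flat(models),
       sam_files = sim$sam_files,
       switch_id = if (switch_gene) "gene_switch" else NULL)
}
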