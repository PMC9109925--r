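#' Read-type count table
#'
#' The central container: one row per (gene, read type), one column per
#' sample, integer (or pseudo, real-valued) counts, plus per-sample library
#' sizes (total mapped reads, not only exonic ones).
#'
#' @param counts Numeric matrix, rows = (gene, type) pairs, columns = samples
#'   (column names are sample IDs).
#' @param gene Character vector of gene IDs, one per row.
#' @param type Character vector of read-type chains ("1-2") or group labels
#'   ("1+1-2"), one per row.
#' @param lib_sizes Named numeric vector of per-sample total mapped reads.
#' @return An object of class \code{sgnb_counts}.
#' @export
count_table <- function(counts, gene, type, lib_sizes) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(gene), nrow(counts) == length(type))
  if (is.null(colnames(counts))) colnames(counts) <- names(lib_sizes)
  lib_sizes <- lib_sizes[colnames(counts)]
  if (any(is.na(lib_sizes)) || any(lib_sizes <= 0))
    stop("library sizes must be positive for every sample column")
  if (any(counts < 0)) stop("negative counts")
  structure(list(counts = counts, gene = as.character(gene),
                 type = as.character(type), lib_sizes = lib_sizes),
            class = "sgnb_counts")
}

#' @export
print.sgnb_counts <- function(x, ...) {
  cat("sgnb_counts:", nrow(x$counts), "read-type rows,",
      length(unique(x$gene)), "genes,", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Write / read a count table as TSV
#'
#' Columns: gene_id, read_type, then one column per sample.  Library sizes
#' travel in a companion header line prefixed \code{#lib_sizes}.
#'
#' @param table An \code{sgnb_counts} object.
#' @param path File path.
#' @return \code{write_count_table}: \code{path} invisibly;
#'   \code{read_count_table}: an \code{sgnb_counts}.
#' @export
write_count_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#lib_sizes\t", paste(names(table$lib_sizes),
                                          table$lib_sizes,
                                          sep = "=", collapse = "\t")), con)
  df <- data.frame(gene_id = table$gene, read_type = table$type,
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#lib_sizes\t")) stop("missing #lib_sizes header")
  kv <- strsplit(strsplit(sub("^#lib_sizes\t", "", first), "\t")[[1]], "=")
  lib_sizes <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                               vapply(kv, `[`, "", 1L))
  df <- read.delim(path, skip = 1L, check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  count_table(counts, gene = df$gene_id, type = df$read_type,
              lib_sizes = lib_sizes)
}

#' Two-condition design
#'
#' @param condition Named vector (names = sample IDs) of condition labels
#'   coercible to 0/1.
#' @return Named integer vector of 0/1 with class \code{sgnb_design}.
#' @export
design_info <- function(condition) {
  cond <- as.integer(condition)
  if (!all(cond %in% c(0L, 1L))) stop("conditions must be 0 or 1")
  names(cond) <- names(condition)
  if (sum(cond == 0L) < 2L || sum(cond == 1L) < 2L)
    stop("each condition needs at least 2 samples")
  structure(cond, class = "sgnb_design")
}

#' Extract aligned match blocks from a BAM/SAM file
#'
#' Keeps mapped, primary, non-supplementary alignments; splits each
#' alignment into match blocks at junction (\code{N}) gaps; soft/hard clips
#' are excluded and small insertions/deletions are absorbed into the
#' enclosing block.  SAM files are converted on the fly.
#'
#' @param path BAM or SAM file.
#' @return List with \code{blocks} (a \code{GRangesList}, one element per
#'   kept read), \code{n_mapped} (number of kept primary alignments) and
#'   \code{n_discarded} (named tally of discard reasons).
#' @export
blocks_from_alignment <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
    path <- bam
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags)
  aln <- GenomicAlignments::readGAlignments(path, param = param,
                                            use.names = TRUE)
  total <- Rsamtools::countBam(path)$records
  blocks <- GenomicAlignments::grglist(aln, drop.D.ranges = FALSE)
  list(blocks = blocks, n_mapped = length(aln),
       n_discarded = c(unmapped_secondary_supplementary =
                         total - length(aln)))
}

#' Assign read types to aligned reads of one sample
#'
#' A read gets the type whose chain is the ordered set of distinct flat-exon
#' IDs its blocks overlap, provided every base of every block lies inside
#' flat exons of exactly one gene.  Otherwise the read is discarded, with the
#' reason tallied: \code{no_gene} (no exonic overlap at all),
#' \code{multi_gene} (exons of more than one gene touched), or
#' \code{outside_exons} (partial overlap, e.g. hanging into an intron).
#'
#' @param blocks \code{GRangesList} of match blocks per read.
#' @param flat Flat annotation \code{data.frame}.
#' @return List with \code{types} (data.frame \code{gene_id}, \code{type},
#'   \code{count}) and \code{discards} (named tally).
#' @export
assign_read_types <- function(blocks, flat) {
  exons <- GenomicRanges::GRanges(
    flat$chrom,
    IRanges::IRanges(flat$start, flat$end),
    gene_id = flat$gene_id, exon_id = flat$exon_id)
  flat_bl <- unlist(blocks, use.names = FALSE)
  read_of <- rep(seq_along(blocks), lengths(blocks))
  ov <- GenomicRanges::findOverlaps(flat_bl, exons)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  inter_w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(flat_bl)[qh], IRanges::ranges(exons)[sh]))
  n_reads <- length(blocks)
  # per (read, gene): total intersected width; per read: total block width
  gene_hit <- flat$gene_id[sh]
  key <- paste(read_of[qh], gene_hit, sep = "\r")
  cov_by_gene <- rowsum(inter_w, key)
  kg <- strsplit(rownames(cov_by_gene), "\r", fixed = TRUE)
  r_idx <- as.integer(vapply(kg, `[`, "", 1L))
  g_idx <- vapply(kg, `[`, "", 2L)
  genes_per_read <- tabulate(r_idx, nbins = n_reads)
  block_w <- rowsum(IRanges::width(flat_bl), read_of)
  read_w <- numeric(n_reads)
  read_w[as.integer(rownames(block_w))] <- block_w[, 1L]

  status <- rep("no_gene", n_reads)
  status[genes_per_read > 1L] <- "multi_gene"
  one <- which(genes_per_read == 1L)
  cov1 <- stats::setNames(cov_by_gene[match(one, r_idx), 1L], NULL)
  full <- one[cov1 == read_w[one]]
  status[one] <- "outside_exons"
  status[full] <- "assigned"

  # chains for fully-contained single-gene reads
  discards <- table(factor(status, levels = c("assigned", "no_gene",
                                              "multi_gene", "outside_exons")))
  discards <- stats::setNames(as.integer(discards), names(discards))
  if (length(full) == 0L) {
    return(list(types = data.frame(gene_id = character(0),
                                   type = character(0), count = integer(0),
                                   stringsAsFactors = FALSE),
                discards = discards))
  }
  sel <- read_of[qh] %in% full
  df <- data.frame(read = read_of[qh][sel], gene = gene_hit[sel],
                   exon = flat$exon_id[sh][sel])
  df <- unique(df)
  df <- df[order(df$read, df$exon), ]
  chains <- vapply(split(df$exon, df$read), chain_label, character(1))
  genes <- vapply(split(df$gene, df$read), `[`, "", 1L)
  key <- paste(genes, chains, sep = "\r")
  tab <- table(key)
  gk <- strsplit(names(tab), "\r", fixed = TRUE)
  tdf <- data.frame(gene_id = vapply(gk, `[`, "", 1L),
                    type = vapply(gk, `[`, "", 2L),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  rownames(tdf) <- NULL
  list(types = tdf[order(tdf$gene_id, chain_key(tdf$type)), ],
       discards = discards)
}

#' Count read types across samples
#'
#' Runs \code{\link{blocks_from_alignment}} and
#' \code{\link{assign_read_types}} per sample and assembles the
#' \code{sgnb_counts} table.  Library size N_j is the number of mapped
#' primary alignments in sample j, whether or not they fall in exons.
#'
#' @param files Named character vector, sample ID -> BAM/SAM path.
#' @param flat Flat annotation \code{data.frame}.
#' @return List with \code{table} (an \code{sgnb_counts}) and
#'   \code{discards} (per-sample tallies).
#' @export
count_read_types <- function(files, flat) {
  if (length(files) < 1L) stop("need at least one sample")
  per <- lapply(names(files), function(s) {
    bl <- blocks_from_alignment(files[[s]])
    if (bl$n_mapped == 0L) stop("sample ", s, " has zero mapped reads")
    at <- assign_read_types(bl$blocks, flat)
    list(sample = s, lib_size = bl$n_mapped, types = at$types,
         discards = at$discards)
  })
  keys <- unique(do.call(rbind, lapply(per, function(p)
    p$types[, c("gene_id", "type")])))
  keys <- keys[order(keys$gene_id, chain_key(keys$type)), ]
  counts <- matrix(0L, nrow(keys), length(per),
                   dimnames = list(NULL, vapply(per, `[[`, "", "sample")))
  for (j in seq_along(per)) {
    p <- per[[j]]
    idx <- match(paste(p$types$gene_id, p$types$type),
                 paste(keys$gene_id, keys$type))
    counts[idx, j] <- p$types$count
  }
  lib_sizes <- stats::setNames(vapply(per, `[[`, numeric(1), "lib_size"),
                               colnames(counts))
  discards <- do.call(rbind, lapply(per, `[[`, "discards"))
  rownames(discards) <- colnames(counts)
  list(table = count_table(counts, keys$gene_id, keys$type, lib_sizes),
       discards = discards)
}
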