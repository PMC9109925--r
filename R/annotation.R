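#' @importFrom stats optimize rnbinom rnorm rpois runif dnbinom pnbinom
#'   qnbinom dbinom dpois ppois p.adjust rmultinom
#' @importFrom utils read.delim write.table
NULL

#' Parse exon records from a GTF/GFF2 annotation
#'
#' Reads an annotation file and extracts, for every gene, the genomic
#' intervals of its exon features.  Only records whose feature type is
#' \code{"exon"} are kept; duplicate identical intervals within a gene are
#' collapsed.  Coordinates are 1-based inclusive (the GTF convention).
#'
#' Lines that do not have the nine tab-separated GTF columns, or whose
#' attribute field carries no \code{gene_id}, are skipped with a warning so
#' that one malformed record does not abort a whole run.
#'
#' @param path Path to a GTF/GFF2 file.
#' @return A named list, one element per gene, each a \code{data.frame} with
#'   columns \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @export
parse_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("annotation contains no records")
  nfield <- lengths(regmatches(lines, gregexpr("\t", lines))) + 1L
  bad <- nfield < 9L
  if (any(bad)) {
    warning(sum(bad), " malformed annotation line(s) skipped")
    lines <- lines[!bad]
  }
  if (length(lines) == 0L) stop("annotation contains no exon records")
  tmp <- tempfile(fileext = ".gtf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  gr <- rtracklayer::import(tmp, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) stop("annotation contains no exon records")
  gid <- as.character(gr$gene_id)
  no_gene <- is.na(gid) | !nzchar(gid)
  if (any(no_gene)) {
    warning(sum(no_gene), " exon record(s) without gene_id skipped")
    gr <- gr[!no_gene]
    gid <- gid[!no_gene]
  }
  if (length(gr) == 0L) stop("annotation contains no exon records")
  df <- data.frame(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  out <- lapply(split(df[, -1L], df$gene_id), function(d) {
    d <- unique(d)
    rownames(d) <- NULL
    d
  })
  out[order(names(out))]
}

#' Flatten possibly-overlapping exons into non-overlapping exons
#'
#' Converts one gene's exon intervals into the minimal set of disjoint
#' intervals whose union equals the union of the inputs, split at every
#' breakpoint where the set of covering input exons changes.  The flat exons
#' are numbered 1..E left to right along the genome, so a read overlapping
#' any base has exactly one exon ID per base and read types are unambiguous.
#'
#' Strand is recorded but ignored for numbering: IDs always increase with
#' genomic coordinate.
#'
#' @param intervals \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive) and optionally \code{strand}; all rows on
#'   one chromosome.
#' @return \code{data.frame} with columns \code{exon_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, sorted by \code{start}.
#' @export
flatten_exons <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) stop("no exon intervals to flatten")
  if (length(unique(intervals$chrom)) != 1L)
    stop("exons of one gene must lie on one chromosome")
  if (any(intervals$start > intervals$end)) stop("interval with start > end")
  ir <- IRanges::IRanges(start = intervals$start, end = intervals$end)
  flat <- IRanges::disjoin(ir)
  strand <- if ("strand" %in% names(intervals)) intervals$strand[1L] else "."
  data.frame(
    exon_id = seq_along(flat),
    chrom = intervals$chrom[1L],
    start = IRanges::start(flat),
    end = IRanges::end(flat),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Flatten a whole annotation
#'
#' Applies \code{\link{flatten_exons}} gene by gene.  Genes are flattened
#' independently even if their exons overlap another gene's; reads falling in
#' such shared regions are discarded later, at typing time.
#'
#' @param annotation Named list of interval data.frames as returned by
#'   \code{\link{parse_annotation}}.
#' @return A flat annotation \code{data.frame} with columns \code{gene_id},
#'   \code{exon_id}, \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @export
flatten_annotation <- function(annotation) {
  pieces <- lapply(names(annotation), function(g) {
    f <- flatten_exons(annotation[[g]])
    cbind(gene_id = g, f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write / read a flat annotation as BED-like TSV
#'
#' The on-disk format is 6 columns without header: chrom, start (0-based),
#' end (exclusive), gene_id, exon_id, strand — i.e. BED coordinates, while
#' the in-memory representation stays 1-based inclusive.  Reading validates
#' the per-gene invariants (consecutive exon IDs from 1, disjoint intervals,
#' one chromosome) and fails loudly on violation.
#'
#' @param flat Flat annotation \code{data.frame} (see
#'   \code{\link{flatten_annotation}}).
#' @param path Output/input file path.
#' @return \code{write_flat_annotation}: \code{path}, invisibly.
#'   \code{read_flat_annotation}: the flat annotation \code{data.frame}.
#' @export
write_flat_annotation <- function(flat, path) {
  bed <- data.frame(
    chrom = flat$chrom,
    start = flat$start - 1L,
    end = flat$end,
    gene_id = flat$gene_id,
    exon_id = flat$exon_id,
    strand = flat$strand,
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_flat_annotation
#' @export
read_flat_annotation <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "gene_id",
                                  "exon_id", "strand"))
  flat <- data.frame(
    gene_id = as.character(bed$gene_id),
    exon_id = as.integer(bed$exon_id),
    chrom = as.character(bed$chrom),
    start = as.integer(bed$start) + 1L,
    end = as.integer(bed$end),
    strand = as.character(bed$strand),
    stringsAsFactors = FALSE
  )
  validate_flat_annotation(flat)
  flat
}

validate_flat_annotation <- function(flat) {
  for (g in unique(flat$gene_id)) {
    d <- flat[flat$gene_id == g, ]
    d <- d[order(d$start), ]
    if (!identical(sort(d$exon_id), seq_len(nrow(d))))
      stop("gene ", g, ": exon IDs are not consecutive 1..E")
    if (!identical(d$exon_id, seq_len(nrow(d))))
      stop("gene ", g, ": exon IDs do not increase with genomic start")
    if (length(unique(d$chrom)) != 1L)
      stop("gene ", g, ": exons on multiple chromosomes")
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))
      stop("gene ", g, ": overlapping flat exons")
    if (any(d$start > d$end)) stop("gene ", g, ": start > end")
  }
  invisible(flat)
}

# exon lengths of one gene, in exon_id order
gene_exon_lengths <- function(flat, gene_id) {
  d <- flat[flat$gene_id == gene_id, ]
  d <- d[order(d$exon_id), ]
  d$end - d$start + 1L
}
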