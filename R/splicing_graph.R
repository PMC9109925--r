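# Read-type chains are stored as their string form, integer exon IDs joined
# by "-", e.g. "1-2-4".  Helpers below convert and order them.

#' Parse / format read-type chains
#'
#' A read type is a strictly increasing chain of flat-exon IDs, written with
#' "-" between IDs ("1-2").  \code{chain_ids} parses the string form;
#' \code{chain_label} formats an integer vector; \code{chain_order} returns
#' an ordering permutation under chain lexicographic order, i.e. elementwise
#' integer comparison with a shorter prefix ranking first
#' ("1" < "1-2" < "1-3" < "2").
#'
#' @param x Character vector of chain labels, or (for \code{chain_label}) an
#'   integer vector of exon IDs.
#' @return \code{chain_ids}: list of integer vectors. \code{chain_label}:
#'   character scalar. \code{chain_order}: integer permutation.
#' @export
chain_ids <- function(x) {
  lapply(strsplit(x, "-", fixed = TRUE), as.integer)
}

#' @rdname chain_ids
#' @export
chain_label <- function(x) paste(x, collapse = "-")

# fixed-width key so plain string order == chain lexicographic order
chain_key <- function(x) {
  vapply(chain_ids(x), function(ids) paste(sprintf("%06d", ids), collapse = ""),
         character(1))
}

#' @rdname chain_ids
#' @export
chain_order <- function(x) order(chain_key(x))

#' Build the splicing graph over one gene's observed read types
#'
#' Nodes are the observed read-type chains of a single gene plus pseudo
#' \code{START} and \code{END} nodes.  A directed edge u -> v is drawn when v
#' is the immediate continuation of u: either v equals u with exactly one
#' exon ID appended after u's last ID, or v equals u with its first exon ID
#' removed.  \code{START} connects to the lexicographically smallest node
#' only, and only the largest node connects to \code{END}.  Pseudo-node
#' edges count toward node degrees.
#'
#' @param chains Character vector of observed read-type chains ("1", "1-2", ...).
#' @return An object of class \code{sgnb_graph}: list with \code{nodes}
#'   (chains in lexicographic order), \code{edges} (data.frame \code{from},
#'   \code{to}), \code{outdeg} and \code{indeg} (named integer vectors over
#'   real nodes, pseudo edges included).
#' @export
build_graph <- function(chains) {
  chains <- unique(chains)
  if (length(chains) == 0L) stop("no observed read types")
  chains <- chains[chain_order(chains)]
  ids <- chain_ids(chains)
  idx <- seq_along(chains)
  from <- character(0); to <- character(0)
  set <- new.env(hash = TRUE, parent = emptyenv())
  for (i in idx) assign(chains[i], TRUE, envir = set)
  has <- function(lbl) exists(lbl, envir = set, inherits = FALSE)
  for (i in idx) {
    u <- ids[[i]]
    # (a) append one exon ID after u's last
    cand <- chains[vapply(ids, function(v)
      length(v) == length(u) + 1L && identical(v[seq_along(u)], u), logical(1))]
    # (b) drop u's first exon ID
    if (length(u) >= 2L) {
      d <- chain_label(u[-1L])
      if (has(d)) cand <- c(cand, d)
    }
    if (length(cand)) {
      from <- c(from, rep(chains[i], length(cand)))
      to <- c(to, cand)
    }
  }
  from <- c(from, "START", chains[length(chains)])
  to <- c(to, chains[1L], "END")
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  outdeg <- table(factor(edges$from, levels = chains))
  indeg <- table(factor(edges$to, levels = chains))
  structure(list(nodes = chains, edges = edges,
                 outdeg = stats::setNames(as.integer(outdeg), chains),
                 indeg = stats::setNames(as.integer(indeg), chains)),
            class = "sgnb_graph")
}

#' Merge read types that always show together
#'
#' Two read types are merged when they are connected by an edge u -> v with
#' out-degree(u) = in-degree(v) = 1: any isoform generating one must then
#' generate the other, so their rows in the type-by-isoform probability
#' matrix are proportional and a single test on their sum loses nothing.
#' Merging is closed transitively along such chains; all remaining nodes are
#' singleton groups.
#'
#' @param graph An \code{sgnb_graph} from \code{\link{build_graph}}.
#' @return List of character vectors, each a group of chains (sorted
#'   lexicographically); the list partitions the graph's nodes and is ordered
#'   by its first member.
#' @export
merge_always_together <- function(graph) {
  nodes <- graph$nodes
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  e <- graph$edges
  real <- e$from %in% nodes & e$to %in% nodes
  for (k in which(real)) {
    u <- e$from[k]; v <- e$to[k]
    if (graph$outdeg[[u]] == 1L && graph$indeg[[v]] == 1L) {
      ru <- find(match(u, nodes)); rv <- find(match(v, nodes))
      if (ru != rv) parent[ru] <- rv
    }
  }
  root <- vapply(seq_along(nodes), find, integer(1))
  groups <- split(nodes, root)
  groups <- lapply(groups, function(g) g[chain_order(g)])
  names(groups) <- NULL
  groups[chain_order(vapply(groups, `[`, character(1), 1L))]
}

#' Group label from member chains
#'
#' Members joined by \code{"+"} in lexicographic chain order, e.g.
#' \code{"1+1-2+2"}.
#' @param members Character vector of chains.
#' @return Character scalar.
#' @export
group_label <- function(members) paste(members[chain_order(members)], collapse = "+")

#' Sum a count table's rows over read-type groups
#'
#' @param table An \code{sgnb_counts} object (see
#'   \code{\link{count_table}}).
#' @param groups Named list: per gene, a list of chain groups as returned by
#'   \code{\link{merge_always_together}}.
#' @return A new \code{sgnb_counts} with one row per (gene, group); the
#'   \code{type} column holds the group label.  Per-sample column sums are
#'   unchanged.
#' @export
group_counts <- function(table, groups) {
  stopifnot(inherits(table, "sgnb_counts"))
  rows_gene <- character(0); rows_type <- character(0)
  mat <- NULL
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- names(groups)[gi]
    sel <- table$gene == g
    if (!any(sel)) stop("gene ", g, " absent from count table")
    sub <- table$counts[sel, , drop = FALSE]
    rownames(sub) <- table$type[sel]
    grs <- groups[[gi]]
    covered <- unlist(grs)
    if (!setequal(covered, rownames(sub)) || anyDuplicated(covered))
      stop("groups do not partition the observed read types of gene ", g)
    m <- t(vapply(grs, function(members) {
      colSums(sub[members, , drop = FALSE])
    }, numeric(ncol(sub))))
    if (ncol(sub) == 1L) m <- matrix(m, ncol = 1L)  # vapply drops dim
    out[[gi]] <- list(gene = rep(g, length(grs)),
                      type = vapply(grs, group_label, character(1)),
                      counts = m)
  }
  counts <- do.call(rbind, lapply(out, `[[`, "counts"))
  colnames(counts) <- colnames(table$counts)
  count_table(counts,
              gene = unlist(lapply(out, `[[`, "gene")),
              type = unlist(lapply(out, `[[`, "type")),
              lib_sizes = table$lib_sizes)
}

#' Merge the read types of every gene in a count table
#'
#' Convenience wrapper: per gene, builds the splicing graph over the
#' observed types (total count >= 1), merges always-showing-together types
#' and sums the counts.
#'
#' @param table An \code{sgnb_counts} object.
#' @return List with \code{table} (grouped \code{sgnb_counts}) and
#'   \code{groups} (per-gene list of chain groups).
#' @export
merge_count_table <- function(table) {
  genes <- unique(table$gene)
  groups <- lapply(genes, function(g) {
    merge_always_together(build_graph(table$type[table$gene == g]))
  })
  names(groups) <- genes
  list(table = group_counts(table, groups), groups = groups)
}

#' Write a splicing graph in DOT format
#'
#' @param graph An \code{sgnb_graph}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_graph_dot <- function(graph, path) {
  lines <- c("digraph splicing_graph {",
             sprintf("  \"%s\" -> \"%s\";", graph$edges$from, graph$edges$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}
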