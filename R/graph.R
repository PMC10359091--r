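## Promoter-promoter spatial-interaction graph for one (cell, chromosome):
## nodes carry sequence encodings, edges carry 23-value Hi-C features, and
## every node has a 1000-length base-pair methylation target with a mask.

#' Default sequence encoder: L1-normalized overlapping k-mer frequencies
#'
#' Returns an encoder function suitable for [assemble_graph()]. The default
#' k = 6 yields a 4096-length vector; k-mers containing `N` are skipped. The
#' encoder interface accepts any replacement function with a fixed output
#' dimension (attribute `out_dim`).
#'
#' @param k k-mer size.
#' @return function(seq, strand, clipped) -> numeric vector of length `4^k`.
#' @export
make_kmer_encoder <- function(k = 6) {
  f <- function(seq, strand = "+", clipped = FALSE)
    encode_node_sequence(seq, strand, k = k, clipped = clipped)
  attr(f, "out_dim") <- 4L^k
  f
}

#' Encode a promoter sequence as k-mer frequencies
#'
#' For a minus-strand promoter the complementary bases of the stored
#' positive-strand window are encoded in positive-strand 5'-to-3' order, i.e.
#' the sequence is complemented but not reversed.
#'
#' @param seq character; the positive-strand sequence window (1000 bp unless
#'   `clipped`).
#' @param strand "+" or "-".
#' @param k k-mer size (default 6).
#' @param clipped set TRUE to allow windows shortened at chromosome edges.
#' @return numeric vector of length `4^k`, L1-normalized (all zero when no
#'   valid k-mer exists).
#' @export
encode_node_sequence <- function(seq, strand = "+", k = 6, clipped = FALSE) {
  seq <- toupper(seq)
  if (nchar(seq) != SEQ_WINDOW_WIDTH && !clipped)
    stop("sequence window must be ", SEQ_WINDOW_WIDTH,
         " bp (got ", nchar(seq), "); pass clipped = TRUE for edge regions")
  if (strand == "-") seq <- chartr("ACGT", "TGCA", seq)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  tot <- sum(counts)
  if (tot == 0) return(numeric(4L^k))
  as.numeric(counts) / tot
}

#' Edge feature for a promoter pair in a Hi-C meta-cell
#'
#' The feature has k + 3 values for a meta-cell with k neighbours (23 at the
#' default k = 20): the per-member contact counts for the pair (target cell
#' first, then neighbours in selection order), one occurrence value summarizing
#' how many members have a nonzero count for the pair, and the genomic distance
#' between the two TSSs in bp.
#'
#' @param i,j node indices (1-based, order irrelevant).
#' @param meta a `hic_metacell`.
#' @param regions the chromosome's region data.frame (node order).
#' @param chrom chromosome name.
#' @param occurrence "count" (number of members with a nonzero count; integer
#'   in `[1, k+1]`) or "fraction" (that count divided by k + 1).
#' @return numeric vector of length k + 3.
#' @export
compute_edge_feature <- function(i, j, meta, regions, chrom,
                                 occurrence = c("count", "fraction")) {
  occurrence <- match.arg(occurrence)
  agg <- meta$aggregated[[chrom]]
  if (agg[i, j] < 1) stop("(", i, ",", j, ") is not an edge: no aggregated contact")
  per_cell <- vapply(meta$member_matrices[[chrom]], function(m) m[i, j], 0)
  occ <- sum(per_cell > 0)
  if (occurrence == "fraction") occ <- occ / length(per_cell)
  dist <- abs(regions$tss[i] - regions$tss[j])
  c(per_cell, occ, dist)
}

#' Base-pair methylation targets for one promoter
#'
#' The mask is TRUE exactly at positions that are the C or G of a CpG in the
#' reference sequence window AND are covered by the pooled meta-cell calls: a
#' plus-strand call at the C position sets the C offset, a minus-strand call
#' (cytosine on the negative strand) sets the G offset. Values are pooled
#' levels; positions with mask FALSE carry NA.
#'
#' @param meth_meta a `meth_metacell`.
#' @param region one row of a region data.frame.
#' @param genome named character vector of chromosome sequences.
#' @return list with `values` (numeric 1000) and `mask` (logical 1000).
#' @export
build_targets <- function(meth_meta, region, genome) {
  values <- rep(NA_real_, SEQ_WINDOW_WIDTH)
  mask <- rep(FALSE, SEQ_WINDOW_WIDTH)
  sq <- substr(genome[[region$chrom]], region$seq_start + 1L, region$seq_end)
  off <- cpg_offsets(sq)
  if (length(off$c_off) == 0)
    return(list(values = values, mask = mask))
  pooled <- meth_meta$pooled
  pooled <- pooled[pooled$chrom == region$chrom &
                   pooled$pos >= region$seq_start &
                   pooled$pos < region$seq_end, , drop = FALSE]
  if (nrow(pooled)) {
    woff <- pooled$pos - region$seq_start + 1L  # 1-based window offset
    plus <- pooled$strand == "+" & woff %in% off$c_off
    minus <- pooled$strand == "-" & woff %in% off$g_off
    sel <- plus | minus
    if (any(sel)) {
      mask[woff[sel]] <- TRUE
      values[woff[sel]] <- pooled$level[sel]
    }
  }
  list(values = values, mask = mask)
}

#' Assemble the promoter graph for one (cell, chromosome)
#'
#' Nodes are the chromosome's promoters in TSS order; an undirected edge
#' (i, j) exists iff the aggregated meta-cell contact count is at least 1.
#'
#' @param hic_meta `hic_metacell` for the cell.
#' @param meth_meta `meth_metacell` for the cell.
#' @param chrom chromosome name.
#' @param regions_by_chrom named list of region data.frames.
#' @param genome named character vector of sequences.
#' @param encoder sequence encoder from [make_kmer_encoder()] (or compatible).
#' @param occurrence passed to [compute_edge_feature()].
#' @return a `promoter_graph`: list with `cell_id`, `chrom`, `node_features`
#'   (n x D), `edges` (m x 2 integer matrix, i < j), `edge_features` (m x
#'   (k+3)), `targets` (n x 1000), `mask` (n x 1000 logical), `regions`.
#' @export
assemble_graph <- function(hic_meta, meth_meta, chrom, regions_by_chrom,
                           genome, encoder = make_kmer_encoder(),
                           occurrence = "count") {
  regions <- regions_by_chrom[[chrom]]
  n <- nrow(regions)
  dim_expect <- attr(encoder, "out_dim")
  node_features <- NULL
  for (r in seq_len(n)) {
    sq <- substr(genome[[chrom]], regions$seq_start[r] + 1L, regions$seq_end[r])
    v <- encoder(sq, regions$strand[r], regions$clipped[r])
    if (is.null(node_features))
      node_features <- matrix(0, n, length(v))
    else if (length(v) != ncol(node_features))
      stop("encoder output dimension changed between nodes")
    node_features[r, ] <- v
  }
  if (is.null(node_features))
    node_features <- matrix(0, 0, dim_expect %||% 0)
  agg <- hic_meta$aggregated[[chrom]]
  idx <- which(upper.tri(agg) & agg >= 1, arr.ind = TRUE)
  edges <- matrix(as.integer(idx), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  edge_features <- if (nrow(edges) == 0)
    matrix(0, 0, length(hic_meta$member_ids) + 2L)
  else t(apply(edges, 1, function(e)
    compute_edge_feature(e[1], e[2], hic_meta, regions, chrom, occurrence)))
  targets <- matrix(NA_real_, n, SEQ_WINDOW_WIDTH)
  mask <- matrix(FALSE, n, SEQ_WINDOW_WIDTH)
  for (r in seq_len(n)) {
    tg <- build_targets(meth_meta, regions[r, ], genome)
    targets[r, ] <- tg$values
    mask[r, ] <- tg$mask
  }
  structure(list(cell_id = hic_meta$target_cell_id, chrom = chrom,
                 node_features = node_features, edges = edges,
                 edge_features = edge_features, targets = targets,
                 mask = mask, regions = regions),
            class = "promoter_graph")
}

#' @export
print.promoter_graph <- function(x, ...) {
  cat("<promoter_graph>", x$cell_id, x$chrom, "|",
      nrow(x$node_features), "nodes,", nrow(x$edges), "edges,",
      sum(x$mask), "masked target positions\n")
  invisible(x)
}

#' Node degrees of a promoter graph
#' @param graph a `promoter_graph`.
#' @return integer vector, one entry per node.
#' @export
graph_degrees <- function(graph) {
  n <- nrow(graph$node_features)
  tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = n)
}
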