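## Meta-cell construction: pool a target cell with its most similar cells to
## densify sparse single-cell Hi-C contacts and methylation calls.

#' Promoter-promoter contact matrix for one cell and chromosome
#'
#' `counts[i, j]` is the number of contacts with one end inside region i's
#' contact window and the other inside region j's contact window (i != j).
#' When contact windows overlap, a contact increments every qualifying
#' unordered promoter pair. The diagonal is zero.
#'
#' @param cell a `cell` object (or anything with a `contacts` data.frame).
#' @param regions target regions of a single chromosome, sorted by TSS.
#' @return symmetric integer matrix with attributes `cell_id` and `chrom`.
#' @export
build_promoter_contact_matrix <- function(cell, regions) {
  if (length(unique(regions$chrom)) > 1)
    stop("regions must come from a single chromosome")
  chrom <- regions$chrom[1]
  n <- nrow(regions)
  counts <- matrix(0L, n, n)
  contacts <- cell$contacts
  contacts <- contacts[contacts$chrom1 == chrom & contacts$chrom2 == chrom, ,
                       drop = FALSE]
  if (nrow(contacts) > 0 && n > 0) {
    win <- IRanges::IRanges(start = regions$contact_start + 1L,
                            end = regions$contact_end)  # 1-based closed
    hit_regions <- function(pos) {
      q <- IRanges::IRanges(start = pos + 1L, width = 1L)
      ov <- IRanges::findOverlaps(q, win)
      data.frame(contact = S4Vectors::queryHits(ov),
                 region = S4Vectors::subjectHits(ov))
    }
    ha <- hit_regions(contacts$pos1)
    hb <- hit_regions(contacts$pos2)
    if (nrow(ha) && nrow(hb)) {
      pairs <- merge(ha, hb, by = "contact")
      pairs <- pairs[pairs$region.x != pairs$region.y, , drop = FALSE]
      if (nrow(pairs)) {
        i <- pmin(pairs$region.x, pairs$region.y)
        j <- pmax(pairs$region.x, pairs$region.y)
        key <- paste(pairs$contact, i, j)
        dupes <- duplicated(key)
        i <- i[!dupes]; j <- j[!dupes]
        tab <- table(paste(i, j))
        ij <- do.call(rbind, strsplit(names(tab), " "))
        ii <- as.integer(ij[, 1]); jj <- as.integer(ij[, 2])
        counts[cbind(ii, jj)] <- as.integer(tab)
        counts[cbind(jj, ii)] <- as.integer(tab)
      }
    }
  }
  attr(counts, "cell_id") <- cell$cell_id
  attr(counts, "chrom") <- chrom
  counts
}

#' Genome-wide binned contact vector of a cell
#'
#' Bins both contact ends at `bin_size` and counts occurrences of canonical
#' bin pairs. Used by [hic_cell_similarity()].
#'
#' @keywords internal
contact_bin_keys <- function(cell, bin_size) {
  ct <- cell$contacts
  if (nrow(ct) == 0) stop("cell ", cell$cell_id, " has no contacts")
  b1 <- ct$pos1 %/% bin_size
  b2 <- ct$pos2 %/% bin_size
  paste(ct$chrom1, b1, ct$chrom2, b2, sep = ":")
}

#' Cosine similarity of two cells' binned Hi-C contact profiles
#'
#' @param a,b `cell` objects with at least one contact each.
#' @param bin_size bin width in bp (default 1 Mb).
#' @return cosine similarity in `[0, 1]` (counts are non-negative).
#' @export
hic_cell_similarity <- function(a, b, bin_size = 1e6) {
  ka <- table(contact_bin_keys(a, bin_size))
  kb <- table(contact_bin_keys(b, bin_size))
  keys <- union(names(ka), names(kb))
  va <- as.numeric(ka[keys]); va[is.na(va)] <- 0
  vb <- as.numeric(kb[keys]); vb[is.na(vb)] <- 0
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' Pairwise Hi-C similarity matrix over a list of cells
#'
#' Same metric as [hic_cell_similarity()], computed once for all pairs.
#'
#' @param cells list of `cell` objects.
#' @param bin_size bin width in bp.
#' @return symmetric matrix with cell ids as dimnames.
#' @export
hic_similarity_matrix <- function(cells, bin_size = 1e6) {
  tabs <- lapply(cells, function(cl) table(contact_bin_keys(cl, bin_size)))
  keys <- unique(unlist(lapply(tabs, names)))
  M <- matrix(0, length(cells), length(keys))
  for (i in seq_along(tabs)) {
    v <- as.numeric(tabs[[i]][keys]); v[is.na(v)] <- 0
    M[i, ] <- v
  }
  M <- M / sqrt(rowSums(M^2))
  S <- tcrossprod(M)
  ids <- vapply(cells, `[[`, "", "cell_id")
  dimnames(S) <- list(ids, ids)
  S
}

#' Select Hi-C neighbours and build an aggregated meta-cell
#'
#' Picks the `k` cells most similar to the target (cosine over binned contact
#' profiles), ties broken by lexicographic cell id, and sums the member
#' promoter-promoter contact matrices per chromosome. For training and
#' validation cells the pool is restricted to the target's labelled cell type;
#' blind-test cells draw from the full pool.
#'
#' @param target a `cell`.
#' @param pool list of candidate `cell`s (may include the target; it is
#'   excluded automatically).
#' @param regions_by_chrom named list of per-chromosome region data.frames.
#' @param k number of neighbours (default 20; the edge feature length is
#'   k + 3).
#' @param restrict_to_type if TRUE, only candidates sharing the target's type
#'   are eligible.
#' @param bin_size similarity bin width in bp.
#' @param sims optional precomputed similarity matrix from
#'   [hic_similarity_matrix()] covering target and pool.
#' @param matrices optional precomputed per-cell contact matrices:
#'   `matrices[[cell_id]][[chrom]]`.
#' @return a `hic_metacell`: list with `target_cell_id`, `neighbor_ids`,
#'   `member_ids` (target first), `member_matrices` and `aggregated` (both
#'   named lists by chromosome).
#' @export
select_hic_neighbors <- function(target, pool, regions_by_chrom, k = 20,
                                 restrict_to_type = FALSE, bin_size = 1e6,
                                 sims = NULL, matrices = NULL) {
  ids <- vapply(pool, `[[`, "", "cell_id")
  elig <- ids != target$cell_id
  if (restrict_to_type) {
    types <- vapply(pool, function(cl) cl$cell_type %||% NA_character_, "")
    elig <- elig & !is.na(types) & types == target$cell_type
  }
  cand <- pool[elig]
  if (length(cand) < k)
    stop("need ", k, " eligible neighbour cells but only ", length(cand),
         " available for target ", target$cell_id)
  cand_ids <- ids[elig]
  sim <- if (!is.null(sims)) sims[target$cell_id, cand_ids]
         else vapply(cand, function(cl)
           hic_cell_similarity(target, cl, bin_size), 0)
  ord <- order(-sim, cand_ids)
  sel <- ord[seq_len(k)]
  neighbors <- cand[sel]
  neighbor_ids <- cand_ids[sel]
  members <- c(list(target), neighbors)
  member_ids <- c(target$cell_id, neighbor_ids)

  get_matrix <- function(cl, chrom)
    if (!is.null(matrices)) matrices[[cl$cell_id]][[chrom]]
    else build_promoter_contact_matrix(cl, regions_by_chrom[[chrom]])
  member_matrices <- lapply(names(regions_by_chrom), function(chrom)
    lapply(members, get_matrix, chrom = chrom))
  names(member_matrices) <- names(regions_by_chrom)
  aggregated <- lapply(member_matrices, function(ms) Reduce(`+`, ms))
  structure(list(target_cell_id = target$cell_id,
                 neighbor_ids = neighbor_ids,
                 member_ids = member_ids,
                 neighbor_similarity = sim[sel],
                 member_matrices = member_matrices,
                 aggregated = aggregated),
            class = "hic_metacell")
}

#' Cosine similarity of two cells' methylation profiles on shared sites
#'
#' Sites are keyed by (chrom, pos, strand); the similarity is the cosine of
#' the two level vectors restricted to sites covered in both cells, and 0 when
#' no site is shared (or a shared profile is all-zero).
#'
#' @param a,b `cell` objects.
#' @return similarity in `[0, 1]`.
#' @export
meth_cell_similarity <- function(a, b) {
  ka <- paste(a$meth$chrom, a$meth$pos, a$meth$strand)
  kb <- paste(b$meth$chrom, b$meth$pos, b$meth$strand)
  shared <- intersect(ka, kb)
  if (length(shared) == 0) return(0)
  va <- a$meth$level[match(shared, ka)]
  vb <- b$meth$level[match(shared, kb)]
  den <- sqrt(sum(va^2) * sum(vb^2))
  if (den == 0) return(0)
  sum(va * vb) / den
}

#' Pool methylation calls into a meta-cell
#'
#' Selects the `k` candidates with the most similar methylation profiles
#' (ties by cell id) and sums methylated and total read counts per site over
#' the target plus neighbours; the pooled level is the ratio of the sums, so
#' deeper-covered sites weigh more.
#'
#' @param target a `cell`.
#' @param pool list of candidate `cell`s.
#' @param k number of neighbours.
#' @param restrict_to_type restrict the pool to the target's cell type.
#' @return a `meth_metacell`: list with `target_cell_id`, `neighbor_ids` and
#'   `pooled` (data.frame chrom, pos, strand, n_meth, n_total, level).
#' @export
aggregate_methylation <- function(target, pool, k = 20,
                                  restrict_to_type = FALSE) {
  ids <- vapply(pool, `[[`, "", "cell_id")
  elig <- ids != target$cell_id
  if (restrict_to_type) {
    types <- vapply(pool, function(cl) cl$cell_type %||% NA_character_, "")
    elig <- elig & !is.na(types) & types == target$cell_type
  }
  cand <- pool[elig]
  if (length(cand) < k)
    stop("need ", k, " eligible neighbour cells but only ", length(cand),
         " available for target ", target$cell_id)
  cand_ids <- ids[elig]
  sim <- vapply(cand, function(cl) meth_cell_similarity(target, cl), 0)
  ord <- order(-sim, cand_ids)
  sel <- ord[seq_len(k)]
  members <- c(list(target), cand[sel])
  all_meth <- do.call(rbind, lapply(members, `[[`, "meth"))
  key <- paste(all_meth$chrom, all_meth$pos, all_meth$strand)
  n_meth <- rowsum(all_meth$n_meth, key)
  n_total <- rowsum(all_meth$n_total, key)
  first <- !duplicated(key)
  pooled <- data.frame(chrom = all_meth$chrom[first],
                       pos = all_meth$pos[first],
                       strand = all_meth$strand[first],
                       stringsAsFactors = FALSE)
  kf <- key[first]
  pooled$n_meth <- as.integer(n_meth[kf, 1])
  pooled$n_total <- as.integer(n_total[kf, 1])
  pooled$level <- pooled$n_meth / pooled$n_total
  pooled <- pooled[order(pooled$chrom, pooled$pos, pooled$strand), ,
                   drop = FALSE]
  rownames(pooled) <- NULL
  structure(list(target_cell_id = target$cell_id,
                 neighbor_ids = cand_ids[sel],
                 pooled = pooled),
            class = "meth_metacell")
}
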