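## Synthetic paired single-cell Hi-C + base-pair methylation data with
## planted cell-type structure: each cell type has promoter cliques with
## elevated contact probability, and CpG methylation probability depends on
## local sequence and on clique membership, so the Hi-C graph carries the
## type signal that the predictor must exploit.

#' Simulation configuration
#'
#' Defaults are the benchmark study conditions: 2 chromosomes with 20
#' promoters each (40 genome-wide), 4 cell types of 40 cells, strong planted
#' topology signal.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_promoters promoters per chromosome, evenly spaced TSSs.
#' @param n_cell_types number of planted cell types.
#' @param cells_per_type cells per type.
#' @param contacts_per_cell Poisson mean number of Hi-C contacts per cell.
#' @param reads_per_cpg Poisson mean read depth per CpG per cell (zero-read
#'   sites are absent, mimicking sparse single-cell coverage).
#' @param clique_size promoters per type-specific clique (per chromosome);
#'   cliques of different types are disjoint.
#' @param contact_boost multiplicative weight added to intra-clique promoter
#'   pairs when sampling contacts (0 = no topology signal).
#' @param baseline_logit baseline log-odds of methylation (negative = mostly
#'   unmethylated background, giving the observed 0/1-dominated levels).
#' @param beta_seq coefficient of the local-sequence motif score (GC content
#'   of the 7-bp context, scaled to `[-1, 1]`); type-independent.
#' @param beta_topo log-odds shift for CpGs in the cell type's own clique
#'   promoters (0 = methylation carries no type signal).
#' @param noise_sd SD of per-CpG Gaussian noise on the logit scale (shared
#'   across types, emulating unmodelled sequence context).
#' @param cpg_per_promoter expected planted CpGs per 1-kb promoter window.
#' @param tss_spacing distance between consecutive TSSs in bp.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 250000, n_promoters = 20,
                       n_cell_types = 4, cells_per_type = 40,
                       contacts_per_cell = 60, reads_per_cpg = 1.0,
                       clique_size = 5, contact_boost = 10,
                       baseline_logit = -4, beta_seq = 2, beta_topo = 8,
                       noise_sd = 0.5, cpg_per_promoter = 20,
                       tss_spacing = 12000) {
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              n_promoters = n_promoters, n_cell_types = n_cell_types,
              cells_per_type = cells_per_type,
              contacts_per_cell = contacts_per_cell,
              reads_per_cpg = reads_per_cpg, clique_size = clique_size,
              contact_boost = contact_boost, baseline_logit = baseline_logit,
              beta_seq = beta_seq, beta_topo = beta_topo, noise_sd = noise_sd,
              cpg_per_promoter = cpg_per_promoter, tss_spacing = tss_spacing)
  stopifnot(cfg$n_promoters >= 1, cfg$cells_per_type >= 1,
            cfg$clique_size * cfg$n_cell_types <= cfg$n_promoters,
            cfg$chrom_length >= 12000 + (cfg$n_promoters - 1) * cfg$tss_spacing)
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with CpG-enriched promoter windows
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; the output is deterministic given the seed.
#' @return list with `genome` (named character), `anno` (gene_id, chrom, tss,
#'   strand), `chrom_lengths`, `regions_by_chrom`.
#' @export
simulate_genome <- function(config, seed = 1) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome <- character(0)
  anno <- list()
  for (ci in seq_along(chroms)) {
    sq <- sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3))
    tss <- 6000L + (seq_len(config$n_promoters) - 1L) * config$tss_spacing
    if (any(tss + 5001L > config$chrom_length))
      stop("promoter contact windows exceed the chromosome")
    for (t in tss) {
      ## plant CpGs at even offsets inside the 1-kb sequence window
      n_cpg <- config$cpg_per_promoter
      offs <- sample(seq(t - 498L, t + 496L, by = 2L), n_cpg)
      sq[offs + 1L] <- "C"     # offs are 0-based C positions
      sq[offs + 2L] <- "G"
    }
    genome[chroms[ci]] <- paste(sq, collapse = "")
    anno[[ci]] <- data.frame(
      gene_id = sprintf("%s_gene%02d", chroms[ci], seq_along(tss)),
      chrom = chroms[ci], tss = tss,
      strand = rep(c("+", "-"), length.out = length(tss)),
      stringsAsFactors = FALSE)
  }
  anno <- do.call(rbind, anno)
  chrom_lengths <- stats::setNames(rep(config$chrom_length, length(chroms)),
                                   chroms)
  regions <- target_regions(anno, chrom_lengths)
  regions_by_chrom <- split(regions, regions$chrom)
  list(genome = genome, anno = anno, chrom_lengths = chrom_lengths,
       regions_by_chrom = regions_by_chrom)
}

## type-specific promoter cliques: type t owns promoters
## (t-1)*clique_size + 1 .. t*clique_size on every chromosome
sim_cliques <- function(config) {
  lapply(seq_len(config$n_cell_types), function(t)
    (t - 1L) * config$clique_size + seq_len(config$clique_size))
}

## per-(type, CpG site) methylation probabilities
sim_cpg_probs <- function(config, genome_obj) {
  cliques <- sim_cliques(config)
  rows <- list()
  for (chrom in names(genome_obj$regions_by_chrom)) {
    regions <- genome_obj$regions_by_chrom[[chrom]]
    sq <- genome_obj$genome[[chrom]]
    for (r in seq_len(nrow(regions))) {
      win <- substr(sq, regions$seq_start[r] + 1L, regions$seq_end[r])
      off <- cpg_offsets(win)$c_off
      if (length(off) == 0) next
      cpos <- regions$seq_start[r] + off - 1L  # 0-based C positions
      ctx <- vapply(cpos, function(p)
        substr(sq, max(1L, p - 2L), min(nchar(sq), p + 4L)), "")
      gc <- vapply(strsplit(ctx, ""), function(b)
        mean(b %in% c("C", "G")), 0)
      motif <- 2 * gc - 1
      eps <- stats::rnorm(length(cpos), sd = config$noise_sd)
      for (t in seq_len(config$n_cell_types)) {
        in_clique <- as.numeric(r %in% cliques[[t]])
        logit <- config$baseline_logit + config$beta_seq * motif +
          config$beta_topo * in_clique + eps
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, pos = cpos, promoter = r, type = t,
          motif = motif, p = stats::plogis(logit),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate cells: sparse contacts plus sparse CpG methylation calls
#'
#' Contacts of a type-`t` cell sample promoter pairs with weight
#' `1 + contact_boost` for pairs inside the type's clique and 1 otherwise;
#' end positions are uniform within each promoter's contact window. Each CpG
#' site gets `Poisson(reads_per_cpg)` reads per strand (C call on `+`, the
#' paired G position reported on `-`), methylated counts are Binomial with
#' the type/site probability, and zero-read sites are absent.
#'
#' @param config a [sim_config()].
#' @param genome_obj output of [simulate_genome()].
#' @param seed RNG seed.
#' @return list with `cells` (list of `cell` objects), `truth` (list:
#'   `cell_types` data.frame, `cpg_prob` data.frame, `cliques`).
#' @export
simulate_cells <- function(config, genome_obj, seed = 1) {
  set.seed(seed + 1L)
  cpg_prob <- sim_cpg_probs(config, genome_obj)
  cliques <- sim_cliques(config)
  chroms <- names(genome_obj$regions_by_chrom)

  ## per-chromosome promoter-pair tables and per-type sampling weights
  pair_tab <- lapply(chroms, function(chrom) {
    n <- nrow(genome_obj$regions_by_chrom[[chrom]])
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  })
  names(pair_tab) <- chroms
  pair_weights <- lapply(seq_len(config$n_cell_types), function(t)
    lapply(chroms, function(chrom) {
      pr <- pair_tab[[chrom]]
      cl <- cliques[[t]]
      1 + config$contact_boost * (pr[, 1] %in% cl & pr[, 2] %in% cl)
    }))

  n_cells <- config$n_cell_types * config$cells_per_type
  cells <- vector("list", n_cells)
  types <- rep(seq_len(config$n_cell_types), each = config$cells_per_type)
  ids <- sprintf("cell_%03d", seq_len(n_cells))
  type_names <- sprintf("type%d", types)

  for (ci in seq_len(n_cells)) {
    t <- types[ci]
    ## contacts
    n_ct <- max(1L, stats::rpois(1, config$contacts_per_cell))
    wts <- pair_weights[[t]]
    chrom_w <- vapply(wts, sum, 0)
    chrom_pick <- sample(length(chroms), n_ct, replace = TRUE,
                         prob = chrom_w)
    ct_rows <- lapply(seq_along(chroms), function(k) {
      nk <- sum(chrom_pick == k)
      if (nk == 0) return(NULL)
      regions <- genome_obj$regions_by_chrom[[chroms[k]]]
      pr <- pair_tab[[chroms[k]]]
      pick <- sample(nrow(pr), nk, replace = TRUE, prob = wts[[k]])
      i <- pr[pick, 1]; j <- pr[pick, 2]
      p1 <- regions$contact_start[i] +
        floor(stats::runif(nk) * (regions$contact_end[i] -
                                  regions$contact_start[i]))
      p2 <- regions$contact_start[j] +
        floor(stats::runif(nk) * (regions$contact_end[j] -
                                  regions$contact_start[j]))
      data.frame(chrom1 = chroms[k], pos1 = as.integer(p1),
                 chrom2 = chroms[k], pos2 = as.integer(p2),
                 stringsAsFactors = FALSE)
    })
    contacts <- canonicalize_contacts(
      do.call(rbind, ct_rows[!vapply(ct_rows, is.null, TRUE)]))

    ## methylation calls: site table for this cell's type
    st <- cpg_prob[cpg_prob$type == t, ]
    reads_c <- stats::rpois(nrow(st), config$reads_per_cpg)
    reads_g <- stats::rpois(nrow(st), config$reads_per_cpg)
    keep_c <- reads_c > 0
    keep_g <- reads_g > 0
    meth <- rbind(
      if (any(keep_c)) data.frame(
        chrom = st$chrom[keep_c], pos = st$pos[keep_c], strand = "+",
        n_meth = stats::rbinom(sum(keep_c), reads_c[keep_c], st$p[keep_c]),
        n_total = reads_c[keep_c], stringsAsFactors = FALSE),
      if (any(keep_g)) data.frame(
        chrom = st$chrom[keep_g], pos = st$pos[keep_g] + 1L, strand = "-",
        n_meth = stats::rbinom(sum(keep_g), reads_g[keep_g], st$p[keep_g]),
        n_total = reads_g[keep_g], stringsAsFactors = FALSE))
    if (is.null(meth) || nrow(meth) == 0) {
      ## enforce at least one call
      meth <- data.frame(chrom = st$chrom[1], pos = st$pos[1], strand = "+",
                         n_meth = stats::rbinom(1, 1, st$p[1]), n_total = 1L,
                         stringsAsFactors = FALSE)
    }
    meth <- meth[order(meth$chrom, meth$pos, meth$strand), , drop = FALSE]
    rownames(meth) <- NULL
    meth$level <- meth$n_meth / meth$n_total
    cells[[ci]] <- new_cell(ids[ci], type_names[ci], contacts, meth)
  }
  truth <- list(cell_types = data.frame(cell_id = ids, type = type_names,
                                        stringsAsFactors = FALSE),
                cpg_prob = cpg_prob, cliques = cliques)
  list(cells = cells, truth = truth)
}

#' Write a simulated dataset to disk in the package's file formats
#'
#' Emits a FASTA genome, a BED6 TSS annotation, one contact file and one
#' methylation file per cell (1-based positions), a manifest and the truth
#' tables.
#'
#' @param sim output of [simulate_cells()].
#' @param genome_obj output of [simulate_genome()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(sim, genome_obj, dir) {
  dir.create(file.path(dir, "cells"), recursive = TRUE, showWarnings = FALSE)
  dss <- Biostrings::DNAStringSet(genome_obj$genome)
  Biostrings::writeXStringSet(dss, file.path(dir, "genome.fa"))
  anno <- genome_obj$anno
  plus <- anno$strand == "+"
  bed <- data.frame(chrom = anno$chrom,
                    start = ifelse(plus, anno$tss, anno$tss - 999L),
                    end = ifelse(plus, anno$tss + 1000L, anno$tss + 1L),
                    name = anno$gene_id, score = 0L, strand = anno$strand)
  utils::write.table(bed, file.path(dir, "tss.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  man <- do.call(rbind, lapply(sim$cells, function(cl) {
    cpath <- file.path("cells", paste0(cl$cell_id, ".contacts.tsv"))
    mpath <- file.path("cells", paste0(cl$cell_id, ".meth.tsv"))
    ct <- cl$contacts
    utils::write.table(
      data.frame(ct$chrom1, ct$pos1 + 1L, ct$chrom2, ct$pos2 + 1L),
      file.path(dir, cpath), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    mt <- cl$meth
    utils::write.table(
      data.frame(mt$chrom, mt$pos + 1L, mt$strand, mt$n_meth, mt$n_total),
      file.path(dir, mpath), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    data.frame(cell_id = cl$cell_id, cell_type = cl$cell_type,
               contacts_path = cpath, methylation_path = mpath,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$cell_types, file.path(dir, "cell_types.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$cpg_prob, file.path(dir, "cpg_prob.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Deterministic tiny dataset for unit tests
#'
#' One chromosome, 12 promoters, 2 cell types of 25 cells, fixed seed;
#' generation takes well under a second and is byte-identical across calls.
#'
#' @return list with `config`, `genome_obj`, `cells`, `truth`.
#' @export
fixture_small <- function() {
  config <- sim_config(n_chroms = 1, chrom_length = 150000, n_promoters = 12,
                       n_cell_types = 2, cells_per_type = 25,
                       contacts_per_cell = 30, clique_size = 5,
                       tss_spacing = 12000)
  genome_obj <- simulate_genome(config, seed = 42)
  sim <- simulate_cells(config, genome_obj, seed = 42)
  list(config = config, genome_obj = genome_obj, cells = sim$cells,
       truth = sim$truth)
}
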