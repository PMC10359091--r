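## File formats and the genomic coordinate model.
##
## All coordinates are 0-based, half-open internally. Input conventions are
## declared per format: GTF is 1-based, BED is 0-based, contact-pair and
## methylation files default to 1-based but are configurable.

SEQ_WINDOW_WIDTH <- 1000L
CONTACT_FLANK <- 5000L

#' Build target-region windows around TSS anchors
#'
#' Each region carries two windows anchored on the transcription start site:
#' a 1000-bp sequence/target window `[tss - 500, tss + 500)` and a 10,001-bp
#' contact window `[tss - 5000, tss + 5001)` (5 kb on either side of the TSS
#' plus the TSS base itself). Windows are clipped to chromosome bounds and
#' flagged when clipping occurred.
#'
#' @param anno data.frame with columns `gene_id`, `chrom`, `tss` (0-based
#'   position of the TSS base) and `strand` (`"+"` or `"-"`).
#' @param chrom_lengths named integer vector of chromosome lengths, or NULL to
#'   skip right-end clipping.
#' @return data.frame of target regions, sorted by (chrom, tss), with window
#'   bounds (`seq_start`, `seq_end`, `contact_start`, `contact_end`; 0-based
#'   half-open) and a logical `clipped` column.
#' @export
target_regions <- function(anno, chrom_lengths = NULL) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(anno)))
  if (nrow(anno) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      tss = integer(), strand = character(),
                      seq_start = integer(), seq_end = integer(),
                      contact_start = integer(), contact_end = integer(),
                      clipped = logical()))
  }
  if (any(is.na(anno$strand)) || !all(anno$strand %in% c("+", "-")))
    stop("every region needs a '+' or '-' strand")
  if (any(anno$tss < 0)) stop("negative TSS coordinate")
  dup <- duplicated(anno$gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene_id(s); keeping first occurrence")
    anno <- anno[!dup, , drop = FALSE]
  }
  tss <- as.integer(anno$tss)
  half <- SEQ_WINDOW_WIDTH %/% 2L
  seq_start <- tss - half
  seq_end <- tss + half
  contact_start <- tss - CONTACT_FLANK
  contact_end <- tss + CONTACT_FLANK + 1L
  len <- if (is.null(chrom_lengths)) rep(NA_integer_, nrow(anno))
         else as.integer(chrom_lengths[anno$chrom])
  clip_lo <- pmax(0L, seq_start) != seq_start | pmax(0L, contact_start) != contact_start
  clip_hi <- !is.na(len) & (seq_end > len | contact_end > len)
  out <- data.frame(
    gene_id = as.character(anno$gene_id), chrom = as.character(anno$chrom),
    tss = tss, strand = as.character(anno$strand),
    seq_start = pmax(0L, seq_start),
    seq_end = ifelse(is.na(len), seq_end, pmin(seq_end, len)),
    contact_start = pmax(0L, contact_start),
    contact_end = ifelse(is.na(len), contact_end, pmin(contact_end, len)),
    clipped = clip_lo | clip_hi,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$tss, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a tab-separated Hi-C contact-pair file
#'
#' Expected columns: chrom1, pos1, chrom2, pos2. Lines starting with `#` are
#' headers. Records are canonicalized so that end A sorts before end B by
#' (chrom, pos).
#'
#' @param path file path.
#' @param one_based logical; whether input positions are 1-based (default).
#' @return data.frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (0-based positions).
#' @export
read_contact_pairs <- function(path, one_based = TRUE) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(chrom1 = character(), pos1 = integer(),
                      chrom2 = character(), pos2 = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("malformed contact line ", lineno[which(nf < 4)[1]],
         ": fewer than 4 fields")
  chrom1 <- vapply(fields, `[[`, "", 1L)
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  chrom2 <- vapply(fields, `[[`, "", 3L)
  pos2 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(pos1) | is.na(pos2))
  if (length(bad))
    stop("malformed contact line ", lineno[bad[1]], ": non-numeric position")
  if (one_based) { pos1 <- pos1 - 1L; pos2 <- pos2 - 1L }
  if (any(pos1 < 0 | pos2 < 0))
    stop("negative position in contact file (line ",
         lineno[which(pos1 < 0 | pos2 < 0)[1]], ")")
  canonicalize_contacts(data.frame(chrom1 = chrom1, pos1 = pos1,
                                   chrom2 = chrom2, pos2 = pos2,
                                   stringsAsFactors = FALSE))
}

#' @keywords internal
canonicalize_contacts <- function(contacts) {
  swap <- contacts$chrom2 < contacts$chrom1 |
    (contacts$chrom2 == contacts$chrom1 & contacts$pos2 < contacts$pos1)
  if (any(swap)) {
    tmp_c <- contacts$chrom1[swap]; tmp_p <- contacts$pos1[swap]
    contacts$chrom1[swap] <- contacts$chrom2[swap]
    contacts$pos1[swap] <- contacts$pos2[swap]
    contacts$chrom2[swap] <- tmp_c
    contacts$pos2[swap] <- tmp_p
  }
  contacts
}

#' Read coverage-style CpG methylation calls
#'
#' Expected columns: chrom, pos, strand, methylated reads, total reads. A
#' record on the `-` strand is a cytosine on the negative strand, i.e. it
#' reports the G position of the CpG on the positive strand. Records with zero
#' total reads are dropped with a warning.
#'
#' @param path file path.
#' @param one_based logical; whether positions are 1-based (default).
#' @return data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `n_meth`, `n_total`, `level`.
#' @export
read_methylation_calls <- function(path, one_based = TRUE) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), n_meth = integer(),
                      n_total = integer(), level = numeric())
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5)) stop("malformed methylation line: need 5 fields")
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    pos = as.integer(vapply(fields, `[[`, "", 2L)),
    strand = vapply(fields, `[[`, "", 3L),
    n_meth = as.integer(vapply(fields, `[[`, "", 4L)),
    n_total = as.integer(vapply(fields, `[[`, "", 5L)),
    stringsAsFactors = FALSE)
  if (one_based) df$pos <- df$pos - 1L
  if (any(df$pos < 0)) stop("negative position in methylation file")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$n_meth > df$n_total))
    stop("n_methylated exceeds n_total in methylation file")
  if (any(df$n_meth < 0)) stop("negative read count")
  zero <- df$n_total == 0
  if (any(zero)) {
    warning(sum(zero), " methylation record(s) with zero total reads skipped")
    df <- df[!zero, , drop = FALSE]
  }
  if (nrow(df) == 0) return(empty)
  df$level <- df$n_meth / df$n_total
  rownames(df) <- NULL
  df
}

#' Read a TSS annotation (GTF or BED6) into target regions
#'
#' The TSS is the 5' end of the feature respecting strand. GTF input is
#' filtered to `gene` records when a `type` column is present.
#'
#' @param path file path; format guessed from the extension unless given.
#' @param format one of "auto", "bed", "gtf".
#' @param chrom_lengths optional named vector for clipping.
#' @return data.frame of target regions (see [target_regions()]).
#' @export
read_tss_annotation <- function(path, format = c("auto", "bed", "gtf"),
                                chrom_lengths = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
              else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  if (length(gr) == 0)
    return(target_regions(data.frame(gene_id = character(), chrom = character(),
                                     tss = integer(), strand = character()),
                          chrom_lengths))
  if (format == "gtf" && "type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop("annotation features without strand")
  ids <- if (!is.null(gr$gene_id)) as.character(gr$gene_id)
         else if (!is.null(gr$name)) as.character(gr$name)
         else paste0("feature_", seq_along(gr))
  start0 <- BiocGenerics::start(gr) - 1L   # GRanges is 1-based
  end0 <- BiocGenerics::end(gr)            # half-open end
  tss <- ifelse(strand == "+", start0, end0 - 1L)
  target_regions(data.frame(gene_id = ids,
                            chrom = as.character(GenomicRanges::seqnames(gr)),
                            tss = tss, strand = strand,
                            stringsAsFactors = FALSE),
                 chrom_lengths)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm)) stop("duplicate contig name in FASTA: ",
                              nm[duplicated(nm)][1])
  seqs <- toupper(as.character(dss))
  names(seqs) <- nm
  seqs
}

#' Locate CpG cytosine/guanine offsets within a region's sequence window
#'
#' @keywords internal
cpg_offsets <- function(seq_window) {
  m <- gregexpr("CG", seq_window, fixed = TRUE)[[1]]
  if (m[1] == -1) return(list(c_off = integer(), g_off = integer()))
  list(c_off = as.integer(m), g_off = as.integer(m) + 1L)  # 1-based offsets
}

#' Write per-base methylation predictions as a bedGraph-style file
#'
#' One line per CpG cytosine or guanine position inside each region's sequence
#' window: chrom, start, end (0-based half-open) and the predicted level.
#'
#' @param path output path.
#' @param regions target-region data.frame (one chromosome or several).
#' @param predictions numeric matrix, one row per region, 1000 columns.
#' @param genome named character vector of chromosome sequences.
#' @return invisibly, the data.frame written.
#' @export
write_predictions <- function(path, regions, predictions, genome) {
  stopifnot(nrow(regions) == nrow(predictions))
  rows <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    sq <- substr(genome[[reg$chrom]], reg$seq_start + 1L, reg$seq_end)
    off <- cpg_offsets(sq)
    pos1 <- sort(c(off$c_off, off$g_off))       # 1-based offsets in window
    if (length(pos1) == 0) next
    val <- predictions[r, pos1]
    if (any(val < 0 | val > 1)) stop("prediction outside [0, 1]")
    start <- reg$seq_start + pos1 - 1L
    rows[[r]] <- data.frame(chrom = reg$chrom, start = start,
                            end = start + 1L, value = val,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(chrom = character(), start = integer(),
                                      end = integer(), value = numeric())
  utils::write.table(format(out, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(out)
}

#' Read a predictions file written by [write_predictions()]
#' @param path file path.
#' @return data.frame with columns chrom, start, end, value.
#' @export
read_predictions <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric"))
  out
}

#' Read a cell manifest table
#'
#' Tab-separated with header: cell_id, cell_type, contacts_path,
#' methylation_path. Paths are resolved relative to the manifest's directory.
#'
#' @param path manifest file.
#' @return data.frame.
#' @export
read_cell_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_type", "contacts_path", "methylation_path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in manifest")
  base <- dirname(path)
  rel <- !grepl("^/", df$contacts_path)
  df$contacts_path[rel] <- file.path(base, df$contacts_path[rel])
  rel <- !grepl("^/", df$methylation_path)
  df$methylation_path[rel] <- file.path(base, df$methylation_path[rel])
  df
}

#' Load one cell's contacts and methylation calls
#'
#' @param manifest_row one row of a manifest data.frame.
#' @param one_based coordinate convention of the per-cell files.
#' @return a `cell` object: list with `cell_id`, `cell_type`, `contacts`,
#'   `meth`.
#' @export
load_cell <- function(manifest_row, one_based = TRUE) {
  new_cell(manifest_row$cell_id, manifest_row$cell_type,
           read_contact_pairs(manifest_row$contacts_path, one_based),
           read_methylation_calls(manifest_row$methylation_path, one_based))
}

#' @keywords internal
new_cell <- function(cell_id, cell_type, contacts, meth) {
  structure(list(cell_id = cell_id, cell_type = cell_type,
                 contacts = contacts, meth = meth),
            class = "cell")
}

#' @export
print.cell <- function(x, ...) {
  cat("<cell>", x$cell_id, "type:", x$cell_type %||% "NA",
      "|", nrow(x$contacts), "contacts,", nrow(x$meth), "methylation calls\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
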