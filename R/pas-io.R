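# File formats and the read->PAS assignment / annotation-cleaning rules.
#
# PAS annotations travel as a BED6 dialect whose name field packs
# gene_id|pas_id|region_class; the cleavage position is the 0-based BED
# start. Counts travel as a long TSV with one row per
# sample x gene x PAS x allele channel.

#' Load PAS annotations from the BED6 dialect
#'
#' Columns: chrom, start, end, name (`gene_id|pas_id|region_class`), score,
#' strand. The cleavage position is `start` (0-based). `utr_rank` is derived
#' from coordinate order respecting strand: on the minus strand a smaller
#' coordinate is more distal (transcriptionally 3').
#'
#' @param path BED file (plain or gzip).
#' @return Validated annotation `data.frame` (see [simulate_gene_models()]
#'   for the column set).
#' @export
load_pas_annotations <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^track|^browser", lines)]
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    return(data.frame(gene_id = character(), pas_id = character(),
                      chrom = character(), strand = character(),
                      cleavage_pos = integer(), region_class = character(),
                      utr_rank = integer(), stringsAsFactors = FALSE))
  }
  rows <- vector("list", length(lines))
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L) {
      stop("malformed BED line ", i, ": expected 6 tab-separated fields")
    }
    name <- strsplit(f[4L], "|", fixed = TRUE)[[1L]]
    start <- suppressWarnings(as.integer(f[2L]))
    if (is.na(start) || length(name) != 3L || !f[6L] %in% c("+", "-")) {
      stop("malformed BED line ", i,
           ": need integer start, name 'gene|pas|class', strand +/-")
    }
    rows[[i]] <- data.frame(gene_id = name[1L], pas_id = name[2L],
                            chrom = f[1L], strand = f[6L],
                            cleavage_pos = start, region_class = name[3L],
                            utr_rank = NA_integer_, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows[keep])
  rownames(ann) <- NULL
  key <- paste(ann$gene_id, ann$pas_id)
  if (anyDuplicated(key)) {
    stop("duplicate pas_id within gene: ", key[duplicated(key)][1L])
  }
  derive_utr_rank(ann)
}

# Fill utr_rank (contiguous 1..m over a gene's utr3 PASs in transcriptional
# 5'->3' order).
derive_utr_rank <- function(ann) {
  ann$utr_rank <- NA_integer_
  for (idx in split(seq_len(nrow(ann)), ann$gene_id)) {
    utr <- idx[ann$region_class[idx] == "utr3"]
    if (!length(utr)) next
    o <- if (ann$strand[idx[1L]] == "+") {
      order(ann$cleavage_pos[utr])
    } else {
      order(-ann$cleavage_pos[utr])
    }
    ann$utr_rank[utr[o]] <- seq_along(utr)
  }
  validate_annotations(ann)
  ann
}

#' Write PAS annotations in the BED6 dialect
#'
#' @param annotations annotation `data.frame`.
#' @param path output file (gzip if the name ends in .gz).
#' @return `path`, invisibly.
#' @export
write_pas_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  lines <- sprintf("%s\t%d\t%d\t%s|%s|%s\t0\t%s",
                   annotations$chrom, annotations$cleavage_pos,
                   annotations$cleavage_pos + 1L, annotations$gene_id,
                   annotations$pas_id, annotations$region_class,
                   annotations$strand)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Remove genes whose assignment windows overlap another gene's
#'
#' A gene is removed when any of its PAS assignment windows
#' `[cleavage_pos - window, cleavage_pos + window]` overlaps a window of a
#' *different* gene on the same chromosome and strand, so that every
#' subsequent read assignment is unambiguous between genes.
#'
#' @param annotations annotation `data.frame`.
#' @param window half-width of the assignment window in nt (default 24, the
#'   read-assignment distance).
#' @return List with `annotations` (survivors) and `removed` (a
#'   `data.frame` of removed genes and the gene each collided with).
#' @export
drop_overlapping_pas_genes <- function(annotations, window = 24L) {
  validate_annotations(annotations)
  removed <- data.frame(gene_id = character(), collides_with = character(),
                        stringsAsFactors = FALSE)
  grp <- paste(annotations$chrom, annotations$strand)
  for (idx in split(seq_len(nrow(annotations)), grp)) {
    ir <- IRanges::IRanges(start = annotations$cleavage_pos[idx] - window,
                           end = annotations$cleavage_pos[idx] + window)
    hits <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    diff_gene <- annotations$gene_id[idx[qh]] != annotations$gene_id[idx[sh]]
    if (any(diff_gene)) {
      removed <- rbind(removed, unique(data.frame(
        gene_id = annotations$gene_id[idx[qh[diff_gene]]],
        collides_with = annotations$gene_id[idx[sh[diff_gene]]],
        stringsAsFactors = FALSE)))
    }
  }
  keep <- !(annotations$gene_id %in% removed$gene_id)
  list(annotations = annotations[keep, , drop = FALSE], removed = removed)
}

#' Assign read 3'-end records to PASs
#'
#' A read increments exactly one (gene, PAS, channel) counter iff its end
#' position lies within `max_dist` nt (inclusive) of an annotated cleavage
#' position on the matching chromosome and strand. Ties within a gene break
#' to the nearer PAS, then to the smaller coordinate. Unassigned reads are
#' tallied per channel in the discard report.
#'
#' @param reads read-end `data.frame` (`chrom`, `strand`, `end_pos`,
#'   `sample_id`, `tissue`, `replicate`, `allele_channel`).
#' @param annotations annotation table that has passed
#'   [drop_overlapping_pas_genes()].
#' @param max_dist inclusive assignment distance in nt (default 24).
#' @return List with `counts` (long counts `data.frame`) and `discarded`
#'   (per-channel tally of unassigned reads).
#' @export
assign_reads_to_pas <- function(reads, annotations, max_dist = 24L) {
  validate_annotations(annotations)
  req <- c("chrom", "strand", "end_pos", "sample_id", "tissue", "replicate",
           "allele_channel")
  miss <- setdiff(req, names(reads))
  if (length(miss)) stop("reads table is missing columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(reads)
  assigned <- rep(NA_integer_, n)
  rgrp <- paste(reads$chrom, reads$strand)
  agrp <- paste(annotations$chrom, annotations$strand)
  for (g in unique(rgrp)) {
    ridx <- which(rgrp == g)
    aidx <- which(agrp == g)
    if (!length(aidx)) next
    # sort PASs by coordinate; tie-break "nearer, then smaller coordinate"
    # falls out of scanning the two flanking candidates in coordinate order
    o <- aidx[order(annotations$cleavage_pos[aidx])]
    pos <- annotations$cleavage_pos[o]
    x <- reads$end_pos[ridx]
    right <- findInterval(x, pos) # index of rightmost pos <= x
    left_d <- ifelse(right >= 1L, x - pos[pmax(right, 1L)], Inf)
    right_d <- ifelse(right < length(pos), pos[pmin(right + 1L, length(pos))] - x, Inf)
    pick <- ifelse(left_d <= right_d, right, right + 1L)
    d <- pmin(left_d, right_d)
    ok <- is.finite(d) & d <= max_dist
    assigned[ridx[ok]] <- o[pick[ok]]
  }
  ok <- !is.na(assigned)
  discarded <- if (any(!ok)) {
    tb <- table(reads$allele_channel[!ok])
    data.frame(channel = names(tb), n = as.integer(tb),
               stringsAsFactors = FALSE)
  } else {
    data.frame(channel = character(), n = integer(), stringsAsFactors = FALSE)
  }
  if (!any(ok)) {
    counts <- data.frame(sample = character(), tissue = character(),
                         replicate = integer(), gene_id = character(),
                         pas_id = character(), channel = character(),
                         count = integer(), stringsAsFactors = FALSE)
    return(list(counts = counts, discarded = discarded))
  }
  key <- paste(reads$sample_id[ok], reads$tissue[ok], reads$replicate[ok],
               annotations$gene_id[assigned[ok]],
               annotations$pas_id[assigned[ok]],
               reads$allele_channel[ok], sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  counts <- data.frame(sample = parts[, 1L], tissue = parts[, 2L],
                       replicate = as.integer(parts[, 3L]),
                       gene_id = parts[, 4L], pas_id = parts[, 5L],
                       channel = parts[, 6L],
                       count = as.integer(tab), stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  counts <- counts[order(counts$gene_id, counts$pas_id, counts$sample,
                         counts$channel), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, discarded = discarded)
}

#' Read / write the long counts TSV
#'
#' Columns: sample, tissue, replicate, gene_id, pas_id, channel, count.
#' Gzip is used when the file name ends in `.gz`.
#'
#' @param counts long counts `data.frame`.
#' @param path TSV file path.
#' @return `write_counts_tsv` returns `path` invisibly; `read_counts_tsv`
#'   returns the validated counts `data.frame`.
#' @export
write_counts_tsv <- function(counts, path) {
  validate_counts(counts)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_counts(counts)
}
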