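# Sequence-feature scoring: C-terminal peptide conservation under an
# affine-gap BLOSUM62 global alignment, mean conservation-track scores over
# PAS-anchored regions, and microRNA target-site density.

the_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Global affine-gap alignment score
#'
#' Optimal Needleman-Wunsch score under affine gap costs where a gap of
#' length L costs `gap_open + (L - 1) * gap_extend` (the first gapped
#' residue pays the full opening penalty, each extension one unit more).
#' End gaps are penalized (true global alignment). Three-state dynamic
#' programming; integer scores for integer matrices.
#'
#' @param pep1,pep2 non-empty peptide strings over the matrix alphabet
#'   (`X` is scored through the matrix's X rows).
#' @param scoring_matrix substitution matrix (default BLOSUM62 from
#'   Biostrings).
#' @param gap_open cost of the first gapped residue (default -11).
#' @param gap_extend cost of each further gapped residue (default -1).
#' @param open_plus_extend if TRUE, use the alternative convention where the
#'   first gapped residue costs `gap_open + gap_extend` (default FALSE).
#' @return The optimal global alignment score (scalar).
#' @export
global_affine_align_score <- function(pep1, pep2, scoring_matrix = NULL,
                                      gap_open = -11, gap_extend = -1,
                                      open_plus_extend = FALSE) {
  if (!nzchar(pep1) || !nzchar(pep2)) stop("peptides must be non-empty")
  S <- scoring_matrix %||% the_blosum62()
  a <- strsplit(pep1, "")[[1L]]
  b <- strsplit(pep2, "")[[1L]]
  bad <- setdiff(c(a, b), rownames(S))
  if (length(bad)) stop("residue(s) without matrix entry: ",
                        paste(bad, collapse = ", "))
  first_gap <- if (open_plus_extend) gap_open + gap_extend else gap_open
  n <- length(a)
  m <- length(b)
  NEG <- -1e18
  # M: a[i] aligned to b[j]; X: gap in pep2 (a[i] unmatched); Y: gap in pep1
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) {
    X[i + 1L, 1L] <- first_gap + (i - 1L) * gap_extend
  }
  for (j in seq_len(m)) {
    Y[1L, j + 1L] <- first_gap + (j - 1L) * gap_extend
  }
  for (i in seq_len(n)) {
    si <- S[a[i], ]
    for (j in seq_len(m)) {
      s <- si[[b[j]]]
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + first_gap,
                               X[i, j + 1L] + gap_extend,
                               Y[i, j + 1L] + first_gap)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + first_gap,
                               X[i + 1L, j] + first_gap,
                               Y[i + 1L, j] + gap_extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

#' C-terminal peptide conservation
#'
#' Conservation = global affine-gap BLOSUM62 alignment score divided by the
#' mean peptide length; a pair is conserved iff the score is strictly
#' positive. Intended for the C-terminal peptides specific to the dominant
#' and minor last-exon isoforms of a gene.
#'
#' @inheritParams global_affine_align_score
#' @return List with `alignment_score`, `mean_length`, `conservation`,
#'   `conserved`.
#' @export
cterm_conservation <- function(pep1, pep2, scoring_matrix = NULL, gap_open = -11,
                               gap_extend = -1) {
  score <- global_affine_align_score(pep1, pep2, scoring_matrix = scoring_matrix,
                                     gap_open = gap_open,
                                     gap_extend = gap_extend)
  mean_len <- (nchar(pep1) + nchar(pep2)) / 2
  cons <- score / mean_len
  list(alignment_score = score, mean_length = mean_len, conservation = cons,
       conserved = cons > 0)
}

#' Score C-terminal conservation for FASTA peptide pairs
#'
#' Reads a peptide FASTA in which consecutive records are isoform pairs of
#' one gene (names `gene|isoform`), scoring each pair with
#' [cterm_conservation()].
#'
#' @param path peptide FASTA file.
#' @return `data.frame` per pair: `gene_id`, `isoform_a`, `isoform_b`,
#'   `alignment_score`, `mean_length`, `conservation`, `conserved`.
#' @export
cterm_conservation_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  nm <- do.call(rbind, strsplit(names(seqs), "|", fixed = TRUE))
  genes <- unique(nm[, 1L])
  rows <- lapply(genes, function(g) {
    ix <- which(nm[, 1L] == g)
    if (length(ix) != 2L) stop("gene ", g, " must have exactly two isoforms")
    cc <- cterm_conservation(as.character(seqs[[ix[1L]]]),
                             as.character(seqs[[ix[2L]]]))
    data.frame(gene_id = g, isoform_a = nm[ix[1L], 2L],
               isoform_b = nm[ix[2L], 2L],
               alignment_score = cc$alignment_score,
               mean_length = cc$mean_length, conservation = cc$conservation,
               conserved = cc$conserved, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# strand-oriented region upstream of a position: `len` bases ending at (and
# excluding) the cleavage position on the transcriptional 5' side
upstream_region <- function(pos, strand, len) {
  if (strand == "+") c(pos - len, pos - 1L) else c(pos + 1L, pos + len)
}

#' MicroRNA target-site density over PAS-anchored regions
#'
#' Two region families: (i) the inter-PAS region — `min(1000, distance)` nt
#' transcriptionally upstream of the distal of the two PASs (used for
#' dominant-vs-rank-2 pairs, both in the 3'UTR); (ii) the 300-nt upstream
#' region of a single PAS, truncated to its non-overlapping 3'UTR part when
#' CDS intervals are supplied. Density is the coverage sum (number of target
#' sites covering each position, summed) divided by the region length; the
#' aggregated per-offset profile is also returned.
#'
#' @param sites `data.frame` of target-site intervals (`chrom`, `start`,
#'   `end`; 0-based half-open).
#' @param regions `data.frame` with one row per region: `chrom`, `strand`,
#'   and either (`pas_pos`, `partner_pos`) for inter-PAS regions or
#'   `pas_pos` alone for upstream regions; plus an `id` column.
#' @param mode "inter_pas" or "upstream".
#' @param upstream_len upstream-region length (default 300; 1000 cap for
#'   inter-PAS regions).
#' @param cds optional CDS intervals (`chrom`, `start`, `end`) used to
#'   truncate upstream regions at coding overlap.
#' @return `data.frame` per region: `id`, `length`, `coverage_sum`,
#'   `density` (`NA` with zero length, flagged by `missing`); the per-offset
#'   profile in `attr(, "profile")`.
#' @export
mirna_density <- function(sites, regions, mode = c("inter_pas", "upstream"),
                          upstream_len = 300L, cds = NULL) {
  mode <- match.arg(mode)
  cap <- if (mode == "inter_pas") 1000L else upstream_len
  prof <- stats::setNames(numeric(cap), seq_len(cap))
  prof_n <- 0L
  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (mode == "inter_pas") {
      dist <- abs(r$pas_pos - r$partner_pos)
      len <- min(cap, dist)
      reg <- upstream_region(distal_pos(r), r$strand, len)
    } else {
      reg <- upstream_region(r$pas_pos, r$strand, upstream_len)
      if (!is.null(cds)) reg <- truncate_at_cds(reg, r, cds)
      len <- if (is.null(reg)) 0L else reg[2L] - reg[1L] + 1L
    }
    if (is.null(reg) || len <= 0L) {
      rows[[i]] <- data.frame(id = r$id, length = 0L, coverage_sum = 0,
                              density = NA_real_, missing = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    ss <- sites[sites$chrom == r$chrom & sites$end > reg[1L] &
                  sites$start <= reg[2L], , drop = FALSE]
    cov <- numeric(len)
    for (k in seq_len(nrow(ss))) {
      lo <- max(reg[1L], ss$start[k])
      hi <- min(reg[2L], ss$end[k] - 1L)
      if (hi >= lo) {
        cov[(lo - reg[1L] + 1L):(hi - reg[1L] + 1L)] <-
          cov[(lo - reg[1L] + 1L):(hi - reg[1L] + 1L)] + 1
      }
    }
    rows[[i]] <- data.frame(id = r$id, length = len, coverage_sum = sum(cov),
                            density = sum(cov) / len, missing = FALSE,
                            stringsAsFactors = FALSE)
    # offset 1 = position nearest the anchoring PAS (transcriptional 3' end)
    ori <- if (r$strand == "+") rev(cov) else cov
    prof[seq_len(len)] <- prof[seq_len(len)] + ori
    prof_n <- prof_n + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "profile") <- data.frame(offset = seq_len(cap),
                                     mean_coverage = if (prof_n) prof / prof_n
                                     else prof)
  out
}

# distal (transcriptionally 3'-most) of the two positions of an inter-PAS row
distal_pos <- function(r) {
  if (r$strand == "+") max(r$pas_pos, r$partner_pos) else
    min(r$pas_pos, r$partner_pos)
}

# shorten an upstream region so it does not overlap any CDS interval,
# keeping the part adjacent to the PAS (the non-overlapping 3'UTR side)
truncate_at_cds <- function(reg, r, cds) {
  ov <- cds[cds$chrom == r$chrom & cds$end > reg[1L] & cds$start <= reg[2L], ,
            drop = FALSE]
  if (!nrow(ov)) return(reg)
  if (r$strand == "+") {
    # keep the 3' (right) side after the rightmost CDS overlap
    lo <- max(ov$end) # first base after the CDS (0-based half-open end)
    if (lo > reg[2L]) return(NULL)
    c(max(reg[1L], lo), reg[2L])
  } else {
    hi <- min(ov$start) - 1L
    if (hi < reg[1L]) return(NULL)
    c(reg[1L], min(reg[2L], hi))
  }
}

#' Mean conservation score over a PAS-anchored interval
#'
#' Averages a per-base conservation track over the strand-oriented interval
#' `[window[1], window[2]]` relative to the cleavage position (negative =
#' transcriptionally upstream, both ends inclusive). Bases absent from the
#' track score 0 and are counted in the denominator; their number is
#' reported.
#'
#' @param track `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open) and `score` columns (bedGraph-style).
#' @param chrom,pos,strand anchor cleavage site.
#' @param window relative window (default `c(-50, 0)`).
#' @return List with `mean_score`, `n_bases`, `n_missing`.
#' @export
region_mean_conservation <- function(track, chrom, pos, strand,
                                     window = c(-50L, 0L)) {
  len <- window[2L] - window[1L] + 1L
  offs <- seq(window[1L], window[2L])
  bases <- if (strand == "+") pos + offs else pos - offs
  sc <- numeric(len)
  hit <- logical(len)
  tt <- track[track$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(tt))) {
    inside <- bases >= tt$start[k] & bases < tt$end[k]
    sc[inside] <- tt$score[k]
    hit[inside] <- TRUE
  }
  list(mean_score = sum(sc) / len, n_bases = len, n_missing = sum(!hit))
}

#' Read a bedGraph conservation track
#'
#' @param path bedGraph file.
#' @return `data.frame` with `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "score"),
                          comment.char = "#")
  df[!grepl("^track", df$chrom), , drop = FALSE]
}

#' Read BED intervals (variants, target sites, CDS)
#'
#' Uses rtracklayer when available, else a minimal three-column reader.
#'
#' @param path BED file.
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open) and
#'   `pos` (= start, convenience for point features).
#' @export
read_bed_intervals <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
    df <- data.frame(chrom = as.character(gr$seqnames),
                     start = as.integer(gr$start) - 1L,
                     end = as.integer(gr$end), stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    df <- data.frame(chrom = raw[[1L]], start = as.integer(raw[[2L]]),
                     end = as.integer(raw[[3L]]), stringsAsFactors = FALSE)
  }
  df$pos <- df$start
  df
}
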