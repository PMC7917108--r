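# The lncRNA screening pipeline: a strict ordered filter cascade over
# assembled transcripts, followed by positional classification of the
# survivors against the protein-coding annotation.

#' Screening parameters for lncRNA identification
#'
#' @param min_length Minimum transcript length in nt; transcripts shorter
#'   than this are excluded (200 nt by default, so a 200-nt transcript is
#'   kept).
#' @param drop_monoexonic_below_fpkm Mono-exonic transcripts whose maximum
#'   FPKM across all samples falls below this value are treated as
#'   low-reliability assembly artifacts and removed (default 2).
#' @param orf_aa_cutoff Longest-ORF length (aa) at or above which a
#'   transcript is called coding by the built-in stand-in; only used when
#'   no external coding labels are supplied.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_length = 200, drop_monoexonic_below_fpkm = 2,
                          orf_aa_cutoff = 100) {
  stopifnot(min_length >= 1, drop_monoexonic_below_fpkm >= 0,
            orf_aa_cutoff >= 0)
  structure(list(min_length = min_length,
                 drop_monoexonic_below_fpkm = drop_monoexonic_below_fpkm,
                 orf_aa_cutoff = orf_aa_cutoff),
            class = "filter_params")
}

exon_granges <- function(ann) {
  ex <- ann %>%
    select("transcript_id", "chrom", "strand", "exons") %>%
    unnest("exons")
  strand <- ex$strand
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = strand)
  gr$transcript_id <- ex$transcript_id
  gr
}

span_granges <- function(ann) {
  strand <- ann$strand
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = strand)
  gr$transcript_id <- ann$transcript_id
  gr
}

coding_genes <- function(genes) {
  filter(genes, .data$biotype == "protein_coding")
}

# transcripts whose exons overlap a protein-coding exon by >= 1 bp,
# split by relative strand
exon_overlap_ids <- function(transcripts, coding, same_strand = TRUE) {
  if (nrow(transcripts) == 0 || nrow(coding) == 0) return(character())
  tx_ex <- exon_granges(transcripts)
  cd_ex <- exon_granges(coding)
  if (!same_strand) cd_ex <- invert_strand(cd_ex)
  ov <- GenomicRanges::findOverlaps(tx_ex, cd_ex, minoverlap = 1L,
                                    ignore.strand = FALSE)
  unique(tx_ex$transcript_id[S4Vectors::queryHits(ov)])
}

invert_strand <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "+"] <- "tmp"; s[s == "-"] <- "+"; s[s == "tmp"] <- "-"
  GenomicRanges::strand(gr) <- s
  gr
}

intron_granges <- function(coding) {
  rows <- list()
  multi <- coding[vapply(coding$exons, nrow, integer(1)) >= 2, ,
                  drop = FALSE]
  for (i in seq_len(nrow(multi))) {
    e <- multi$exons[[i]]
    rows[[length(rows) + 1]] <- tibble(
      chrom = multi$chrom[i],
      start = e$end[-nrow(e)],
      end = e$start[-1]
    )
  }
  if (length(rows) == 0)
    return(GenomicRanges::GRanges())
  intr <- bind_rows(rows)
  intr <- intr[intr$end > intr$start, , drop = FALSE]
  GenomicRanges::GRanges(seqnames = intr$chrom,
                         ranges = IRanges::IRanges(start = intr$start + 1L,
                                                   end = intr$end))
}

#' Apply the lncRNA candidate filter cascade
#'
#' Filters assembled transcripts in order: (1) length below
#' `min_length`; (2) mono-exonic with maximum FPKM below the reliability
#' cutoff; (3) same-strand exon overlap (>= 1 bp) with a protein-coding
#' exon (antisense overlappers survive -- they are the lncNAT class);
#' (4) called coding, either by supplied labels or by the longest-ORF
#' stand-in. A transcript is removed at its first failing step.
#'
#' @param transcripts Candidate transcript tibble
#'   (see [read_annotation()]).
#' @param genes Reference annotation tibble; protein-coding entries drive
#'   the overlap filter.
#' @param expr An `fpkm_tbl`; features absent from it count as FPKM 0.
#' @param params A [filter_params()] list.
#' @param coding_labels Optional named character vector
#'   (transcript -> `"coding"`/`"noncoding"`).
#' @param seqs Optional named character vector of transcript sequences for
#'   the ORF stand-in when labels are absent.
#' @return Tibble: the input transcripts plus `max_fpkm`, logical
#'   `retained`, and `fail_step` (`length`, `expression`, `overlap`,
#'   `coding`, or `NA` when retained). The per-step columns
#'   `pass_length`, `pass_expression`, `pass_overlap`, `pass_coding`
#'   record the filter trace (`NA` = not evaluated).
#' @export
filter_candidates <- function(transcripts, genes, expr = NULL,
                              params = filter_params(),
                              coding_labels = NULL, seqs = NULL) {
  out <- transcripts
  if (nrow(out) == 0) {
    out$max_fpkm <- numeric()
    out$pass_length <- out$pass_expression <- logical()
    out$pass_overlap <- out$pass_coding <- logical()
    out$retained <- logical()
    out$fail_step <- character()
    return(out)
  }
  max_fpkm <- rep(0, nrow(out))
  if (!is.null(expr)) {
    m <- expr_matrix(expr)
    mx <- apply(m, 1, max)
    hit <- match(out$transcript_id, names(mx))
    max_fpkm[!is.na(hit)] <- mx[hit[!is.na(hit)]]
  }
  out$max_fpkm <- max_fpkm

  out$pass_length <- out$length >= params$min_length
  alive <- out$pass_length

  out$pass_expression <- NA
  out$pass_expression[alive] <-
    !(out$n_exons[alive] == 1 &
        out$max_fpkm[alive] < params$drop_monoexonic_below_fpkm)
  alive <- alive & out$pass_expression %in% TRUE

  same <- exon_overlap_ids(out[alive, , drop = FALSE],
                           coding_genes(genes), same_strand = TRUE)
  out$pass_overlap <- NA
  out$pass_overlap[alive] <- !(out$transcript_id[alive] %in% same)
  alive <- alive & out$pass_overlap %in% TRUE

  out$pass_coding <- NA
  is_coding <- function(ids) {
    if (!is.null(coding_labels)) {
      lab <- coding_labels[ids]
      !is.na(lab) & lab == "coding"
    } else if (!is.null(seqs)) {
      vapply(ids, function(id) {
        s <- seqs[[id]]
        !is.null(s) && orf_stand_in(s) >= params$orf_aa_cutoff
      }, logical(1))
    } else {
      rep(FALSE, length(ids))
    }
  }
  out$pass_coding[alive] <- !is_coding(out$transcript_id[alive])
  out$retained <- out$pass_coding %in% TRUE
  steps <- c("length", "expression", "overlap", "coding")
  passes <- cbind(out$pass_length, out$pass_expression, out$pass_overlap,
                  out$pass_coding)
  out$fail_step <- apply(passes, 1, function(p) {
    i <- which(p %in% FALSE)
    if (length(i) == 0) NA_character_ else steps[i[1]]
  })
  out
}

#' Longest open reading frame, in amino acids
#'
#' A deliberately simple coding-potential stand-in (documented as *not*
#' equivalent to dedicated coding-potential classifiers): the longest
#' ATG..stop open reading frame across the three forward frames, length
#' in amino acids excluding the stop codon. A reading frame with no
#' in-frame stop after the ATG does not count.
#'
#' @param seq Nucleotide string over A/C/G/T/N (U accepted).
#' @return Integer aa length (0 when no ORF).
#' @export
orf_stand_in <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  chars <- strsplit(s, "")[[1]]
  best <- 0L
  for (frame in 0:2) {
    idx <- seq(frame + 1, length(chars) - 2, by = 3)
    if (frame + 3 > length(chars)) next
    codons <- vapply(idx, function(i)
      paste0(chars[i], chars[i + 1], chars[i + 2]), character(1))
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    atgs <- which(codons == "ATG")
    for (a in atgs) {
      nx <- stops[stops > a]
      if (length(nx) > 0) best <- max(best, nx[1] - a)
    }
  }
  as.integer(best)
}

#' Positional class of one retained lncRNA
#'
#' Classifies a filtered transcript by its position relative to
#' protein-coding genes: `lncNAT` when >= 1 bp of exon overlaps a coding
#' exon on the opposite strand; otherwise `incRNA` when the transcript
#' span lies fully inside one intron of a coding transcript (either
#' strand); otherwise `lincRNA`. Precedence: lncNAT > incRNA > lincRNA.
#' A transcript still overlapping a coding exon on the same strand is an
#' error -- it should have been removed by [filter_candidates()].
#'
#' @param tx One-row transcript tibble.
#' @param genes Reference annotation tibble.
#' @return `"lincRNA"`, `"incRNA"`, or `"lncNAT"`.
#' @export
classify_position <- function(tx, genes) {
  stopifnot(nrow(tx) == 1)
  classify_lncrnas(tx, genes)$positional_class
}

#' Positional classes for a set of retained lncRNAs
#'
#' Vectorized form of [classify_position()].
#'
#' @param lncrnas Transcript tibble of retained candidates.
#' @param genes Reference annotation tibble.
#' @return `lncrnas` with a `positional_class` column.
#' @export
classify_lncrnas <- function(lncrnas, genes) {
  out <- lncrnas
  if (nrow(out) == 0) {
    out$positional_class <- character()
    return(out)
  }
  coding <- coding_genes(genes)
  same <- exon_overlap_ids(out, coding, same_strand = TRUE)
  if (length(same) > 0)
    abort(paste0("same-strand coding exon overlap (should have been ",
                 "filtered): ", paste(same, collapse = ", ")))
  anti <- exon_overlap_ids(out, coding, same_strand = FALSE)

  spans <- span_granges(out)
  introns <- intron_granges(coding)
  inside <- if (length(introns) > 0) {
    ov <- GenomicRanges::findOverlaps(spans, introns, type = "within",
                                      ignore.strand = TRUE)
    unique(spans$transcript_id[S4Vectors::queryHits(ov)])
  } else character()

  out$positional_class <- dplyr::case_when(
    out$transcript_id %in% anti ~ "lncNAT",
    out$transcript_id %in% inside ~ "incRNA",
    TRUE ~ "lincRNA"
  )
  out
}

#' Identify and classify lncRNAs in one call
#'
#' Runs [filter_candidates()] then [classify_lncrnas()] on the survivors
#' and returns the full catalog (filter trace for every candidate,
#' positional class for every retained lncRNA).
#'
#' @inheritParams filter_candidates
#' @return Tibble of class `lnc_catalog`.
#' @export
identify_lncrnas <- function(transcripts, genes, expr = NULL,
                             params = filter_params(),
                             coding_labels = NULL, seqs = NULL) {
  flt <- filter_candidates(transcripts, genes, expr, params,
                           coding_labels = coding_labels, seqs = seqs)
  kept <- classify_lncrnas(flt[flt$retained, , drop = FALSE], genes)
  flt$positional_class <- NA_character_
  flt$positional_class[match(kept$transcript_id, flt$transcript_id)] <-
    kept$positional_class
  structure(flt, params = params,
            class = c("lnc_catalog", class(tibble())))
}

#' @export
glance.lnc_catalog <- function(x, ...) {
  kept <- x[x$retained, , drop = FALSE]
  tibble(n_candidates = nrow(x),
         n_lncrna = nrow(kept),
         n_lincRNA = sum(kept$positional_class == "lincRNA"),
         n_incRNA = sum(kept$positional_class == "incRNA"),
         n_lncNAT = sum(kept$positional_class == "lncNAT"),
         mean_length = if (nrow(kept)) mean(kept$length) else NA_real_,
         median_length = if (nrow(kept)) median(kept$length) else NA_real_)
}
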