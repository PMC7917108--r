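# I/O for the standard formats the pipeline touches. One coordinate
# convention everywhere inside the package: 0-based, half-open, so an
# exon printed as start=101 end=200 in GFF/GTF becomes (100, 200) with
# length 200 - 100 = 100. Conversion happens only here, at the boundary.

VALID_STRANDS <- c("+", "-", ".")

#' Read a gene/transcript annotation (GFF3 or GTF)
#'
#' Parses an annotation file into a transcript-level tibble with nested
#' exons. Coordinates are converted from the 1-based inclusive convention
#' of GFF/GTF to 0-based half-open intervals. Exon records are grouped
#' under their transcript, transcripts under their gene; unknown feature
#' types are ignored (a count is reported). A transcript whose gene record
#' is absent keeps its stated `gene_id` and a single-transcript gene is
#' implied (reported via a message).
#'
#' @param path Path to a GFF3 or GTF file.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return A tibble with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `biotype`, `n_exons`, `length` (sum of exon lengths), and an `exons`
#'   list-column of tibbles with `start`/`end`.
#' @export
read_annotation <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  check_annotation_lines(path)
  gr <- rtracklayer::import(path, format = dialect)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$strand <- as.character(df$strand)
  df$strand[df$strand == "*"] <- "."
  # 1-based inclusive -> 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  type <- as.character(df$type)

  if (dialect == "gtf") {
    tx_id <- as.character(df$transcript_id)
    gene_id <- as.character(df$gene_id)
    biotype <- annotation_attr(df, c("gene_biotype", "transcript_biotype",
                                     "biotype"))
  } else {
    id <- annotation_attr(df, "ID")
    parent <- df$Parent
    parent <- vapply(seq_len(nrow(df)), function(i) {
      p <- parent[[i]]
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
    tx_id <- ifelse(type == "exon", parent, id)
    gene_id <- ifelse(type == "exon", NA_character_, parent)
    biotype <- annotation_attr(df, c("biotype", "gene_biotype"))
  }

  tx_types <- c("transcript", "mRNA", "lnc_RNA", "lincRNA", "ncRNA")
  known <- type %in% c("gene", "exon", tx_types)
  n_ignored <- sum(!known)
  if (n_ignored > 0)
    inform(paste0("read_annotation: ignored ", n_ignored,
                  " record(s) of unhandled feature type"))

  genes <- df[type == "gene", , drop = FALSE]
  gene_bio <- setNames(biotype[type == "gene"],
                       if (dialect == "gtf") gene_id[type == "gene"]
                       else annotation_attr(genes, "ID"))

  is_tx <- type %in% tx_types
  tx_tbl <- tibble(
    transcript_id = tx_id[is_tx],
    gene_id = gene_id[is_tx],
    chrom = as.character(df$seqnames)[is_tx],
    start = df$start0[is_tx],
    end = df$end0[is_tx],
    strand = df$strand[is_tx],
    biotype = biotype[is_tx]
  )
  # fall back to the gene's biotype when the transcript carries none
  need <- is.na(tx_tbl$biotype) & tx_tbl$gene_id %in% names(gene_bio)
  tx_tbl$biotype[need] <- gene_bio[tx_tbl$gene_id[need]]
  tx_tbl$biotype[is.na(tx_tbl$biotype)] <- "unknown"

  orphan <- !(tx_tbl$gene_id %in% names(gene_bio))
  if (dialect == "gff3" && length(gene_bio) > 0 && any(orphan))
    inform(paste0("read_annotation: synthesized single-transcript gene for ",
                  sum(orphan), " transcript(s) with no gene record"))
  tx_tbl$gene_id[is.na(tx_tbl$gene_id)] <-
    tx_tbl$transcript_id[is.na(tx_tbl$gene_id)]

  ex <- tibble(
    transcript_id = tx_id[type == "exon"],
    start = df$start0[type == "exon"],
    end = df$end0[type == "exon"]
  ) %>%
    arrange(.data$transcript_id, .data$start)
  ex_by_tx <- split(ex[c("start", "end")], ex$transcript_id)

  tx_tbl$exons <- lapply(tx_tbl$transcript_id, function(id) {
    e <- ex_by_tx[[id]]
    if (is.null(e)) abort(paste0("transcript without exon records: ", id))
    as_tibble(e)
  })
  tx_tbl$n_exons <- vapply(tx_tbl$exons, nrow, integer(1))
  tx_tbl$length <- vapply(tx_tbl$exons, function(e)
    sum(e$end - e$start), numeric(1))
  validate_annotation(tx_tbl)
  arrange(tx_tbl, .data$chrom, .data$start, .data$transcript_id)
}

# Cheap structural pre-scan so malformed input fails with a line number
# before being handed to the importer.
check_annotation_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld != 9)) {
    bad <- which(body)[which(nfld != 9)[1]]
    abort(paste0("malformed annotation line ", bad, ": expected 9 fields, got ",
                 nfld[which(nfld != 9)[1]]))
  }
  st <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  en <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  if (any(is.na(st) | is.na(en))) {
    bad <- which(body)[which(is.na(st) | is.na(en))[1]]
    abort(paste0("malformed annotation line ", bad, ": non-numeric coordinates"))
  }
  if (any(en < st)) {
    bad <- which(body)[which(en < st)[1]]
    abort(paste0("malformed annotation line ", bad, ": end < start"))
  }
  invisible(TRUE)
}

annotation_attr <- function(df, candidates) {
  for (nm in candidates)
    if (nm %in% names(df)) return(as.character(df[[nm]]))
  rep(NA_character_, nrow(df))
}

validate_annotation <- function(ann) {
  stopifnot(all(ann$start >= 0), all(ann$end > ann$start),
            all(ann$strand %in% VALID_STRANDS))
  for (i in seq_len(nrow(ann))) {
    e <- ann$exons[[i]]
    stopifnot(nrow(e) >= 1, all(diff(e$start) > 0),
              all(e$start >= ann$start[i]), all(e$end <= ann$end[i]),
              all(e$end > e$start))
    if (nrow(e) > 1) stopifnot(all(e$start[-1] >= e$end[-nrow(e)]))
  }
  invisible(ann)
}

#' Write an annotation tibble to GFF3 or GTF
#'
#' Inverse of [read_annotation()]: coordinates are converted back to the
#' 1-based inclusive convention. `read_annotation(write_annotation(x))`
#' reproduces `x`.
#'
#' @param ann Transcript tibble as returned by [read_annotation()].
#' @param path Output path.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  rows <- list()
  genes <- ann %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), strand = first(.data$strand),
              biotype = first(.data$biotype), .groups = "drop")
  mk <- function(chrom, start, end, strand, type, id, parent, gene, tx, bio) {
    tibble(chrom = chrom, start = start, end = end, strand = strand,
           type = type, ID = id, Parent = parent, gene_id = gene,
           transcript_id = tx, biotype = bio)
  }
  rows[[1]] <- mk(genes$chrom, genes$start, genes$end, genes$strand, "gene",
                  genes$gene_id, NA_character_, genes$gene_id,
                  NA_character_, genes$biotype)
  rows[[2]] <- mk(ann$chrom, ann$start, ann$end, ann$strand, "transcript",
                  ann$transcript_id, ann$gene_id, ann$gene_id,
                  ann$transcript_id, ann$biotype)
  ex <- ann %>%
    select("transcript_id", "gene_id", "chrom", "strand", "biotype",
           "exons") %>%
    unnest("exons")
  rows[[3]] <- mk(ex$chrom, ex$start, ex$end, ex$strand, "exon",
                  NA_character_, ex$transcript_id, ex$gene_id,
                  ex$transcript_id, ex$biotype)
  all <- bind_rows(rows)
  strand <- all$strand
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = all$chrom,
    ranges = IRanges::IRanges(start = all$start + 1L, end = all$end),
    strand = strand
  )
  gr$type <- all$type
  if (dialect == "gtf") {
    keep <- all$type != "gene"
    gr <- gr[keep]
    gr$type <- all$type[keep]
    gr$gene_id <- all$gene_id[keep]
    gr$transcript_id <- all$transcript_id[keep]
    gr$gene_biotype <- all$biotype[keep]
    rtracklayer::export(gr, path, format = "gtf")
  } else {
    gr$ID <- all$ID
    gr$Parent <- all$Parent
    gr$biotype <- all$biotype
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited header token; sequences
#' are uppercased and `U` is normalized to `T` so DNA and RNA inputs are
#' comparable (the duplex machinery re-interprets `T` as `U`).
#'
#' @param path FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    abort(paste0("duplicate FASTA id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0))
    abort(paste0("empty sequence for id: ", ids[nchar(seqs) == 0][1]))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    abort(paste0("invalid characters in sequence: ", ids[bad][1]))
  setNames(seqs, ids)
}

#' Write a named set of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(gsub("(.{60})", "\\1\n", seqs[[i]], perl = TRUE), con)
  }
  invisible(path)
}

#' Read BLAST tabular (outfmt 6) homology hits
#'
#' Reads 12-column BLAST tabular output and retains rows with
#' `evalue < max_evalue` (strict, matching the `E < 1e-5` convention used
#' throughout the package).
#'
#' @param path Tabular file (qseqid sseqid pident length mismatch gapopen
#'   qstart qend sstart send evalue bitscore).
#' @param max_evalue Strict upper bound on the E-value.
#' @param subject_species Optional single species label, or a function of
#'   the subject id returning one.
#' @return Tibble of hits with snake-case column names plus
#'   `subject_species`.
#' @export
read_blast_tab <- function(path, max_evalue = 1e-5, subject_species = NA) {
  if (!file.exists(path)) abort(paste0("BLAST table not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld != 12)) {
    bad <- which(nfld != 12)[1]
    abort(paste0("BLAST tabular line ", bad, ": expected 12 columns, got ",
                 nfld[bad]))
  }
  m <- do.call(rbind, fields)
  hits <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12])
  )
  hits$subject_species <- if (is.function(subject_species))
    vapply(hits$subject_id, subject_species, character(1))
  else as.character(subject_species)
  keep <- hits$e_value < max_evalue
  inform(paste0("read_blast_tab: kept ", sum(keep), ", dropped ",
                sum(!keep), " hit(s) at E < ", format(max_evalue)))
  hits[keep, , drop = FALSE]
}

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(),
         percent_identity = numeric(), alignment_length = integer(),
         mismatches = integer(), gap_opens = integer(),
         q_start = integer(), q_end = integer(), s_start = integer(),
         s_end = integer(), e_value = numeric(), bit_score = numeric(),
         subject_species = character())
}

#' Export a network as node and edge TSV files
#'
#' Writes `<prefix>_nodes.tsv` and `<prefix>_edges.tsv` with deterministic
#' ordering (sorted by id), ready for import into Gephi or Cytoscape.
#'
#' @param nodes Tibble with at least `id` and `type`
#'   (lncRNA/mRNA/miRNA).
#' @param edges Tibble with at least `from` and `to` referencing node ids;
#'   extra columns are written as edge attributes.
#' @param path_prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_network_tsv <- function(nodes, edges, path_prefix) {
  stopifnot(all(c("id", "type") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  dangling <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(dangling) > 0)
    abort(paste0("edge endpoint(s) not in node table: ",
                 paste(dangling, collapse = ", ")))
  nodes <- arrange(nodes, .data$id)
  edges <- arrange(edges, .data$from, .data$to)
  paths <- paste0(path_prefix, c("_nodes.tsv", "_edges.tsv"))
  readr::write_tsv(nodes, paths[1])
  readr::write_tsv(edges, paths[2])
  invisible(paths)
}

#' Read a network written by [write_network_tsv()]
#' @param path_prefix Prefix used when writing.
#' @return List with `nodes` and `edges` tibbles.
#' @export
read_network_tsv <- function(path_prefix) {
  list(
    nodes = readr::read_tsv(paste0(path_prefix, "_nodes.tsv"),
                            show_col_types = FALSE),
    edges = readr::read_tsv(paste0(path_prefix, "_edges.tsv"),
                            show_col_types = FALSE)
  )
}
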