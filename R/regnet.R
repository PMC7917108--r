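# The lncRNA-mRNA regulatory relations: cis (genomic proximity within a
# window), trans (Pearson coexpression above strict thresholds), their
# intersection, and sense-antisense pairing.

gene_spans <- function(genes) {
  coding_genes(genes) %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), strand = first(.data$strand),
              .groups = "drop")
}

#' Protein-coding genes within a genomic window of each lncRNA (cis)
#'
#' Screens protein-coding genes whose span lies within `window` bases
#' upstream or downstream of each lncRNA span. Distance is 0 for any
#' overlap, otherwise the gap between the nearest boundaries; the window
#' boundary is inclusive (`distance <= window`) unless
#' `exclusive = TRUE`.
#'
#' @param lncrnas Tibble of lncRNAs with `transcript_id`, `chrom`,
#'   `start`, `end` (e.g. the retained rows of an `lnc_catalog`).
#' @param genes Reference annotation tibble.
#' @param window Window size in nt (default 100000).
#' @param exclusive Use a strict `distance < window` boundary.
#' @return Tibble of edges: `lncrna_id`, `mrna_id`, `mode = "cis"`,
#'   `distance_bp`.
#' @export
cis_targets <- function(lncrnas, genes, window = 100000,
                        exclusive = FALSE) {
  gs <- gene_spans(genes)
  if (nrow(lncrnas) == 0 || nrow(gs) == 0)
    return(tibble(lncrna_id = character(), mrna_id = character(),
                  mode = character(), distance_bp = numeric()))
  lnc_gr <- GenomicRanges::GRanges(
    seqnames = lncrnas$chrom,
    ranges = IRanges::IRanges(start = lncrnas$start + 1L,
                              end = lncrnas$end))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = gs$chrom,
    ranges = IRanges::IRanges(start = gs$start + 1L, end = gs$end))
  ov <- GenomicRanges::findOverlaps(lnc_gr, gene_gr,
                                    maxgap = as.integer(window),
                                    ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  d <- GenomicRanges::distance(lnc_gr[qi], gene_gr[si])
  keep <- if (exclusive) d < window else d <= window
  tibble(lncrna_id = lncrnas$transcript_id[qi][keep],
         mrna_id = gs$gene_id[si][keep],
         mode = "cis",
         distance_bp = as.numeric(d[keep])) %>%
    distinct(.data$lncrna_id, .data$mrna_id, .keep_all = TRUE) %>%
    arrange(.data$lncrna_id, .data$mrna_id)
}

#' Coexpressed lncRNA-mRNA pairs (trans)
#'
#' Declares a trans edge for every (DE lncRNA, DE mRNA) pair whose
#' Pearson correlation satisfies `|r| > r_min` and `p < p_max` (both
#' strict). The correlation basis is either per-stage mean FPKM
#' (`"stages"`, n = number of stages, the default) or all replicate
#' columns (`"replicates"`).
#'
#' @param expr An `fpkm_tbl` containing every feature.
#' @param de_lnc,de_mrna Character vectors of DE lncRNA / mRNA ids.
#' @param r_min,p_max Strict thresholds (defaults 0.95 and 0.01).
#' @param basis `"stages"` or `"replicates"`.
#' @param de Optional `de_result` tibble; when given, each edge records
#'   the comparisons in which *both* endpoints are DE.
#' @return Tibble of edges: `lncrna_id`, `mrna_id`, `mode = "trans"`,
#'   `r`, `p`, and (when `de` is given) `comparisons_present`,
#'   `n_comparisons`.
#' @export
trans_targets <- function(expr, de_lnc, de_mrna, r_min = 0.95,
                          p_max = 0.01,
                          basis = c("stages", "replicates"), de = NULL) {
  basis <- match.arg(basis)
  m <- if (basis == "stages") stage_means(expr) else expr_matrix(expr)
  missing <- setdiff(c(de_lnc, de_mrna), rownames(m))
  if (length(missing) > 0)
    abort(paste0("features absent from expression table: ",
                 paste(head(missing, 5), collapse = ", ")))
  const <- rownames(m)[apply(m, 1, sd) == 0]
  if (length(const) > 0) {
    inform(paste0("trans_targets: skipped ", length(const),
                  " constant feature(s)"))
    de_lnc <- setdiff(de_lnc, const)
    de_mrna <- setdiff(de_mrna, const)
  }
  if (length(de_lnc) == 0 || length(de_mrna) == 0)
    return(tibble(lncrna_id = character(), mrna_id = character(),
                  mode = character(), r = numeric(), p = numeric()))
  n <- ncol(m)
  R <- cor(t(m[de_lnc, , drop = FALSE]), t(m[de_mrna, , drop = FALSE]))
  R[R > 1] <- 1; R[R < -1] <- -1
  P <- matrix(mapply(pcc_pvalue, R, MoreArgs = list(n = n)), nrow = nrow(R))
  hit <- which(abs(R) > r_min & P < p_max, arr.ind = TRUE)
  edges <- tibble(lncrna_id = de_lnc[hit[, 1]],
                  mrna_id = de_mrna[hit[, 2]],
                  mode = "trans",
                  r = R[hit], p = P[hit]) %>%
    arrange(.data$lncrna_id, .data$mrna_id)
  if (!is.null(de)) edges <- add_edge_comparisons(edges, de)
  edges
}

add_edge_comparisons <- function(edges, de) {
  de_sets <- de %>%
    filter(.data$de) %>%
    distinct(.data$comparison, .data$feature_id)
  comps <- sort(unique(de$comparison))
  present <- vapply(seq_len(nrow(edges)), function(i) {
    both <- vapply(comps, function(cc) {
      ids <- de_sets$feature_id[de_sets$comparison == cc]
      edges$lncrna_id[i] %in% ids && edges$mrna_id[i] %in% ids
    }, logical(1))
    paste(comps[both], collapse = ";")
  }, character(1))
  edges$comparisons_present <- present
  edges$n_comparisons <- vapply(strsplit(present, ";"),
                                function(x) sum(nzchar(x)), integer(1))
  edges
}

#' Pairs that are both cis and trans targets
#'
#' Intersects cis and trans edge sets on the (lncRNA, mRNA) pair key,
#' retaining distance, r and p.
#'
#' @param cis Edges from [cis_targets()].
#' @param trans Edges from [trans_targets()].
#' @return Tibble of edges with `mode = "both"`.
#' @export
combine_cis_trans <- function(cis, trans) {
  inner_join(select(cis, "lncrna_id", "mrna_id", "distance_bp"),
             select(trans, -"mode"),
             by = c("lncrna_id", "mrna_id")) %>%
    mutate(mode = "both", .after = "mrna_id") %>%
    arrange(.data$lncrna_id, .data$mrna_id)
}

#' Flag sense-antisense (SA) pairs
#'
#' An edge is an SA pair when the lncRNA and the gene lie on opposite
#' strands and their spans overlap by at least 1 bp.
#'
#' @param edges Edge tibble (`lncrna_id`, `mrna_id`, ...).
#' @param lncrnas Tibble with lncRNA spans and strands.
#' @param genes Reference annotation tibble.
#' @return `edges` with a logical `sa_pair` column.
#' @export
sa_pairs <- function(edges, lncrnas, genes) {
  gs <- gene_spans(genes)
  li <- match(edges$lncrna_id, lncrnas$transcript_id)
  gi <- match(edges$mrna_id, gs$gene_id)
  stopifnot(!anyNA(li), !anyNA(gi))
  opp <- (lncrnas$strand[li] == "+" & gs$strand[gi] == "-") |
    (lncrnas$strand[li] == "-" & gs$strand[gi] == "+")
  overlap <- lncrnas$chrom[li] == gs$chrom[gi] &
    lncrnas$start[li] < gs$end[gi] & gs$start[gi] < lncrnas$end[li]
  edges$sa_pair <- opp & overlap
  edges
}

#' Degree tables of a regulatory edge set
#'
#' @param edges Edge tibble.
#' @return List with `lncrna` (per-lncRNA target counts) and `mrna`
#'   (per-mRNA regulator counts), each sorted by decreasing degree then
#'   id.
#' @export
degree_tables <- function(edges) {
  list(
    lncrna = edges %>% count(id = .data$lncrna_id, name = "degree") %>%
      arrange(dplyr::desc(.data$degree), .data$id),
    mrna = edges %>% count(id = .data$mrna_id, name = "degree") %>%
      arrange(dplyr::desc(.data$degree), .data$id)
  )
}

#' Assemble a regulatory network object
#'
#' Bundles an edge set with its node table (typed lncRNA/mRNA) for
#' export, tidying and plotting.
#'
#' @param edges Edge tibble (any of cis/trans/both, possibly row-bound).
#' @return List of class `reg_network` with `edges` and `nodes`.
#' @export
reg_network <- function(edges) {
  nodes <- bind_rows(
    tibble(id = unique(edges$lncrna_id), type = "lncRNA"),
    tibble(id = unique(edges$mrna_id), type = "mRNA")
  ) %>% arrange(.data$id)
  structure(list(edges = edges, nodes = nodes), class = "reg_network")
}

#' @export
tidy.reg_network <- function(x, ...) as_tibble(x$edges)

#' @export
glance.reg_network <- function(x, ...) {
  e <- x$edges
  tibble(n_nodes = nrow(x$nodes),
         n_lncrna = sum(x$nodes$type == "lncRNA"),
         n_mrna = sum(x$nodes$type == "mRNA"),
         n_edges = nrow(e),
         n_cis = sum(e$mode == "cis"),
         n_trans = sum(e$mode == "trans"),
         n_both = sum(e$mode == "both"),
         n_sa = if ("sa_pair" %in% names(e)) sum(e$sa_pair) else NA_integer_)
}

#' Write a regulatory network as node/edge TSV files
#' @param x A `reg_network`.
#' @param path_prefix Output prefix (see [write_network_tsv()]).
#' @return The written paths, invisibly.
#' @export
write_reg_network <- function(x, path_prefix) {
  edges <- x$edges %>% rename(from = "lncrna_id", to = "mrna_id")
  write_network_tsv(x$nodes, edges, path_prefix)
}
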