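# Shared fixture builders. Everything is generated in code; the small
# parameter set keeps per-file runtime low while exercising every
# planted structure.

small_params <- function(seed = 42) {
  sim_params(seed = seed, n_genes = 60, n_lnc_per_class = 6,
             n_fail_per_kind = 3, n_planted_trans_pairs = 20,
             n_mirnas = 3, n_species = 3, n_families = 5,
             n_lnc_per_species = 8)
}

# one-row transcript tibble in the package's annotation schema
make_tx <- function(id, chrom = "chr1", strand = "+",
                    exons = list(c(0, 300)), gene_id = id,
                    biotype = "assembled") {
  ex <- tibble::tibble(
    start = vapply(exons, `[`, numeric(1), 1),
    end = vapply(exons, `[`, numeric(1), 2))
  tibble::tibble(
    transcript_id = id, gene_id = gene_id, chrom = chrom,
    start = min(ex$start), end = max(ex$end), strand = strand,
    biotype = biotype, exons = list(ex), n_exons = nrow(ex),
    length = sum(ex$end - ex$start))
}

# a three-exon protein-coding gene at `s` (exons of 400 nt, introns of
# 2000 nt), the geometry used by the annotation simulator
make_coding_gene <- function(id, s, strand = "+", chrom = "chr1") {
  make_tx(paste0(id, ".t1"), chrom, strand,
          exons = list(c(s, s + 400), c(s + 2400, s + 2800),
                       c(s + 4800, s + 5200)),
          gene_id = id, biotype = "protein_coding")
}

# expression table with a single constant value for the given features
flat_expr <- function(feature_ids, value = 5) {
  stages <- c("control", "T1")
  samples <- as.vector(outer(stages, 1:2, paste, sep = "_"))
  m <- matrix(value, nrow = length(feature_ids),
              ncol = length(samples),
              dimnames = list(feature_ids, samples))
  fpkm_matrix(m)
}

# site pairing a miRNA given its per-position partner bases (see the
# duplex conventions): partners reversed, with optional bulged bases
# inserted between the partners of positions k and k+1
decoy_site <- function(partners, bulge_k = NA, bulge_len = 0,
                       bulge_bases = NULL) {
  L <- length(partners)
  if (bulge_len == 0) return(paste(rev(partners), collapse = ""))
  bulge_bases <- bulge_bases %||%
    sample(c("A", "C", "G", "T"), bulge_len, replace = TRUE)
  paste(c(rev(partners[(bulge_k + 1):L]), bulge_bases,
          rev(partners[1:bulge_k])), collapse = "")
}

complement1 <- c(A = "T", C = "G", G = "C", T = "A")
mismatch1 <- c(A = "G", C = "A", G = "A", T = "C")

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
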