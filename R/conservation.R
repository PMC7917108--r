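# Cross-species conservation: a deterministic seeded nucleotide aligner
# (word-seeded, ungapped extension, Karlin-Altschul E-values) as the
# zero-dependency stand-in for BLASTN, plus precursor-family accounting.
# Precomputed BLAST tabular hits (read_blast_tab) are the alternative
# production path; both feed the same downstream set logic.

#' Seeded ungapped homology search between two sequence sets
#'
#' Finds local, gap-free alignments between every query and subject
#' sequence that share at least one exact word of `word_size`
#' nucleotides. Each seed-containing diagonal is scanned for its
#' best-scoring contiguous segment (match `+1`, mismatch `-2`), and the
#' best segment per query/subject pair is reported with a
#' Karlin-Altschul-style E-value `E = K * m * N * exp(-lambda * S)`
#' (`m` query length, `N` total subject length). Hits with
#' `E < max_evalue` (strict) are returned. Fully deterministic.
#'
#' @param query,subject Named character vectors of nucleotide sequences.
#' @param max_evalue Strict E-value cutoff (default `1e-5`).
#' @param word_size Seed word length (default 11).
#' @param match,mismatch Scoring (default +1/-2).
#' @param lambda,K Karlin-Altschul parameters for the +1/-2 scheme
#'   (defaults 1.33 and 0.621; fixed, not tuned).
#' @param subject_species Optional species label attached to every hit.
#' @return Tibble of hits in BLAST outfmt-6 column layout (snake case)
#'   plus `subject_species`, best hit per query/subject pair, sorted by
#'   ascending E-value.
#' @export
homology_search <- function(query, subject, max_evalue = 1e-5,
                            word_size = 11, match = 1, mismatch = -2,
                            lambda = 1.33, K = 0.621,
                            subject_species = NA) {
  if (length(query) == 0 || length(subject) == 0) return(empty_hits())
  stopifnot(!is.null(names(query)), !is.null(names(subject)))
  n_db <- sum(nchar(subject))
  subj_chars <- lapply(subject, function(s) strsplit(s, "")[[1]])
  subj_index <- lapply(subject, seq_index, word_size = word_size)
  rows <- list()
  for (qi in seq_along(query)) {
    qseq <- query[[qi]]
    m <- nchar(qseq)
    if (m < word_size) next
    qchars <- strsplit(qseq, "")[[1]]
    qwords <- seq_words(qseq, word_size)
    for (si in seq_along(subject)) {
      idx <- subj_index[[si]]
      diags <- integer(0)
      for (i in seq_along(qwords)) {
        js <- idx[[qwords[i]]]
        if (!is.null(js)) diags <- c(diags, js - i)
      }
      diags <- sort(unique(diags))
      if (length(diags) == 0) next
      schars <- subj_chars[[si]]
      n <- length(schars)
      best <- NULL
      for (d in diags) {
        # overlap of query positions i with subject positions i + d
        i0 <- max(1L, 1L - d)
        i1 <- min(m, n - d)
        if (i1 - i0 + 1 < word_size) next
        qs <- qchars[i0:i1]
        ss <- schars[(i0:i1) + d]
        eq <- qs == ss
        seg <- max_subarray(ifelse(eq, match, mismatch))
        if (seg$score <= 0) next
        cand <- list(score = seg$score,
                     q_start = i0 + seg$from - 1L,
                     q_end = i0 + seg$to - 1L,
                     d = d,
                     n_ident = sum(eq[seg$from:seg$to]))
        if (is.null(best) || cand$score > best$score ||
            (cand$score == best$score && cand$q_start < best$q_start))
          best <- cand
      }
      if (is.null(best)) next
      len <- best$q_end - best$q_start + 1L
      e_val <- K * m * n_db * exp(-lambda * best$score)
      rows[[length(rows) + 1]] <- tibble(
        query_id = names(query)[qi], subject_id = names(subject)[si],
        percent_identity = 100 * best$n_ident / len,
        alignment_length = len, mismatches = len - best$n_ident,
        gap_opens = 0L,
        q_start = best$q_start, q_end = best$q_end,
        s_start = best$q_start + best$d, s_end = best$q_end + best$d,
        e_value = e_val,
        bit_score = (lambda * best$score - log(K)) / log(2),
        subject_species = as.character(subject_species))
    }
  }
  if (length(rows) == 0) return(empty_hits())
  hits <- bind_rows(rows)
  hits <- hits[hits$e_value < max_evalue, , drop = FALSE]
  arrange(hits, .data$e_value, .data$query_id, .data$subject_id)
}

seq_words <- function(seq, word_size) {
  n <- nchar(seq)
  if (n < word_size) return(character(0))
  starts <- 1:(n - word_size + 1)
  substring(seq, starts, starts + word_size - 1)
}

seq_index <- function(seq, word_size) {
  w <- seq_words(seq, word_size)
  idx <- split(seq_along(w), w)
  list2env(idx, hash = TRUE, size = max(1L, length(idx)))
}

# Kadane's maximum contiguous subarray, with 1-based bounds.
max_subarray <- function(v) {
  best <- 0; cur <- 0; from <- 1L; to <- 0L; cur_from <- 1L
  for (i in seq_along(v)) {
    if (cur <= 0) { cur <- v[i]; cur_from <- i } else cur <- cur + v[i]
    if (cur > best) { best <- cur; from <- cur_from; to <- i }
  }
  list(score = best, from = from, to = to)
}

#' Share of query sequences with at least one homolog
#'
#' @param query Named character vector of query sequences (or a character
#'   vector of query ids, or a single total count).
#' @param hits Hit tibble referencing `query_id`.
#' @return One-row tibble: `n_with_homolog`, `n_total`, `percent`
#'   (rounded to 2 digits, half-even).
#' @export
homolog_share <- function(query, hits) {
  n_total <- if (is.numeric(query)) as.integer(query)
  else length(query)
  ids <- if (is.numeric(query)) unique(hits$query_id)
  else intersect(unique(hits$query_id),
                 if (is.null(names(query))) query else names(query))
  n <- length(ids)
  tibble(n_with_homolog = n, n_total = n_total,
         percent = percent_of(n, n_total))
}

#' Scan lncRNAs for miRNA-precursor (hairpin) content
#'
#' Searches every lncRNA against a set of miRNA hairpin sequences and
#' reports one record per (lncRNA, family) with at least one qualifying
#' hit at `E < max_evalue`. The family of a hairpin is its header token
#' before the first `_` or `-` separator (so cross-species hairpins of
#' one family collapse). A lncRNA may match several families.
#'
#' @param lncrnas Named character vector of lncRNA sequences.
#' @param hairpins Named character vector of hairpin sequences
#'   (names like `MIR400_bra`).
#' @param max_evalue Strict E-value cutoff.
#' @return Tibble with `lncrna_id`, `family`.
#' @export
precursor_scan <- function(lncrnas, hairpins, max_evalue = 1e-5) {
  hits <- homology_search(lncrnas, hairpins, max_evalue = max_evalue)
  if (nrow(hits) == 0)
    return(tibble(lncrna_id = character(), family = character()))
  hits %>%
    mutate(family = hairpin_family(.data$subject_id)) %>%
    distinct(lncrna_id = .data$query_id, .data$family) %>%
    arrange(.data$lncrna_id, .data$family)
}

hairpin_family <- function(id) sub("[_-].*$", "", id)

#' Family-by-species presence matrix
#'
#' @param records Tibble with `species` and `family` (one row per
#'   detected precursor family in a species; duplicates collapse).
#' @return Wide tibble: `family` column plus one logical column per
#'   species.
#' @export
family_presence <- function(records) {
  stopifnot(all(c("species", "family") %in% names(records)))
  records %>%
    distinct(.data$family, .data$species) %>%
    mutate(present = TRUE) %>%
    pivot_wider(names_from = "species", values_from = "present",
                values_fill = FALSE) %>%
    arrange(.data$family)
}

#' Common and unique precursor families
#'
#' `common`: families present in *all* members of `species_subset`.
#' `unique`: families present in exactly one species of the whole matrix,
#' with that species.
#'
#' @param presence Presence matrix from [family_presence()].
#' @param species_subset Species over which to intersect (default: all
#'   species in the matrix).
#' @return List with `common` (character), `unique` (tibble `family`,
#'   `species`), `n_common`, `n_unique`.
#' @export
unique_common <- function(presence, species_subset = NULL) {
  species <- setdiff(names(presence), "family")
  species_subset <- species_subset %||% species
  missing <- setdiff(species_subset, species)
  if (length(missing) > 0)
    abort(paste0("species absent from presence matrix: ",
                 paste(missing, collapse = ", ")))
  grid <- as.matrix(presence[species])
  common <- presence$family[rowSums(grid[, species_subset, drop = FALSE]) ==
                              length(species_subset)]
  uniq_rows <- which(rowSums(grid) == 1)
  uniq <- tibble(
    family = presence$family[uniq_rows],
    species = species[apply(grid[uniq_rows, , drop = FALSE], 1, which)])
  list(common = common, unique = uniq,
       n_common = length(common), n_unique = nrow(uniq))
}
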