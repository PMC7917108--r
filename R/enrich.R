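# Hypergeometric functional enrichment and the summary arithmetic used
# in reporting (printed-percentage rounding, sequencing-run aggregation,
# lncRNA set summaries).

#' Hypergeometric (upper-tail) enrichment with BH correction
#'
#' For each term, tests over-representation of the query set in the term
#' via `P(X >= k)` under hypergeometric(N, K, n), where N is the
#' background size, K the term size within the background, n the query
#' size and k the overlap. Q-values are Benjamini-Hochberg across all
#' tested terms; a term is significant when `q < alpha_q`.
#'
#' @param query Character vector of feature ids (must be a subset of
#'   `background`).
#' @param background Character vector of background feature ids.
#' @param term_map Tibble with `term_id`, `term_name`, `gene_id`.
#' @param alpha_q Significance threshold on q (default 0.05).
#' @return Tibble of class `lnc_enrichment`: `term_id`, `term_name`,
#'   `k`, `K`, `n`, `N`, `p_value`, `q_value`, `significant`, sorted by
#'   p.
#' @export
hypergeom_enrich <- function(query, background, term_map,
                             alpha_q = 0.05) {
  background <- unique(background)
  if (length(background) == 0) abort("empty background set")
  query <- unique(query)
  stray <- setdiff(query, background)
  if (length(stray) > 0)
    abort(paste0("query features missing from background: ",
                 paste(head(stray, 5), collapse = ", ")))
  tm <- term_map %>%
    filter(.data$gene_id %in% background) %>%
    distinct(.data$term_id, .data$term_name, .data$gene_id)
  N <- length(background)
  n <- length(query)
  res <- tm %>%
    group_by(.data$term_id, .data$term_name) %>%
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = sum(unique(.data$gene_id) %in% query),
              .groups = "drop") %>%
    mutate(n = n, N = N,
           p_value = phyper(.data$k - 1, .data$K, N - .data$K, n,
                            lower.tail = FALSE))
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < alpha_q
  res <- arrange(res, .data$p_value, .data$term_id)
  structure(res, alpha_q = alpha_q,
            class = c("lnc_enrichment", class(tibble())))
}

#' @export
glance.lnc_enrichment <- function(x, ...) {
  tibble(n_terms = nrow(x), n_significant = sum(x$significant),
         alpha_q = attr(x, "alpha_q"))
}

#' Printed percentage of a count
#'
#' `round(100 * count / total, digits)` with R's round-half-even, the
#' rounding used for all printed percentages in the package so that
#' reported numbers are deterministic.
#'
#' @param count,total Non-negative counts, `count <= total`,
#'   `total > 0`.
#' @param digits Decimal places (default 2).
#' @return Numeric percentage.
#' @export
percent_of <- function(count, total, digits = 2) {
  if (any(total <= 0)) abort("percent_of: total must be positive")
  stopifnot(all(count >= 0), all(count <= total))
  round(100 * count / total, digits)
}

#' Read the bundled heat-stress sequencing-run statistics
#'
#' Per-replicate clean read counts, clean bases, Q30 percentages and
#' uniquely mapped read counts for a five-stage (control + four heating
#' durations) by three-replicate lncRNA sequencing experiment in Chinese
#' cabbage; input for [aggregate_sample_stats()].
#'
#' @return Tibble with `sample`, `replicate`, `clean_reads`,
#'   `clean_bases_gb`, `q30_percent`, `unique_mapped_reads`.
#' @export
sequencing_stats <- function() {
  path <- system.file("extdata", "heat_stress_seq_stats.tsv",
                      package = "lncregnet")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Aggregate sequencing-run statistics
#'
#' @param rows Tibble as returned by [sequencing_stats()].
#' @return List with `total_clean_bases_gb` (sum over all replicates,
#'   2 digits), `per_sample` (per-sample sums of reads and bases), and
#'   `per_replicate` (the input plus `mapped_percent`, the unique-mapped
#'   share of clean reads).
#' @export
aggregate_sample_stats <- function(rows) {
  stopifnot(nrow(rows) >= 1,
            all(rows$unique_mapped_reads <= rows$clean_reads))
  per_sample <- rows %>%
    group_by(.data$sample) %>%
    summarise(clean_reads = sum(.data$clean_reads),
              clean_bases_gb = round(sum(.data$clean_bases_gb), 2),
              .groups = "drop")
  per_replicate <- rows %>%
    mutate(mapped_percent = percent_of(.data$unique_mapped_reads,
                                       .data$clean_reads))
  list(total_clean_bases_gb = round(sum(rows$clean_bases_gb), 2),
       per_sample = per_sample,
       per_replicate = per_replicate)
}

#' Summary statistics of a lncRNA set
#'
#' @param catalog An `lnc_catalog` (or any tibble with `retained`,
#'   `length`, `n_exons`, `positional_class`); only retained rows are
#'   summarized.
#' @param expr Optional `fpkm_tbl` for mean/median FPKM (per-feature
#'   mean across samples).
#' @return List with `stats` (one-row tibble: `n`, `mean_length`,
#'   `median_length`, `mean_exons`, `mean_fpkm`, `median_fpkm`) and
#'   `class_counts` (tibble `positional_class`, `n`, `percent`).
#' @export
summarize_lncrnas <- function(catalog, expr = NULL) {
  kept <- if ("retained" %in% names(catalog))
    catalog[catalog$retained, , drop = FALSE] else catalog
  if (nrow(kept) == 0) {
    return(list(
      stats = tibble(n = 0L, mean_length = 0, median_length = 0,
                     mean_exons = 0, mean_fpkm = 0, median_fpkm = 0),
      class_counts = tibble(positional_class = character(),
                            n = integer(), percent = numeric())))
  }
  fpkm <- rep(NA_real_, nrow(kept))
  if (!is.null(expr)) {
    m <- rowMeans(expr_matrix(expr))
    fpkm <- unname(m[kept$transcript_id])
  }
  stats <- tibble(
    n = nrow(kept),
    mean_length = mean(kept$length),
    median_length = median(kept$length),
    mean_exons = mean(kept$n_exons),
    mean_fpkm = if (all(is.na(fpkm))) NA_real_ else
      mean(fpkm, na.rm = TRUE),
    median_fpkm = if (all(is.na(fpkm))) NA_real_ else
      median(fpkm, na.rm = TRUE))
  class_counts <- kept %>%
    count(.data$positional_class) %>%
    mutate(percent = percent_of(.data$n, sum(.data$n))) %>%
    arrange(dplyr::desc(.data$n))
  list(stats = stats, class_counts = class_counts)
}
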