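# Expression-level machinery over the FPKM matrix: the container, stage
# detection, the Pearson correlation core used by the trans network, and
# the documented two-group differential-expression stand-in.

#' Construct an FPKM expression table
#'
#' The package-wide expression container: a wide tibble (one row per
#' feature, one column per sample) carrying the sample-to-stage design as
#' attributes. Values are FPKM and must be non-negative; every sample
#' maps to exactly one stage and each stage has at least one sample.
#'
#' @param values Matrix (features x samples, with dimnames) or wide tibble
#'   whose first column is `feature_id`.
#' @param samples Tibble with `sample_id`, `stage`, `replicate`. Defaults
#'   to parsing `stage_rep` sample names.
#' @param stage_order Stage labels in treatment order; defaults to order
#'   of first appearance in `samples`.
#' @return A tibble of class `fpkm_tbl`.
#' @export
fpkm_matrix <- function(values, samples = NULL, stage_order = NULL) {
  if (is.matrix(values)) {
    stopifnot(!is.null(rownames(values)), !is.null(colnames(values)))
    tbl <- bind_cols(tibble(feature_id = rownames(values)),
                     as_tibble(values))
  } else {
    tbl <- as_tibble(values)
    names(tbl)[1] <- "feature_id"
  }
  sample_ids <- setdiff(names(tbl), "feature_id")
  if (is.null(samples)) {
    parts <- strsplit(sample_ids, "_")
    stopifnot(all(lengths(parts) == 2))
    samples <- tibble(sample_id = sample_ids,
                      stage = vapply(parts, `[`, "", 1L),
                      replicate = vapply(parts, `[`, "", 2L))
  }
  stopifnot(setequal(samples$sample_id, sample_ids),
            !anyDuplicated(samples$sample_id))
  vals <- as.matrix(tbl[sample_ids])
  if (any(vals < 0)) abort("FPKM values must be non-negative")
  if (anyDuplicated(tbl$feature_id)) abort("duplicate feature ids")
  stage_order <- stage_order %||% unique(samples$stage)
  stopifnot(setequal(stage_order, unique(samples$stage)))
  structure(tbl,
            samples = samples[match(sample_ids, samples$sample_id), ],
            stage_order = stage_order,
            class = c("fpkm_tbl", class(tibble())))
}

#' Sample design of an expression table
#' @param expr An `fpkm_tbl`.
#' @return Tibble with `sample_id`, `stage`, `replicate`.
#' @export
sample_info <- function(expr) attr(expr, "samples")

#' Stage labels of an expression table, in treatment order
#' @param expr An `fpkm_tbl`.
#' @return Character vector.
#' @export
stage_order <- function(expr) attr(expr, "stage_order")

#' Expression values as a plain numeric matrix
#' @param expr An `fpkm_tbl`.
#' @return Matrix, features in rows, samples in columns.
#' @export
expr_matrix <- function(expr) {
  m <- as.matrix(expr[setdiff(names(expr), "feature_id")])
  rownames(m) <- expr$feature_id
  storage.mode(m) <- "double"
  m
}

#' Per-stage mean FPKM
#' @param expr An `fpkm_tbl`.
#' @return Matrix, features in rows, stages (in treatment order) in
#'   columns.
#' @export
stage_means <- function(expr) {
  m <- expr_matrix(expr)
  si <- sample_info(expr)
  stages <- stage_order(expr)
  out <- vapply(stages, function(s)
    rowMeans(m[, si$sample_id[si$stage == s], drop = FALSE]),
    numeric(nrow(m)))
  rownames(out) <- rownames(m)
  out
}

#' Write / read an FPKM table as TSV
#'
#' First column `feature_id`, header row of sample ids in `stage_rep`
#' form.
#' @param expr An `fpkm_tbl`.
#' @param path Output path.
#' @return `path` invisibly (write); an `fpkm_tbl` (read).
#' @export
write_fpkm_tsv <- function(expr, path) {
  readr::write_tsv(as_tibble(expr), path)
  invisible(path)
}

#' @rdname write_fpkm_tsv
#' @param stage_order Passed to [fpkm_matrix()].
#' @export
read_fpkm_tsv <- function(path, stage_order = NULL) {
  fpkm_matrix(readr::read_tsv(path, show_col_types = FALSE),
              stage_order = stage_order)
}

#' Features detected at a stage
#'
#' A feature counts as detected at a stage when its mean FPKM across that
#' stage's replicates exceeds `min_fpkm` (strict). The threshold is a
#' package choice (the field has no universal value) and is recorded on
#' the result.
#'
#' @param expr An `fpkm_tbl`.
#' @param stage Stage label.
#' @param min_fpkm Detection threshold (default 0.1).
#' @return Character vector of feature ids, with attribute `min_fpkm`.
#' @export
detect_expressed <- function(expr, stage, min_fpkm = 0.1) {
  if (!stage %in% stage_order(expr))
    abort(paste0("unknown stage: ", stage))
  sm <- stage_means(expr)
  ids <- rownames(sm)[sm[, stage] > min_fpkm]
  structure(ids, min_fpkm = min_fpkm)
}

#' Features detected exclusively at one stage
#'
#' @param detected Named list of per-stage detection sets (see
#'   [detect_expressed()]).
#' @return Tibble with `stage` and `feature_id`, one row per feature
#'   detected at exactly that stage and no other.
#' @export
stage_specific <- function(detected) {
  stopifnot(!is.null(names(detected)))
  all_ids <- unlist(detected, use.names = FALSE)
  times_seen <- table(all_ids)
  once <- names(times_seen)[times_seen == 1]
  bind_rows(lapply(names(detected), function(s) {
    tibble(stage = s, feature_id = intersect(detected[[s]], once))
  }))
}

#' Pearson correlation with two-sided t-test p-value
#'
#' Product-moment correlation computed by direct summation, with the
#' two-sided p-value from the t transform `t = r * sqrt((n-2)/(1-r^2))`
#' on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return One-row tibble with `r`, `p_value`, `n`.
#' @export
pcc <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    abort("correlation undefined for a constant vector")
  dx <- x - mean(x)
  dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  r <- max(-1, min(1, r))
  p <- pcc_pvalue(r, n)
  tibble(r = r, p_value = p, n = n)
}

pcc_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
}

#' Two-group differential expression (t-test stand-in)
#'
#' A deliberately simple two-sample test on `log2(FPKM + 1)` with
#' Benjamini-Hochberg adjustment across features within the comparison.
#' It is *not* equivalent to assembly-aware DE tools; precomputed DE
#' tables can be supplied to downstream steps instead.
#'
#' @param expr An `fpkm_tbl`.
#' @param stage_a Treatment stage.
#' @param stage_b Reference stage (the comparison is named
#'   `stageA_vs_stageB`).
#' @param alpha_q Significance threshold on the BH-adjusted q-value.
#' @return Tibble of class `de_result`: `feature_id`, `comparison`,
#'   `log2fc`, `p_value`, `q_value`, `direction`, `de`.
#' @export
de_call <- function(expr, stage_a, stage_b, alpha_q = 0.05) {
  si <- sample_info(expr)
  a_cols <- si$sample_id[si$stage == stage_a]
  b_cols <- si$sample_id[si$stage == stage_b]
  if (length(a_cols) < 2 || length(b_cols) < 2)
    abort("de_call requires >= 2 replicates per stage")
  m <- log2(expr_matrix(expr) + 1)
  a <- m[, a_cols, drop = FALSE]
  b <- m[, b_cols, drop = FALSE]
  log2fc <- rowMeans(a) - rowMeans(b)
  p <- vapply(seq_len(nrow(m)), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    if (sd(xa) == 0 && sd(xb) == 0) return(1)
    t.test(xa, xb)$p.value
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  out <- tibble(
    feature_id = rownames(m),
    comparison = paste0(stage_a, "_vs_", stage_b),
    log2fc = log2fc, p_value = p, q_value = q,
    direction = if_else(log2fc >= 0, "up", "down"),
    de = q < alpha_q
  )
  structure(out, alpha_q = alpha_q,
            class = c("de_result", class(tibble())))
}

#' Differential expression across all treatment stages vs the reference
#'
#' Runs [de_call()] for every non-reference stage against the reference
#' (first stage in treatment order by default), mirroring the
#' treatment-vs-control design of a stress time course.
#'
#' @param expr An `fpkm_tbl`.
#' @param reference Reference stage (default: first of
#'   [stage_order()]).
#' @param alpha_q Significance threshold.
#' @return Row-bound `de_result` tibble over all comparisons.
#' @export
de_all_stages <- function(expr, reference = NULL, alpha_q = 0.05) {
  stages <- stage_order(expr)
  reference <- reference %||% stages[1]
  out <- bind_rows(lapply(setdiff(stages, reference), function(s)
    de_call(expr, s, reference, alpha_q = alpha_q)))
  structure(out, alpha_q = alpha_q,
            class = c("de_result", class(tibble())))
}

#' @export
glance.de_result <- function(x, ...) {
  tibble(n_tests = nrow(x),
         n_comparisons = length(unique(x$comparison)),
         n_de = sum(x$de),
         n_features_de = length(unique(x$feature_id[x$de])))
}
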