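# ggplot2 helpers for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_histogram facet_wrap labs theme_minimal scale_y_log10
NULL

#' Plot positional-class composition of a lncRNA catalog
#' @param object An `lnc_catalog`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lnc_catalog <- function(object, ...) {
  kept <- object[object$retained, , drop = FALSE]
  counts <- dplyr::count(kept, .data$positional_class)
  ggplot(counts, aes(x = .data$positional_class, y = .data$n,
                     fill = .data$positional_class)) +
    geom_col(show.legend = FALSE) +
    labs(x = NULL, y = "lncRNAs",
         title = "Positional classes of retained lncRNAs") +
    theme_minimal()
}

#' Plot per-stage expression profiles of selected features
#'
#' Stage-mean `log2(FPKM + 1)` per feature across the treatment course.
#'
#' @param expr An `fpkm_tbl`.
#' @param features Feature ids to draw.
#' @return A ggplot.
#' @export
plot_stage_profiles <- function(expr, features) {
  sm <- stage_means(expr)
  stopifnot(all(features %in% rownames(sm)))
  long <- as_tibble(sm[features, , drop = FALSE],
                    rownames = "feature_id") %>%
    pivot_longer(-"feature_id", names_to = "stage",
                 values_to = "fpkm") %>%
    mutate(stage = factor(.data$stage, levels = colnames(sm)))
  ggplot(long, aes(x = .data$stage, y = log2(.data$fpkm + 1),
                   group = .data$feature_id,
                   colour = .data$feature_id)) +
    geom_line() + geom_point() +
    labs(x = "treatment stage", y = "log2(FPKM + 1)", colour = NULL) +
    theme_minimal()
}

#' Plot the degree distributions of a regulatory network
#' @param object A `reg_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reg_network <- function(object, ...) {
  deg <- degree_tables(object$edges)
  long <- bind_rows(
    mutate(deg$lncrna, role = "targets per lncRNA"),
    mutate(deg$mrna, role = "regulators per mRNA"))
  ggplot(long, aes(x = .data$degree)) +
    geom_histogram(bins = 30) +
    facet_wrap(~role, scales = "free") +
    labs(x = "degree", y = "nodes") +
    theme_minimal()
}

#' Plot top enriched terms
#' @param object An `lnc_enrichment`.
#' @param top Number of terms to draw (by p-value).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lnc_enrichment <- function(object, top = 20, ...) {
  d <- head(arrange(as_tibble(object), .data$p_value), top)
  ggplot(d, aes(x = -log10(.data$q_value),
                y = stats::reorder(.data$term_name, -.data$p_value),
                size = .data$k, colour = .data$significant)) +
    geom_point() +
    labs(x = "-log10(q)", y = NULL, size = "overlap",
         colour = "q < threshold") +
    theme_minimal()
}
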