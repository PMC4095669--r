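# ggplot2 views of the main result types. Each autoplot returns a ggplot the
# caller can restyle; nothing is printed as a side effect.

#' @describeIn coex_network Degree distribution of the network (isolated
#'   genes included).
#' @param object A `coex_network`.
#' @export
autoplot.coex_network <- function(object, ...) {
  deg <- network_degrees(object)
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::labs(
      x = "degree", y = "genes",
      title = sprintf("Degree distribution (%d genes, %d edges)",
                      length(object$universe), nrow(object$edges)),
      subtitle = sprintf("%s, %s rule, threshold %.3g",
                         object$method, object$edge_rule, object$threshold)) +
    ggplot2::theme_minimal()
}

#' @describeIn test_all_genes Seed connectivity overview: each gene's degree
#'   against `-log10(p)`, seed genes highlighted, with the conventional
#'   `1e-8` friend cutoff drawn.
#' @param object A `seed_friend_test`.
#' @param alpha Cutoff line to draw (default `1e-8`).
#' @export
autoplot.seed_friend_test <- function(object, alpha = 1e-8, ...) {
  tbl <- object$results
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$n, y = -.data$log10_p,
                                    colour = .data$is_seed)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                                 labels = c(`FALSE` = "other", `TRUE` = "seed"),
                                 name = NULL) +
    ggplot2::labs(x = "degree n", y = expression(-log[10](p)),
                  title = sprintf("Connectivity to the '%s' set (%d genes)",
                                  object$seed_name, length(object$seed))) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_friend_sets Category counts as a bar chart.
#' @param object A `friend_comparison`.
#' @export
autoplot.friend_comparison <- function(object, ...) {
  counts <- dplyr::count(object$table, .data$category)
  counts$category <- factor(counts$category,
                            levels = c("both", "only_a", "only_b", "unassessable"))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = sprintf("Friend overlap: %s vs %s",
                                  object$label_a, object$label_b)) +
    ggplot2::theme_minimal()
}

#' Bar chart of top enriched terms
#'
#' @param rows An enrichment tibble from [enrich()].
#' @param top_n Number of terms to show (by ascending p-value).
#' @return A ggplot.
#' @export
plot_enrichment <- function(rows, top_n = 10) {
  rows <- head(rows[order(rows$p_value), , drop = FALSE], top_n)
  if (nrow(rows) == 0L) abort_empty("no enrichment rows to plot.")
  rows$term <- factor(rows$term_name, levels = rev(rows$term_name))
  ggplot2::ggplot(rows, ggplot2::aes(x = -log10(.data$p_value), y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  title = "Over-represented terms") +
    ggplot2::theme_minimal()
}
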