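#' @importFrom ggplot2 ggplot aes geom_point geom_jitter geom_boxplot
#'   geom_tile geom_text geom_segment geom_hline scale_fill_gradient2 labs
#'   theme_minimal facet_wrap scale_color_manual
NULL

#' Volcano-style view of an IVP correlation screen
#'
#' Plots each feature's squared correlation with IVP against -log10(p),
#' colored by whether it passes the retention rule.
#'
#' @param object An `ivp_screen` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ivp_screen <- function(object, ...) {
  s <- attr(object, "screen")
  ggplot(object, aes(x = r2, y = -log10(p), color = passes_nominal)) +
    geom_point(alpha = 0.7) +
    scale_color_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey60"),
                       name = "retained") +
    labs(x = expression(r^2 ~ "against IVP"), y = expression(-log[10](p)),
         title = sprintf("IVP screen (%s): %d of %d retained",
                         s$kind, sum(object$passes_nominal), s$m)) +
    theme_minimal()
}

#' IVP score distribution by clinical group
#'
#' @param phenotypes Phenotype tibble.
#' @return A ggplot object (boxplot plus jittered scores).
#' @export
plot_ivp_by_group <- function(phenotypes) {
  ggplot(phenotypes, aes(x = group, y = ivp_score)) +
    geom_boxplot(outlier.shape = NA, width = 0.5) +
    geom_jitter(width = 0.12, alpha = 0.7, aes(color = group)) +
    labs(x = NULL, y = "induced visceral pain (0-100)") +
    theme_minimal()
}

#' Heatmap of the family-by-gene linkage matrix
#'
#' Tile fill encodes the signed edge count (positive minus negative edges
#' from that family's OTUs to the gene); the printed number is the total
#' count, and tiles with at least one high (r^2 >= 0.5) edge are outlined.
#'
#' @param fgm A `family_gene_matrix` tibble.
#' @return A ggplot object.
#' @export
plot_family_gene_matrix <- function(fgm) {
  df <- dplyr::mutate(fgm, net = n_pos - n_neg, total = n_pos + n_neg)
  ggplot(df, aes(x = gene_id, y = family)) +
    geom_tile(aes(fill = net), color = "white") +
    geom_tile(data = df[df$any_high, ], fill = NA, color = "black",
              linewidth = 0.6) +
    geom_text(aes(label = total), size = 2.6) +
    scale_fill_gradient2(low = "#e08214", mid = "white", high = "#2166ac",
                         name = "net sign") +
    labs(x = NULL, y = NULL,
         title = "OTU-gene linkage counts by bacterial family") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Dumbbell plot of differential occupancy
#'
#' One segment per reported OTU connecting its occupancy fraction in the two
#' compared groups.
#'
#' @param object An `occupancy_delta` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occupancy_delta <- function(object, ...) {
  g <- attr(object, "groups")
  df <- dplyr::mutate(object,
                      otu_id = factor(otu_id, levels = rev(object$otu_id)))
  ggplot(df, aes(y = otu_id)) +
    geom_segment(aes(x = fraction_b, xend = fraction_a, yend = otu_id),
                 color = "grey70") +
    geom_point(aes(x = fraction_a, color = g[["a"]])) +
    geom_point(aes(x = fraction_b, color = g[["b"]])) +
    scale_color_manual(values = setNames(c("#b2182b", "#2166ac"), g),
                       name = NULL) +
    labs(x = "occupancy fraction", y = NULL,
         title = sprintf("Differential occupancy: %s vs %s",
                         g[["a"]], g[["b"]])) +
    theme_minimal()
}
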