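as_feature_ids <- function(x) {
  if (is.data.frame(x)) x$feature_id else as.character(x)
}

#' Cross-correlate IVP-correlated OTUs against IVP-correlated genes
#'
#' Stage 2 of the data-reduction design: every retained OTU is correlated
#' against every retained gene over the shared (responder) sample set. An
#' edge is `significant` when p < `p_max` (unadjusted; this stage applies no
#' multiplicity correction) and `high` when r^2 >= `high_r2` (default 0.5,
#' the "exceeds 50%" rule used for the strong tier of the linkage matrices).
#'
#' @param otu_hits,gene_hits Retained features: character vectors of ids or
#'   screen tibbles (their `feature_id` column is used).
#' @param abundance OTU abundance matrix.
#' @param expression Expression matrix.
#' @param sample_ids Samples over which to correlate (normally the stage-1
#'   responder set; see [screen_features()]).
#' @param p_max Edge significance level (strict).
#' @param high_r2 Threshold for the high-correlation flag (inclusive).
#' @return A `linkage_edges` tibble with one row per (OTU, gene) pair having
#'   a defined correlation: `otu_id`, `gene_id`, `n`, `r`, `r2`, `p`,
#'   `significant`, `high`. Pairs involving a constant feature are dropped
#'   with a message. Summary counts (edges, high edges, genes linked by at
#'   least one significant edge) via [glance()].
#' @export
cross_correlate <- function(otu_hits, gene_hits, abundance, expression,
                            sample_ids, p_max = 0.05, high_r2 = 0.5) {
  otus <- as_feature_ids(otu_hits)
  genes <- as_feature_ids(gene_hits)
  empty <- tibble(otu_id = character(), gene_id = character(), n = integer(),
                  r = double(), r2 = double(), p = double(),
                  significant = logical(), high = logical())
  if (length(otus) == 0 || length(genes) == 0) {
    warn("empty hit list; no linkage edges to compute.")
    class(empty) <- c("linkage_edges", class(empty))
    return(empty)
  }
  missing_o <- setdiff(otus, rownames(abundance))
  missing_g <- setdiff(genes, rownames(expression))
  if (length(missing_o) > 0 || length(missing_g) > 0) {
    abort(sprintf("hit ids absent from the matrices: %s",
                  paste(head(c(missing_o, missing_g), 5), collapse = ", ")),
          class = "painlink_validation_error")
  }
  samples <- intersect(sample_ids, intersect(colnames(abundance), colnames(expression)))
  n <- length(samples)
  if (n < 3) {
    abort("fewer than 3 shared samples for cross-correlation.",
          class = "painlink_validation_error")
  }
  A <- abundance[otus, samples, drop = FALSE]
  E <- expression[genes, samples, drop = FALSE]
  const_o <- apply(A, 1, sd) == 0
  const_g <- apply(E, 1, sd) == 0
  if (any(const_o) || any(const_g)) {
    inform(sprintf("dropping %d OTU(s) and %d gene(s) with zero variance over the sample set.",
                   sum(const_o), sum(const_g)))
    A <- A[!const_o, , drop = FALSE]
    E <- E[!const_g, , drop = FALSE]
  }
  if (nrow(A) == 0 || nrow(E) == 0) {
    class(empty) <- c("linkage_edges", class(empty))
    return(empty)
  }
  R <- cor(t(A), t(E))
  t_stat <- R * sqrt((n - 2) / pmax(1 - R^2, 0))
  P <- ifelse(abs(R) >= 1, 0, 2 * pt(-abs(t_stat), df = n - 2))
  out <- tibble(
    otu_id = rep(rownames(A), times = ncol(R)),
    gene_id = rep(colnames(R), each = nrow(R)),
    n = n,
    r = as.vector(R),
    r2 = as.vector(R)^2,
    p = as.vector(P)
  )
  out <- dplyr::mutate(out, significant = p < p_max, high = r2 >= high_r2)
  out <- dplyr::arrange(out, otu_id, gene_id)
  attr(out, "linkage") <- list(n_samples = n, p_max = p_max, high_r2 = high_r2)
  class(out) <- c("linkage_edges", class(out))
  out
}

#' @export
glance.linkage_edges <- function(x, ...) {
  sig <- x[x$significant, ]
  tibble(n_pairs = nrow(x),
         n_edges = nrow(sig),
         n_high = sum(x$high),
         n_otus_linked = dplyr::n_distinct(sig$otu_id),
         n_genes_linked = dplyr::n_distinct(sig$gene_id))
}

#' Family-by-gene linkage count matrix
#'
#' Aggregates significant linkage edges into the family-level matrix used to
#' display microbe--transcriptome coupling: for each (bacterial family, gene)
#' cell, the number of that family's OTUs correlating positively (`n_pos`)
#' and negatively (`n_neg`) with the gene, plus `any_high`, true when at
#' least one contributing edge has r^2 at or above the high threshold.
#'
#' @param edges A `linkage_edges` tibble.
#' @param taxonomy Taxonomy tibble; OTUs without a record are counted under
#'   family `"unclassified"` (with a message).
#' @return A `family_gene_matrix` tibble (`family`, `gene_id`, `n_pos`,
#'   `n_neg`, `any_high`). Per-family edge totals via [family_edge_totals()].
#' @export
build_family_gene_matrix <- function(edges, taxonomy) {
  sig <- edges[edges$significant, , drop = FALSE]
  fam <- family_of(sig$otu_id, taxonomy)
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(sig, family = fam), family, gene_id),
    n_pos = sum(r > 0),
    n_neg = sum(r < 0),
    any_high = any(high),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, family, gene_id)
  class(out) <- c("family_gene_matrix", class(out))
  out
}

family_of <- function(otu_ids, taxonomy) {
  fam <- taxonomy$family[match(otu_ids, taxonomy$otu_id)]
  n_missing <- sum(is.na(fam))
  if (n_missing > 0) {
    inform(sprintf("%d edge(s) from OTUs without a taxonomy record counted under family 'unclassified'.",
                   n_missing))
    fam[is.na(fam)] <- "unclassified"
  }
  fam
}

#' Total significant edges per bacterial family
#' @inheritParams build_family_gene_matrix
#' @return Tibble (`family`, `n_edges`) sorted by decreasing count.
#' @export
family_edge_totals <- function(edges, taxonomy) {
  sig <- edges[edges$significant, , drop = FALSE]
  fam <- family_of(sig$otu_id, taxonomy)
  dplyr::arrange(dplyr::count(tibble(family = fam), family, name = "n_edges"),
                 desc(n_edges), family)
}

#' Species-level roster of IVP-correlated OTUs
#'
#' Restricts an OTU screen to OTUs identified to the species level and
#' classifies each by direction (sign of its IVP correlation) and strength:
#' `strong` when |r| >= `strong_cut` (default 0.7), otherwise `moderate`.
#' When linkage edges are supplied, each record lists the genes linked to
#' that OTU by a high edge.
#'
#' @param otu_hits An `ivp_screen` tibble (or subset) carrying `feature_id`
#'   and `r` against IVP.
#' @param taxonomy Taxonomy tibble.
#' @param edges Optional `linkage_edges` tibble for the high-gene lists.
#' @param strong_cut |r| threshold for the strong tier (inclusive).
#' @return Tibble (`otu_id`, `species`, `r`, `direction`, `strength`,
#'   `high_genes` list-column).
#' @export
species_ivp_lists <- function(otu_hits, taxonomy, edges = NULL, strong_cut = 0.7) {
  tax <- taxonomy[match(otu_hits$feature_id, taxonomy$otu_id), ]
  keep <- !is.na(tax$species) & tax$species != "unclassified"
  sub <- otu_hits[keep, , drop = FALSE]
  tax <- tax[keep, , drop = FALSE]
  species_label <- ifelse(tax$genus == "unclassified", tax$species,
                          paste(tax$genus, tax$species))
  high_by_otu <- if (!is.null(edges)) {
    he <- edges[edges$high, c("otu_id", "gene_id")]
    split(he$gene_id, he$otu_id)
  } else {
    list()
  }
  tibble(
    otu_id = sub$feature_id,
    species = species_label,
    r = sub$r,
    direction = ifelse(sub$r >= 0, "positive", "negative"),
    strength = ifelse(abs(sub$r) >= strong_cut, "strong", "moderate"),
    high_genes = purrr::map(sub$feature_id, ~ sort(high_by_otu[[.x]] %||% character()))
  )
}

#' Export a linkage edge list
#'
#' Writes `otu_id`, `gene_id`, `r`, `p`, `high` as TSV in deterministic
#' (otu_id, gene_id) order, suitable for graph tools.
#'
#' @param edges A `linkage_edges` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path) {
  out <- dplyr::arrange(edges[c("otu_id", "gene_id", "r", "p", "high")],
                        otu_id, gene_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a linkage edge list written by [export_network()]
#' @param path Edge-list TSV path.
#' @return Tibble (`otu_id`, `gene_id`, `r`, `p`, `high`).
#' @export
read_network <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    otu_id = readr::col_character(), gene_id = readr::col_character(),
    r = readr::col_double(), p = readr::col_double(), high = readr::col_logical()
  ), progress = FALSE)
}
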