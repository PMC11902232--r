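#' @keywords internal
expression_stages <- function() {
  c("raw", "global_normalized", "log_scaled", "gene_summarized")
}

#' Processing stage of an expression matrix
#' @param expr An expression matrix.
#' @return The stage string (`"raw"` if untagged).
#' @export
expression_stage <- function(expr) {
  attr(expr, "stage") %||% "raw"
}

check_stage <- function(expr, expected) {
  got <- expression_stage(expr)
  if (!identical(got, expected)) {
    abort(sprintf("expression matrix is at stage '%s'; this step requires stage '%s'.",
                  got, expected),
          class = "painlink_stage_error")
  }
  invisible(expr)
}

#' Global-mean normalization of a raw expression matrix
#'
#' Scales every sample column so that its mean equals the grand mean of all
#' column means, the standard single-channel-array "global mean" adjustment.
#' After normalization every column mean equals the grand mean (to within
#' floating-point tolerance).
#'
#' @param expr Raw expression matrix (features x samples), all values > 0.
#' @return The normalized matrix, tagged stage `"global_normalized"`.
#' @export
global_mean_normalize <- function(expr) {
  assert_feature_matrix(expr, "expr")
  check_stage(expr, "raw")
  if (any(expr <= 0)) {
    abort("global-mean normalization requires strictly positive values (the log stage follows).",
          class = "painlink_validation_error")
  }
  cm <- colMeans(expr)
  grand <- mean(cm)
  out <- sweep(expr, 2, grand / cm, `*`)
  attr(out, "stage") <- "global_normalized"
  out
}

#' Natural-log transform scaled to a target mean intensity
#'
#' Takes natural logs and then shifts all values by a common constant so the
#' overall mean equals `target_log_value` (default `log(500)`, the customary
#' target signal for this array chemistry). The shift is additive in log
#' space, i.e. multiplicative on the intensity scale.
#'
#' @param expr Expression matrix at stage `"global_normalized"`, values > 0.
#' @param target_log_value Target overall mean on the natural-log scale.
#' @return The log-scaled matrix, tagged stage `"log_scaled"`.
#' @export
log_scale_to_target <- function(expr, target_log_value = log(500)) {
  assert_feature_matrix(expr, "expr")
  check_stage(expr, "global_normalized")
  if (any(expr <= 0)) {
    abort("log transform requires strictly positive values.",
          class = "painlink_validation_error")
  }
  lg <- log(expr)
  out <- lg + (target_log_value - mean(lg))
  attr(out, "stage") <- "log_scaled"
  out
}

#' Summarize probe-level expression to one value per gene
#'
#' Collapses a log-scaled probe matrix to gene level using the per-sample
#' median (default) or mean over each gene's probes. Probes absent from the
#' map ("unspecified" probes) are dropped and counted in a message.
#'
#' @param expr Expression matrix at stage `"log_scaled"` with probe rownames.
#' @param probe_gene_map Tibble/data frame with columns `probe_id`, `gene_id`;
#'   each probe may appear at most once.
#' @param method `"median"` (default) or `"mean"`.
#' @return A gene-by-sample matrix tagged stage `"gene_summarized"`, genes in
#'   order of first appearance in the map (restricted to probes present).
#' @export
summarize_probes_to_genes <- function(expr, probe_gene_map, method = c("median", "mean")) {
  assert_feature_matrix(expr, "expr")
  check_stage(expr, "log_scaled")
  method <- match.arg(method)
  fun <- if (method == "median") median else mean
  map <- as_tibble(probe_gene_map)
  if (!all(c("probe_id", "gene_id") %in% names(map)) || nrow(map) == 0) {
    abort("probe_gene_map must be a nonempty table with columns probe_id, gene_id.",
          class = "painlink_format_error")
  }
  if (anyDuplicated(map$probe_id)) {
    abort("probe_gene_map maps some probe more than once.",
          class = "painlink_validation_error")
  }
  gene_of <- setNames(map$gene_id, map$probe_id)
  probes <- rownames(expr)
  mapped <- probes %in% names(gene_of)
  n_drop <- sum(!mapped)
  if (n_drop > 0) {
    inform(sprintf("dropping %d unmapped probe(s) before gene summarization.", n_drop))
  }
  if (!any(mapped)) {
    abort("no probe in the expression matrix is covered by the map.",
          class = "painlink_validation_error")
  }
  sub <- expr[mapped, , drop = FALSE]
  genes_per_row <- gene_of[rownames(sub)]
  gene_order <- unique(genes_per_row)
  idx <- split(seq_len(nrow(sub)), factor(genes_per_row, levels = gene_order))
  out <- t(vapply(idx, function(i) {
    apply(sub[i, , drop = FALSE], 2, fun)
  }, numeric(ncol(sub))))
  colnames(out) <- colnames(sub)
  attr(out, "stage") <- "gene_summarized"
  out
}

#' Run the full expression preprocessing chain
#'
#' `global_mean_normalize()` then [log_scale_to_target()] then (if a probe map
#' is supplied) [summarize_probes_to_genes()]. The chain is scale-equivariant:
#' multiplying the raw input by any positive constant leaves the log-scaled
#' output unchanged.
#'
#' @inheritParams summarize_probes_to_genes
#' @inheritParams log_scale_to_target
#' @param expr Raw expression matrix.
#' @return The prepared matrix at stage `"log_scaled"` or `"gene_summarized"`.
#' @export
prep_expression <- function(expr, probe_gene_map = NULL,
                            target_log_value = log(500),
                            method = c("median", "mean")) {
  out <- log_scale_to_target(global_mean_normalize(expr), target_log_value)
  if (!is.null(probe_gene_map)) {
    out <- summarize_probes_to_genes(out, probe_gene_map, method = method)
  }
  out
}
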