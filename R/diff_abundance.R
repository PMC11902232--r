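#' Per-OTU differential abundance between clinical groups
#'
#' Compares each OTU's abundance between two clinical groups with a Welch
#' two-sample t-test on ln(x + 1)-transformed intensities (default; robust
#' to the unequal variances and heavy right tails of hybridization
#' intensities) or a Mann--Whitney test. Reports the per-OTU p-value, the
#' direction of the difference, nominal significance at `alpha`, and a
#' Bonferroni tier at `alpha / m` with `m` the number of OTUs actually
#' compared.
#'
#' OTUs with zero variance in both groups carry no information for the test
#' and are skipped with a message; an OTU constant at a different value in
#' each group (no within-group variance at all) is likewise skipped.
#'
#' @param abundance OTU abundance matrix.
#' @param phenotypes Phenotype tibble.
#' @param group_a,group_b Group labels (`HC`, `IBS`, `IBS-C`, `IBS-D`,
#'   `IBS-M`); both need at least 2 profiled samples.
#' @param test `"welch"` (default) or `"mannwhitney"`.
#' @param alpha Nominal significance level (strict).
#' @param log_transform Apply ln(x + 1) before testing (default TRUE).
#' @return An `abundance_comparison` tibble: `otu_id`, `statistic`, `p`,
#'   `direction` (`up_in_a` / `down_in_a`), `passes_nominal`,
#'   `passes_bonferroni`, sorted by p. Summary counts via [glance()].
#' @export
compare_abundance <- function(abundance, phenotypes, group_a = "IBS",
                              group_b = "HC", test = c("welch", "mannwhitney"),
                              alpha = 0.05, log_transform = TRUE) {
  assert_feature_matrix(abundance, "abundance")
  test <- match.arg(test)
  ids_a <- intersect(colnames(abundance), group_sample_ids(phenotypes, group_a))
  ids_b <- intersect(colnames(abundance), group_sample_ids(phenotypes, group_b))
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    abort("each group needs at least 2 profiled samples.",
          class = "painlink_validation_error")
  }
  A <- abundance[, ids_a, drop = FALSE]
  B <- abundance[, ids_b, drop = FALSE]
  if (log_transform) {
    A <- log(A + 1); B <- log(B + 1)
  }
  res <- purrr::map(rownames(abundance), function(id) {
    x <- A[id, ]; y <- B[id, ]
    if (sd(x) == 0 && sd(y) == 0) return(NULL)
    ht <- if (test == "welch") {
      tryCatch(t.test(x, y, var.equal = FALSE), error = function(e) NULL)
    } else {
      suppressWarnings(wilcox.test(x, y, exact = FALSE))
    }
    if (is.null(ht)) return(NULL)
    tibble(otu_id = id,
           statistic = unname(ht$statistic),
           p = ht$p.value,
           direction = if (mean(x) >= mean(y)) "up_in_a" else "down_in_a")
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  if (skipped > 0) {
    inform(sprintf("skipping %d OTU(s) with no within-group variance.", skipped))
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    abort("no OTU could be tested.", class = "painlink_degenerate_error")
  }
  m <- nrow(out)
  bonf <- alpha / m
  out <- dplyr::mutate(out,
                       passes_nominal = p < alpha,
                       passes_bonferroni = p < bonf)
  out <- dplyr::arrange(out, p, otu_id)
  attr(out, "comparison") <- list(group_a = group_a, group_b = group_b,
                                  test = test, alpha = alpha, m = m,
                                  bonferroni_threshold = bonf,
                                  n_a = length(ids_a), n_b = length(ids_b),
                                  log_transform = log_transform)
  class(out) <- c("abundance_comparison", class(out))
  out
}

#' @export
glance.abundance_comparison <- function(x, ...) {
  s <- attr(x, "comparison")
  sig <- x[x$passes_nominal, ]
  tibble(group_a = s$group_a, group_b = s$group_b, test = s$test,
         n_tested = s$m,
         n_significant = nrow(sig),
         n_up_in_a = sum(sig$direction == "up_in_a"),
         n_down_in_a = sum(sig$direction == "down_in_a"),
         n_bonferroni = sum(x$passes_bonferroni),
         bonferroni_threshold = s$bonferroni_threshold,
         bonferroni_display = signif(s$bonferroni_threshold, 1))
}

#' Family composition of significant differential OTUs by direction
#'
#' @param comparison An `abundance_comparison` tibble.
#' @param taxonomy Taxonomy tibble.
#' @return Tibble (`direction`, `family`, `n`, `proportion`), proportions
#'   within each direction.
#' @export
direction_family_composition <- function(comparison, taxonomy) {
  sig <- comparison[comparison$passes_nominal, ]
  if (nrow(sig) == 0) {
    return(tibble(direction = character(), family = character(),
                  n = integer(), proportion = double()))
  }
  fam <- family_of(sig$otu_id, taxonomy)
  counts <- dplyr::count(tibble(direction = sig$direction, family = fam),
                         direction, family)
  out <- dplyr::mutate(dplyr::group_by(counts, direction),
                       proportion = n / sum(n))
  dplyr::arrange(dplyr::ungroup(out), direction, desc(n), family)
}
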