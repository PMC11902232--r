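#' Pearson correlation with a two-sided t-test
#'
#' Product-moment correlation between two vectors after pairwise removal of
#' incomplete observations, with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (`|r| = 1` gives p = 0). A constant vector has no defined correlation and
#' raises a condition of class `painlink_degenerate_error`; screening
#' functions catch it and skip the feature rather than reporting a silent 0.
#'
#' @param x,y Numeric vectors of equal length, at least 3 complete pairs.
#' @return A `painlink_cor` object with elements `r`, `r2`, `p`, `n`,
#'   `statistic` (t), `df`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort("need at least 3 complete pairs for a correlation test.",
          class = "painlink_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: one of the vectors is constant.",
          class = "painlink_degenerate_error")
  }
  ht <- suppressWarnings(cor.test(x, y, method = "pearson", alternative = "two.sided"))
  r <- unname(ht$estimate)
  structure(list(r = r, r2 = r^2, p = ht$p.value, n = n,
                 statistic = unname(ht$statistic), df = unname(ht$parameter)),
            class = "painlink_cor")
}

#' @export
print.painlink_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4f (r^2 = %.4f), t = %.3f on %d df, p = %.3g, n = %d\n",
              x$r, x$r2, x$statistic, x$df, x$p, x$n))
  invisible(x)
}

#' @export
tidy.painlink_cor <- function(x, ...) {
  tibble(r = x$r, r2 = x$r2, statistic = x$statistic, df = x$df, p = x$p, n = x$n)
}

#' Bonferroni per-test threshold
#'
#' @param m Number of tests (>= 1).
#' @param alpha Family-wise error level.
#' @return A list with `threshold = alpha / m` and `display`, the threshold
#'   rounded to one significant figure as customarily printed in reports
#'   (e.g. m = 1049 at alpha 0.05 gives threshold 4.77e-5, displayed 0.00005).
#' @export
bonferroni_alpha <- function(m, alpha = 0.05) {
  if (length(m) != 1 || is.na(m) || m < 1) {
    abort("m must be a single count >= 1.", class = "painlink_validation_error")
  }
  thr <- alpha / m
  list(threshold = thr, display = signif(thr, 1))
}

# Vectorized feature-by-feature Pearson against one vector; same algebra as
# cor.test. Returns NA for zero-variance features.
correlate_rows <- function(mat, y) {
  keep_sd <- apply(mat, 1, sd)
  r <- rep(NA_real_, nrow(mat))
  usable <- keep_sd > 0
  if (any(usable)) {
    r[usable] <- as.vector(cor(t(mat[usable, , drop = FALSE]), y))
  }
  n <- length(y)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- ifelse(abs(r) >= 1, 0, 2 * pt(-abs(t_stat), df = n - 2))
  list(r = r, p = p, n = n)
}

#' Screen features for correlation with the IVP score
#'
#' Correlates every row of a feature-by-sample matrix against the IVP score
#' over the responder sample set (participants with IVP strictly above the
#' responder threshold, pooled across clinical groups), and applies the
#' retention rule `r^2 > r2_min` and `p < p_max` (both strict). A secondary
#' Bonferroni tier uses `p < family_wise_alpha / m` with `m` the number of
#' features actually tested in the run.
#'
#' Default `r2_min` is 0.2 for OTUs and 0 for genes: gene retention in this
#' design is driven by the nominal p-value, with correlations as low as
#' r^2 ~ 0.19 retained.
#'
#' @param mat Feature-by-sample numeric matrix (OTU abundance or expression).
#' @param phenotypes Phenotype tibble covering the matrix's samples.
#' @param kind `"otu"` or `"gene"` (sets the default `r2_min`).
#' @param r2_min Minimum squared correlation (strict); `NULL` for the
#'   kind-specific default.
#' @param p_max Nominal significance level (strict).
#' @param family_wise_alpha Family-wise level for the Bonferroni tier.
#' @param responders_only Use responders only (default) or all phenotyped
#'   samples present in the matrix.
#' @param responder_threshold IVP threshold defining a responder.
#' @param log_abundance Natural-log-transform (log(x+1)) the matrix before
#'   correlating; off by default.
#' @return An `ivp_screen` tibble sorted by p-value with columns
#'   `feature_id`, `kind`, `n`, `r`, `r2`, `p`, `passes_nominal`,
#'   `passes_bonferroni`. Features with an undefined (constant) correlation
#'   are skipped with a message. The number of tests and thresholds are
#'   recoverable via [glance()].
#' @export
screen_features <- function(mat, phenotypes, kind = c("otu", "gene"),
                            r2_min = NULL, p_max = 0.05,
                            family_wise_alpha = 0.05,
                            responders_only = TRUE, responder_threshold = 0,
                            log_abundance = FALSE) {
  assert_feature_matrix(mat, "mat")
  kind <- match.arg(kind)
  r2_min <- r2_min %g% (if (kind == "otu") 0.2 else 0)
  ids <- if (responders_only) {
    identify_responders(phenotypes, responder_threshold)
  } else {
    phenotypes$participant_id
  }
  samples <- intersect(colnames(mat), ids)
  if (length(samples) < 3) {
    abort("fewer than 3 usable samples for the correlation screen.",
          class = "painlink_validation_error")
  }
  ivp <- phenotypes$ivp_score[match(samples, phenotypes$participant_id)]
  if (sd(ivp) == 0) {
    abort("IVP is constant over the selected samples; correlations are undefined.",
          class = "painlink_degenerate_error")
  }
  sub <- mat[, samples, drop = FALSE]
  if (log_abundance) sub <- log(sub + 1)
  cc <- correlate_rows(sub, ivp)
  skipped <- is.na(cc$r)
  if (any(skipped)) {
    inform(sprintf("skipping %d feature(s) with undefined (constant) correlation.",
                   sum(skipped)))
  }
  m <- sum(!skipped)
  if (m == 0) abort("no feature has a defined correlation.",
                    class = "painlink_degenerate_error")
  bonf <- family_wise_alpha / m
  out <- tibble(
    feature_id = rownames(sub)[!skipped],
    kind = kind,
    n = cc$n,
    r = cc$r[!skipped],
    r2 = cc$r[!skipped]^2,
    p = cc$p[!skipped]
  )
  out <- dplyr::mutate(out,
                       passes_nominal = (r2 > r2_min) & (p < p_max),
                       passes_bonferroni = p < bonf)
  out <- dplyr::arrange(out, p, feature_id)
  attr(out, "screen") <- list(kind = kind, m = m, r2_min = r2_min, p_max = p_max,
                              family_wise_alpha = family_wise_alpha,
                              bonferroni_threshold = bonf,
                              n_samples = cc$n, samples = samples,
                              responders_only = responders_only)
  class(out) <- c("ivp_screen", class(out))
  out
}

#' @export
glance.ivp_screen <- function(x, ...) {
  s <- attr(x, "screen")
  tibble(kind = s$kind,
         n_tested = s$m,
         n_samples = s$n_samples,
         n_nominal = sum(x$passes_nominal),
         n_bonferroni = sum(x$passes_bonferroni),
         r2_min = s$r2_min,
         p_max = s$p_max,
         bonferroni_threshold = s$bonferroni_threshold,
         bonferroni_display = signif(s$bonferroni_threshold, 1))
}

#' Retained features from a screen
#' @param screen An `ivp_screen` tibble.
#' @param tier `"nominal"` (default) or `"bonferroni"`.
#' @return The retained subset of the screen tibble.
#' @export
screen_hits <- function(screen, tier = c("nominal", "bonferroni")) {
  tier <- match.arg(tier)
  if (tier == "nominal") screen[screen$passes_nominal, ] else screen[screen$passes_bonferroni, ]
}
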