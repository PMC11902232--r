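#' Identify pain responders
#'
#' A responder is a participant whose induced visceral pain (IVP) score is
#' strictly greater than `threshold` (default 0). Correlation stages use
#' responders only, because a large mass of exact zeros in the non-responding
#' controls makes pooled correlations bimodal.
#'
#' @param phenotypes Phenotype tibble.
#' @param threshold IVP threshold (score must strictly exceed it).
#' @return Character vector of responder participant ids.
#' @export
identify_responders <- function(phenotypes, threshold = 0) {
  stopifnot(threshold >= 0)
  phenotypes$participant_id[phenotypes$ivp_score > threshold]
}

#' Per-group phenotype summary
#'
#' Reproduces the per-group clinical summary: group size, responder count and
#' whole-percent responder rate (rounded half-up), IVP mean/SD over all group
#' members and over responders only, the responder IVP range, age mean/SD, and
#' sex/race proportions. All standard deviations use the sample (n-1)
#' denominator. Values are returned at full precision; round for display.
#'
#' When a group has fewer than two responders its responder SD is undefined
#' and reported as `NA` (never 0).
#'
#' @param phenotypes Phenotype tibble.
#' @param groups Group labels to summarize (default both `HC` and `IBS`).
#' @param responder_threshold IVP threshold passed to [identify_responders()].
#' @return A `group_summary` tibble, one row per group, with list-columns
#'   `sex_proportions` and `race_proportions` (named numeric vectors).
#' @examples
#' p <- read_phenotype_table(painlink_example("phenotype_cohort36.tsv"))
#' summarize_cohort(p)
#' @export
summarize_cohort <- function(phenotypes, groups = c("HC", "IBS"),
                             responder_threshold = 0) {
  absent <- setdiff(groups, unique(phenotypes$group))
  if (length(absent) > 0) {
    abort(sprintf("group(s) not present in the phenotype table: %s",
                  paste(absent, collapse = ", ")),
          class = "painlink_validation_error")
  }
  responders <- identify_responders(phenotypes, responder_threshold)
  rows <- purrr::map(groups, function(g) {
    sub <- phenotypes[phenotypes$group == g, ]
    resp <- sub[sub$participant_id %in% responders, ]
    n <- nrow(sub)
    nr <- nrow(resp)
    tibble(
      group = g,
      n = n,
      n_responders = nr,
      responder_percent = round_half_up(100 * nr / n),
      ivp_mean_all = mean(sub$ivp_score),
      ivp_sd_all = if (n >= 2) sd(sub$ivp_score) else NA_real_,
      ivp_mean_responders = if (nr >= 1) mean(resp$ivp_score) else NA_real_,
      ivp_sd_responders = if (nr >= 2) sd(resp$ivp_score) else NA_real_,
      ivp_min_responders = if (nr >= 1) min(resp$ivp_score) else NA_real_,
      ivp_max_responders = if (nr >= 1) max(resp$ivp_score) else NA_real_,
      age_mean = mean(sub$age),
      age_sd = if (n >= 2) sd(sub$age) else NA_real_,
      sex_proportions = list(proportions_of(sub$sex)),
      race_proportions = list(proportions_of(sub$race))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("group_summary", class(out))
  out
}

proportions_of <- function(x) {
  tab <- table(x)
  setNames(as.numeric(tab) / length(x), names(tab))
}

#' Round a group summary to the conventional print precision
#'
#' Means/SDs over whole groups to two decimals, responder-only statistics to
#' one decimal, responder rate already a whole percent — matching how such
#' clinical tables are customarily printed. Rounding is half-up.
#'
#' @param summary A `group_summary` tibble from [summarize_cohort()].
#' @return A tibble of display-rounded numeric columns.
#' @export
format_group_summary <- function(summary) {
  dplyr::mutate(
    as_tibble(summary)[c("group", "n", "n_responders", "responder_percent",
                         "ivp_mean_all", "ivp_sd_all", "ivp_mean_responders",
                         "ivp_sd_responders", "ivp_min_responders",
                         "ivp_max_responders", "age_mean", "age_sd")],
    across(c("ivp_mean_all", "ivp_sd_all", "age_mean", "age_sd"),
           ~ round_half_up(.x, 2)),
    across(c("ivp_mean_responders", "ivp_sd_responders",
             "ivp_min_responders", "ivp_max_responders"),
           ~ round_half_up(.x, 1))
  )
}

#' @export
glance.group_summary <- function(x, ...) {
  tibble(n_groups = nrow(x),
         n_total = sum(x$n),
         n_responders = sum(x$n_responders))
}
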