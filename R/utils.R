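#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange filter mutate select group_by summarise ungroup
#'   left_join n distinct bind_rows count across all_of desc if_else pull rename
#' @importFrom stats cor cor.test median pnorm pt qnorm rnorm runif sd setNames
#'   t.test wilcox.test rbinom complete.cases
#' @importFrom utils head
NULL

#' Decimal rounding with ties away from zero
#'
#' Base `round()` rounds half to even (0.5 becomes 0); clinical summary
#' tables conventionally round half-up, which this helper does.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%g%` <- function(x, default) if (is.null(x)) default else x

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

assert_feature_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (features x samples).", what))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must have feature rownames and sample colnames.", what))
  }
  if (anyDuplicated(rownames(x))) abort(sprintf("duplicate feature ids in `%s`.", what))
  if (anyDuplicated(colnames(x))) abort(sprintf("duplicate sample ids in `%s`.", what))
  invisible(x)
}
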