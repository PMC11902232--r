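#' Presence/absence calls from an abundance matrix
#'
#' An OTU is called present in a sample when its abundance strictly exceeds
#' `detection_threshold` (default 0, i.e. any nonzero intensity counts as
#' detection). If the hybridization platform supplied explicit presence
#' calls, pass them as `calls` and they are returned unchanged.
#'
#' @param abundance OTU abundance matrix.
#' @param detection_threshold Detection threshold (strict; >= 0).
#' @param calls Optional logical matrix of explicit presence calls with the
#'   same dimensions/dimnames as `abundance`.
#' @return A logical OTU-by-sample matrix.
#' @export
presence_calls <- function(abundance, detection_threshold = 0, calls = NULL) {
  assert_feature_matrix(abundance, "abundance")
  if (!is.null(calls)) {
    if (!is.logical(calls) || !identical(dim(calls), dim(abundance)) ||
        !identical(dimnames(calls), dimnames(abundance))) {
      abort("explicit presence calls must be a logical matrix matching the abundance matrix.",
            class = "painlink_validation_error")
    }
    return(calls)
  }
  stopifnot(detection_threshold >= 0)
  abundance > detection_threshold
}

# Sample ids for a clinical group label. "HC"/"IBS" select on group;
# "IBS-C"/"IBS-D"/"IBS-M" select on subtype.
group_sample_ids <- function(phenotypes, label) {
  switch(label,
    "HC" = ,
    "IBS" = phenotypes$participant_id[phenotypes$group == label],
    "IBS-C" = phenotypes$participant_id[phenotypes$subtype == "C"],
    "IBS-D" = phenotypes$participant_id[phenotypes$subtype == "D"],
    "IBS-M" = phenotypes$participant_id[phenotypes$subtype == "M"],
    abort(sprintf("unknown group label '%s' (use HC, IBS, IBS-C, IBS-D, IBS-M).", label),
          class = "painlink_validation_error")
  )
}

#' Within-group occupancy profiles
#'
#' For each OTU and clinical group, the number and fraction of the group's
#' samples in which the OTU is present. Groups smaller than
#' `min_group_size` (default 3) are excluded with a warning; a two-person
#' subtype tells little about occupancy.
#'
#' @param presence Logical presence matrix from [presence_calls()].
#' @param phenotypes Phenotype tibble.
#' @param groups Group labels (`HC`, `IBS`, `IBS-C`, `IBS-D`, `IBS-M`).
#' @param min_group_size Minimum group size to profile.
#' @return Tibble (`otu_id`, `group`, `n_present`, `n_total`, `fraction`).
#' @export
occupancy_by_group <- function(presence, phenotypes, groups = c("HC", "IBS"),
                               min_group_size = 3) {
  rows <- purrr::map(groups, function(g) {
    ids <- intersect(colnames(presence), group_sample_ids(phenotypes, g))
    if (length(ids) < min_group_size) {
      warn(sprintf("group '%s' has %d profiled sample(s) (< %d); excluded from occupancy profiling.",
                   g, length(ids), min_group_size))
      return(NULL)
    }
    np <- unname(rowSums(presence[, ids, drop = FALSE]))
    tibble(otu_id = rownames(presence), group = g,
           n_present = as.integer(np), n_total = length(ids),
           fraction = np / length(ids))
  })
  dplyr::bind_rows(rows)
}

#' Substantial-presence filter
#'
#' Keeps, per group, the OTUs present in at least `min_fraction` of that
#' group's samples (inclusive; default 30%). Restricting profile comparisons
#' to substantially present OTUs avoids single-sample outliers dominating a
#' group's community description.
#'
#' @param profiles Occupancy tibble from [occupancy_by_group()].
#' @param min_fraction Minimum occupancy fraction (inclusive).
#' @return The filtered profile tibble.
#' @export
substantial_presence <- function(profiles, min_fraction = 0.30) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  profiles[profiles$fraction >= min_fraction, , drop = FALSE]
}

#' Differential commonness between two groups
#'
#' Compares per-OTU occupancy between two groups and reports OTUs whose
#' presence fractions differ by strictly more than `min_delta` (percentage
#' points of occupancy, default 0.25). Exclusivity flags mark OTUs always
#' present (fraction exactly 1) or always absent (exactly 0) in either group
#' — the asterisk convention of the published rosters.
#'
#' @param profiles Occupancy tibble covering both groups (same OTU universe).
#' @param group_a,group_b Group labels present in `profiles`.
#' @param min_delta Minimum absolute occupancy difference (strict).
#' @param otus Optional OTU id subset to consider (e.g. the union of the two
#'   groups' [substantial_presence()] sets).
#' @return An `occupancy_delta` tibble: `otu_id`, `fraction_a`, `fraction_b`,
#'   `delta` (= a - b), `more_common_in`, the four exclusivity flags, and a
#'   compact `flag` string (e.g. `"A*"`) for export.
#' @export
differential_commonness <- function(profiles, group_a, group_b,
                                    min_delta = 0.25, otus = NULL) {
  pa <- profiles[profiles$group == group_a, ]
  pb <- profiles[profiles$group == group_b, ]
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    abort("both groups must be present in the occupancy profiles.",
          class = "painlink_validation_error")
  }
  shared <- intersect(pa$otu_id, pb$otu_id)
  if (!is.null(otus)) shared <- intersect(shared, otus)
  fa <- pa$fraction[match(shared, pa$otu_id)]
  fb <- pb$fraction[match(shared, pb$otu_id)]
  out <- tibble(
    otu_id = shared,
    fraction_a = fa,
    fraction_b = fb,
    delta = fa - fb,
    more_common_in = ifelse(fa >= fb, group_a, group_b),
    always_present_a = fa == 1,
    always_absent_a = fa == 0,
    always_present_b = fb == 1,
    always_absent_b = fb == 0
  )
  out <- out[abs(out$delta) > min_delta, , drop = FALSE]
  out <- dplyr::mutate(out, flag = paste0(
    ifelse(always_present_a | always_absent_a, paste0(group_a, "*"), ""),
    ifelse((always_present_a | always_absent_a) &
             (always_present_b | always_absent_b), " ", ""),
    ifelse(always_present_b | always_absent_b, paste0(group_b, "*"), "")
  ))
  out <- dplyr::arrange(out, desc(abs(delta)), otu_id)
  attr(out, "groups") <- c(a = group_a, b = group_b)
  class(out) <- c("occupancy_delta", class(out))
  out
}

#' Per-family composition of substantially present OTUs
#'
#' For each group, the number and proportion of that group's substantially
#' present OTUs belonging to each bacterial family (OTUs without a taxonomy
#' record count as family `"unclassified"`). Proportions within a group sum
#' to 1.
#'
#' @param kept Filtered occupancy tibble from [substantial_presence()]
#'   (columns `otu_id`, `group`).
#' @param taxonomy Taxonomy tibble.
#' @return Tibble (`group`, `family`, `n`, `proportion`).
#' @seealso [family_proportion_gap()] for the between-group differences.
#' @export
family_proportions <- function(kept, taxonomy) {
  fam <- family_of(kept$otu_id, taxonomy)
  counts <- dplyr::count(tibble(group = kept$group, family = fam), group, family)
  out <- dplyr::mutate(dplyr::group_by(counts, group),
                       proportion = n / sum(n))
  dplyr::arrange(dplyr::ungroup(out), group, desc(n), family)
}

#' Largest between-group difference in family proportions
#'
#' @param fp Family-proportion tibble from [family_proportions()].
#' @return Tibble (`family`, `max_abs_diff`) with the maximum absolute
#'   between-group difference in each family's proportional representation
#'   (families absent from a group count as proportion 0).
#' @export
family_proportion_gap <- function(fp) {
  wide <- tidyr::pivot_wider(fp[c("group", "family", "proportion")],
                             names_from = "group", values_from = "proportion",
                             values_fill = 0)
  mat <- as.matrix(wide[-1])
  gap <- apply(mat, 1, function(v) max(v) - min(v))
  dplyr::arrange(tibble(family = wide$family, max_abs_diff = gap),
                 desc(max_abs_diff), family)
}
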