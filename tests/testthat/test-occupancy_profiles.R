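# Phenotype table shaped like the published subtype breakdown used in the
# occupancy rosters: 18 HC, 18 IBS of which 7 D / 9 C / 2 M.
roster_phenotypes <- function() {
  tibble::tibble(
    participant_id = c(sprintf("HC%02d", 1:18), sprintf("IBS%02d", 1:18)),
    group = rep(c("HC", "IBS"), each = 18),
    subtype = c(rep("NONE", 18), rep(c("D", "C", "M"), c(7, 9, 2))),
    ivp_score = c(rep(0, 18), rep(30, 18)),
    sex = "female", age = 30, race = "Caucasian")
}

# Presence matrix with exact per-group presence counts.
presence_with_counts <- function(phen, counts) {
  # counts: named list otu -> c(HC = k, D = k, C = k, M = k)
  samples <- phen$participant_id
  m <- matrix(FALSE, nrow = length(counts), ncol = length(samples),
              dimnames = list(names(counts), samples))
  for (otu in names(counts)) {
    for (g in names(counts[[otu]])) {
      ids <- if (g == "HC") {
        phen$participant_id[phen$group == "HC"]
      } else {
        phen$participant_id[phen$subtype == g]
      }
      k <- counts[[otu]][[g]]
      if (k > 0) m[otu, ids[seq_len(k)]] <- TRUE
    }
  }
  m
}

test_that("presence calls use a strict detection threshold or explicit calls", {
  ab <- toy_matrix(c(0, 5, 10, 2, 0, 7), c("O1", "O2"), c("S1", "S2", "S3"))
  expect_equal(unname(presence_calls(ab)[1, ]), c(FALSE, TRUE, TRUE))
  # threshold 5 elementwise oracle
  expect_equal(presence_calls(ab, 5), ab > 5)
  # value exactly at the threshold is absent
  expect_false(presence_calls(ab, 5)["O1", "S2"])
  # explicit platform calls pass through unchanged
  calls <- ab >= 2
  expect_identical(presence_calls(ab, calls = calls), calls)
  expect_error(presence_calls(ab, calls = calls[1, , drop = FALSE]),
               class = "painlink_validation_error")
})

test_that("occupancy fractions count presence within each clinical group", {
  phen <- roster_phenotypes()
  pres <- presence_with_counts(phen, list(
    fuso = c(HC = 0, D = 2, C = 3, M = 1),        # 6/18 IBS, absent in HC
    lachno = c(HC = 18, D = 4, C = 8, M = 1),     # 18/18 HC, 13/18 IBS
    empty = c(HC = 0, D = 0, C = 0, M = 0)))
  expect_warning(
    prof <- occupancy_by_group(pres, phen,
                               groups = c("HC", "IBS", "IBS-D", "IBS-C", "IBS-M")),
    "IBS-M")  # two-person subtype excluded
  expect_false("IBS-M" %in% prof$group)
  expect_equal(prof$fraction[prof$otu_id == "fuso" & prof$group == "IBS"], 6 / 18)
  expect_equal(prof$fraction[prof$otu_id == "fuso" & prof$group == "IBS-D"], 2 / 7)
  expect_equal(prof$fraction[prof$otu_id == "lachno" & prof$group == "HC"], 1)
  expect_equal(prof$fraction[prof$otu_id == "empty" & prof$group == "IBS"], 0)
  expect_error(occupancy_by_group(pres, phen, groups = "IBS-X"),
               class = "painlink_validation_error")
})

test_that("substantial presence keeps >= 30% inclusively", {
  prof <- tibble::tibble(otu_id = c("a", "b", "c"), group = "IBS",
                         n_present = c(6, 5, 0), n_total = 18,
                         fraction = c(6, 5, 0) / 18)
  kept <- substantial_presence(prof)
  expect_equal(kept$otu_id, "a")          # 6/18 = 33.3% kept, 5/18 = 27.8% dropped
  expect_equal(substantial_presence(prof, 0)$otu_id, c("a", "b", "c"))
})

test_that("differential commonness reproduces the published roster row logic", {
  phen <- roster_phenotypes()
  pres <- presence_with_counts(phen, list(
    fuso = c(HC = 0, D = 2, C = 3, M = 1),
    lachno = c(HC = 18, D = 4, C = 8, M = 1),
    same = c(HC = 9, D = 3, C = 5, M = 1)))
  prof <- occupancy_by_group(pres, phen)
  delta <- differential_commonness(prof, "IBS", "HC")

  fuso <- delta[delta$otu_id == "fuso", ]
  expect_equal(fuso$delta, 6 / 18, tolerance = 1e-12)   # > 0.25: reported
  expect_true(fuso$always_absent_b)                     # never present in HC
  expect_equal(fuso$more_common_in, "IBS")
  expect_match(fuso$flag, "HC\\*")

  lachno <- delta[delta$otu_id == "lachno", ]
  expect_equal(lachno$delta, 13 / 18 - 1, tolerance = 1e-12)  # ~ -0.278
  expect_true(lachno$always_present_b)                  # always present in HC
  expect_equal(lachno$more_common_in, "HC")

  expect_false("same" %in% delta$otu_id)                # 9/18 both: delta 0
})

test_that("differential commonness is antisymmetric and flags match fractions", {
  set.seed(55)
  phen <- roster_phenotypes()
  pres <- matrix(runif(30 * 36) < 0.5, nrow = 30,
                 dimnames = list(sprintf("O%02d", 1:30), phen$participant_id))
  pres[1, ] <- TRUE   # force exclusivity cases into the draw
  pres[2, phen$group == "HC"] <- FALSE
  prof <- occupancy_by_group(pres, phen)
  ab <- differential_commonness(prof, "IBS", "HC", min_delta = 0)
  ba <- differential_commonness(prof, "HC", "IBS", min_delta = 0)
  shared <- intersect(ab$otu_id, ba$otu_id)
  expect_equal(ab$delta[match(shared, ab$otu_id)],
               -ba$delta[match(shared, ba$otu_id)])
  expect_equal(ab$always_present_a, ab$fraction_a == 1)
  expect_equal(ab$always_absent_a, ab$fraction_a == 0)
  expect_equal(ab$always_present_b, ab$fraction_b == 1)
  expect_equal(ab$always_absent_b, ab$fraction_b == 0)
  expect_true(all(ab$delta >= -1 & ab$delta <= 1))

  # strictness of the 25-point rule
  quarter <- tibble::tibble(otu_id = "q", group = c("IBS", "HC"),
                            n_present = c(9, 0), n_total = c(36, 36),
                            fraction = c(0.25, 0))
  expect_equal(nrow(differential_commonness(quarter, "IBS", "HC")), 0)
})

test_that("family proportions sum to one per group and track the generator", {
  phen <- roster_phenotypes()
  set.seed(77)
  pres <- matrix(runif(40 * 36) < 0.6, nrow = 40,
                 dimnames = list(sprintf("O%02d", 1:40), phen$participant_id))
  tax <- toy_taxonomy(rownames(pres),
                      family = rep(c("Lachnospiraceae", "Prevotellaceae",
                                     "unclassified", "Veillonellaceae"), 10))
  kept <- substantial_presence(occupancy_by_group(pres, phen))
  fp <- family_proportions(kept, tax)
  sums <- dplyr::summarise(dplyr::group_by(fp, group), s = sum(proportion))
  expect_equal(sums$s, rep(1, nrow(sums)))
  # counts are a direct tally
  one <- fp[fp$group == "HC" & fp$family == "Lachnospiraceae", ]
  hc_kept <- kept$otu_id[kept$group == "HC"]
  expect_equal(one$n, sum(tax$family[match(hc_kept, tax$otu_id)] == "Lachnospiraceae"))

  gap <- family_proportion_gap(fp)
  expect_true(all(gap$max_abs_diff >= 0 & gap$max_abs_diff <= 1))

  # synthetic occupancy-shift cohort: masked OTUs match manifest probabilities
  sim <- simulate_cohort(small_sim_config(seed = 12))
  pres2 <- presence_calls(sim$abundance)
  prof2 <- occupancy_by_group(pres2, sim$phenotype)
  occ <- sim$manifest$occupancy
  hard <- occ[occ$p_hc == 1, ]
  expect_true(all(prof2$fraction[prof2$group == "HC" &
                                 prof2$otu_id %in% hard$otu_id] == 1))
})
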