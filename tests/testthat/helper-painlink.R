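# Shared builders for the test suite. Everything is generated in code; the
# only stored fixture is the packaged 36-participant phenotype table.

cohort36 <- function() {
  read_phenotype_table(painlink_example("phenotype_cohort36.tsv"))
}

# Tiny phenotype table with explicit IVP scores.
toy_phenotypes <- function(ivp_hc = c(0, 0, 5), ivp_ibs = c(10, 20, 30)) {
  n_hc <- length(ivp_hc); n_ibs <- length(ivp_ibs)
  tibble::tibble(
    participant_id = c(sprintf("H%02d", seq_len(n_hc)),
                       sprintf("I%02d", seq_len(n_ibs))),
    group = rep(c("HC", "IBS"), c(n_hc, n_ibs)),
    subtype = c(rep("NONE", n_hc), rep(c("C", "D", "M"), length.out = n_ibs)),
    ivp_score = c(ivp_hc, ivp_ibs),
    sex = "female",
    age = 30,
    race = "Caucasian"
  )
}

# Feature-by-sample matrix with deterministic contents.
toy_matrix <- function(values, features, samples) {
  matrix(values, nrow = length(features), ncol = length(samples),
         dimnames = list(features, samples), byrow = TRUE)
}

toy_taxonomy <- function(otu_ids, family = "Lachnospiraceae",
                         genus = "unclassified", species = "unclassified",
                         phylum = "Firmicutes") {
  tibble::tibble(otu_id = otu_ids, phylum = phylum, family = family,
                 genus = genus, species = species)
}

# Hand-written product-moment + t-distribution oracle, independent of the
# implementation path (no cor(), no cor.test()).
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t_stat), df = n - 2))
}

# A small cohort config used across tests (fast but realistic shape).
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_otus = 60, n_genes = 80, n_pain_otus = 8, n_pain_genes = 10,
             n_coupled_pairs = 4,
             occupancy_shifts = data.frame(p_hc = c(1, 0.9), p_ibs = c(0.5, 0.3)),
             seed = seed, ...)
}
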