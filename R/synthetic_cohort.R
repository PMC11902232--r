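#' Configuration for the synthetic cohort generator
#'
#' Defines a simulated study: cohort sizes and subtype split, the zero-mass
#' pain distribution of healthy controls, the clipped-normal IVP distribution
#' of the IBS group, and the planted structure — OTUs and genes with known
#' target correlations to IVP, OTU--gene couplings with known correlation,
#' and OTUs with group-specific presence probabilities.
#'
#' Defaults mirror the study design the package emulates: 18 + 18
#' participants, IBS subtype split 8 C / 8 D / 2 M, an 11% control responder
#' rate with responder scores near 8.1 +/- 2.7, and IBS scores drawn from a
#' normal(32.7, 26.7) clamped to the 0--100 instrument scale (the clamp's
#' zero mass reproduces the ~89% IBS responder rate). Feature counts default
#' to a desk-scale community of 200 OTUs and 300 genes.
#'
#' @param n_hc,n_ibs Group sizes.
#' @param subtype_split Named proportions over `c(C, D, M)` for IBS subtypes
#'   (assigned deterministically by largest remainder).
#' @param hc_responder_prob Probability that a control reports any pain.
#' @param hc_responder_ivp_mean,hc_responder_ivp_sd Moments of the
#'   zero-truncated normal for control responders.
#' @param ivp_ibs_mean,ivp_ibs_sd Moments of the IBS IVP distribution before
#'   clamping to `[0, 100]`.
#' @param n_otus,n_genes Community and transcriptome sizes.
#' @param n_pain_otus,n_pain_genes Planted pain-correlated feature counts.
#' @param planted_r_range Magnitude interval for planted IVP correlations.
#' @param planted_neg_prob_otu,planted_neg_prob_gene Probability a planted
#'   feature's correlation is negative (most pain-associated OTUs in this
#'   system correlate negatively).
#' @param n_coupled_pairs Number of planted OTU--gene couplings (assigned to
#'   the first planted pain OTUs, recycling into null OTUs if needed).
#' @param coupling_r Target correlation of each coupled pair.
#' @param occupancy_shifts Data frame with one row per occupancy-shifted OTU
#'   and columns `p_hc`, `p_ibs`: group-specific presence probabilities.
#' @param abundance_meanlog,abundance_sigma Lognormal intensity model for
#'   abundance (see the methods vignette for why sigma defaults to 0.2).
#' @param expression_mean,expression_sigma Normal model for (log-scale)
#'   expression values.
#' @param sex_prob Probability a simulated participant is male.
#' @param race_prob Named race probabilities.
#' @param age_mean,age_sd,age_range Truncated-normal age model (years).
#' @param seed Master integer seed; each stage uses a fixed offset substream.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_hc = 18, n_ibs = 18,
                       subtype_split = c(C = 8, D = 8, M = 2) / 18,
                       hc_responder_prob = 2 / 18,
                       hc_responder_ivp_mean = 8.1, hc_responder_ivp_sd = 2.7,
                       ivp_ibs_mean = 32.7, ivp_ibs_sd = 26.7,
                       n_otus = 200, n_genes = 300,
                       n_pain_otus = 20, n_pain_genes = 30,
                       planted_r_range = c(0.5, 0.9),
                       planted_neg_prob_otu = 0.75,
                       planted_neg_prob_gene = 0.5,
                       n_coupled_pairs = 10, coupling_r = 0.75,
                       occupancy_shifts = data.frame(
                         p_hc = rep(c(1, 0.9, 0.3), each = 4),
                         p_ibs = rep(c(0.5, 0.3, 0.9), each = 4)),
                       abundance_meanlog = log(500), abundance_sigma = 0.2,
                       expression_mean = log(500), expression_sigma = 1,
                       sex_prob = 13 / 36,
                       race_prob = c("Caucasian" = 15, "African-American" = 13,
                                     "Asian" = 4, "Mixed/Other" = 4) / 36,
                       age_mean = 28, age_sd = 7, age_range = c(13, 45),
                       seed = 1L) {
  cfg <- list(n_hc = n_hc, n_ibs = n_ibs, subtype_split = subtype_split,
              hc_responder_prob = hc_responder_prob,
              hc_responder_ivp_mean = hc_responder_ivp_mean,
              hc_responder_ivp_sd = hc_responder_ivp_sd,
              ivp_ibs_mean = ivp_ibs_mean, ivp_ibs_sd = ivp_ibs_sd,
              n_otus = n_otus, n_genes = n_genes,
              n_pain_otus = n_pain_otus, n_pain_genes = n_pain_genes,
              planted_r_range = planted_r_range,
              planted_neg_prob_otu = planted_neg_prob_otu,
              planted_neg_prob_gene = planted_neg_prob_gene,
              n_coupled_pairs = n_coupled_pairs, coupling_r = coupling_r,
              occupancy_shifts = as_tibble(occupancy_shifts),
              abundance_meanlog = abundance_meanlog,
              abundance_sigma = abundance_sigma,
              expression_mean = expression_mean,
              expression_sigma = expression_sigma,
              sex_prob = sex_prob, race_prob = race_prob,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_hc, cfg$n_ibs, cfg$n_otus, cfg$n_genes, cfg$n_pain_otus,
              cfg$n_pain_genes, cfg$n_coupled_pairs)
  if (any(counts < 0)) abort("counts must be nonnegative.",
                             class = "painlink_validation_error")
  probs <- c(cfg$hc_responder_prob, cfg$sex_prob,
             cfg$occupancy_shifts$p_hc, cfg$occupancy_shifts$p_ibs)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1].",
                                        class = "painlink_validation_error")
  rr <- cfg$planted_r_range
  if (length(rr) != 2 || any(abs(rr) >= 1) || rr[1] > rr[2]) {
    abort("planted_r_range must be an ordered interval inside (-1, 1).",
          class = "painlink_validation_error")
  }
  if (abs(cfg$coupling_r) >= 1) abort("coupling_r must lie in (-1, 1).",
                                      class = "painlink_validation_error")
  if (cfg$n_pain_otus + nrow(cfg$occupancy_shifts) > cfg$n_otus) {
    abort("more planted OTUs (pain + occupancy-shifted) than total OTUs.",
          class = "painlink_validation_error")
  }
  if (cfg$n_pain_genes + cfg$n_coupled_pairs > cfg$n_genes) {
    abort("more planted genes (pain + coupled) than total genes.",
          class = "painlink_validation_error")
  }
  if (!is.null(names(cfg$subtype_split)) &&
      !setequal(names(cfg$subtype_split), c("C", "D", "M"))) {
    abort("subtype_split must be named over C, D, M.",
          class = "painlink_validation_error")
  }
  invisible(cfg)
}

# Inverse-CDF truncated normal sampler.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Largest-remainder apportionment of n into proportions p (named).
apportion <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(p))
}

#' Generate a synthetic phenotype table
#'
#' Controls report zero IVP except for Bernoulli(`hc_responder_prob`)
#' responders drawn from a low-mean zero-truncated normal; IBS scores are
#' drawn from normal(`ivp_ibs_mean`, `ivp_ibs_sd`) clamped to the 0--100
#' instrument scale, so the clamp's mass at zero yields the non-responding
#' tail of the IBS group. Demographics come from configurable categorical
#' and truncated-normal models.
#'
#' @param config A [sim_config()].
#' @return A phenotype tibble (same schema as [read_phenotype_table()]).
#' @export
generate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_hc + config$n_ibs < 4) {
    abort("need at least 4 participants in total (correlations need degrees of freedom).",
          class = "painlink_validation_error")
  }
  set.seed(config$seed + 101L)
  n_hc <- config$n_hc; n_ibs <- config$n_ibs
  hc_resp <- runif(n_hc) < config$hc_responder_prob
  hc_ivp <- numeric(n_hc)
  hc_ivp[hc_resp] <- pmin(rtruncnorm(sum(hc_resp), config$hc_responder_ivp_mean,
                                     config$hc_responder_ivp_sd, lower = 0), 100)
  ibs_ivp <- pmin(pmax(rnorm(n_ibs, config$ivp_ibs_mean, config$ivp_ibs_sd), 0), 100)
  sub_counts <- apportion(n_ibs, config$subtype_split[c("C", "D", "M")])
  subtype <- rep(names(sub_counts), times = sub_counts)
  n <- n_hc + n_ibs
  ages <- round(rtruncnorm(n, config$age_mean, config$age_sd,
                           config$age_range[1], config$age_range[2]))
  sex <- ifelse(runif(n) < config$sex_prob, "male", "female")
  race <- sample(names(config$race_prob), n, replace = TRUE,
                 prob = config$race_prob)
  tibble(
    participant_id = c(sprintf("SIM-HC%02d", seq_len(n_hc)),
                       sprintf("SIM-IBS%02d", seq_len(n_ibs))),
    group = rep(c("HC", "IBS"), c(n_hc, n_ibs)),
    subtype = c(rep("NONE", n_hc), subtype),
    ivp_score = c(hc_ivp, ibs_ivp),
    sex = sex,
    age = ages,
    race = race
  )
}

# Latent feature correlated at `a` with z over the responder positions;
# independent standard normal elsewhere.
planted_latent <- function(a, z, resp_idx, n_samples) {
  lat <- rnorm(n_samples)
  lat[resp_idx] <- a * z + sqrt(1 - a^2) * rnorm(length(z))
  lat
}

#' Generate a synthetic OTU abundance matrix
#'
#' Pain OTUs are planted with a target Pearson correlation to the IVP score
#' over responders: their latent value over responders is
#' `a * z(IVP) + sqrt(1 - a^2) * noise`, mapped to a strictly positive
#' intensity by `exp(meanlog + sigma * latent)`. Null OTUs are independent
#' lognormal intensities. Occupancy-shifted OTUs are masked to exactly 0 by
#' group-specific Bernoulli presence draws.
#'
#' @param phenotypes Phenotype tibble (normally from [generate_phenotypes()]).
#' @param config A [sim_config()].
#' @return List with `abundance` (matrix) and `manifest` (tibbles
#'   `pain_otus` with planted r, `occupancy` with presence probabilities).
#' @export
generate_microbiome <- function(phenotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(phenotypes) == 0) abort("phenotype table is empty.",
                                   class = "painlink_validation_error")
  set.seed(config$seed + 202L)
  samples <- phenotypes$participant_id
  n <- length(samples)
  resp_idx <- which(phenotypes$ivp_score > 0)
  if (length(resp_idx) < 3) {
    abort("need at least 3 responders to plant correlations.",
          class = "painlink_validation_error")
  }
  z <- as.vector(scale(phenotypes$ivp_score[resp_idx]))
  n_pain <- config$n_pain_otus
  n_occ <- nrow(config$occupancy_shifts)
  otu_ids <- sprintf("OTU%04d", seq_len(config$n_otus))
  planted_r <- if (n_pain > 0) {
    mag <- runif(n_pain, config$planted_r_range[1], config$planted_r_range[2])
    sgn <- ifelse(runif(n_pain) < config$planted_neg_prob_otu, -1, 1)
    mag * sgn
  } else {
    numeric()
  }
  lat <- matrix(rnorm(config$n_otus * n), nrow = config$n_otus)
  for (i in seq_len(n_pain)) {
    lat[i, ] <- planted_latent(planted_r[i], z, resp_idx, n)
  }
  ab <- exp(config$abundance_meanlog + config$abundance_sigma * lat)
  # occupancy block sits after the pain block
  occ_rows <- seq_len(n_occ) + n_pain
  is_ibs <- phenotypes$group == "IBS"
  for (k in seq_len(n_occ)) {
    p <- ifelse(is_ibs, config$occupancy_shifts$p_ibs[k],
                config$occupancy_shifts$p_hc[k])
    present <- runif(n) < p
    ab[occ_rows[k], !present] <- 0
  }
  dimnames(ab) <- list(otu_ids, samples)
  manifest <- list(
    pain_otus = tibble(otu_id = otu_ids[seq_len(n_pain)], planted_r = planted_r),
    occupancy = tibble(otu_id = otu_ids[occ_rows],
                       p_hc = config$occupancy_shifts$p_hc,
                       p_ibs = config$occupancy_shifts$p_ibs)
  )
  list(abundance = ab, manifest = manifest)
}

#' Generate a synthetic expression matrix
#'
#' Pain genes are planted against z(IVP) over responders exactly as pain
#' OTUs are; coupled genes are built from the standardized log-abundance of
#' their partner OTU with the configured coupling correlation; all remaining
#' genes are independent noise. Values live on a log-like scale (the
#' generator emulates data after the preprocessing chain, so the matrix is
#' tagged stage `"gene_summarized"`).
#'
#' @param phenotypes Phenotype tibble.
#' @param abundance Abundance matrix from [generate_microbiome()] (couplings
#'   reference its OTUs).
#' @param config A [sim_config()].
#' @return List with `expression` (matrix, stage `"gene_summarized"`) and
#'   `manifest` (tibbles `pain_genes`, `coupled_pairs`).
#' @export
generate_expression <- function(phenotypes, abundance, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_feature_matrix(abundance, "abundance")
  set.seed(config$seed + 303L)
  samples <- phenotypes$participant_id
  if (!all(samples %in% colnames(abundance))) {
    abort("abundance matrix does not cover all phenotyped participants.",
          class = "painlink_validation_error")
  }
  n <- length(samples)
  resp_idx <- which(phenotypes$ivp_score > 0)
  z <- as.vector(scale(phenotypes$ivp_score[resp_idx]))
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  n_pain <- config$n_pain_genes
  n_cpl <- config$n_coupled_pairs
  planted_r <- if (n_pain > 0) {
    mag <- runif(n_pain, config$planted_r_range[1], config$planted_r_range[2])
    sgn <- ifelse(runif(n_pain) < config$planted_neg_prob_gene, -1, 1)
    mag * sgn
  } else {
    numeric()
  }
  lat <- matrix(rnorm(config$n_genes * n), nrow = config$n_genes)
  for (i in seq_len(n_pain)) {
    lat[i, ] <- planted_latent(planted_r[i], z, resp_idx, n)
  }
  # coupled genes follow the pain block; partners are the leading OTUs
  # (pain OTUs first, so couplings land on features that survive stage 1)
  cpl_rows <- seq_len(n_cpl) + n_pain
  partner_otus <- rownames(abundance)[seq_len(n_cpl)]
  if (n_cpl > 0 && anyNA(partner_otus)) {
    abort("coupling references an OTU beyond the abundance matrix.",
          class = "painlink_validation_error")
  }
  for (k in seq_len(n_cpl)) {
    x <- abundance[partner_otus[k], samples]
    if (any(x <= 0) || sd(x) == 0) {
      abort("coupled partner OTU must have strictly positive, non-constant abundance.",
            class = "painlink_validation_error")
    }
    xs <- as.vector(scale(log(x)))
    lat[cpl_rows[k], ] <- config$coupling_r * xs +
      sqrt(1 - config$coupling_r^2) * rnorm(n)
  }
  expr <- config$expression_mean + config$expression_sigma * lat
  dimnames(expr) <- list(gene_ids, samples)
  attr(expr, "stage") <- "gene_summarized"
  manifest <- list(
    pain_genes = tibble(gene_id = gene_ids[seq_len(n_pain)], planted_r = planted_r),
    coupled_pairs = tibble(otu_id = partner_otus,
                           gene_id = gene_ids[cpl_rows],
                           planted_r = rep(config$coupling_r, n_cpl))
  )
  list(expression = expr, manifest = manifest)
}

# Synthetic taxonomy: families drawn from a pool weighted like an oral
# community dominated by Lachnospiraceae; a small fraction of OTUs carry
# genus/species labels so species-roster code paths are exercised.
generate_taxonomy <- function(otu_ids, config) {
  set.seed(config$seed + 404L)
  fam_pool <- c("Lachnospiraceae" = 0.21, "Prevotellaceae" = 0.06,
                "Veillonellaceae" = 0.05, "Moraxellaceae" = 0.06,
                "Pseudomonadaceae" = 0.06, "Rikenellaceae" = 0.05,
                "Bacillaceae" = 0.05, "Streptococcaceae" = 0.05,
                "Fusobacteriaceae" = 0.03, "Porphyromonadaceae" = 0.03,
                "unclassified" = 0.35)
  phylum_of <- c("Lachnospiraceae" = "Firmicutes", "Prevotellaceae" = "Bacteroidetes",
                 "Veillonellaceae" = "Firmicutes", "Moraxellaceae" = "Proteobacteria",
                 "Pseudomonadaceae" = "Proteobacteria", "Rikenellaceae" = "Bacteroidetes",
                 "Bacillaceae" = "Firmicutes", "Streptococcaceae" = "Firmicutes",
                 "Fusobacteriaceae" = "Fusobacteria", "Porphyromonadaceae" = "Bacteroidetes",
                 "unclassified" = "unclassified")
  genus_of <- c("Prevotellaceae" = "Prevotella", "Veillonellaceae" = "Veillonella",
                "Pseudomonadaceae" = "Pseudomonas", "Streptococcaceae" = "Streptococcus",
                "Fusobacteriaceae" = "Fusobacterium", "Bacillaceae" = "Bacillus")
  n <- length(otu_ids)
  fam <- sample(names(fam_pool), n, replace = TRUE, prob = fam_pool)
  genus <- ifelse(fam %in% names(genus_of) & runif(n) < 0.5,
                  genus_of[fam], "unclassified")
  species <- ifelse(genus != "unclassified" & runif(n) < 0.3,
                    paste0("sp", seq_len(n)), "unclassified")
  tibble(otu_id = otu_ids, phylum = unname(phylum_of[fam]), family = fam,
         genus = unname(genus), species = species)
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_phenotypes()], [generate_microbiome()],
#' [generate_expression()], and a synthetic taxonomy, and assembles the
#' ground-truth manifest. Identical `(config, seed)` produce byte-identical
#' tables across runs.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort` list: `phenotype`, `abundance`, `taxonomy`,
#'   `expression`, and `manifest` (planted correlations, coupled pairs,
#'   occupancy probabilities, seed).
#' @examples
#' sim <- simulate_cohort(sim_config(n_otus = 50, n_genes = 60, seed = 7))
#' sim$manifest$pain_otus
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  phen <- generate_phenotypes(config)
  mic <- generate_microbiome(phen, config)
  expr <- generate_expression(phen, mic$abundance, config)
  tax <- generate_taxonomy(rownames(mic$abundance), config)
  manifest <- c(mic$manifest, expr$manifest,
                list(seed = config$seed,
                     n_samples = nrow(phen),
                     sample_ids = phen$participant_id))
  structure(list(phenotype = phen, abundance = mic$abundance, taxonomy = tax,
                 expression = expr$expression, manifest = manifest),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes the four TSV tables plus the ground-truth manifest as JSON.
#'
#' @param sim A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_phenotype_table(sim$phenotype, file.path(dir, "phenotype.tsv"))
  write_feature_matrix(sim$abundance, file.path(dir, "abundance.tsv"),
                       id_column = "otu_id")
  write_taxonomy_table(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_feature_matrix(sim$expression, file.path(dir, "expression.tsv"),
                       id_column = "gene_id")
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d OTUs, %d genes (seed %d)\n",
              nrow(x$phenotype), nrow(x$abundance), nrow(x$expression),
              x$manifest$seed))
  cat(sprintf("  planted: %d pain OTUs, %d pain genes, %d coupled pairs, %d occupancy-shifted OTUs\n",
              nrow(x$manifest$pain_otus), nrow(x$manifest$pain_genes),
              nrow(x$manifest$coupled_pairs), nrow(x$manifest$occupancy)))
  invisible(x)
}
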