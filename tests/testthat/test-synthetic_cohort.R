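test_that("sim_config validates counts, probabilities, and planted ranges", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_otus = -1), class = "painlink_validation_error")
  expect_error(sim_config(hc_responder_prob = 1.2),
               class = "painlink_validation_error")
  expect_error(sim_config(planted_r_range = c(0.5, 1)),
               class = "painlink_validation_error")
  expect_error(sim_config(n_otus = 10, n_pain_otus = 20),
               class = "painlink_validation_error")
  expect_error(generate_phenotypes(sim_config(n_hc = 1, n_ibs = 2)),
               class = "painlink_validation_error")
})

test_that("generation is deterministic in (config, seed) down to written bytes", {
  cfg <- small_sim_config(seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$phenotype, s2$phenotype)
  expect_identical(s1$abundance, s2$abundance)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$manifest, s2$manifest)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(s1, d1); write_cohort(s2, d2)
  for (f in dir(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }

  s3 <- simulate_cohort(small_sim_config(seed = 100))
  expect_false(identical(s1$abundance, s3$abundance))
})

test_that("control pain scores follow the zero-inflated responder model", {
  cfg <- sim_config(hc_responder_prob = 0, seed = 5)
  phen <- generate_phenotypes(cfg)
  expect_true(all(phen$ivp_score[phen$group == "HC"] == 0))
  expect_true(all(phen$subtype[phen$group == "HC"] == "NONE"))
  expect_equal(sum(phen$subtype == "C"), 8)
  expect_equal(sum(phen$subtype == "D"), 8)
  expect_equal(sum(phen$subtype == "M"), 2)

  cfg2 <- sim_config(hc_responder_prob = 1, seed = 5)
  phen2 <- generate_phenotypes(cfg2)
  hc2 <- phen2$ivp_score[phen2$group == "HC"]
  expect_true(all(hc2 > 0))     # zero-truncated responder distribution
  expect_true(all(phen2$ivp_score >= 0 & phen2$ivp_score <= 100))
})

test_that("IBS pain scores match the clipped-normal moments (numerical-integration oracle)", {
  cfg <- sim_config(n_hc = 0, n_ibs = 1000, subtype_split = c(C = 1, D = 1, M = 1) / 3,
                    seed = 8)
  phen <- generate_phenotypes(cfg)
  x <- phen$ivp_score
  # oracle: mean of normal(32.7, 26.7) censored to [0, 100] by numerical
  # integration plus the boundary masses
  mu <- 32.7; sg <- 26.7
  core <- stats::integrate(function(v) v * stats::dnorm(v, mu, sg), 0, 100)$value
  emean <- core + 100 * (1 - stats::pnorm(100, mu, sg))
  e2 <- stats::integrate(function(v) v^2 * stats::dnorm(v, mu, sg), 0, 100)$value +
    100^2 * (1 - stats::pnorm(100, mu, sg))
  esd <- sqrt(e2 - emean^2)
  expect_lt(abs(mean(x) - emean), 2 * esd / sqrt(1000))
  # the clip's zero mass is the non-responder fraction (~11%)
  expect_lt(abs(mean(x == 0) - stats::pnorm(0, mu, sg)), 0.035)
})

test_that("planted OTU correlations are recovered on the intensity scale", {
  r_emp <- vapply(1:200, function(s) {
    cfg <- sim_config(n_otus = 2, n_genes = 1, n_pain_otus = 1, n_pain_genes = 0,
                      n_coupled_pairs = 0,
                      occupancy_shifts = data.frame(p_hc = numeric(), p_ibs = numeric()),
                      planted_r_range = c(0.8, 0.8), planted_neg_prob_otu = 0,
                      seed = 10000 + s)
    phen <- generate_phenotypes(cfg)
    mic <- generate_microbiome(phen, cfg)
    resp <- phen$ivp_score > 0
    cor(mic$abundance[1, resp], phen$ivp_score[resp])
  }, numeric(1))
  expect_lt(abs(mean(r_emp) - 0.8), 0.05)
})

test_that("null OTUs are uncorrelated with pain on average", {
  r_null <- vapply(1:250, function(s) {
    cfg <- sim_config(n_otus = 2, n_genes = 1, n_pain_otus = 0, n_pain_genes = 0,
                      n_coupled_pairs = 0,
                      occupancy_shifts = data.frame(p_hc = numeric(), p_ibs = numeric()),
                      seed = 20000 + s)
    phen <- generate_phenotypes(cfg)
    mic <- generate_microbiome(phen, cfg)
    resp <- phen$ivp_score > 0
    cor(mic$abundance[1, resp], phen$ivp_score[resp])
  }, numeric(1))
  # mean empirical r of a null feature is 0 within Monte-Carlo error
  expect_lt(abs(mean(r_null)), 3 / sqrt(250 * 16))
})

test_that("occupancy-shifted OTUs are masked to exact zeros at the planted rates", {
  cfg <- sim_config(n_otus = 30, n_pain_otus = 0, n_genes = 1, n_pain_genes = 0,
                    n_coupled_pairs = 0, n_hc = 200, n_ibs = 200,
                    occupancy_shifts = data.frame(p_hc = 1, p_ibs = 0.5),
                    seed = 31)
  phen <- generate_phenotypes(cfg)
  mic <- generate_microbiome(phen, cfg)
  otu <- mic$manifest$occupancy$otu_id[1]
  hc_vals <- mic$abundance[otu, phen$group == "HC"]
  ibs_vals <- mic$abundance[otu, phen$group == "IBS"]
  expect_true(all(hc_vals > 0))                       # p = 1: always present
  ibs_rate <- mean(ibs_vals > 0)
  expect_lt(abs(ibs_rate - 0.5), 3 * sqrt(0.25 / 200))  # binomial band
  expect_true(all(mic$abundance >= 0))
  expect_true(all(ibs_vals[ibs_vals == 0] == 0))      # masked entries exact zeros
})

test_that("planted OTU-gene couplings carry the configured correlation", {
  r_cpl <- vapply(1:200, function(s) {
    cfg <- sim_config(n_otus = 2, n_genes = 2, n_pain_otus = 0, n_pain_genes = 0,
                      n_coupled_pairs = 1, coupling_r = 0.75,
                      occupancy_shifts = data.frame(p_hc = numeric(), p_ibs = numeric()),
                      seed = 40000 + s)
    phen <- generate_phenotypes(cfg)
    mic <- generate_microbiome(phen, cfg)
    expr <- generate_expression(phen, mic$abundance, cfg)
    pair <- expr$manifest$coupled_pairs
    cor(mic$abundance[pair$otu_id, ], expr$expression[pair$gene_id, ])
  }, numeric(1))
  expect_lt(abs(mean(r_cpl) - 0.75), 0.05)
})

test_that("expression generation validates its coupling references", {
  cfg <- sim_config(n_otus = 3, n_genes = 5, n_pain_otus = 0, n_pain_genes = 0,
                    n_coupled_pairs = 4,
                    occupancy_shifts = data.frame(p_hc = numeric(), p_ibs = numeric()),
                    seed = 3)
  phen <- generate_phenotypes(cfg)
  mic <- generate_microbiome(phen, cfg)
  expect_error(generate_expression(phen, mic$abundance, cfg),
               class = "painlink_validation_error")

  # coupling to a masked (zero-containing) OTU is refused
  cfg2 <- sim_config(n_otus = 2, n_genes = 2, n_pain_otus = 0, n_pain_genes = 0,
                     n_coupled_pairs = 1,
                     occupancy_shifts = data.frame(p_hc = 0.2, p_ibs = 0.2),
                     seed = 4)
  phen2 <- generate_phenotypes(cfg2)
  mic2 <- generate_microbiome(phen2, cfg2)
  expect_error(generate_expression(phen2, mic2$abundance, cfg2),
               class = "painlink_validation_error")
})
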