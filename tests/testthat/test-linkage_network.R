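linkage_fixture <- function(seed = 101) {
  set.seed(seed)
  samples <- sprintf("S%02d", 1:12)
  ab <- rbind(O1 = exp(rnorm(12)), O2 = exp(rnorm(12)), O3 = exp(rnorm(12)))
  colnames(ab) <- samples
  ex <- rbind(G1 = ab["O1", ],               # duplicate of an OTU row: r = 1
              G2 = rnorm(12),
              G3 = 0.9 * scale(log(ab["O2", ]))[, 1] + 0.3 * rnorm(12))
  colnames(ex) <- samples
  list(ab = ab, ex = ex, samples = samples)
}

test_that("cross_correlate computes one edge per pair with exact boundary flags", {
  f <- linkage_fixture()
  edges <- cross_correlate(c("O1", "O2", "O3"), c("G1", "G2", "G3"),
                           f$ab, f$ex, f$samples)
  expect_equal(nrow(edges), 9)
  e11 <- edges[edges$otu_id == "O1" & edges$gene_id == "G1", ]
  expect_equal(e11$r, 1, tolerance = 1e-12)
  expect_equal(e11$p, 0)
  expect_true(e11$high && e11$significant)

  # edge-level r/p match the scalar test pair by pair
  for (i in seq_len(nrow(edges))) {
    direct <- pearson_test(f$ab[edges$otu_id[i], ], f$ex[edges$gene_id[i], ])
    expect_equal(edges$r[i], direct$r, tolerance = 1e-12)
    expect_equal(edges$p[i], direct$p, tolerance = 1e-10)
  }

  # the high flag is exactly r2 >= 0.5, inclusive at the boundary
  expect_equal(edges$high, edges$r2 >= 0.5)

  # on n >= 8 samples a high edge is always significant
  expect_true(all(!edges$high | edges$significant))

  expect_warning(empty <- cross_correlate(character(), "G1", f$ab, f$ex,
                                          f$samples), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("screen tibbles feed cross_correlate and glance counts genes linked", {
  f <- linkage_fixture()
  edges <- cross_correlate(tibble::tibble(feature_id = c("O1", "O2")),
                           tibble::tibble(feature_id = c("G1", "G3")),
                           f$ab, f$ex, f$samples)
  g <- glance(edges)
  expect_equal(g$n_pairs, 4)
  expect_equal(g$n_edges, sum(edges$significant))
  expect_equal(g$n_genes_linked,
               length(unique(edges$gene_id[edges$significant])))
})

test_that("family matrix counts conserve edges and split by sign", {
  f <- linkage_fixture()
  tax <- toy_taxonomy(c("O1", "O2", "O3"),
                      family = c("Lachnospiraceae", "Lachnospiraceae",
                                 "Prevotellaceae"))
  edges <- cross_correlate(c("O1", "O2", "O3"), c("G1", "G2", "G3"),
                           f$ab, f$ex, f$samples)
  fgm <- build_family_gene_matrix(edges, tax)

  # conservation: cell counts sum to the number of significant edges
  expect_equal(sum(fgm$n_pos) + sum(fgm$n_neg), sum(edges$significant))

  # direct count oracle for one cell
  sig <- edges[edges$significant, ]
  lachno_g1 <- sig[sig$gene_id == "G1" & sig$otu_id %in% c("O1", "O2"), ]
  cell <- fgm[fgm$family == "Lachnospiraceae" & fgm$gene_id == "G1", ]
  if (nrow(lachno_g1) > 0) {
    expect_equal(cell$n_pos, sum(lachno_g1$r > 0))
    expect_equal(cell$n_neg, sum(lachno_g1$r < 0))
    expect_equal(cell$any_high, any(lachno_g1$high))
  } else {
    expect_equal(nrow(cell), 0)
  }

  # family totals are reproducible from the edge list alone
  tot <- family_edge_totals(edges, tax)
  expect_equal(sum(tot$n_edges), sum(edges$significant))

  # missing taxonomy goes to 'unclassified' with a message (O1 has a
  # guaranteed significant edge: its duplicate gene G1)
  expect_message(fgm2 <- build_family_gene_matrix(edges, tax[-1, ]),
                 "unclassified")
  expect_true("unclassified" %in% fgm2$family)
  expect_equal(sum(fgm2$n_pos) + sum(fgm2$n_neg), sum(edges$significant))

  # no edges -> empty matrix
  none <- edges[edges$r2 > 2, ]
  expect_equal(nrow(build_family_gene_matrix(none, tax)), 0)
})

test_that("species roster applies direction and strength rules", {
  hits <- tibble::tibble(feature_id = c("O1", "O2", "O3", "O4"),
                         r = c(0.75, -0.45, 0.9, -0.72))
  tax <- tibble::tibble(
    otu_id = c("O1", "O2", "O3", "O4"),
    phylum = "Firmicutes",
    family = c("Mycoplasmataceae", "Veillonellaceae", "Lachnospiraceae",
               "Bacillaceae"),
    genus = c("Mycoplasma", "Veillonella", "unclassified", "Gemella"),
    species = c("hominis", "dispar", "unclassified", "sanguinis"))
  roster <- species_ivp_lists(hits, tax)
  expect_equal(roster$otu_id, c("O1", "O2", "O4"))  # species-labeled only
  expect_equal(roster$species, c("Mycoplasma hominis", "Veillonella dispar",
                                 "Gemella sanguinis"))
  expect_equal(roster$direction, c("positive", "negative", "negative"))
  expect_equal(roster$strength, c("strong", "moderate", "strong"))

  # with edges provided, each record lists its high-linked genes
  edges <- tibble::tibble(otu_id = c("O1", "O1", "O2"),
                          gene_id = c("GB", "GA", "GC"),
                          r = c(0.8, 0.75, 0.4), r2 = c(0.64, 0.5625, 0.16),
                          p = c(0.001, 0.002, 0.2),
                          significant = c(TRUE, TRUE, FALSE),
                          high = c(TRUE, TRUE, FALSE))
  roster2 <- species_ivp_lists(hits, tax, edges = edges)
  expect_equal(roster2$high_genes[[1]], c("GA", "GB"))
  expect_equal(roster2$high_genes[[2]], character())
})

test_that("network export is deterministic and round-trips", {
  f <- linkage_fixture()
  edges <- cross_correlate(c("O2", "O1"), c("G2", "G1"), f$ab, f$ex, f$samples)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  export_network(edges, tmp)
  lines <- readLines(tmp)
  expect_equal(length(lines), nrow(edges) + 1)
  ids <- sub("\t.*", "", lines[-1])
  expect_equal(ids, sort(ids))  # lexicographic by otu_id

  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  export_network(edges, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))  # rerun: byte-identical

  back <- read_network(tmp)
  expect_equal(back$r, dplyr::arrange(edges, otu_id, gene_id)$r)
  expect_equal(back$high, dplyr::arrange(edges, otu_id, gene_id)$high)
})
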