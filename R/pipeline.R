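#' Build a run configuration
#'
#' Drives [run_pipeline()]. Supply either paths to the four input tables
#' (`phenotype_path` is the only hard requirement: with no omics tables the
#' pipeline runs in phenotype-statistics-only mode) or a `simulate` block (a
#' [sim_config()]), not neither.
#'
#' @param phenotype_path,abundance_path,taxonomy_path,expression_path Input
#'   TSV paths.
#' @param probe_gene_map_path Optional probe-to-gene map (two-column TSV)
#'   triggering the expression preprocessing chain from a raw matrix.
#' @param simulate Optional [sim_config()]; when present, inputs are
#'   generated rather than read and the master `seed` overrides the block's.
#' @param out_dir Directory for all artifacts.
#' @param seed Master seed for any randomness in the run.
#' @param screen,linkage,occupancy,diffabund Named lists of stage options
#'   (defaults are those of [screen_features()], [cross_correlate()],
#'   [occupancy_by_group()]/[differential_commonness()], and
#'   [compare_abundance()]).
#' @return A `run_config` list.
#' @export
run_config <- function(phenotype_path = NULL, abundance_path = NULL,
                       taxonomy_path = NULL, expression_path = NULL,
                       probe_gene_map_path = NULL, simulate = NULL,
                       out_dir = tempfile("painlink-run-"), seed = 1L,
                       screen = list(), linkage = list(),
                       occupancy = list(), diffabund = list()) {
  if (is.null(simulate) && is.null(phenotype_path)) {
    abort("supply either input paths or a simulate block.",
          class = "painlink_validation_error")
  }
  structure(list(phenotype_path = phenotype_path,
                 abundance_path = abundance_path,
                 taxonomy_path = taxonomy_path,
                 expression_path = expression_path,
                 probe_gene_map_path = probe_gene_map_path,
                 simulate = simulate, out_dir = out_dir,
                 seed = as.integer(seed),
                 screen = screen, linkage = linkage,
                 occupancy = occupancy, diffabund = diffabund),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' The JSON mirrors [run_config()]; a `simulate` object is converted with
#' [sim_config()] (its `occupancy_shifts` given as an object of `p_hc` /
#' `p_ibs` arrays).
#'
#' @param path JSON config path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(raw$simulate)) {
    args <- raw$simulate
    if (!is.null(args$subtype_split)) args$subtype_split <- unlist(args$subtype_split)
    if (!is.null(args$race_prob)) args$race_prob <- unlist(args$race_prob)
    if (!is.null(args$occupancy_shifts)) {
      args$occupancy_shifts <- as_tibble(args$occupancy_shifts)
    }
    sim <- do.call(sim_config, args)
  }
  run_config(phenotype_path = raw$phenotype_path,
             abundance_path = raw$abundance_path,
             taxonomy_path = raw$taxonomy_path,
             expression_path = raw$expression_path,
             probe_gene_map_path = raw$probe_gene_map_path,
             simulate = sim,
             out_dir = raw$out_dir %g% tempfile("painlink-run-"),
             seed = raw$seed %g% 1L,
             screen = raw$screen %g% list(),
             linkage = raw$linkage %g% list(),
             occupancy = raw$occupancy %g% list(),
             diffabund = raw$diffabund %g% list())
}

#' Run the full linkage analysis end-to-end
#'
#' Executes input loading (or synthesis), phenotype summary, bundle
#' validation, optional expression preprocessing, the OTU and gene IVP
#' screens, OTU-by-gene cross-correlation with the family matrix and species
#' roster, occupancy profiling with the two differential-commonness rosters,
#' and differential abundance — writing every stage's table under
#' `config$out_dir` plus a machine-readable `run_summary.json`. Any stage
#' failure aborts with the stage name; artifacts written so far remain on
#' disk, and each stage can be re-run in isolation from them.
#'
#' With only a phenotype table, the run stops after the phenotype summary.
#'
#' @param config A [run_config()].
#' @return A `painlink_run` list of stage results and counts, invisibly
#'   printable; [glance()] gives the headline counts as a one-row tibble.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "painlink_stage_error", parent = e)
    })
  }

  manifest <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    sim <- stage("simulate", {
      s <- simulate_cohort(sim_cfg)
      write_cohort(s, file.path(out_dir, "inputs"))
      s
    })
    phen <- sim$phenotype; ab <- sim$abundance
    tax <- sim$taxonomy; expr <- sim$expression
    manifest <- sim$manifest
    note("simulated cohort: %d participants, %d OTUs, %d genes",
         nrow(phen), nrow(ab), nrow(expr))
  } else {
    phen <- stage("read_phenotype", read_phenotype_table(config$phenotype_path))
    ab <- if (!is.null(config$abundance_path)) {
      stage("read_abundance", read_abundance_table(config$abundance_path))
    }
    tax <- if (!is.null(config$taxonomy_path)) {
      stage("read_taxonomy", read_taxonomy_table(config$taxonomy_path))
    }
    expr <- if (!is.null(config$expression_path)) {
      stage("read_expression", read_expression_table(config$expression_path))
    }
  }

  summary_tbl <- stage("phenotype_stats", summarize_cohort(phen))
  readr::write_tsv(format_group_summary(summary_tbl),
                   file.path(out_dir, "phenotype_summary.tsv"), progress = FALSE)
  responders <- identify_responders(phen)
  note("%d responders of %d participants", length(responders), nrow(phen))

  if (is.null(ab) || is.null(expr)) {
    note("no omics tables; phenotype-statistics-only run")
    summary <- list(mode = "phenotype_only", seed = config$seed,
                    n_participants = nrow(phen),
                    n_responders = length(responders),
                    version = as.character(utils::packageVersion("painlink")))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    return(invisible(structure(list(summary = summary,
                                    phenotype_summary = summary_tbl,
                                    config = config),
                               class = "painlink_run")))
  }
  if (is.null(tax)) {
    tax <- tibble(otu_id = character(), phylum = character(), family = character(),
                  genus = character(), species = character())
  }

  if (identical(expression_stage(expr), "raw")) {
    expr <- stage("expression_prep", {
      map <- if (!is.null(config$probe_gene_map_path)) {
        readr::read_tsv(config$probe_gene_map_path,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
      }
      prep_expression(expr, probe_gene_map = map)
    })
    note("expression preprocessed to stage '%s'", expression_stage(expr))
  }

  bundle <- cohort_bundle(phen, ab, tax, expr)
  report <- stage("validate_bundle", validate_bundle(bundle))
  write_validation_report(report, file.path(out_dir, "bundle_validation.json"))
  note("analysis sample set: %d samples", report$counts$n_analysis)

  otu_screen <- stage("ivp_screen_otu", do.call(screen_features, c(
    list(mat = ab, phenotypes = phen, kind = "otu"), config$screen)))
  gene_screen <- stage("ivp_screen_gene", do.call(screen_features, c(
    list(mat = expr, phenotypes = phen, kind = "gene"), config$screen)))
  readr::write_tsv(as_tibble(otu_screen), file.path(out_dir, "otu_screen.tsv"),
                   progress = FALSE)
  readr::write_tsv(as_tibble(gene_screen), file.path(out_dir, "gene_screen.tsv"),
                   progress = FALSE)
  otu_hits <- screen_hits(otu_screen)
  gene_hits <- screen_hits(gene_screen)
  note("screen retained %d OTUs and %d genes", nrow(otu_hits), nrow(gene_hits))

  sample_set <- intersect(attr(otu_screen, "screen")$samples,
                          report$analysis_samples)
  edges <- stage("linkage_network", do.call(cross_correlate, c(
    list(otu_hits = otu_hits, gene_hits = gene_hits, abundance = ab,
         expression = expr, sample_ids = sample_set), config$linkage)))
  export_network(edges, file.path(out_dir, "edges.tsv"))
  fgm <- stage("family_gene_matrix", build_family_gene_matrix(edges, tax))
  readr::write_tsv(as_tibble(fgm), file.path(out_dir, "family_gene_matrix.tsv"),
                   progress = FALSE)
  species <- stage("species_roster",
                   species_ivp_lists(otu_hits, tax, edges = edges))
  readr::write_tsv(dplyr::mutate(species, high_genes = purrr::map_chr(
    high_genes, paste, collapse = ",")),
    file.path(out_dir, "species_ivp.tsv"), progress = FALSE)
  eg <- glance(edges)
  note("%d significant edges (%d high); %d genes linked", eg$n_edges, eg$n_high,
       eg$n_genes_linked)

  occ <- stage("occupancy_profiles", {
    pres <- presence_calls(ab, detection_threshold =
                             config$occupancy$detection_threshold %g% 0)
    groups <- config$occupancy$groups %g% c("HC", "IBS", "IBS-C", "IBS-D", "IBS-M")
    prof <- withCallingHandlers(
      occupancy_by_group(pres, phen, groups = groups),
      warning = function(w) {
        note("occupancy: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    min_fraction <- config$occupancy$min_fraction %g% 0.30
    min_delta <- config$occupancy$min_delta %g% 0.25
    kept <- substantial_presence(prof, min_fraction)
    universe <- unique(kept$otu_id)
    delta <- differential_commonness(prof, "IBS", "HC", min_delta = min_delta,
                                     otus = universe)
    more_ibs <- delta[delta$more_common_in == "IBS", ]
    more_hc <- delta[delta$more_common_in == "HC", ]
    readr::write_tsv(as_tibble(more_ibs),
                     file.path(out_dir, "occupancy_more_common_IBS.tsv"),
                     progress = FALSE)
    readr::write_tsv(as_tibble(more_hc),
                     file.path(out_dir, "occupancy_more_common_HC.tsv"),
                     progress = FALSE)
    fp <- family_proportions(kept, tax)
    readr::write_tsv(fp, file.path(out_dir, "family_proportions.tsv"),
                     progress = FALSE)
    list(profiles = prof, kept = kept, delta = delta,
         family_proportions = fp, gap = family_proportion_gap(fp),
         n_more_ibs = nrow(more_ibs), n_more_hc = nrow(more_hc))
  })
  note("occupancy rosters: %d OTUs more common in IBS, %d in HC",
       occ$n_more_ibs, occ$n_more_hc)

  da <- stage("diff_abundance", do.call(compare_abundance, c(
    list(abundance = ab, phenotypes = phen), config$diffabund)))
  readr::write_tsv(as_tibble(da), file.path(out_dir, "diff_abundance.tsv"),
                   progress = FALSE)
  dg <- glance(da)
  note("differential abundance: %d nominal (%d up, %d down), %d Bonferroni",
       dg$n_significant, dg$n_up_in_a, dg$n_down_in_a, dg$n_bonferroni)

  summary <- list(
    mode = if (is.null(config$simulate)) "real_data" else "synthetic",
    seed = config$seed,
    version = as.character(utils::packageVersion("painlink")),
    n_participants = nrow(phen),
    n_responders = length(responders),
    n_analysis_samples = report$counts$n_analysis,
    n_otus = nrow(ab),
    n_genes = nrow(expr),
    n_otu_hits = nrow(otu_hits),
    n_gene_hits = nrow(gene_hits),
    n_edges = eg$n_edges,
    n_high_edges = eg$n_high,
    n_genes_linked = eg$n_genes_linked,
    n_occupancy_more_ibs = occ$n_more_ibs,
    n_occupancy_more_hc = occ$n_more_hc,
    n_da_nominal = dg$n_significant,
    n_da_up_in_a = dg$n_up_in_a,
    n_da_down_in_a = dg$n_down_in_a,
    n_da_bonferroni = dg$n_bonferroni,
    thresholds = list(
      r2_min_otu = attr(otu_screen, "screen")$r2_min,
      r2_min_gene = attr(gene_screen, "screen")$r2_min,
      p_max = attr(otu_screen, "screen")$p_max,
      bonferroni_otu = attr(otu_screen, "screen")$bonferroni_threshold,
      bonferroni_gene = attr(gene_screen, "screen")$bonferroni_threshold,
      occupancy_min_fraction = config$occupancy$min_fraction %g% 0.30,
      occupancy_min_delta = config$occupancy$min_delta %g% 0.25
    )
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(structure(list(summary = summary, phenotype_summary = summary_tbl,
                           validation = report, otu_screen = otu_screen,
                           gene_screen = gene_screen, edges = edges,
                           family_gene_matrix = fgm, species = species,
                           occupancy = occ, diff_abundance = da,
                           manifest = manifest, config = config),
                      class = "painlink_run"))
}

#' @export
print.painlink_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("painlink run (%s mode, seed %d)\n", s$mode, s$seed))
  cat(sprintf("  participants: %d (%d responders)\n",
              s$n_participants, s$n_responders))
  if (!is.null(s$n_otu_hits)) {
    cat(sprintf("  screen: %d OTUs, %d genes retained\n",
                s$n_otu_hits, s$n_gene_hits))
    cat(sprintf("  linkage: %d edges (%d high), %d genes linked\n",
                s$n_edges, s$n_high_edges, s$n_genes_linked))
    cat(sprintf("  occupancy: %d OTUs more common in IBS, %d in HC\n",
                s$n_occupancy_more_ibs, s$n_occupancy_more_hc))
    cat(sprintf("  differential abundance: %d nominal, %d Bonferroni\n",
                s$n_da_nominal, s$n_da_bonferroni))
  }
  invisible(x)
}

#' @export
glance.painlink_run <- function(x, ...) {
  s <- x$summary
  keep <- s[vapply(s, function(v) is.numeric(v) || is.character(v), logical(1))]
  as_tibble(keep)
}
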