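#' Run the full analysis pipeline on simulated data
#'
#' Chains every stage end to end: count simulation, upper-quartile
#' normalization, ratio-to-baseline profiles, time-course and
#' strain-difference tests, regulon assignment, within-regulon UPGMA
#' clustering, genome simulation for the temporally shifted sigJ clusters,
#' promoter extraction, motif discovery, consensus construction, J-Box
#' genome scanning and a qPCR round trip. All stage outputs are written to
#' `out_dir` with stable names, and a JSON manifest records every parameter,
#' path and seed; rerunning with the same configuration reproduces identical
#' stage outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [cascade_config()]; its `seed` drives every stage
#'   (derived seeds are used for the genome and qPCR fixtures).
#' @param fdr BH threshold for all DE flags.
#' @param pseudocount pseudocount for [ratio_profiles()].
#' @param cluster_height,min_cluster_size passed to [cluster_regulons()].
#' @param motif_width motif width for promoter discovery.
#' @param rule [jbox_rule()] used for planting and scanning.
#' @param genome_planted_fraction fraction of fixture promoters given a
#'   J-Box (default 0.8, matching the observed share of J-Box-bearing
#'   promoters in the shifted clusters).
#' @param max_genome_genes cap on fixture size.
#' @return invisibly, a named list of output paths plus the key result
#'   tibbles (`regulons`, `summary`, `clusters`, `consensus_offset`,
#'   `jbox_hits`).
#' @export
run_pipeline <- function(out_dir,
                         config = cascade_config(),
                         fdr = 0.05,
                         pseudocount = 1,
                         cluster_height = 2,
                         min_cluster_size = 5,
                         motif_width = 9,
                         rule = jbox_rule(),
                         genome_planted_fraction = 0.8,
                         max_genome_genes = 60) {
  stopifnot(inherits(config, "cascade_config"))
  if (fdr <= 0 || fdr > 1) abort("`fdr` must be in (0, 1].")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  paths <- list()

  sim <- simulate_timecourse(config)
  write_expression_tsv(sim$dataset, p("counts.tsv"), p("samples.tsv"))
  readr::write_tsv(sim$truth, p("truth.tsv"))
  paths$counts <- p("counts.tsv"); paths$samples <- p("samples.tsv")
  paths$truth <- p("truth.tsv")

  norm <- normalize_uq(sim$dataset)
  write_expression_tsv(norm, p("normalized.tsv"), p("samples.tsv"))
  paths$normalized <- p("normalized.tsv")

  ratios <- ratio_profiles(norm, pseudocount = pseudocount)
  profiles <- mean_profiles(ratios)
  pm <- profile_matrix(profiles)
  readr::write_tsv(as_tibble(pm, rownames = "gene_id"), p("ratio_matrix.tsv"))
  paths$ratio_matrix <- p("ratio_matrix.tsv")

  de <- de_analysis(ratios, fdr = fdr)
  readr::write_tsv(de, p("de.tsv"))
  paths$de <- p("de.tsv")

  labels <- assign_regulons(de)
  readr::write_tsv(labels, p("regulons.tsv"))
  summary_tbl <- regulon_summary(labels)
  readr::write_tsv(summary_tbl, p("regulon_summary.tsv"))
  paths$regulons <- p("regulons.tsv")
  paths$regulon_summary <- p("regulon_summary.tsv")

  clusters <- cluster_regulons(profiles, labels,
                               min_size = min_cluster_size,
                               height = cluster_height)
  readr::write_tsv(clusters, p("clusters.tsv"))
  paths$clusters <- p("clusters.tsv")

  # genome fixture for the temporally shifted sigJ clusters (the J-Box hosts)
  shift_genes <- sim$truth$gene_id[sim$truth$is_shift_cluster]
  shift_genes <- utils::head(shift_genes, max_genome_genes)
  if (length(shift_genes) < 5)
    abort("Too few shift-cluster genes to build the genome fixture.")
  fixture <- simulate_genome(n_genes = length(shift_genes),
                             planted_fraction = genome_planted_fraction,
                             seed = config$seed + 1L,
                             gene_ids = shift_genes,
                             rule = rule)
  write_genome_fixture(fixture, p("genome.fasta"), p("features.gff3"))
  readr::write_tsv(fixture$planted, p("planted_sites.tsv"))
  paths$genome <- p("genome.fasta"); paths$features <- p("features.gff3")
  paths$planted <- p("planted_sites.tsv")

  leaders <- select_promoter_genes(fixture$features)
  promoters <- extract_promoters(fixture$contigs, leaders)
  write_promoter_fasta(promoters, p("promoters.fasta"))
  readr::write_tsv(promoters[, setdiff(names(promoters), "sequence")],
                   p("promoters.tsv"))
  paths$promoters <- p("promoters.fasta")

  seqs <- setNames(promoters$sequence, promoters$gene_id)
  model <- discover_motif(seqs, width = motif_width)
  consensus_offset <- NA_real_
  if (!is.null(model)) {
    write_meme_minimal(model, p("motif.meme"))
    readr::write_tsv(model$sites, p("motif_sites.tsv"))
    paths$motif <- p("motif.meme")
    run <- strrep("G", rule$g_run)
    fw <- model$sites[model$sites$strand == "+", ]
    anchored <- vapply(seq_len(nrow(fw)), function(i) {
      wm <- substr(seqs[[fw$seq_id[i]]], fw$start[i], fw$start[i] + motif_width - 1L)
      grepl(run, wm, fixed = TRUE)
    }, logical(1))
    fw <- fw[anchored, ]
    if (nrow(fw) >= 2) {
      cons <- build_consensus(seqs[fw$seq_id], fw$start, width = motif_width,
                              tss_pos = 61, g_run = rule$g_run)
      freq_tbl <- as_tibble(t(cons$freq))
      freq_tbl$rel <- cons$rel; freq_tbl$ic <- cons$ic
      readr::write_tsv(freq_tbl, p("consensus_matrix.tsv"))
      paths$consensus <- p("consensus_matrix.tsv")
      consensus_offset <- tss_motif_offset(cons)
    }
  }

  hits <- scan_jbox_upstream(fixture$contigs, fixture$features, rule)
  readr::write_tsv(hits, p("jbox_hits.tsv"))
  paths$jbox_hits <- p("jbox_hits.tsv")

  ct <- simulate_qpcr(c(sigC = 4, sigF = 2), ct_noise_sd = 0,
                      seed = config$seed + 2L)
  readr::write_tsv(ct, p("qpcr_ct.tsv"))
  folds <- bind_rows(
    ddct_fold_change(ct, "sigC", "rnpB", "control"),
    ddct_fold_change(ct, "sigF", "rnpB", "control"))
  readr::write_tsv(folds, p("qpcr_folds.tsv"))
  paths$qpcr <- p("qpcr_folds.tsv")

  manifest <- list(
    subcommand = "run_all",
    version = as.character(utils::packageVersion("jboxr")),
    seed = config$seed,
    parameters = list(
      config = unclass(config), fdr = fdr, pseudocount = pseudocount,
      cluster_height = cluster_height, min_cluster_size = min_cluster_size,
      motif_width = motif_width, rule = unclass(rule),
      genome_planted_fraction = genome_planted_fraction,
      max_genome_genes = max_genome_genes),
    outputs = paths,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths$manifest <- p("manifest.json")

  invisible(list(paths = paths, regulons = labels, summary = summary_tbl,
                 clusters = clusters, consensus_offset = consensus_offset,
                 jbox_hits = hits, truth = sim$truth))
}
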