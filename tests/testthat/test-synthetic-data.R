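test_that("truth table conserves the configured regulon sizes and DE totals", {
  sim <- default_analysis()$sim
  tr <- sim$truth
  expect_equal(sum(tr$category == "sigJ"), 389)
  expect_equal(sum(tr$category == "sigC"), 300)
  expect_equal(sum(tr$category == "sigF"), 37)
  expect_equal(sum(tr$category == "shared"), 408)
  expect_equal(sum(tr$direction == "up", na.rm = TRUE), 601)
  expect_equal(sum(tr$direction == "down", na.rm = TRUE), 533)
  # every gene in the count matrix appears exactly once in the truth
  expect_setequal(tr$gene_id, rownames(sim$dataset$counts))
  expect_equal(anyDuplicated(tr$gene_id), 0L)
})

test_that("strain amplitudes encode the regulatory hierarchy", {
  tr <- default_analysis()$sim$truth
  dep <- tr$category %in% c("sigJ", "sigC", "sigF")
  expect_true(all(tr$amp_dsigJ[dep] == 0))
  expect_true(all(tr$amp_dsigF[tr$category == "sigF"] == 0))
  # sigF deletion leaves every other category's amplitude intact
  expect_equal(tr$amp_dsigF[!tr$category == "sigF"],
               tr$amp_WT[!tr$category == "sigF"])
  # the temporal shift advances onset only in the sigC deletion background
  sh <- tr$is_shift_cluster
  expect_true(all(tr$category[sh] == "sigJ"))
  expect_true(all(tr$onset_dsigC[sh] < tr$onset_WT[sh]))
  expect_equal(tr$onset_dsigC[!sh], tr$onset_WT[!sh])
})

test_that("count simulation is deterministic and design-complete", {
  cfg <- small_config()
  a <- simulate_timecourse(cfg)
  b <- simulate_timecourse(cfg)
  expect_identical(a$dataset$counts, b$dataset$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(ncol(a$dataset$counts), 4 * 5 * 3)
  expect_equal(sort(unique(a$dataset$samples$strain)),
               sort(c("WT", "dsigJ", "dsigC", "dsigF")))
  expect_equal(sort(unique(a$dataset$samples$time_h)), c(0, 1, 6, 12, 18))
})

test_that("zero-amplitude configuration yields flat wild-type trajectories", {
  sim <- null_analysis()$sim
  expect_true(all(sim$truth$amp_WT == 0))
  prof <- mean_profiles(ratio_profiles(normalize_uq(sim$dataset)))
  wt <- dplyr::filter(prof, strain == "WT")
  # mean trajectory stays near zero everywhere (no induction signal)
  drift <- tapply(wt$log2_ratio, wt$time_h, mean)
  expect_true(all(abs(drift) < 0.1))
})

test_that("invalid cascade configurations are rejected", {
  expect_error(cascade_config(n_genes = 100), "sum to")
  expect_error(cascade_config(times_h = c(0, 6, 1, 12, 18)), "increasing")
  expect_error(cascade_config(times_h = c(1, 6, 12)), "start at 0")
  expect_error(cascade_config(nb_dispersion = -1), "dispersion")
})

test_that("genome fixture plants a scannable J-Box upstream of every gene", {
  fx <- cached("fx_full", simulate_genome(n_genes = 25, planted_fraction = 1,
                                          seed = 5))
  hits <- scan_jbox_upstream(fx$contigs, fx$features)
  expect_setequal(unique(hits$gene_id), fx$features$gene_id)
  # planted substring matches the rule at the recorded coordinates
  contig <- fx$contigs[["contig1"]]
  for (i in seq_len(nrow(fx$planted))) {
    s <- substr(contig, fx$planted$start[i], fx$planted$end[i])
    if (fx$planted$strand[i] == "-") s <- revcomp(s)
    expect_equal(nrow(scan_jbox(s)), 1)
    expect_equal(scan_jbox(s)$start, 0)
  }
})

test_that("unplanted genome fixtures contain no J-Box in any scanned window", {
  fx0 <- simulate_genome(n_genes = 15, planted_fraction = 0, seed = 6)
  hits <- scan_jbox_upstream(fx0$contigs, fx0$features)
  expect_equal(nrow(hits), 0)
  leaders <- select_promoter_genes(fx0$features)
  pr <- extract_promoters(fx0$contigs, leaders)
  expect_true(all(vapply(pr$sequence, function(s) nrow(scan_jbox(s)) == 0,
                         logical(1))))
})

test_that("genome fixture serialization is byte-identical across runs", {
  fx <- simulate_genome(n_genes = 8, planted_fraction = 0.5, seed = 9,
                        operon_fraction = 0.4)
  d1 <- withr::local_tempdir()
  write_genome_fixture(fx, file.path(d1, "a.fasta"), file.path(d1, "a.gff3"))
  fx2 <- simulate_genome(n_genes = 8, planted_fraction = 0.5, seed = 9,
                         operon_fraction = 0.4)
  write_genome_fixture(fx2, file.path(d1, "b.fasta"), file.path(d1, "b.gff3"))
  expect_identical(readBin(file.path(d1, "a.fasta"), "raw", 1e6),
                   readBin(file.path(d1, "b.fasta"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, "a.gff3"), "raw", 1e6),
                   readBin(file.path(d1, "b.gff3"), "raw", 1e6))
})

test_that("TSSs keep clearance from contig ends and GFF round trip works", {
  fx <- simulate_genome(n_genes = 10, planted_fraction = 1, seed = 3,
                        operon_fraction = 0.5)
  f <- fx$features
  len <- nchar(fx$contigs[[1]])
  has <- !is.na(f$tss)
  up <- ifelse(f$strand[has] == "+", f$tss[has] - 1, len - f$tss[has])
  dn <- ifelse(f$strand[has] == "+", len - f$tss[has], f$tss[has] - 1)
  expect_true(all(up >= 60))
  expect_true(all(dn >= 20))
  d <- withr::local_tempdir()
  write_genome_fixture(fx, file.path(d, "g.fasta"), file.path(d, "g.gff3"))
  back <- read_features_gff(file.path(d, "g.gff3"))
  back <- back[match(f$gene_id, back$gene_id), ]
  expect_equal(back$cds_start, f$cds_start)
  expect_equal(back$cds_end, f$cds_end)
  expect_equal(back$strand, f$strand)
  expect_equal(back$tss, f$tss)
  expect_equal(back$operon_rank[!is.na(f$operon_id)],
               f$operon_rank[!is.na(f$operon_id)])
})

test_that("qPCR fixture round-trips planted folds at zero noise", {
  ct <- simulate_qpcr(c(geneX = 4, geneY = 1), ct_noise_sd = 0, seed = 2)
  fx <- ddct_fold_change(ct, "geneX", "rnpB", "control")
  expect_equal(fx$fold_mean[fx$condition == "induced"], 4)
  expect_equal(fx$fold_mean[fx$condition == "control"], 1)
  fy <- ddct_fold_change(ct, "geneY", "rnpB", "control")
  expect_equal(fy$fold_mean[fy$condition == "induced"], 1)
  expect_error(simulate_qpcr(c(bad = -2)), "positive")
})

test_that("noisy qPCR fold estimates match the lognormal closed form", {
  # 1000 independent single-gene experiments (reference wells drawn afresh
  # each time, so no noise is shared between replicates of the experiment)
  n <- 1000; sigma <- 0.2; fold <- 2
  folds <- vapply(seq_len(n), function(i) {
    ct <- simulate_qpcr(c(gx = fold), ct_noise_sd = sigma, seed = 5000 + i)
    f <- ddct_fold_change(ct, "gx", "rnpB", "control")
    f$fold_mean[f$condition == "induced"]
  }, numeric(1))
  # dCt noise has SD sigma (two tech reps averaged, target minus reference);
  # ddCt adds the calibrator mean over 3 replicates -> variance sigma^2 * 4/3
  v <- sigma^2 * (1 + 1/3)
  analytic <- fold * exp(log(2)^2 * v / 2)
  se <- stats::sd(folds) / sqrt(n)
  expect_lt(abs(mean(folds) - analytic), 3 * se)
})
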