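test_that("information content hits its closed-form anchor values", {
  expect_equal(info_content(c(1, 0, 0, 0)), 2)
  expect_equal(info_content(c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(info_content(c(0.5, 0.5, 0, 0)), 1)
})

test_that("ZOOPS EM recovers a planted motif with every site", {
  pp <- cached("planted20", planted_promoters(n = 20, seed = 123))
  m <- cached("planted20_model", discover_motif(pp$seqs, width = 9))
  expect_s3_class(m, "motif_model")
  expect_equal(m$consensus, "GGGAATACT")
  expect_equal(nrow(m$sites), 20)
  expect_true(all(m$sites$strand == "+"))
  got <- m$sites$start[match(names(pp$seqs), m$sites$seq_id)]
  expect_equal(got, pp$pos)
  expect_equal(m$same_orientation_fraction, 1)
})

test_that("the same-orientation gate suppresses a motif planted in under half the set", {
  pp <- planted_promoters(n = 20, n_planted = 8, seed = 321)
  m <- discover_motif(pp$seqs, width = 9)
  expect_null(m)
})

test_that("the ZOOPS log likelihood is non-decreasing and PWM columns stay simplex", {
  pp <- cached("planted20", planted_promoters(n = 20, seed = 123))
  m <- cached("planted20_model", discover_motif(pp$seqs, width = 9))
  expect_true(all(diff(m$loglik_trace) >= -1e-6))
  expect_equal(colSums(m$pwm), rep(1, 9), tolerance = 1e-9)
  expect_true(all(m$pwm >= 0))
  # a motif planted on the reverse strand is found there
  pp2 <- planted_promoters(n = 10, motif = revcomp("GGGAATACT"), seed = 55)
  m2 <- discover_motif(pp2$seqs, width = 9)
  expect_s3_class(m2, "motif_model")
  expect_true(m2$consensus %in% c("GGGAATACT", revcomp("GGGAATACT")))
})

test_that("null-sequence motifs sit at the selection-bias floor, far below planted ones", {
  # Picking the best of ~2*(81-9+1) candidate windows per sequence buys
  # roughly log2(2*73)/9 ~ 0.87 bits per column even from pure noise; any
  # ZOOPS fit on uniform sequences hovers at that floor, while a planted
  # motif approaches the 2-bit ceiling. The discriminating signal is the gap.
  set.seed(60)
  ics <- vapply(1:20, function(i) {
    seqs <- random_dna(20, 81)
    m <- discover_motif(seqs, width = 9, min_orientation_frac = 0)
    mean(apply(m$pwm, 2, info_content))
  }, numeric(1))
  floor_bits <- log2(2 * (81 - 9 + 1)) / 9
  expect_lt(mean(ics), floor_bits + 0.25)
  pp <- cached("planted20", planted_promoters(n = 20, seed = 123))
  m_planted <- cached("planted20_model", discover_motif(pp$seqs, width = 9))
  planted_ic <- mean(apply(m_planted$pwm, 2, info_content))
  expect_gt(planted_ic, mean(ics) + 0.8)
})

test_that("degenerate motif inputs are rejected", {
  expect_error(discover_motif(random_dna(3, 30, seed = 1)), "at least 5")
  expect_error(discover_motif(random_dna(6, 8, seed = 2), width = 9),
               "shortest sequence")
})

test_that("the GGG-anchored consensus aligns sites and annotates elements", {
  # identical sites: every aligned motif column carries 2 bits
  seqs <- rep(paste0(strrep("T", 45), "GGGAATACT", strrep("C", 27)), 8)
  names(seqs) <- paste0("s", 1:8)
  cons <- build_consensus(seqs, site_start = rep(46, 8), tss_pos = 61)
  e <- cons$elements
  motif_cols <- c(e$EXT, e$minus10)
  expect_equal(unname(cons$ic[motif_cols]), rep(2, 9))
  expect_equal(cons$rel[e$plus1], 1)
  expect_equal(cons$rel[e$EXT[1]], -15)
  # sites at shifted window positions still align on the first G
  seqs2 <- c(a = paste0(strrep("A", 10), "GGGAATACT", strrep("A", 20)),
             b = paste0(strrep("A", 20), "GGGAATACT", strrep("A", 10)))
  cons2 <- build_consensus(seqs2, site_start = c(11, 21), tss_pos = c(26, 36))
  expect_equal(unname(cons2$ic[cons2$elements$EXT]), rep(2, 3))
  # a site without the anchor errors
  expect_error(build_consensus(c(x = strrep("A", 30)), 5), "anchor")
})

test_that("mixed-frequency consensus columns reproduce hand-computed bits", {
  seqs <- c(s1 = paste0("GGGAATACT", "A"), s2 = paste0("GGGAATACT", "C"),
            s3 = paste0("GGGAATACT", "G"), s4 = paste0("GGGAATACT", "T"),
            s5 = paste0("GGGAATACT", "A"), s6 = paste0("GGGAATACT", "C"),
            s7 = paste0("GGGAATACT", "G"), s8 = paste0("GGGAATACT", "T"))
  cons <- build_consensus(seqs, site_start = rep(1, 8), tss_pos = 10)
  expect_equal(unname(cons$ic[10]), 0)          # uniform column: 0 bits
  seqs2 <- c(s1 = "GGGAATACTA", s2 = "GGGAATACTA", s3 = "GGGAATACTC",
             s4 = "GGGAATACTC", s5 = "GGGAATACTA", s6 = "GGGAATACTA",
             s7 = "GGGAATACTC", s8 = "GGGAATACTC")
  cons2 <- build_consensus(seqs2, site_start = rep(1, 8), tss_pos = 10)
  expect_equal(unname(cons2$ic[10]), 1)         # half/half column: 1 bit
})

test_that("the TSS sits 10 bases from the aAtacT center in the standard layout", {
  # first G at -15 within a -60..+20 window puts the hexad center at -10
  pp <- lapply(1:12, function(i) {
    s <- random_dna(1, 81, seed = 400 + i)
    substr(s, 46, 54) <- "GGGAATACT"
    s
  })
  seqs <- setNames(unlist(pp), paste0("p", 1:12))
  cons <- build_consensus(seqs, site_start = rep(46, 12), tss_pos = 61)
  expect_equal(tss_motif_offset(cons), 10)
  # degenerate layout: TSS coincident with the element center
  cons0 <- build_consensus(seqs, site_start = rep(46, 12), tss_pos = 51)
  expect_equal(tss_motif_offset(cons0), 0)
  # element one base further upstream -> 11
  pp11 <- lapply(1:12, function(i) {
    s <- random_dna(1, 81, seed = 500 + i)
    substr(s, 45, 53) <- "GGGAATACT"
    s
  })
  seqs11 <- setNames(unlist(pp11), paste0("q", 1:12))
  cons11 <- build_consensus(seqs11, site_start = rep(45, 12), tss_pos = 61)
  expect_equal(tss_motif_offset(cons11), 11)
})

test_that("MEME-minimal output round-trips the PWM", {
  pp <- cached("planted20", planted_promoters(n = 20, seed = 123))
  m <- cached("planted20_model", discover_motif(pp$seqs, width = 9))
  d <- withr::local_tempdir()
  write_meme_minimal(m, file.path(d, "m.meme"))
  lines <- readLines(file.path(d, "m.meme"))
  expect_true(any(grepl("^MOTIF GGGAATACT", lines)))
  mat <- do.call(rbind, lapply(grep("^ [0-9]", lines, value = TRUE),
                               function(l) scan(text = l, quiet = TRUE)))
  expect_equal(dim(mat), c(9, 4))
  expect_equal(unname(t(mat)), unname(round(m$pwm, 6)), tolerance = 1e-5)
})
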