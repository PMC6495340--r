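toy_genome <- function(len = 200, seed = 77) {
  set.seed(seed)
  setNames(paste0(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "c1")
}

test_that("operon-leader selection keeps monocistronic genes and leaders only", {
  f <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    operon_id = c("op1", "op1", "op1", NA),
    operon_rank = c(1L, 2L, 3L, NA))
  f$operon_rank[4] <- 1L  # monocistronic: no operon id
  kept <- select_promoter_genes(f)
  expect_setequal(kept$gene_id, c("g1", "g4"))
  # genes with no operon annotation at all are retained with a warning
  f2 <- tibble::tibble(gene_id = "gx", operon_id = NA_character_,
                       operon_rank = NA_integer_)
  expect_warning(kept2 <- select_promoter_genes(f2), "operon annotation")
  expect_equal(kept2$gene_id, "gx")
  expect_equal(nrow(select_promoter_genes(f[0, ])), 0)
})

test_that("forward-strand windows span [tss-60, tss+20] with 81 bases", {
  g <- toy_genome(200)
  f <- tibble::tibble(gene_id = "g1", contig = "c1", strand = "+", tss = 100L)
  pr <- extract_promoters(g, f)
  expect_equal(pr$start, 40)
  expect_equal(pr$end, 120)
  expect_equal(nchar(pr$sequence), 81)
  expect_equal(pr$sequence, substr(g[["c1"]], 40, 120))
  expect_equal(pr$tss_offset, 61)
  expect_false(pr$clipped)
})

test_that("windows overrunning the contig error unless clipping is requested", {
  g <- toy_genome(200)
  f <- tibble::tibble(gene_id = "g1", contig = "c1", strand = "+", tss = 30L)
  expect_error(extract_promoters(g, f), "overruns")
  pr <- extract_promoters(g, f, clip = TRUE)
  expect_true(pr$clipped)
  expect_equal(pr$start, 1)
  expect_equal(nchar(pr$sequence), 50)  # 29 upstream + TSS + 20 downstream
})

test_that("reverse-strand extraction reverse-complements the mirrored span", {
  g <- toy_genome(200)
  f <- tibble::tibble(gene_id = "g1", contig = "c1", strand = "-", tss = 100L)
  pr <- extract_promoters(g, f)
  expect_equal(pr$start, 80)
  expect_equal(pr$end, 160)
  expect_equal(pr$sequence, revcomp(substr(g[["c1"]], 80, 160)))
  expect_equal(pr$tss_offset, 61)
})

test_that("extraction commutes with genome reverse-complementation", {
  fx <- cached("fx_full", simulate_genome(n_genes = 25, planted_fraction = 1,
                                          seed = 5))
  len <- nchar(fx$contigs[[1]])
  rc_genome <- setNames(revcomp(fx$contigs[[1]]), names(fx$contigs))
  f <- select_promoter_genes(fx$features)
  mirrored <- dplyr::mutate(f, tss = len - tss + 1L,
                            strand = ifelse(strand == "+", "-", "+"))
  a <- extract_promoters(fx$contigs, f)
  b <- extract_promoters(rc_genome, mirrored)
  expect_equal(b$sequence, a$sequence)
})

test_that("relative coordinates round-trip to the genomic span endpoints", {
  expect_equal(rel_to_genomic(100, "+", -60), 40)
  expect_equal(rel_to_genomic(100, "+", 20), 119)  # +1 is the TSS base itself
  expect_equal(rel_to_genomic(100, "+", 1), 100)
  expect_equal(rel_to_genomic(100, "-", -60), 160)
  expect_equal(rel_to_genomic(100, "-", 20), 81)
  expect_equal(rel_to_genomic(100, "-", 1), 100)
  expect_error(rel_to_genomic(100, "+", 0), "0")
  # endpoints of the extracted 81-base span: -60 upstream edge, 21st
  # transcribed base downstream (the span covers +1..+21 past the TSS)
  g <- toy_genome(200)
  f <- tibble::tibble(gene_id = "g1", contig = "c1", strand = "+", tss = 100L)
  pr <- extract_promoters(g, f)
  expect_equal(rel_to_genomic(100, "+", -60), pr$start)
  expect_equal(rel_to_genomic(100, "+", 21), pr$end)
})

test_that("promoter FASTA output is readable and carries coordinates", {
  fx <- cached("fx_full", simulate_genome(n_genes = 25, planted_fraction = 1,
                                          seed = 5))
  pr <- extract_promoters(fx$contigs, select_promoter_genes(fx$features))
  d <- withr::local_tempdir()
  write_promoter_fasta(pr, file.path(d, "p.fasta"))
  back <- Biostrings::readDNAStringSet(file.path(d, "p.fasta"))
  expect_equal(length(back), nrow(pr))
  expect_equal(unname(as.character(back)), pr$sequence)
  expect_true(all(grepl("^gene\\d+ contig1:\\d+\\([+-]\\)", names(back))))
})
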