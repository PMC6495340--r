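samples2 <- function(n) {
  tibble::tibble(sample_id = paste0("s", seq_len(n)), strain = "WT",
                 time_h = 0, replicate = seq_len(n))
}

test_that("upper-quartile normalization follows the stated rule on a toy matrix", {
  m <- matrix(c(2, 4, 8, 4, 8, 16), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ds <- expression_dataset(m, samples2(2))
  nm <- normalize_uq(ds)
  # both columns scaled so their upper quartile equals the geometric mean
  expect_equal(unname(nm$counts[, 1]), c(2, 4, 8) * sqrt(2))
  expect_equal(unname(nm$counts[, 2]), c(2, 4, 8) * sqrt(2))
  # doubling a column halves its factor; identical columns get equal factors
  expect_equal(unname(nm$scale_factors[2]), unname(nm$scale_factors[1]) / 2)
  m2 <- cbind(s1 = c(3, 5, 9), s2 = c(3, 5, 9))
  rownames(m2) <- paste0("g", 1:3)
  nm2 <- normalize_uq(expression_dataset(m2, samples2(2)))
  expect_equal(nm2$counts[, 1], nm2$counts[, 2])
  expect_equal(unname(nm2$scale_factors), c(1, 1))
})

test_that("normalization is idempotent and rejects degenerate samples", {
  set.seed(4)
  m <- matrix(rpois(60, 40), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  nm <- normalize_uq(expression_dataset(m, samples2(6)))
  renorm <- normalize_uq(expression_dataset(nm$counts, nm$samples))
  expect_lt(max(abs(renorm$counts - nm$counts) / pmax(nm$counts, 1e-12)), 1e-9)
  m0 <- m; m0[, 3] <- 0
  expect_error(normalize_uq(expression_dataset(m0, samples2(6))), "s3")
  expect_error(normalize_uq(nm), "already normalized")
})

test_that("log2 ratios to the wild-type 0-h baseline follow the formula", {
  # 1 gene: WT 0-h replicates average to 50; later sample measures 200
  m <- matrix(c(40, 50, 60, 200, 0), 1,
              dimnames = list("g1", paste0("s", 1:5)))
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:5), strain = "WT",
    time_h = c(0, 0, 0, 6, 12), replicate = c(1, 2, 3, 1, 1))
  ds <- expression_dataset(m, samples, normalized = TRUE)
  r0 <- ratio_profiles(ds, pseudocount = 0)
  expect_equal(r0$log2_ratio[r0$sample_id == "s4"], 2)       # 200/50
  expect_equal(r0$log2_ratio[r0$sample_id == "s2"], 0)       # 50/50
  r1 <- ratio_profiles(ds, pseudocount = 1)
  expect_equal(r1$log2_ratio[r1$sample_id == "s5"], log2(1 / 51))
  expect_equal(unique(r0$baseline), 50)
  # the mean wild-type 0-h profile is exactly zero at pseudocount 0
  mp <- mean_profiles(r0)
  expect_equal(mp$log2_ratio[mp$strain == "WT" & mp$time_h == 0], 0)
})

test_that("missing wild-type baseline and unknown strains are rejected", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  s_no0 <- tibble::tibble(sample_id = c("s1", "s2"), strain = "WT",
                          time_h = c(6, 12), replicate = 1:2)
  expect_error(ratio_profiles(expression_dataset(m, s_no0, normalized = TRUE)),
               "0-h")
  s_bad <- tibble::tibble(sample_id = c("s1", "s2"), strain = c("WT", "mutantX"),
                          time_h = 0, replicate = 1:2)
  expect_error(expression_dataset(m, s_bad), "mutantX")
})

test_that("log2 ratio is antisymmetric at pseudocount zero", {
  set.seed(8)
  a <- runif(200, 0.1, 1000); b <- runif(200, 0.1, 1000)
  expect_equal(log2_ratio(a, b), -log2_ratio(b, a))
  expect_equal(log2_ratio(a, a), rep(0, 200))
})

test_that("expression TSV round trip preserves counts and metadata", {
  sim <- simulate_timecourse(small_config())
  d <- withr::local_tempdir()
  write_expression_tsv(sim$dataset, file.path(d, "c.tsv"), file.path(d, "s.tsv"))
  back <- read_expression_tsv(file.path(d, "c.tsv"), file.path(d, "s.tsv"))
  expect_equal(back$counts, sim$dataset$counts)
  expect_equal(as.data.frame(back$samples), as.data.frame(sim$dataset$samples))
})
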