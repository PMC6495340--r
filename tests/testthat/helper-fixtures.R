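# Shared fixtures, memoized so expensive simulations run once per session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# full default-condition analysis: simulation, normalization, ratios, DE,
# regulon labels (2000 genes, paper regulon sizes, amplitude 3, seed 42)
default_analysis <- function() {
  cached("default_analysis", {
    sim <- simulate_timecourse(cascade_config())
    ratios <- ratio_profiles(normalize_uq(sim$dataset))
    de <- de_analysis(ratios)
    labels <- suppressWarnings(assign_regulons(de))
    list(sim = sim, ratios = ratios, de = de, labels = labels)
  })
}

# amplitude-zero (null) wild-type analysis
null_analysis <- function() {
  cached("null_analysis", {
    sim <- simulate_timecourse(cascade_config(amplitude_log2 = 0, seed = 42))
    ratios <- ratio_profiles(normalize_uq(sim$dataset))
    list(sim = sim, wt = test_wt_timecourse(ratios))
  })
}

# small complete cascade config for fast end-to-end runs
small_config <- function(seed = 11) {
  cascade_config(
    n_genes = 300,
    regulon_sizes = list(shared = c(up = 20, down = 30),
                         sigJ = c(up = 40, down = 10),
                         sigC = c(up = 25, down = 15),
                         sigF = c(up = 3, down = 4)),
    seed = seed)
}

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n),
         function(i) paste0(sample(c("A", "C", "G", "T"), len, TRUE),
                            collapse = ""),
         character(1))
}

# sequences with a planted 9-mer at known positions
planted_promoters <- function(n = 20, len = 81, motif = "GGGAATACT",
                              n_planted = n, seed = 123) {
  set.seed(seed)
  seqs <- random_dna(n, len)
  pos <- rep(NA_integer_, n)
  w <- nchar(motif)
  for (i in seq_len(n_planted)) {
    p <- sample(seq_len(len - w + 1L), 1)
    substr(seqs[i], p, p + w - 1L) <- motif
    pos[i] <- p
  }
  # re-randomize any accidental extra copy of the motif elsewhere
  names(seqs) <- paste0("prom", seq_len(n))
  list(seqs = seqs, pos = pos)
}

# replicate-level ratios tibble built directly from a gene x profile spec:
# `values` is a named list gene_id -> function(strain, time, rep) -> value
make_ratios <- function(values, strains = c("WT", "dsigJ", "dsigC", "dsigF"),
                        times = c(0, 1, 6, 12, 18), reps = 3) {
  grid <- expand.grid(strain = strains, time_h = times,
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
  rows <- lapply(names(values), function(g) {
    f <- values[[g]]
    data.frame(gene_id = g,
               sample_id = paste(grid$strain, grid$time_h, grid$replicate,
                                 sep = "_"),
               strain = grid$strain, time_h = grid$time_h,
               replicate = grid$replicate,
               log2_ratio = mapply(f, grid$strain, grid$time_h,
                                   grid$replicate))
  })
  tibble::as_tibble(do.call(rbind, rows))
}
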