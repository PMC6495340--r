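#' Simulate a genome fixture with J-Boxes planted upstream of TSSs
#'
#' Lays genes out on a single contig with strand chosen at random, annotates
#' a transcription start site upstream of each translational start, and for
#' planted genes writes a J-Box into the promoter so that the first G of the
#' GGG trio sits at position -15 relative to the TSS -- placing the center of
#' the `aAtacT` hexad exactly 10 bases upstream of the +1, the consensus SigJ
#' promoter architecture. The three Gs, the conserved A (+4 from the first G)
#' and the conserved T (+8) are written verbatim; the lower-information
#' positions of `GGGaAtacT` vary around the consensus. Upstream windows of
#' non-planted genes (and all flanks) are rejection-sampled so the default
#' scanner rule matches nowhere except at planted sites.
#'
#' A fraction of consecutive same-strand genes is grouped into operons;
#' non-leader members carry no TSS (their upstream region is intragenic), so
#' the operon-leader filter can be exercised.
#'
#' @param n_genes number of genes.
#' @param planted_fraction fraction of promoter-bearing genes given a J-Box.
#' @param seed random seed.
#' @param gene_ids optional gene identifiers (length `n_genes`); defaults to
#'   `gene001`, `gene002`, ...
#' @param operon_fraction fraction of genes recruited into 2-3 gene operons.
#' @param rule the [jbox_rule()] the planted/rejected sites must respect.
#' @param consensus_fidelity probability that each variable J-Box position
#'   carries its consensus base.
#' @return object of class `genome_fixture`: `contigs` (named character),
#'   `features` (tibble: `gene_id`, `contig`, `strand`, `cds_start`,
#'   `cds_end`, `tss`, `operon_id`, `operon_rank`), `planted` (tibble:
#'   `gene_id`, `start`, `end`, `strand` -- genomic span of the 9-mer), and
#'   the generating parameters.
#' @export
simulate_genome <- function(n_genes = 40, planted_fraction = 1, seed = 1,
                            gene_ids = NULL, operon_fraction = 0,
                            rule = jbox_rule(), consensus_fidelity = 0.7) {
  if (planted_fraction < 0 || planted_fraction > 1)
    abort("`planted_fraction` must be in [0, 1].")
  if (!is.null(gene_ids)) {
    if (length(gene_ids) != n_genes)
      abort("`gene_ids` must have length `n_genes`.")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  cds_len <- 300L; igr_len <- 200L; pad <- 150L
  block <- cds_len + igr_len
  contig_len <- pad * 2L + n_genes * block
  seq_chars <- sample(bases, contig_len, replace = TRUE)

  gene_id <- gene_ids %||% sprintf("gene%03d", seq_len(n_genes))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  block_start <- pad + (seq_len(n_genes) - 1L) * block + 1L
  cds_start <- integer(n_genes); cds_end <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    if (strand[i] == "+") {
      cds_start[i] <- block_start[i] + igr_len
      cds_end[i] <- cds_start[i] + cds_len - 1L
    } else {
      cds_start[i] <- block_start[i]
      cds_end[i] <- cds_start[i] + cds_len - 1L
    }
  }

  # operon grouping: runs of consecutive same-strand genes, up to 3 members
  operon_id <- rep(NA_character_, n_genes)
  operon_rank <- rep(1L, n_genes)
  if (operon_fraction > 0 && n_genes >= 2) {
    n_ops <- 0L; i <- 1L
    while (i < n_genes) {
      if (strand[i] == strand[i + 1L] && stats::runif(1) < operon_fraction) {
        size <- min(sample(2:3, 1), n_genes - i + 1L)
        size <- sum(strand[i:(i + size - 1L)] == strand[i])  # same-strand run
        if (size >= 2) {
          n_ops <- n_ops + 1L
          members <- i:(i + size - 1L)
          if (strand[i] == "-") members <- rev(members)  # leader = 5'-most
          operon_id[members] <- sprintf("op%03d", n_ops)
          operon_rank[members] <- seq_along(members)
          i <- i + size
          next
        }
      }
      i <- i + 1L
    }
  }

  # TSS for leaders only; upstream gap from the translational start
  tss <- rep(NA_integer_, n_genes)
  leader <- operon_rank == 1L
  gap <- sample(25:60, n_genes, replace = TRUE)
  for (i in which(leader)) {
    tss[i] <- if (strand[i] == "+") cds_start[i] - gap[i] else cds_end[i] + gap[i]
  }

  planted_idx <- integer(0)
  eligible <- which(leader)
  n_plant <- round(planted_fraction * length(eligible))
  if (n_plant > 0) planted_idx <- sort(sample(eligible, n_plant))

  # draw a J-Box 9-mer: GGG + variable a, required A, variable t/a/c,
  # required T; variable positions never G (keeps the G run unique)
  draw_jbox <- function() {
    pick <- function(cons) {
      others <- setdiff(c("A", "C", "T"), cons)
      sample(c(cons, others), 1,
             prob = c(consensus_fidelity, rep((1 - consensus_fidelity) / 2, 2)))
    }
    c("G", "G", "G", pick("A"), "A", pick("T"), pick("A"), pick("C"), "T")
  }

  planted <- list()
  protected <- rep(FALSE, contig_len)  # planted-site positions, never redrawn
  for (i in planted_idx) {
    jb <- draw_jbox()
    if (strand[i] == "+") {
      gstart <- tss[i] - 15L            # first G at relative -15
      span <- gstart:(gstart + 8L)
      seq_chars[span] <- jb
    } else {
      gstart <- tss[i] + 15L            # first G (on coding strand) at -15
      span <- (gstart - 8L):gstart
      seq_chars[span] <- rev(chartr("ACGT", "TGCA", jb))
    }
    protected[span] <- TRUE
    planted[[length(planted) + 1L]] <-
      tibble(gene_id = gene_id[i], start = min(span), end = max(span),
             strand = strand[i])
  }
  planted <- if (length(planted)) bind_rows(planted) else
    tibble(gene_id = character(), start = integer(), end = integer(),
           strand = character())

  # rejection: remove spurious rule matches from every scanned window
  features <- tibble(gene_id = gene_id, contig = "contig1", strand = strand,
                     cds_start = cds_start, cds_end = cds_end, tss = tss,
                     operon_id = operon_id, operon_rank = operon_rank)
  wanted_start <- setNames(rep(NA_integer_, n_genes), gene_id)
  for (i in planted_idx)
    wanted_start[i] <- if (strand[i] == "+") tss[i] - 15L else tss[i] + 15L

  scan_windows <- function(i) {
    # genomic spans scanned for gene i: upstream-of-CDS window and, for
    # leaders, the promoter window (coding strand)
    spans <- list()
    if (strand[i] == "+") {
      spans$up <- c(max(1L, cds_start[i] - rule$window), cds_start[i] - 1L)
      if (leader[i]) spans$prom <- c(tss[i] - 60L, tss[i] + 20L)
    } else {
      spans$up <- c(cds_end[i] + 1L, min(contig_len, cds_end[i] + rule$window))
      if (leader[i]) spans$prom <- c(tss[i] - 20L, tss[i] + 60L)
    }
    spans
  }

  for (i in seq_len(n_genes)) {
    for (sp in scan_windows(i)) {
      for (attempt in 1:200) {
        win <- paste0(seq_chars[sp[1]:sp[2]], collapse = "")
        if (strand[i] == "-") win <- revcomp(win)
        hits <- scan_jbox(win, rule, seq_id = gene_id[i])
        if (nrow(hits)) {
          # map hit starts back to genomic leftmost positions
          wlen <- rule$t_offset + 1L
          gpos <- if (strand[i] == "+") sp[1] + hits$start else
            sp[2] - hits$start - wlen + 1L
          bad <- gpos != (if (strand[i] == "+") wanted_start[i] else
                            wanted_start[i] - 8L)
          bad[is.na(bad)] <- TRUE
        } else bad <- logical(0)
        if (!any(bad)) break
        for (g in gpos[bad]) {
          span <- g:(g + rule$t_offset)
          redraw <- span[!protected[span]]
          seq_chars[redraw] <- sample(bases, length(redraw), replace = TRUE)
        }
      }
    }
  }

  structure(
    list(contigs = setNames(paste0(seq_chars, collapse = ""), "contig1"),
         features = features, planted = planted,
         params = list(n_genes = n_genes, planted_fraction = planted_fraction,
                       seed = seed, operon_fraction = operon_fraction,
                       consensus_fidelity = consensus_fidelity)),
    class = "genome_fixture")
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat(sprintf("<genome_fixture> %d gene(s) on %d contig(s), %d planted J-Box(es)\n",
              nrow(x$features), length(x$contigs), nrow(x$planted)))
  invisible(x)
}

#' Write a genome fixture as FASTA + GFF3
#'
#' CDS records carry `ID`, `operon_id` and `operon_rank` attributes;
#' 1-bp `transcription_start_site` records carry `Parent`. The files are
#' byte-identical for identical fixtures.
#'
#' @param fixture a [simulate_genome()] object.
#' @param fasta_path,gff_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genome_fixture <- function(fixture, fasta_path, gff_path) {
  stopifnot(inherits(fixture, "genome_fixture"))
  dna <- Biostrings::DNAStringSet(fixture$contigs)
  Biostrings::writeXStringSet(dna, fasta_path)
  f <- fixture$features
  cds <- GenomicRanges::GRanges(
    seqnames = f$contig,
    ranges = IRanges::IRanges(f$cds_start, f$cds_end),
    strand = f$strand, type = "CDS", phase = 0L, ID = f$gene_id,
    operon_id = f$operon_id, operon_rank = f$operon_rank)
  has_tss <- !is.na(f$tss)
  tssr <- GenomicRanges::GRanges(
    seqnames = f$contig[has_tss],
    ranges = IRanges::IRanges(f$tss[has_tss], f$tss[has_tss]),
    strand = f$strand[has_tss], type = "transcription_start_site",
    ID = paste0(f$gene_id[has_tss], "_tss"),
    Parent = f$gene_id[has_tss])
  gr <- c(cds, tssr)
  gr <- gr[order(GenomicRanges::start(gr))]
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta = fasta_path, gff = gff_path))
}
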