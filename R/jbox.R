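#' Define a J-Box matching rule
#'
#' The J-Box is identified by three consecutive Gs (the extended -10 trio)
#' followed by a highly conserved A and T at fixed offsets from the first G.
#' The printed consensus `GGGaAtacT` places the conserved A at offset 4 and
#' the conserved T at offset 8 from the first G (0-based), which are the
#' defaults; any offsets can be configured.
#'
#' @param g_run required run length of Gs (default 3).
#' @param a_offset 0-based offset of the required A from the first G
#'   (default 4).
#' @param t_offset 0-based offset of the required T from the first G
#'   (default 8); must exceed `a_offset`.
#' @param window how many bases upstream of the anchor to scan in
#'   [scan_jbox_upstream()] (default 100).
#' @param strands scan the `"forward"` (coding) strand only, or `"both"`.
#' @return an object of class `jbox_rule`.
#' @export
jbox_rule <- function(g_run = 3, a_offset = 4, t_offset = 8, window = 100,
                      strands = c("forward", "both")) {
  strands <- match.arg(strands)
  if (a_offset <= g_run - 1)
    abort("`a_offset` must lie beyond the G run (> g_run - 1).")
  if (t_offset <= a_offset) abort("`t_offset` must exceed `a_offset`.")
  structure(list(g_run = g_run, a_offset = a_offset, t_offset = t_offset,
                 window = window, strands = strands),
            class = "jbox_rule")
}

#' @export
print.jbox_rule <- function(x, ...) {
  cat(sprintf("<jbox_rule> %d x G, A at +%d, T at +%d (from first G); window %d, %s strand(s)\n",
              x$g_run, x$a_offset, x$t_offset, x$window, x$strands))
  invisible(x)
}

# forward-strand scan of one character vector; returns 0-based starts
.scan_codes <- function(ch, rule) {
  wlen <- rule$t_offset + 1L
  L <- length(ch)
  m <- L - wlen + 1L
  if (m < 1L) return(integer(0))
  isG <- ch == "G"
  hit <- rep(TRUE, m)
  for (k in 0:(rule$g_run - 1L)) hit <- hit & isG[(1L + k):(m + k)]
  hit <- hit & (ch[(1L + rule$a_offset):(m + rule$a_offset)] == "A")
  hit <- hit & (ch[(1L + rule$t_offset):(m + rule$t_offset)] == "T")
  which(hit) - 1L
}

#' Scan a sequence for J-Boxes
#'
#' Reports every position satisfying the rule: `g_run` consecutive Gs with an
#' A and a T at the configured offsets from the first G (case-insensitive).
#' Overlapping matches are all reported. With `strands = "both"` the reverse
#' strand is scanned as well; reverse-strand hits are reported at the 0-based
#' position of the leftmost base of the matched region on the forward axis,
#' with `strand = "-"` and the matched substring read 5'->3' on the minus
#' strand.
#'
#' @param sequence a single DNA string.
#' @param rule a [jbox_rule()].
#' @param seq_id identifier recorded in the hit table.
#' @return tibble of class-annotated hits: `seq_id`, `start` (0-based
#'   position of the first G for forward hits; leftmost matched base for
#'   reverse hits), `strand`, `match`, `g_run`, `a_offset`, `t_offset`.
#' @export
scan_jbox <- function(sequence, rule = jbox_rule(), seq_id = "seq") {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  wlen <- rule$t_offset + 1L
  L <- length(ch)
  starts <- .scan_codes(ch, rule)
  hits <- tibble(seq_id = seq_id, start = starts, strand = "+",
                 match = vapply(starts, function(p)
                   paste0(ch[(p + 1L):(p + wlen)], collapse = ""), character(1)))
  if (rule$strands == "both") {
    rc <- strsplit(revcomp(paste0(ch, collapse = "")), "", fixed = TRUE)[[1]]
    rstarts <- .scan_codes(rc, rule)
    rhits <- tibble(seq_id = seq_id,
                    start = L - rstarts - wlen,  # leftmost forward-axis base
                    strand = "-",
                    match = vapply(rstarts, function(p)
                      paste0(rc[(p + 1L):(p + wlen)], collapse = ""), character(1)))
    hits <- bind_rows(hits, rhits) |> arrange(.data$start)
  }
  hits$g_run <- rule$g_run; hits$a_offset <- rule$a_offset
  hits$t_offset <- rule$t_offset
  hits
}

#' Scan upstream windows of annotated genes for J-Boxes
#'
#' For each gene, takes the `rule$window` bases immediately 5' of the anchor
#' (the translational start by default, mirroring genome-wide `pilB` scans;
#' alternatively the TSS) on the coding strand and scans them with
#' [scan_jbox()]. Windows truncated by a contig end are scanned as the
#' available prefix, with a warning.
#'
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @param features tibble with `gene_id`, `contig`, `strand`, and
#'   `cds_start`/`cds_end` (and `tss` when `anchor = "tss"`).
#' @param rule a [jbox_rule()].
#' @param anchor `"cds_start"` (translational start) or `"tss"`.
#' @return tibble of hits: `gene_id`, `start` (0-based within the oriented
#'   window), `strand`, `match`, plus rule fields. Genes without hits are
#'   absent.
#' @export
scan_jbox_upstream <- function(genome, features, rule = jbox_rule(),
                               anchor = c("cds_start", "tss")) {
  anchor <- match.arg(anchor)
  seqs <- .as_contig_strings(genome)
  clipped <- character(0)
  out <- purrr::pmap(features, function(...) {
    f <- list(...)
    contig <- seqs[[f$contig]]
    len <- nchar(contig)
    a <- if (anchor == "tss") f$tss else if (f$strand == "+") f$cds_start else f$cds_end
    if (f$strand == "+") {
      ws <- a - rule$window; we <- a - 1L
      if (ws < 1L) { clipped <<- c(clipped, f$gene_id); ws <- 1L }
      if (we < ws) return(NULL)
      win <- substr(contig, ws, we)
    } else {
      ws <- a + 1L; we <- a + rule$window
      if (we > len) { clipped <<- c(clipped, f$gene_id); we <- len }
      if (we < ws) return(NULL)
      win <- revcomp(substr(contig, ws, we))
    }
    h <- scan_jbox(win, rule, seq_id = f$gene_id)
    if (nrow(h)) h else NULL
  })
  if (length(clipped))
    warn(sprintf("Upstream window truncated at a contig end for %d gene(s); scanned the available prefix.",
                 length(clipped)))
  res <- bind_rows(out)
  if (!nrow(res))
    res <- tibble(seq_id = character(), start = integer(), strand = character(),
                  match = character(), g_run = integer(), a_offset = integer(),
                  t_offset = integer())
  rename(res, gene_id = "seq_id")
}
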