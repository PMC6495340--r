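#' Select operon-leader genes for promoter analysis
#'
#' Only the first gene of a transcription unit has a promoter immediately
#' upstream, so genes that are neither monocistronic nor the first member of
#' a polycistronic transcript are removed before motif work. Genes lacking
#' operon annotation are retained with a warning (their leader status cannot
#' be decided automatically).
#'
#' @param features tibble of gene features with at least `gene_id`,
#'   `operon_id`, `operon_rank` (rank 1 = leader; `NA` `operon_id` =
#'   monocistronic).
#' @return the subset of `features` eligible for promoter extraction.
#' @export
select_promoter_genes <- function(features) {
  if (!nrow(features)) return(features)
  unknown <- is.na(features$operon_rank) & is.na(features$operon_id)
  if (any(unknown))
    warn(sprintf("%d gene(s) lack operon annotation; retained as putative leaders.",
                 sum(unknown)))
  leader <- unknown | is.na(features$operon_id) | features$operon_rank == 1
  features[leader, , drop = FALSE]
}

#' Map a TSS-relative coordinate to a genomic position
#'
#' The relative coordinate system has no position 0: the transcription start
#' site is +1 and the base immediately upstream is -1.
#'
#' @param tss 1-based genomic TSS position.
#' @param strand `"+"` or `"-"`.
#' @param rel relative coordinate(s), nonzero integers.
#' @return 1-based genomic position(s).
#' @export
rel_to_genomic <- function(tss, strand, rel) {
  if (any(rel == 0)) abort("Relative coordinate 0 does not exist (+1 abuts -1).")
  step <- ifelse(rel > 0, rel - 1, rel)
  if (strand == "+") tss + step else tss - step
}

#' Extract promoter windows around annotated TSSs
#'
#' Retrieves the -60..+20 window (81 bases on the coding strand) around each
#' gene's transcription start site. On the forward strand this is the genomic
#' span `[tss - 60, tss + 20]`; on the reverse strand, the reverse complement
#' of `[tss - 20, tss + 60]`. Windows overrunning a contig end raise an error
#' unless `clip = TRUE`, in which case the available sequence is returned and
#' flagged.
#'
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences.
#' @param features tibble with `gene_id`, `contig`, `strand`, `tss`.
#' @param upstream,downstream window extent in bases (defaults 60 and 20).
#' @param clip return truncated windows instead of erroring at contig ends.
#' @return tibble: `gene_id`, `contig`, `strand`, `tss`, `start`, `end`
#'   (genomic span), `sequence` (coding strand), `tss_offset` (1-based
#'   position of the TSS base within `sequence`), `clipped`.
#' @export
extract_promoters <- function(genome, features, upstream = 60, downstream = 20,
                              clip = FALSE) {
  seqs <- .as_contig_strings(genome)
  rows <- purrr::pmap(
    features[, c("gene_id", "contig", "strand", "tss")],
    function(gene_id, contig, strand, tss) {
      if (!contig %in% names(seqs))
        abort(paste0("Contig '", contig, "' not in genome."))
      len <- nchar(seqs[[contig]])
      if (strand == "+") {
        gstart <- tss - upstream; gend <- tss + downstream
      } else {
        gstart <- tss - downstream; gend <- tss + upstream
      }
      cs <- max(1L, gstart); ce <- min(len, gend)
      clipped <- cs != gstart || ce != gend
      if (clipped && !clip)
        abort(paste0("Promoter window for '", gene_id, "' overruns contig '",
                     contig, "' (span ", gstart, "..", gend, ", length ", len,
                     "); use clip = TRUE to truncate."))
      s <- substr(seqs[[contig]], cs, ce)
      if (strand == "-") s <- revcomp(s)
      tss_off <- if (strand == "+") tss - cs + 1L else ce - tss + 1L
      tibble(gene_id = gene_id, contig = contig, strand = strand, tss = tss,
             start = cs, end = ce, sequence = s,
             tss_offset = tss_off, clipped = clipped)
    })
  bind_rows(rows)
}

# accept DNAStringSet or named character
.as_contig_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else {
    if (is.null(names(genome))) abort("Genome contigs must be named.")
    genome
  }
}

#' Reverse complement of a DNA string
#' @param s a single DNA string (IUPAC bases).
#' @return the reverse complement, preserving case.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read gene features (with TSSs and operon structure) from GFF3
#'
#' Expects CDS records carrying `ID` (gene id) plus optional `operon_id` /
#' `operon_rank` attributes, and `transcription_start_site` records whose
#' `Parent` (or `ID`) names the gene. This is the schema written by
#' [write_genome_fixture()]; GFF3 from other sources needs the same fields.
#'
#' @param path GFF3 file.
#' @return features tibble: `gene_id`, `contig`, `strand`, `cds_start`,
#'   `cds_end`, `tss`, `operon_id`, `operon_rank`.
#' @export
read_features_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  cds <- df |> filter(.data$type == "CDS")
  tssr <- df |> filter(.data$type == "transcription_start_site")
  tss_gene <- if ("Parent" %in% names(tssr)) {
    vapply(tssr$Parent, function(p) as.character(p)[1], character(1))
  } else as.character(tssr$ID)
  tss_pos <- ifelse(as.character(tssr$strand) == "+", tssr$start, tssr$end)
  tss_tbl <- tibble(gene_id = unname(tss_gene), tss = as.integer(tss_pos))
  tibble(gene_id = as.character(cds$ID),
         contig = as.character(cds$seqnames),
         strand = as.character(cds$strand),
         cds_start = as.integer(cds$start),
         cds_end = as.integer(cds$end),
         operon_id = if ("operon_id" %in% names(cds)) as.character(cds$operon_id) else NA_character_,
         operon_rank = if ("operon_rank" %in% names(cds)) as.integer(cds$operon_rank) else NA_integer_) |>
    left_join(tss_tbl, by = "gene_id")
}
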