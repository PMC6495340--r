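#' Write / read an expression dataset as TSV
#'
#' The counts file has `gene_id` plus one column per sample; the sample file
#' has `sample_id`, `strain`, `time_h`, `replicate`. Formats are stable so
#' identical datasets produce byte-identical files.
#'
#' @param dataset an [expression_dataset()].
#' @param counts_path,samples_path output paths.
#' @return invisibly, the paths.
#' @export
write_expression_tsv <- function(dataset, counts_path, samples_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tbl <- as_tibble(dataset$counts, rownames = "gene_id")
  readr::write_tsv(tbl, counts_path)
  readr::write_tsv(dataset$samples, samples_path)
  invisible(c(counts = counts_path, samples = samples_path))
}

#' @rdname write_expression_tsv
#' @param normalized flag recorded on the returned dataset.
#' @export
read_expression_tsv <- function(counts_path, samples_path, normalized = FALSE) {
  tbl <- readr::read_tsv(counts_path, show_col_types = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$gene_id
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  expression_dataset(m, samples, normalized = normalized)
}

#' Write promoter windows as FASTA
#'
#' Headers carry gene id, contig, strand and TSS.
#'
#' @param promoters tibble from [extract_promoters()].
#' @param path output FASTA path.
#' @export
write_promoter_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- sprintf("%s %s:%d(%s)", promoters$gene_id, promoters$contig,
                         promoters$tss, promoters$strand)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a motif in MEME minimal text format
#'
#' @param model a [discover_motif()] model.
#' @param path output path.
#' @param name motif name in the file.
#' @export
write_meme_minimal <- function(model, path, name = model$consensus) {
  stopifnot(inherits(model, "motif_model"))
  bg <- model$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"], bg["G"], bg["T"]),
    "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
            model$width, nrow(model$sites)),
    apply(model$pwm, 2, function(p) sprintf(" %.6f %.6f %.6f %.6f",
                                            p[1], p[2], p[3], p[4])))
  writeLines(lines, path)
  invisible(path)
}
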