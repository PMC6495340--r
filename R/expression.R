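#' Construct an expression dataset
#'
#' Bundles a gene x sample matrix of non-negative expression values with its
#' sample metadata. Columns of `counts` must correspond one-to-one (and in
#' order) with rows of `samples`.
#'
#' @param counts numeric matrix, genes in rows (unique rownames), samples in
#'   columns; all values must be `>= 0`.
#' @param samples data frame with columns `sample_id`, `strain`
#'   (`WT`/`dsigJ`/`dsigC`/`dsigF`), `time_h`, `replicate`; one row per column
#'   of `counts`, in column order.
#' @param normalized logical; has between-sample normalization been applied?
#' @param scale_factors optional numeric vector of per-sample scale factors.
#'
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(counts, samples, normalized = FALSE,
                               scale_factors = NULL) {
  counts <- as.matrix(counts)
  samples <- as_tibble(samples)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    abort("`counts` must have unique rownames (gene ids).")
  if (ncol(counts) != nrow(samples))
    abort("`samples` must have one row per column of `counts`.")
  req <- c("sample_id", "strain", "time_h", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    abort(paste0("`samples` is missing column(s): ", paste(miss, collapse = ", ")))
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), as.character(samples$sample_id)))
    abort("`counts` column names must match `samples$sample_id` in order.")
  colnames(counts) <- samples$sample_id
  bad <- setdiff(unique(samples$strain), .strains)
  if (length(bad))
    abort(paste0("Unknown strain label(s): ", paste(bad, collapse = ", "),
                 ". Expected WT, dsigJ, dsigC, dsigF."))
  if (any(counts < 0)) abort("Expression values must be non-negative.")
  structure(
    list(counts = counts, samples = samples, normalized = normalized,
         scale_factors = scale_factors),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw"))
  cat(sprintf("  strains: %s; times (h): %s; replicates: %s\n",
              paste(unique(x$samples$strain), collapse = ", "),
              paste(sort(unique(x$samples$time_h)), collapse = ", "),
              paste(sort(unique(x$samples$replicate)), collapse = ", ")))
  invisible(x)
}

#' Upper-quartile normalization
#'
#' Scales each sample so that the upper quartile of its nonzero values equals
#' the geometric mean of the per-sample upper quartiles. A monotone per-sample
#' scaling of this kind is the standard depth correction for bulk bacterial
#' RNA-seq and leaves every downstream ratio-based statistic invariant to
#' sequencing depth.
#'
#' @param dataset an [expression_dataset()]; must not already be normalized.
#' @return a normalized `expression_dataset`; per-sample scale factors are
#'   stored in `$scale_factors`.
#' @export
normalize_uq <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (isTRUE(dataset$normalized))
    abort("Dataset is already normalized.")
  m <- dataset$counts
  uq <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[x > 0]
    if (!length(x))
      abort(paste0("Sample '", colnames(m)[j], "' has no nonzero values."))
    stats::quantile(x, 0.75, names = FALSE)
  }, numeric(1))
  target <- exp(mean(log(uq)))
  fac <- target / uq
  norm <- sweep(m, 2, fac, `*`)
  expression_dataset(norm, dataset$samples, normalized = TRUE,
                     scale_factors = setNames(fac, colnames(m)))
}

#' Elementwise log2 ratio
#'
#' `log2((num + pseudocount) / (den + pseudocount))`. With `pseudocount = 0`
#' the ratio is antisymmetric: swapping numerator and denominator negates it.
#'
#' @param num,den non-negative numerics (recycled).
#' @param pseudocount value added to both numerator and denominator.
#' @export
log2_ratio <- function(num, den, pseudocount = 0) {
  log2((num + pseudocount) / (den + pseudocount))
}

#' Log2 ratio-to-baseline expression profiles
#'
#' For every gene and sample, computes
#' `log2(normalized expression / wild-type 0-h baseline)`, the baseline being
#' the mean of the wild-type 0-h biological replicates for that gene. A
#' pseudocount (default 1 normalized unit) is added to numerator and
#' denominator to handle zeros.
#'
#' @param dataset a normalized [expression_dataset()] containing wild-type
#'   0-h replicates.
#' @param pseudocount added to numerator and denominator before the log.
#' @return a tibble with one row per gene x sample:
#'   `gene_id`, `sample_id`, `strain`, `time_h`, `replicate`, `log2_ratio`,
#'   `baseline`. Use [mean_profiles()] to average replicates.
#' @export
ratio_profiles <- function(dataset, pseudocount = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!isTRUE(dataset$normalized))
    warn("Computing ratios on a dataset not flagged as normalized.")
  s <- dataset$samples
  wt0 <- which(s$strain == "WT" & s$time_h == 0)
  if (!length(wt0))
    abort("No wild-type 0-h samples present; cannot form the baseline.")
  m <- dataset$counts
  baseline <- rowMeans(m[, wt0, drop = FALSE])
  lr <- log2(sweep(m + pseudocount, 1, baseline + pseudocount, `/`))
  out <- as_tibble(lr, rownames = "gene_id")
  out <- pivot_longer(out, -"gene_id",
                      names_to = "sample_id", values_to = "log2_ratio")
  vals <- pivot_longer(as_tibble(m, rownames = "gene_id"), -"gene_id",
                       names_to = "sample_id", values_to = "value")
  out <- left_join(out, vals, by = c("gene_id", "sample_id"))
  out <- left_join(out, s, by = "sample_id")
  out$baseline <- unname(baseline[out$gene_id])
  out$pseudocount <- pseudocount
  out[, c("gene_id", "sample_id", "strain", "time_h", "replicate",
          "value", "log2_ratio", "baseline", "pseudocount")]
}

#' Replicate-averaged expression profiles
#'
#' Averages the normalized values within each strain x time point *before*
#' taking the ratio -- `log2(mean expression / wild-type 0-h baseline)` --
#' the quantity displayed in expression heat maps and used for L2-norm
#' ranking and clustering. The wild-type 0-h profile value is therefore
#' exactly 0 at pseudocount 0.
#'
#' @param ratios replicate-level tibble from [ratio_profiles()].
#' @return tibble: `gene_id`, `strain`, `time_h`, `log2_ratio`.
#' @export
mean_profiles <- function(ratios) {
  ratios |>
    group_by(.data$gene_id, .data$strain, .data$time_h) |>
    summarise(log2_ratio = log2((mean(.data$value) + .data$pseudocount[1]) /
                                  (.data$baseline[1] + .data$pseudocount[1])),
              .groups = "drop") |>
    arrange(.data$gene_id, .data$strain, .data$time_h)
}
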