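#' Simulate a qPCR Ct table with known fold changes
#'
#' Builds a Ct table in the layout used for relative quantification: two
#' technical replicates for each of three biological replicates per gene per
#' condition, with a reference gene (`rnpB`) whose Ct is constant up to
#' noise. Fold changes apply to the `"induced"` condition relative to the
#' `"control"` calibrator; with `ct_noise_sd = 0`, [ddct_fold_change()]
#' recovers `fold_truth` exactly.
#'
#' @param fold_truth named numeric vector of true fold changes (> 0) per
#'   target gene.
#' @param ct_noise_sd Gaussian noise SD added to every Ct (cycles).
#' @param seed random seed.
#' @param n_bio,n_tech biological / technical replicates (defaults 3 and 2).
#' @param reference reference gene name (default `"rnpB"`).
#' @param base_ct_target,base_ct_ref noise-free Ct of targets (control) and
#'   of the reference gene.
#' @return Ct tibble: `gene`, `condition`, `bio_rep`, `tech_rep`, `ct`.
#' @export
simulate_qpcr <- function(fold_truth, ct_noise_sd = 0, seed = 1,
                          n_bio = 3, n_tech = 2, reference = "rnpB",
                          base_ct_target = 25, base_ct_ref = 20) {
  if (is.null(names(fold_truth)) || any(!nzchar(names(fold_truth))))
    abort("`fold_truth` must be a named vector.")
  if (any(fold_truth <= 0)) abort("Fold changes must be positive.")
  set.seed(seed)
  genes <- c(names(fold_truth), reference)
  grid <- tidyr::expand_grid(gene = genes,
                             condition = c("control", "induced"),
                             bio_rep = seq_len(n_bio),
                             tech_rep = seq_len(n_tech))
  mean_ct <- function(gene, condition) {
    if (gene == reference) return(base_ct_ref)
    if (condition == "control") return(base_ct_target)
    base_ct_target - log2(fold_truth[[gene]])
  }
  grid |>
    mutate(ct = purrr::map2_dbl(.data$gene, .data$condition, mean_ct) +
             stats::rnorm(dplyr::n(), 0, ct_noise_sd))
}
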