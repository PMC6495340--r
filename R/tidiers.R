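#' Tidy a motif model into its site table
#'
#' @param x a [discover_motif()] model.
#' @param ... unused.
#' @return tibble of called sites: `seq_id`, `start` (1-based), `strand`,
#'   `posterior`.
#' @export
tidy.motif_model <- function(x, ...) x$sites

#' One-row summary of a motif model
#'
#' @param x a [discover_motif()] model.
#' @param ... unused.
#' @return tibble: `width`, `consensus`, `n_sites`, `n_sequences`,
#'   `same_orientation_fraction`, `gamma`, `llr`, `mean_ic`, `iterations`.
#' @export
glance.motif_model <- function(x, ...) {
  tibble(width = x$width, consensus = x$consensus,
         n_sites = nrow(x$sites), n_sequences = x$n_sequences,
         same_orientation_fraction = x$same_orientation_fraction,
         gamma = x$gamma, llr = x$llr,
         mean_ic = mean(apply(x$pwm, 2, info_content)),
         iterations = length(x$loglik_trace))
}

#' Tidy a consensus promoter into per-column frequencies
#'
#' @param x a [build_consensus()] object.
#' @param ... unused.
#' @return tibble with one row per alignment column: `column`, `rel`
#'   (coordinate relative to +1, no position 0), `A`, `C`, `G`, `T`,
#'   `ic` (bits), `n_obs`, `element`.
#' @export
tidy.consensus_promoter <- function(x, ...) {
  W <- ncol(x$freq)
  element <- rep(NA_character_, W)
  e <- x$elements
  element[e$EXT] <- "EXT"
  element[e$minus10] <- "minus10"
  if (!is.na(e$plus1)) element[e$plus1] <- "plus1"
  out <- as_tibble(t(x$freq))
  out$column <- seq_len(W); out$rel <- x$rel
  out$ic <- x$ic; out$n_obs <- x$n_obs; out$element <- element
  out[, c("column", "rel", "A", "C", "G", "T", "ic", "n_obs", "element")]
}

#' One-row summary of a consensus promoter
#'
#' @param x a [build_consensus()] object.
#' @param ... unused.
#' @return tibble: `n_sites`, `n_columns`, `tss_offset` (distance from the
#'   +1 to the -10 element center, `NA` if unannotated), `max_ic`.
#' @export
glance.consensus_promoter <- function(x, ...) {
  off <- tryCatch(tss_motif_offset(x), error = function(e) NA_real_)
  tibble(n_sites = x$n_sites, n_columns = ncol(x$freq),
         tss_offset = off, max_ic = max(x$ic, na.rm = TRUE))
}

#' Tidy a UPGMA tree into its merge table
#'
#' @param x an [upgma()] tree.
#' @param ... unused.
#' @return tibble with one row per merge: `merge1`, `merge2` (negative =
#'   leaf index, positive = earlier merge), `height` (UPGMA merge height,
#'   half the average pairwise distance).
#' @export
tidy.upgma_tree <- function(x, ...) {
  tibble(merge1 = x$merge[, 1], merge2 = x$merge[, 2], height = x$height)
}
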