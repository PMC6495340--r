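#' Relative quantification by the 2^-ddCt method
#'
#' Technical replicates are averaged first; then, per biological replicate,
#' `dCt = Ct(target) - Ct(reference)`; `ddCt` subtracts the mean calibrator
#' `dCt`; the fold change is `2^-ddCt`. By default the fold change is
#' computed per biological replicate and then summarised (mean, SD); set
#' `aggregate = "pooled"` to average `ddCt` across replicates before
#' exponentiation.
#'
#' @param ct tibble with columns `gene`, `condition`, `bio_rep`, `tech_rep`,
#'   `ct` (cycles, > 0).
#' @param target gene to quantify.
#' @param reference normalization gene (e.g. `rnpB`).
#' @param calibrator condition whose mean `dCt` defines fold = 1.
#' @param aggregate `"per_replicate"` (default) or `"pooled"`.
#' @return tibble: `gene`, `condition`, `fold_mean`, `fold_sd`, `n`
#'   (biological replicates). `fold_sd` is `NA` for `"pooled"`.
#' @export
ddct_fold_change <- function(ct, target, reference, calibrator,
                             aggregate = c("per_replicate", "pooled")) {
  aggregate <- match.arg(aggregate)
  req <- c("gene", "condition", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(req, names(ct))
  if (length(miss))
    abort(paste0("`ct` is missing column(s): ", paste(miss, collapse = ", ")))
  if (any(ct$ct <= 0)) abort("Ct values must be positive.")
  tech_avg <- ct |>
    filter(.data$gene %in% c(target, reference)) |>
    group_by(.data$gene, .data$condition, .data$bio_rep) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  conds <- unique(tech_avg$condition[tech_avg$gene == target])
  if (!calibrator %in% conds)
    abort(paste0("Calibrator condition '", calibrator, "' absent for target."))
  ref <- tech_avg |>
    filter(.data$gene == reference) |>
    select("condition", "bio_rep", ref_ct = "ct")
  dct <- tech_avg |>
    filter(.data$gene == target) |>
    left_join(ref, by = c("condition", "bio_rep"))
  if (anyNA(dct$ref_ct)) {
    bad <- unique(dct$condition[is.na(dct$ref_ct)])
    abort(paste0("Reference gene '", reference, "' missing for condition(s): ",
                 paste(bad, collapse = ", ")))
  }
  dct <- mutate(dct, dct = .data$ct - .data$ref_ct)
  cal_mean <- mean(dct$dct[dct$condition == calibrator])
  dct <- mutate(dct, ddct = .data$dct - cal_mean, fold = 2^(-.data$ddct))
  if (aggregate == "per_replicate") {
    dct |>
      group_by(.data$condition) |>
      summarise(gene = target, fold_mean = mean(.data$fold),
                fold_sd = stats::sd(.data$fold), n = dplyr::n(),
                .groups = "drop") |>
      select("gene", "condition", "fold_mean", "fold_sd", "n")
  } else {
    dct |>
      group_by(.data$condition) |>
      summarise(gene = target, fold_mean = 2^(-mean(.data$ddct)),
                fold_sd = NA_real_, n = dplyr::n(), .groups = "drop") |>
      select("gene", "condition", "fold_mean", "fold_sd", "n")
  }
}

#' Primer amplification efficiency from a dilution series
#'
#' Fits `Ct ~ log10(dilution)` by least squares; the efficiency is
#' `10^(-1/slope) - 1` (1.0 = perfect doubling each cycle, slope -3.3219).
#' Pairs pass the quality gate when efficiency exceeds 0.90.
#'
#' @param dilution_series tibble (or data frame) with columns
#'   `log10_dilution` and `ct`; at least 3 distinct dilution points.
#' @return tibble: `slope`, `efficiency`, `pass` (efficiency > 0.90),
#'   `r_squared`, `n`.
#' @export
primer_efficiency <- function(dilution_series) {
  d <- as_tibble(dilution_series)
  if (!all(c("log10_dilution", "ct") %in% names(d)))
    abort("Need columns `log10_dilution` and `ct`.")
  if (nrow(d) < 3) abort("Need at least 3 dilution points.")
  if (length(unique(d$log10_dilution)) < 2)
    abort("Dilution points are identical; slope is undefined.")
  fit <- stats::lm(ct ~ log10_dilution, data = d)
  slope <- unname(coef(fit)[2])
  eff <- 10^(-1 / slope) - 1
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact series fit cleanly
  tibble(slope = slope, efficiency = eff, pass = eff > 0.90,
         r_squared = r2, n = nrow(d))
}
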