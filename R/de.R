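#' Euclidean (L2) norm between two expression trajectories
#'
#' The ranking statistic for regulon assignment: the square root of the sum of
#' squared elementwise differences between a deletion strain's mean log2
#' profile and the wild type's.
#'
#' @param a,b numeric vectors of equal length (mean log2 profiles).
#' @return a single non-negative number; 0 iff the profiles are identical.
#' @export
l2_norm <- function(a, b) {
  if (length(a) != length(b))
    abort("Profiles must have equal length.")
  sqrt(sum((a - b)^2))
}

#' L2 norms of every deletion strain against the wild type
#'
#' @param profiles mean-profile tibble from [mean_profiles()] containing the
#'   wild type and at least one deletion strain on the same time grid.
#' @return tibble: `gene_id`, `strain`, `l2`.
#' @export
l2_norms <- function(profiles) {
  wt <- profiles |>
    filter(.data$strain == "WT") |>
    select("gene_id", "time_h", wt_ratio = "log2_ratio")
  profiles |>
    filter(.data$strain != "WT") |>
    inner_join(wt, by = c("gene_id", "time_h")) |>
    group_by(.data$gene_id, .data$strain) |>
    summarise(l2 = l2_norm(.data$log2_ratio, .data$wt_ratio),
              .groups = "drop")
}

# genes x samples matrix of replicate-level log2 ratios for a sample subset
.ratio_matrix <- function(ratios) {
  wide <- ratios |>
    select("gene_id", "sample_id", "log2_ratio") |>
    pivot_wider(names_from = "sample_id", values_from = "log2_ratio")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  m
}

# quadratic-in-time design columns on a scaled time axis
.time_basis <- function(time_h) {
  ts <- time_h / max(time_h)
  cbind(t1 = ts, t2 = ts^2)
}

#' Moderated F-test for wild-type time-course differential expression
#'
#' Compares, per gene, a quadratic-in-time fit of the replicate-level log2
#' ratios against a constant fit, with empirical-Bayes variance moderation
#' across genes and Benjamini-Hochberg adjustment. This is the package's
#' deterministic replacement for Bayesian time-series machinery: downstream
#' logic consumes only the flags and L2 norms, so the choice of test is
#' isolated here.
#'
#' @param ratios replicate-level tibble from [ratio_profiles()] (wild-type
#'   samples are selected internally).
#' @param fdr Benjamini-Hochberg threshold for the `wt_de` flag.
#' @return tibble: `gene_id`, `wt_stat` (moderated F), `wt_p`, `wt_q`,
#'   `wt_de`, `wt_direction` (`up`/`down`, sign of the mean post-induction
#'   ratio).
#' @export
test_wt_timecourse <- function(ratios, fdr = 0.05) {
  wt <- filter(ratios, .data$strain == "WT")
  times <- sort(unique(wt$time_h))
  if (length(times) < 2) abort("Need at least 2 time points.")
  reps <- wt |> distinct(.data$time_h, .data$sample_id) |> count(.data$time_h)
  if (any(reps$n < 2))
    abort("Need >= 2 replicates per time point for the wild-type test.")
  m <- .ratio_matrix(wt)
  meta <- wt |> distinct(.data$sample_id, .data$time_h)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  design <- cbind(intercept = 1, .time_basis(meta$time_h))
  fit <- limma::eBayes(limma::lmFit(m, design))
  tt <- limma::topTable(fit, coef = 2:3, number = Inf, sort.by = "none")
  post <- wt |>
    filter(.data$time_h > 0) |>
    group_by(.data$gene_id) |>
    summarise(post_mean = mean(.data$log2_ratio), .groups = "drop")
  tibble(gene_id = rownames(m),
         wt_stat = tt$F, wt_p = tt$P.Value,
         wt_q = p.adjust(tt$P.Value, "BH")) |>
    mutate(wt_de = .data$wt_q <= fdr) |>
    left_join(post, by = "gene_id") |>
    mutate(wt_direction = ifelse(.data$post_mean >= 0, "up", "down")) |>
    select(-"post_mean")
}

#' Moderated F-test for strain-versus-wild-type trajectory differences
#'
#' Tests, per gene, whether a deletion strain requires its own trajectory
#' (strain-specific intercept and quadratic time terms) over a curve shared
#' with the wild type, on replicate-level log2 ratios; BH-adjusted across
#' genes within the strain.
#'
#' @param ratios replicate-level tibble from [ratio_profiles()].
#' @param strain one of `dsigJ`, `dsigC`, `dsigF`.
#' @param fdr BH threshold for the difference flag.
#' @return tibble: `gene_id`, `strain`, `stat`, `p`, `q`, `diff_flag`.
#' @export
test_strain_difference <- function(ratios, strain, fdr = 0.05) {
  strain <- match.arg(strain, .mutants)
  keep <- c("WT", strain)
  sub <- filter(ratios, .data$strain %in% keep)
  t_wt <- sort(unique(sub$time_h[sub$strain == "WT"]))
  t_mu <- sort(unique(sub$time_h[sub$strain == strain]))
  if (!identical(t_wt, t_mu))
    abort(paste0("Time grids differ between WT and ", strain, "."))
  if (length(t_wt) < 2) abort("Need at least 2 time points.")
  m <- .ratio_matrix(sub)
  meta <- sub |> distinct(.data$sample_id, .data$strain, .data$time_h)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  tb <- .time_basis(meta$time_h)
  is_mut <- as.numeric(meta$strain == strain)
  design <- cbind(intercept = 1, tb,
                  mut = is_mut, mut_t1 = is_mut * tb[, 1],
                  mut_t2 = is_mut * tb[, 2])
  fit <- limma::eBayes(limma::lmFit(m, design))
  tt <- limma::topTable(fit, coef = 4:6, number = Inf, sort.by = "none")
  tibble(gene_id = rownames(m), strain = strain,
         stat = tt$F, p = tt$P.Value, q = p.adjust(tt$P.Value, "BH")) |>
    mutate(diff_flag = .data$q <= fdr)
}

#' Full differential-expression analysis across strains
#'
#' Runs the wild-type time-course test, the three strain-difference tests and
#' the L2-norm computation, and assembles one wide record per gene -- the
#' input to [assign_regulons()].
#'
#' @param ratios replicate-level tibble from [ratio_profiles()] covering all
#'   four strains.
#' @param fdr BH threshold used for all flags.
#' @return tibble with columns `gene_id`, `wt_stat`, `wt_p`, `wt_q`, `wt_de`,
#'   `wt_direction`, and for each deletion strain `X` in
#'   `dsigJ`/`dsigC`/`dsigF`: `stat_X`, `p_X`, `q_X`, `flag_X`, `l2_X`.
#' @export
de_analysis <- function(ratios, fdr = 0.05) {
  wt <- test_wt_timecourse(ratios, fdr = fdr)
  diffs <- purrr::map(.mutants, \(s) test_strain_difference(ratios, s, fdr = fdr)) |>
    bind_rows()
  l2 <- l2_norms(mean_profiles(ratios))
  wide <- diffs |>
    left_join(l2, by = c("gene_id", "strain")) |>
    pivot_wider(names_from = "strain",
                values_from = c("stat", "p", "q", "diff_flag", "l2"),
                names_glue = "{.value}_{strain}") |>
    rename(flag_dsigJ = "diff_flag_dsigJ", flag_dsigC = "diff_flag_dsigC",
           flag_dsigF = "diff_flag_dsigF")
  left_join(wt, wide, by = "gene_id")
}
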