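#' Configure the synthetic hormogonium cascade
#'
#' Defines the study conditions emulated by [simulate_timecourse()]: a
#' 4-strain (wild type plus sigJ/sigC/sigF deletions) x 5-time-point x
#' 3-replicate design with regulon sizes taken from the hormogonium GRN
#' (sigJ 389 genes, 317 up / 72 down; sigC 300, 167 up / 133 down; sigF 37,
#' 10 up / 27 down; 408 shared, 107 up / 301 down -- 601 upregulated and 533
#' downregulated genes in total), negative-binomial count noise, and the
#' ΔsigC temporal shift of part of the sigJ regulon.
#'
#' @param n_genes total genes simulated (default 2000; regulon counts are
#'   kept at their genome-scale values so category proportions are realistic).
#' @param regulon_sizes named list `shared`/`sigJ`/`sigC`/`sigF`, each
#'   `c(up = , down = )`.
#' @param times_h sampling times in hours, strictly increasing from 0.
#' @param n_replicates biological replicates per strain x time.
#' @param amplitude_log2 mean induction amplitude in log2 units (>= 0; 0
#'   gives a flat null dataset).
#' @param onset_h mean induction onset time (hours).
#' @param rate_per_h steepness of the logistic rise (per hour).
#' @param jitter_frac relative jitter applied to per-gene amplitude and onset.
#' @param shift_clusters_fraction fraction of sigJ-regulon genes whose onset
#'   is advanced in the ΔsigC background (the temporally shifted clusters).
#' @param shift_delta_h onset advance for shift-cluster genes in ΔsigC (h).
#' @param direct_loss_log2 basal expression (log2 units) lost in the strain
#'   deleted for a gene's *direct* regulator; this is what makes the direct
#'   knockout the largest departure from the wild type even when an upstream
#'   deletion also abolishes induction.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param library_size_cv coefficient of variation of per-sample depth
#'   factors.
#' @param seed random seed.
#' @return a validated object of class `cascade_config`.
#' @export
cascade_config <- function(n_genes = 2000,
                           regulon_sizes = list(
                             shared = c(up = 107, down = 301),
                             sigJ = c(up = 317, down = 72),
                             sigC = c(up = 167, down = 133),
                             sigF = c(up = 10, down = 27)),
                           times_h = c(0, 1, 6, 12, 18),
                           n_replicates = 3,
                           amplitude_log2 = 3,
                           onset_h = 5,
                           rate_per_h = 0.7,
                           jitter_frac = 0.2,
                           shift_clusters_fraction = 0.3,
                           shift_delta_h = 3,
                           direct_loss_log2 = 1,
                           nb_dispersion = 0.05,
                           library_size_cv = 0.1,
                           seed = 42) {
  cfg <- mget(names(formals()))
  if (!setequal(names(regulon_sizes), .regulons))
    abort("`regulon_sizes` must name shared, sigJ, sigC, sigF.")
  total <- sum(unlist(regulon_sizes))
  if (total > n_genes)
    abort(sprintf("Regulon sizes sum to %d > n_genes = %d.", total, n_genes))
  if (is.unsorted(times_h, strictly = TRUE) || times_h[1] != 0)
    abort("`times_h` must be strictly increasing and start at 0.")
  if (nb_dispersion < 0) abort("`nb_dispersion` must be >= 0.")
  if (amplitude_log2 < 0) abort("`amplitude_log2` must be >= 0.")
  if (shift_clusters_fraction < 0 || shift_clusters_fraction > 1)
    abort("`shift_clusters_fraction` must be in [0, 1].")
  structure(cfg, class = "cascade_config")
}

# logistic rise in log2 space
.induction <- function(t, onset, rate) 1 / (1 + exp(-rate * (t - onset)))

#' Simulate a knockout time-course RNA-seq dataset with planted cascade truth
#'
#' Generates negative-binomial counts for all four strains across the time
#' course. Wild-type DE genes follow a smooth logistic rise (or fall) in log2
#' space. Strain-specific structure encodes the regulatory hierarchy: the
#' sigJ deletion abolishes induction of sigJ-, sigC- and sigF-regulon genes;
#' each regulon's own deletion additionally removes `direct_loss_log2` of
#' basal expression; the sigC deletion advances the onset of the designated
#' shift clusters within the sigJ regulon; the sigF deletion affects only the
#' sigF regulon; shared genes respond identically in all strains.
#'
#' @param config a [cascade_config()].
#' @return list with `dataset` (an [expression_dataset()] of raw counts) and
#'   `truth` (tibble: `gene_id`, `category`, `direction`,
#'   `is_shift_cluster`, `cluster_id`, `baseline_log2`, and per-strain
#'   `amp_*`, `onset_*`, `basal_*` columns).
#' @export
simulate_timecourse <- function(config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"))
  cfg <- config
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  gene_id <- sprintf("g%04d", seq_len(ng))

  cats <- character(ng); dirs <- rep(NA_character_, ng)
  i <- 1L
  for (cat in c("sigJ", "sigC", "sigF", "shared")) {
    for (dr in c("up", "down")) {
      k <- cfg$regulon_sizes[[cat]][[dr]]
      if (k > 0) {
        cats[i:(i + k - 1L)] <- cat
        dirs[i:(i + k - 1L)] <- dr
        i <- i + k
      }
    }
  }
  if (i <= ng) cats[i:ng] <- "not_de"

  jit <- function(x, n) x * (1 + cfg$jitter_frac * stats::runif(n, -1, 1))
  amp <- ifelse(cats == "not_de", 0, jit(cfg$amplitude_log2, ng))
  onset <- jit(cfg$onset_h, ng)
  sgn <- ifelse(is.na(dirs), 1, ifelse(dirs == "up", 1, -1))
  baseline <- ifelse(!is.na(dirs) & dirs == "down",
                     stats::runif(ng, 6, 9), stats::runif(ng, 4, 7))

  is_sigJ <- cats == "sigJ"
  shift <- rep(FALSE, ng)
  jidx <- which(is_sigJ)
  n_shift <- round(cfg$shift_clusters_fraction * length(jidx))
  if (n_shift > 0) shift[sample(jidx, n_shift)] <- TRUE

  depends_on_J <- cats %in% c("sigJ", "sigC", "sigF")
  # deleting a gene's *direct* regulator perturbs basal expression against
  # the wild-type response: induced targets lose basal activation, repressed
  # targets are derepressed
  direct_basal <- -sgn * cfg$direct_loss_log2
  truth <- tibble(
    gene_id = gene_id, category = cats, direction = dirs,
    is_shift_cluster = shift, baseline_log2 = baseline,
    amp_WT = amp, onset_WT = onset,
    amp_dsigJ = ifelse(depends_on_J, 0, amp),
    onset_dsigJ = onset,
    basal_dsigJ = ifelse(cats == "sigJ", direct_basal, 0),
    amp_dsigC = ifelse(cats == "sigC", 0, amp),
    onset_dsigC = ifelse(shift, pmax(onset - cfg$shift_delta_h, 0.5), onset),
    basal_dsigC = ifelse(cats == "sigC", direct_basal, 0),
    amp_dsigF = ifelse(cats == "sigF", 0, amp),
    onset_dsigF = onset,
    basal_dsigF = ifelse(cats == "sigF", direct_basal, 0))
  truth$basal_WT <- 0
  grp <- interaction(truth$category, truth$direction, truth$is_shift_cluster,
                     drop = TRUE)
  truth$cluster_id <- ifelse(truth$category == "not_de", NA_integer_,
                             as.integer(grp))

  samples <- tidyr::expand_grid(strain = .strains, time_h = cfg$times_h,
                                replicate = seq_len(cfg$n_replicates)) |>
    mutate(sample_id = paste(.data$strain, .data$time_h, .data$replicate,
                             sep = "_")) |>
    select("sample_id", "strain", "time_h", "replicate")

  ns <- nrow(samples)
  sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
  depth <- stats::rlnorm(ns, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  counts <- matrix(0L, ng, ns, dimnames = list(gene_id, samples$sample_id))
  for (j in seq_len(ns)) {
    st <- samples$strain[j]; t <- samples$time_h[j]
    a <- truth[[paste0("amp_", st)]]
    o <- truth[[paste0("onset_", st)]]
    b <- truth[[paste0("basal_", st)]]
    log2mu <- baseline + b + sgn * a * .induction(t, o, cfg$rate_per_h)
    mu <- 2^log2mu * depth[j]
    counts[, j] <- if (cfg$nb_dispersion > 0) {
      stats::rnbinom(ng, mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      stats::rpois(ng, mu)
    }
  }
  list(dataset = expression_dataset(counts, samples),
       truth = truth)
}
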