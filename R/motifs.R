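.base_levels <- c("A", "C", "G", "T")

# encode a DNA string as integer codes 1..4 (NA for anything else)
.encode <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], .base_levels)
}
# complement in code space (A<->T, C<->G); NA-safe
.comp_codes <- function(codes) 5L - codes

#' Per-column information content of a base-frequency vector
#'
#' `IC = 2 + sum(p * log2(p))` bits (no small-sample correction): 2 bits for
#' an invariant column, 0 for a uniform one.
#'
#' @param p numeric vector of base frequencies summing to 1 (zeros allowed).
#' @return information content in bits.
#' @export
info_content <- function(p) {
  p <- p[p > 0]
  2 + sum(p * log2(p))
}

# log-likelihood-ratio scores of every window of width w against pwm/bg.
# codes: integer codes of the sequence; lp: 4 x w matrix log(pwm/bg).
# NA codes contribute 0 (background).
.window_scores <- function(codes, lp) {
  L <- length(codes); w <- ncol(lp)
  m <- L - w + 1L
  if (m < 1L) return(numeric(0))
  sc <- numeric(m)
  for (k in seq_len(w)) {
    v <- lp[codes[k:(k + m - 1L)], k]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc
}

#' Discover a motif with a ZOOPS EM algorithm
#'
#' Fits a zero-or-one-occurrence-per-sequence (ZOOPS) motif model by
#' expectation-maximization, seeding from the w-mers present in the data and
#' keeping the seed whose one-step model attains the highest likelihood. Both
#' strands are searched by default. A sequence's site is called when its
#' posterior probability of containing the motif is at least 0.5. Following
#' the reporting rule for cluster promoter sets, a model is returned only
#' when at least `min_orientation_frac` of the sequences carry a called site
#' in the same orientation; otherwise `NULL`.
#'
#' @param seqs character vector (or `DNAStringSet`) of sequences, named.
#' @param width motif width in bases (default 9, the J-Box width).
#' @param min_orientation_frac same-orientation reporting gate (default 0.5).
#' @param pseudocount added to each base count in the M-step (default 0.1).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 200).
#' @param strands search `"both"` strands or `"forward"` only.
#' @param max_seeds cap on the number of starting w-mers (deterministically
#'   thinned when exceeded).
#' @param gamma_init initial prior probability that a sequence has a site.
#' @return an object of class `motif_model` (fields: `width`, `pwm`,
#'   `background`, `gamma`, `sites` -- a tibble with 1-based `start`,
#'   `strand`, `posterior` -- `same_orientation_fraction`, `llr`,
#'   `consensus`, `loglik_trace`), or `NULL` if the orientation gate fails.
#' @export
discover_motif <- function(seqs, width = 9, min_orientation_frac = 0.5,
                           pseudocount = 0.1, tol = 1e-6, max_iter = 200,
                           strands = c("both", "forward"), max_seeds = 1000,
                           gamma_init = 0.5) {
  strands <- match.arg(strands)
  if (inherits(seqs, "DNAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (n < 5) abort("Motif discovery needs at least 5 sequences.")
  lens <- nchar(seqs)
  if (width > min(lens))
    abort("Motif width exceeds the shortest sequence length.")
  codes <- lapply(seqs, .encode)
  rcodes <- lapply(codes, function(cc) rev(.comp_codes(cc)))

  # fixed 0-order background from the pooled input
  all_codes <- unlist(codes)
  bg <- (tabulate(all_codes, 4) + 1) / (sum(!is.na(all_codes)) + 4)
  bg <- bg / sum(bg)
  bg_loglik <- sum(log(bg)[all_codes[!is.na(all_codes)]])

  # one E+M sweep; returns updated model and the ZOOPS log likelihood of the
  # *current* parameters (computed during the E-step)
  em_step <- function(pwm, gamma) {
    lp <- log(pwm / bg)
    counts <- matrix(pseudocount, 4, width)
    Qs <- numeric(n); ll <- 0
    site_pos <- integer(n); site_strand <- character(n); site_z <- numeric(n)
    for (i in seq_len(n)) {
      fw <- .window_scores(codes[[i]], lp)
      m <- length(fw)
      if (strands == "both") {
        rv <- .window_scores(rcodes[[i]], lp)
        lrs <- c(fw, rv); cand <- 2L * m
      } else {
        lrs <- fw; cand <- m
      }
      lr <- exp(lrs)
      denom <- (1 - gamma) + (gamma / cand) * sum(lr)
      z <- (gamma / cand) * lr / denom
      ll <- ll + log(denom)
      Qs[i] <- sum(z)
      best <- which.max(z)
      if (best <= m) {
        site_pos[i] <- best; site_strand[i] <- "+"
      } else {
        # position in the reverse-complemented sequence -> leftmost forward pos
        p_rc <- best - m
        site_pos[i] <- lens[i] - width + 2L - p_rc
        site_strand[i] <- "-"
      }
      site_z[i] <- z[best]
      # M-step accumulation
      for (k in seq_len(width)) {
        b <- codes[[i]][k:(k + m - 1L)]
        ok <- !is.na(b)
        if (any(ok)) {
          w_add <- z[seq_len(m)][ok]
          counts[, k] <- counts[, k] +
            vapply(1:4, function(x) sum(w_add[b[ok] == x]), numeric(1))
        }
        if (strands == "both") {
          br <- rcodes[[i]][k:(k + m - 1L)]
          okr <- !is.na(br)
          if (any(okr)) {
            w_add <- z[m + seq_len(m)][okr]
            counts[, k] <- counts[, k] +
              vapply(1:4, function(x) sum(w_add[br[okr] == x]), numeric(1))
          }
        }
      }
    }
    # add the fixed background log likelihood so ll is a true log likelihood
    pwm_new <- sweep(counts, 2, colSums(counts), `/`)
    gamma_new <- mean(Qs)
    list(pwm = pwm_new, gamma = gamma_new, loglik = ll + bg_loglik, zoops_ll = ll,
         Q = Qs, site_pos = site_pos, site_strand = site_strand, site_z = site_z)
  }

  seed_pwm <- function(wmer_codes) {
    pwm <- matrix((1 - 0.5) / 3, 4, width)
    for (k in seq_len(width)) pwm[wmer_codes[k], k] <- 0.5
    pwm
  }

  # exhaustive (capped) seeding from forward w-mers present in the data
  wmers <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < width) return(character(0))
    vapply(seq_len(L - width + 1L), function(j) substr(s, j, j + width - 1L),
           character(1))
  }), use.names = FALSE)
  wmers <- toupper(wmers)
  wmers <- wmers[!grepl("[^ACGT]", wmers)]
  if (!length(wmers)) abort("No clean w-mers available for seeding.")
  # recurrent w-mers first (a genuine motif repeats across sequences), then
  # first-occurrence order; deterministic
  counts <- table(factor(wmers, levels = unique(wmers)))
  wmers <- names(counts)[order(-as.integer(counts), seq_along(counts))]
  if (length(wmers) > max_seeds) wmers <- wmers[seq_len(max_seeds)]

  # likelihood-only scorer (cheap E-pass, no count accumulation)
  em_loglik <- function(pwm, gamma) {
    lp <- log(pwm / bg)
    ll <- 0
    for (i in seq_len(n)) {
      fw <- .window_scores(codes[[i]], lp)
      m <- length(fw)
      if (strands == "both") {
        lrs <- c(fw, .window_scores(rcodes[[i]], lp)); cand <- 2L * m
      } else {
        lrs <- fw; cand <- m
      }
      ll <- ll + log((1 - gamma) + (gamma / cand) * sum(exp(lrs)))
    }
    ll + bg_loglik
  }

  seed_ll <- vapply(wmers, function(wm) em_loglik(seed_pwm(.encode(wm)), gamma_init),
                    numeric(1))
  top <- wmers[order(seed_ll, decreasing = TRUE)[seq_len(min(5L, length(wmers)))]]

  run_em <- function(pwm, gamma) {
    trace <- numeric(0); prev <- -Inf; st <- NULL
    for (it in seq_len(max_iter)) {
      st <- em_step(pwm, gamma)
      trace <- c(trace, st$loglik)
      pwm <- st$pwm; gamma <- st$gamma
      if (is.finite(prev) && abs(st$loglik - prev) <= tol * abs(prev)) break
      prev <- st$loglik
    }
    list(pwm = pwm, gamma = gamma, trace = trace, st = st)
  }

  best <- NULL
  for (wm in top) {
    fit <- run_em(seed_pwm(.encode(wm)), gamma_init)
    if (isTRUE(getOption("jboxr.debug_em")))
      message(sprintf("seed %s -> ll %.3f", wm, utils::tail(fit$trace, 1)))
    if (is.null(best) || utils::tail(fit$trace, 1) > utils::tail(best$trace, 1))
      best <- fit
  }
  pwm <- best$pwm; gamma <- best$gamma; trace <- best$trace; st <- best$st
  rownames(pwm) <- .base_levels

  called <- st$Q >= 0.5
  sites <- tibble(seq_id = names(seqs)[called],
                  start = st$site_pos[called],
                  strand = st$site_strand[called],
                  posterior = st$Q[called])
  # the both-strand ZOOPS likelihood is symmetric under reverse
  # complementation of the model; canonicalize to the majority orientation
  if (sum(sites$strand == "-") > sum(sites$strand == "+")) {
    pwm <- pwm[4:1, ncol(pwm):1, drop = FALSE]
    rownames(pwm) <- .base_levels
    sites$strand <- ifelse(sites$strand == "-", "+", "-")
  }
  frac <- max(sum(sites$strand == "+"), sum(sites$strand == "-")) / n
  model <- structure(
    list(width = width, pwm = pwm, background = setNames(bg, .base_levels),
         gamma = gamma, sites = sites, same_orientation_fraction = frac,
         llr = utils::tail(trace, 1) - bg_loglik,
         consensus = paste0(.base_levels[apply(pwm, 2, which.max)], collapse = ""),
         loglik_trace = trace, n_sequences = n),
    class = "motif_model")
  if (frac < min_orientation_frac) return(NULL)
  model
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> width %d, consensus %s\n", x$width, x$consensus))
  cat(sprintf("  %d/%d sites called, same-orientation fraction %.2f, LLR %.2f\n",
              nrow(x$sites), x$n_sequences, x$same_orientation_fraction, x$llr))
  invisible(x)
}

#' Build a GGG-anchored consensus promoter
#'
#' Aligns motif sites on the first G of the conserved G-run (the extended -10
#' trio), stacks the full-length source sequences in that register, and
#' computes per-column base frequencies and information content. Promoter
#' elements are annotated from the anchor: `EXT` = the G-run, `minus10` = the
#' six bases immediately downstream (the `aAtacT` hexad of the J-Box), and
#' `plus1` = the TSS column derived from each sequence's known TSS position.
#'
#' @param seqs named character vector of promoter sequences (coding strand).
#' @param site_start 1-based start of each sequence's motif site (parallel to
#'   `seqs`), e.g. the `start` column of a [discover_motif()] model's sites.
#' @param width motif width used for the anchor search (default 9).
#' @param tss_pos 1-based position of the TSS (+1) base within each sequence
#'   (scalar or vector; 61 for standard -60..+20 windows).
#' @param g_run length of the anchoring G-run (default 3).
#' @return an object of class `consensus_promoter`: `freq` (4 x W), `ic`,
#'   `n_obs`, `rel` (coordinates relative to +1, no position 0), `elements`,
#'   `aligned` (character matrix), `n_sites`.
#' @export
build_consensus <- function(seqs, site_start, width = 9, tss_pos = 61,
                            g_run = 3) {
  n <- length(seqs)
  stopifnot(length(site_start) == n)
  tss_pos <- rep_len(tss_pos, n)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  run <- strrep("G", g_run)
  anchor <- integer(n)
  for (i in seq_len(n)) {
    wmer <- toupper(substr(seqs[i], site_start[i], site_start[i] + width - 1L))
    off <- regexpr(run, wmer, fixed = TRUE)
    if (off < 0)
      abort(paste0("Site in '", names(seqs)[i], "' lacks the ", run, " anchor."))
    anchor[i] <- site_start[i] + as.integer(off) - 1L
  }
  lens <- nchar(seqs)
  rlo <- min(1L - anchor); rhi <- max(lens - anchor)
  W <- rhi - rlo + 1L
  aligned <- matrix(NA_character_, n, W,
                    dimnames = list(names(seqs), NULL))
  for (i in seq_len(n)) {
    cols <- (1L - anchor[i]):(lens[i] - anchor[i]) - rlo + 1L
    aligned[i, cols] <- strsplit(toupper(seqs[i]), "", fixed = TRUE)[[1]]
  }
  freq <- matrix(0, 4, W, dimnames = list(.base_levels, NULL))
  n_obs <- integer(W)
  for (j in seq_len(W)) {
    col <- aligned[, j]
    col <- col[col %in% .base_levels]
    n_obs[j] <- length(col)
    if (length(col)) freq[, j] <- tabulate(match(col, .base_levels), 4) / length(col)
  }
  ic <- apply(freq, 2, function(p) if (sum(p) > 0) info_content(p) else NA_real_)
  a_col <- 1L - rlo  # column of the anchor (first G, r = 0)
  r_tss <- tss_pos - anchor  # anchor-relative TSS offset per site
  r1 <- sort(unique(r_tss))
  if (length(r1) > 1) {
    warn("TSS column differs between sites; using the most frequent one.")
    r1 <- as.integer(names(sort(table(r_tss), decreasing = TRUE))[1])
  }
  plus1 <- a_col + r1
  elements <- list(EXT = a_col:(a_col + g_run - 1L),
                   minus10 = (a_col + g_run):(a_col + g_run + 5L),
                   plus1 = if (plus1 >= 1 && plus1 <= W) plus1 else NA_integer_)
  # relative coordinates (no position 0): +1 at the TSS column
  dcol <- seq_len(W) - plus1
  rel <- ifelse(dcol >= 0, dcol + 1L, dcol)
  structure(
    list(freq = freq, ic = ic, n_obs = n_obs, rel = rel,
         elements = elements, aligned = aligned, n_sites = n,
         anchor_col = a_col),
    class = "consensus_promoter")
}

#' @export
print.consensus_promoter <- function(x, ...) {
  cat(sprintf("<consensus_promoter> %d sites, %d columns\n",
              x$n_sites, ncol(x$freq)))
  cons <- .base_levels[apply(x$freq, 2, which.max)]
  e <- x$elements
  cat("  EXT/-10 consensus: ",
      paste0(cons[c(e$EXT, e$minus10)], collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Distance from the TSS to the center of the -10 element
#'
#' Computes the number of bases between the +1 position and the central
#' position of the `aAtacT` hexad (the midpoint of its 6-base span, rounded
#' toward the element's 5' side), in the no-position-zero promoter coordinate
#' system. For the consensus SigJ promoter this distance is 10 bp.
#'
#' @param consensus a [build_consensus()] object with `plus1` and `minus10`
#'   elements annotated.
#' @return distance in bases (positive when the element center lies upstream
#'   of the TSS).
#' @export
tss_motif_offset <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_promoter"))
  e <- consensus$elements
  if (is.null(e$minus10) || is.null(e$plus1) || is.na(e$plus1))
    abort("Consensus must have minus10 and plus1 elements annotated.")
  center <- e$minus10[3]  # midpoint of 6 columns, rounded to the 5' side
  as.integer(abs(e$plus1 - center))
}
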