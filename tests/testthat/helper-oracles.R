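# Independent brute-force oracles used to cross-check package algorithms.
# These deliberately share no code with the implementations.

# naive O(n^3) UPGMA: track group members, merge the closest average-linkage
# pair, record the merge distance as the cophenetic distance of all
# cross-group leaf pairs
upgma_oracle_cophenetic <- function(d) {
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, n)
  dd <- d
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    best <- c(NA, NA); bestv <- Inf
    for (a in idx) for (b in idx) if (a < b && dd[a, b] < bestv) {
      bestv <- dd[a, b]; best <- c(a, b)
    }
    a <- best[1]; b <- best[2]
    for (i in groups[[a]]) for (j in groups[[b]]) {
      coph[i, j] <- bestv; coph[j, i] <- bestv
    }
    ga <- groups[[a]]; gb <- groups[[b]]
    # unweighted average linkage: size-weighted Lance-Williams update
    for (k in idx) if (k != a && k != b) {
      dd[a, k] <- dd[k, a] <-
        (length(ga) * dd[a, k] + length(gb) * dd[b, k]) /
        (length(ga) + length(gb))
    }
    groups[[a]] <- c(ga, gb)
    active[b] <- FALSE
  }
  coph
}

# regex oracle: overlapping forward-strand matches of a J-Box rule
jbox_regex_oracle <- function(s, rule) {
  tmpl <- rep(".", rule$t_offset + 1)
  tmpl[seq_len(rule$g_run)] <- "G"
  tmpl[rule$a_offset + 1] <- "A"
  tmpl[rule$t_offset + 1] <- "T"
  pat <- paste0("(?=", paste0(tmpl, collapse = ""), ")")
  m <- gregexpr(pat, toupper(s), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}
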