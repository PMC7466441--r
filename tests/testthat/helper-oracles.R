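# Independent brute-force oracles used by the unit and acceptance tests.
# They deliberately share no code with the package internals (own reverse
# complement, substring scans, explicit likelihood loops).

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

oracle_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# 0-based start positions of target 21-mers whose longest exact match
# against the panel (either strand) is >= 20 nt, by exhaustive substring
# search. N-containing windows are never flagged (never enumerated).
oracle_flagged_positions <- function(target_seq, panel_seqs) {
  texts <- c(panel_seqs, vapply(panel_seqs, oracle_revcomp, character(1)))
  L <- nchar(target_seq)
  if (L < 21L) return(integer(0))
  flagged <- integer(0)
  for (i in seq_len(L - 20L)) {            # 1-based window start
    w <- substr(target_seq, i, i + 20L)
    if (grepl("N", w, fixed = TRUE)) next
    hit <- any(grepl(w, texts, fixed = TRUE)) ||
      any(grepl(substr(w, 1L, 20L), texts, fixed = TRUE)) ||
      any(grepl(substr(w, 2L, 21L), texts, fixed = TRUE))
    if (hit) flagged <- c(flagged, i - 1L)
  }
  flagged
}

grepl_fixed_any <- function(patterns, texts) {
  vapply(patterns, function(p) any(grepl(p, texts, fixed = TRUE)), logical(1),
         USE.NAMES = FALSE)
}

# Set of covered 0-based positions of an interval data frame.
oracle_positions <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(integer(0))
  sort(unique(unlist(Map(function(s, e) seq.int(s, e - 1L), iv$start, iv$end))))
}

# Explicit Cox partial log-likelihood for a single binary covariate,
# written as direct loops over the definition (Efron or Breslow).
oracle_cox_loglik <- function(beta, x, time, event, ties = "efron") {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    R <- which(time >= t)
    D <- which(time == t & event == 1)
    d <- length(D)
    ll <- ll + sum(eta[D])
    if (ties == "breslow") {
      ll <- ll - d * log(sum(w[R]))
    } else {
      for (l in seq_len(d) - 1L) {
        ll <- ll - log(sum(w[R]) - (l / d) * sum(w[D]))
      }
    }
  }
  ll
}

# One-dimensional brute-force maximizer of the explicit partial likelihood.
oracle_cox_beta <- function(x, time, event, ties = "efron",
                            lower = -8, upper = 8) {
  stats::optimize(function(b) oracle_cox_loglik(b, x, time, event, ties),
                  interval = c(lower, upper), maximum = TRUE,
                  tol = 1e-9)$maximum
}
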