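# Long-dsRNA candidate design inside the longest species-specific region.
# Each candidate window is scored by the fraction of its 19-mer siRNA
# windows that pass a Reynolds-style rationality rubric (threshold 6 of a
# maximum +10): rational siRNA design favours moderate GC, A/U-rich 3' ends
# of the sense strand, particular end/center bases, and no internal
# inverted repeat that could fold the guide into a hairpin.

#' Specific regions of a target given an exclusion mask
#'
#' The species-specific regions are simply the complement of the excluded
#' (off-target or unverifiable) regions within the transcript.
#'
#' @param mask Interval data frame of excluded regions.
#' @param target_length Transcript length.
#' @return Normalized interval data frame of specific regions.
#' @export
specific_regions <- function(mask, target_length) {
  complement_intervals(mask, target_length)
}

#' Longest specific region
#'
#' Returns the region maximizing `end - start`; ties are broken by the
#' smallest start so the choice is deterministic.
#'
#' @param regions Interval data frame (normalized).
#' @return One-row data frame with `start` and `end`.
#' @export
longest_specific_region <- function(regions) {
  iv <- as_interval_df(regions)
  if (nrow(iv) == 0L) stop("no specific region available")
  len <- iv$end - iv$start
  best <- which(len == max(len))
  best <- best[which.min(iv$start[best])]
  iv[best, , drop = FALSE]
}

# Rubric weights; every component of the score is adjustable but the
# defaults below are the package's documented standard.
sirna_rubric_defaults <- function() {
  list(gc_min = 0.30, gc_max = 0.52, stem = 5L, threshold = 6L)
}

#' Score a single 19-mer siRNA sense strand
#'
#' The integer score (range −2..+10) sums: +1 if GC fraction lies in
#' `[gc_min, gc_max]`; +1 per A/T at sense positions 15–19 (1-based); +1 for
#' A at 19; +1 for A at 3; +1 for T at 10; −1 for G or C at 19; −1 for G at
#' 13; +1 if the 19-mer contains no perfect inverted repeat with stem ≥
#' `stem` (no `i < j`, `j ≥ i + stem`, with the stem at `i` equal to the
#' reverse complement of the stem at `j`). `efficient` means
#' `score ≥ threshold`.
#'
#' @param sense19 A 19-nt sense-strand sequence (no N; U allowed, mapped to T).
#' @param threshold Efficiency threshold (default 6).
#' @param gc_min,gc_max GC-content window rewarded by the rubric.
#' @param stem Minimum inverted-repeat stem length penalized.
#' @return List with `score` (integer) and `efficient` (logical).
#' @examples
#' score_sirna(strrep("T", 19))$score  # 7
#' @export
score_sirna <- function(sense19, threshold = 6L, gc_min = 0.30, gc_max = 0.52,
                        stem = 5L) {
  seq <- normalize_seq(sense19, id = "<sirna>")
  if (nchar(seq) != 19L) stop("siRNA sense strand must be exactly 19 nt")
  if (grepl("N", seq, fixed = TRUE)) stop("siRNA sense strand must not contain N")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  gc <- mean(ch %in% c("G", "C"))
  score <- 0L
  if (gc >= gc_min && gc <= gc_max) score <- score + 1L
  score <- score + sum(ch[15:19] %in% c("A", "T"))
  if (ch[19L] == "A") score <- score + 1L
  if (ch[3L] == "A") score <- score + 1L
  if (ch[10L] == "T") score <- score + 1L
  if (ch[19L] %in% c("G", "C")) score <- score - 1L
  if (ch[13L] == "G") score <- score - 1L
  if (!has_inverted_repeat(seq, stem = stem)) score <- score + 1L
  list(score = as.integer(score), efficient = score >= threshold)
}

# TRUE iff some stem at i equals the revcomp of a stem at j >= i + stem.
has_inverted_repeat <- function(seq, stem = 5L) {
  L <- nchar(seq)
  if (L < 2L * stem) return(FALSE)
  starts <- seq_len(L - stem + 1L)
  stems <- substring(seq, starts, starts + stem - 1L)
  rc <- revcomp(stems)
  for (i in seq_along(starts)) {
    j <- which(starts >= starts[i] + stem)
    if (length(j) && any(stems[j] == rc[i])) return(TRUE)
  }
  FALSE
}

# Vectorized rubric over all 19-mer windows of a sequence. Windows
# containing N get NA. Used by design_candidates; kept separate so tests
# can cross-check it against scalar score_sirna.
sirna_profile <- function(seq, threshold = 6L, gc_min = 0.30, gc_max = 0.52,
                          stem = 5L) {
  L <- nchar(seq)
  if (L < 19L) {
    return(data.frame(position = integer(0), score = integer(0),
                      efficient = logical(0)))
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  is_gc <- as.integer(ch %in% c("G", "C"))
  is_at <- as.integer(ch %in% c("A", "T"))
  cgc <- c(0L, cumsum(is_gc))
  cat_ <- c(0L, cumsum(is_at))
  p <- seq_len(L - 18L)                    # 1-based window starts
  gc_frac <- (cgc[p + 19L] - cgc[p]) / 19
  at_tail <- cat_[p + 19L] - cat_[p + 14L] # positions 15..19 of each window
  score <- as.integer(gc_frac >= gc_min & gc_frac <= gc_max) +
    at_tail +
    as.integer(ch[p + 18L] == "A") +
    as.integer(ch[p + 2L] == "A") +
    as.integer(ch[p + 9L] == "T") -
    as.integer(ch[p + 18L] %in% c("G", "C")) -
    as.integer(ch[p + 12L] == "G")
  windows <- substring(seq, p, p + 18L)
  no_rep <- !vapply(windows, has_inverted_repeat, logical(1), stem = stem,
                    USE.NAMES = FALSE)
  score <- score + as.integer(no_rep)
  has_n <- grepl("N", windows, fixed = TRUE)
  score[has_n] <- NA_integer_
  data.frame(position = p - 1L, score = score,
             efficient = !is.na(score) & score >= threshold)
}

#' Design ranked long-dsRNA candidates within a specific region
#'
#' Enumerates candidate windows of lengths `min_len`, `min_len + step`, ...,
#' `max_len`, with starts advancing by `step`, wholly inside `region`; when
#' the region itself is no longer than `max_len` the full region is also
#' evaluated. Every candidate is scored by the fraction of its 19-mer siRNA
#' windows (advancing by 1 nt) that pass the rubric of [score_sirna()].
#' Candidates are ranked by `efficient_fraction` (descending), then GC
#' fraction closest to 0.45, then smallest start, then smallest end.
#'
#' @param target A [transcript_record].
#' @param region One-row interval data frame (0-based half-open) inside the
#'   target, normally from [longest_specific_region()].
#' @param min_len,max_len Candidate length bounds (defaults 350 and 500 nt,
#'   bracketing typical long-dsRNA constructs).
#' @param step Start/length increment in nt (default 10).
#' @param top_n Number of candidates to return (default 5).
#' @param threshold siRNA efficiency threshold passed to the rubric.
#' @return Data frame of up to `top_n` candidates with columns `target_id`,
#'   `start`, `end`, `length`, `seq`, `n_sirna`, `n_efficient`,
#'   `efficient_fraction`, `gc_fraction`, `rank`.
#' @export
design_candidates <- function(target, region, min_len = 350L, max_len = 500L,
                              step = 10L, top_n = 5L, threshold = 6L) {
  stopifnot(inherits(target, "transcript_record"))
  region <- as_interval_df(region)
  stopifnot(nrow(region) == 1L)
  r0 <- region$start[1L]; r1 <- region$end[1L]
  L <- nchar(target$seq)
  if (r0 < 0L || r1 > L) stop("region outside target")
  if (min_len > max_len) stop("min_len must be <= max_len")
  rlen <- r1 - r0
  if (rlen < min_len) {
    stop("region shorter than minimum dsRNA length (override with --min-len)")
  }
  region_seq <- substr(target$seq, r0 + 1L, r1)
  prof <- sirna_profile(region_seq, threshold = threshold)
  ok <- !is.na(prof$score)
  cum_eval <- c(0L, cumsum(as.integer(ok)))
  cum_eff <- c(0L, cumsum(as.integer(prof$efficient)))
  ch <- strsplit(region_seq, "", fixed = TRUE)[[1L]]
  cum_gc <- c(0L, cumsum(as.integer(ch %in% c("G", "C"))))

  lens <- seq(as.integer(min_len), as.integer(max_len), by = as.integer(step))
  lens <- lens[lens <= rlen]
  wins <- do.call(rbind, lapply(lens, function(l) {
    s <- seq(0L, rlen - l, by = as.integer(step))
    data.frame(s = s, l = l)
  }))
  if (rlen <= max_len && !any(wins$s == 0L & wins$l == rlen)) {
    wins <- rbind(wins, data.frame(s = 0L, l = rlen))
  }
  # siRNA windows with sense start in [s, s + l - 19] (relative, 0-based);
  # profile row for position q is q + 1, prefix sums carry a leading 0
  n_sirna <- cum_eval[wins$s + wins$l - 17L] - cum_eval[wins$s + 1L]
  n_eff <- cum_eff[wins$s + wins$l - 17L] - cum_eff[wins$s + 1L]
  eff_frac <- ifelse(n_sirna > 0L, n_eff / n_sirna, 0)
  gc_frac <- (cum_gc[wins$s + wins$l + 1L] - cum_gc[wins$s + 1L]) / wins$l
  ord <- order(-eff_frac, abs(gc_frac - 0.45), wins$s, wins$s + wins$l)
  keep <- ord[seq_len(min(top_n, length(ord)))]
  out <- data.frame(
    target_id = target$id,
    start = r0 + wins$s[keep],
    end = r0 + wins$s[keep] + wins$l[keep],
    length = wins$l[keep],
    seq = substring(region_seq, wins$s[keep] + 1L, wins$s[keep] + wins$l[keep]),
    n_sirna = n_sirna[keep],
    n_efficient = n_eff[keep],
    efficient_fraction = eff_frac[keep],
    gc_fraction = gc_frac[keep],
    rank = seq_along(keep))
  rownames(out) <- NULL
  out
}

#' End-to-end dsRNA design pipeline
#'
#' Builds the off-target index from the panel, screens the target, masks
#' excluded and N-containing windows, selects the longest specific region
#' and designs ranked candidates inside it. With `screen = FALSE` the whole
#' target is treated as one specific region (the mode used for non-specific
#' control molecules such as dsGFP/dsEGFP).
#'
#' @param target A [transcript_record].
#' @param panel List of non-target [transcript_record]s (ignored when
#'   `screen = FALSE`).
#' @param screen Perform the off-target screen (default `TRUE`).
#' @param ... Passed to [design_candidates()].
#' @return List with `hits`, `mask`, `regions`, `region` (the selected one)
#'   and `candidates`.
#' @export
design_dsrna <- function(target, panel = list(), screen = TRUE, ...) {
  L <- nchar(target$seq)
  if (isTRUE(screen)) {
    index <- build_offtarget_index(panel)
    hits <- screen_transcript(target, index)
    mask <- exclusion_mask(hits, L, target = target)
  } else {
    hits <- data.frame(target_pos = integer(0), kmer = character(0),
                       match_class = integer(0))
    mask <- exclusion_mask(hits, L, target = target)  # still mask N windows
  }
  regions <- specific_regions(mask, L)
  region <- longest_specific_region(regions)
  cands <- design_candidates(target, region, ...)
  list(hits = hits, mask = mask, regions = regions, region = region,
       candidates = cands)
}
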