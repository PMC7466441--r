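# Off-target specificity screen: every 21-mer of the target is flagged if a
# perfect, ungapped 20- or 21-nt match exists anywhere in the non-target
# panel, on either strand. Within a 21-nt query any 20-nt exact match is one
# of the two terminal 20-mers, so the screen reduces to three hash-set
# lookups per k-mer against canonical k-mer indexes.

#' Enumerate N-free k-mers of a transcript
#'
#' Returns every window `seq[i, i + k)` that contains no N, with 0-based
#' start positions in strictly increasing order. A sequence shorter than `k`
#' yields an empty result, not an error.
#'
#' @param record A [transcript_record].
#' @param k Window length (default 21).
#' @return Data frame with columns `pos` (0-based start) and `kmer`.
#' @export
enumerate_kmers <- function(record, k = 21L) {
  stopifnot(inherits(record, "transcript_record"), k >= 1L)
  k <- as.integer(k)
  L <- nchar(record$seq)
  if (L < k) return(data.frame(pos = integer(0), kmer = character(0)))
  starts <- seq_len(L - k + 1L)               # 1-based
  keep <- rep(TRUE, length(starts))
  npos <- gregexpr("N", record$seq, fixed = TRUE)[[1L]]
  if (npos[1L] != -1L) {
    for (j in as.integer(npos)) {
      lo <- max(1L, j - k + 1L)
      hi <- min(j, L - k + 1L)
      if (lo <= hi) keep[lo:hi] <- FALSE
    }
  }
  starts <- starts[keep]
  data.frame(pos = starts - 1L,
             kmer = substring(record$seq, starts, starts + k - 1L))
}

#' Build a canonical k-mer index over a non-target panel
#'
#' Collects the canonical form (lexicographic minimum of a k-mer and its
#' reverse complement) of every N-free 20-mer and 21-mer in the panel.
#' Canonicalization makes the index strand-symmetric without doubling it.
#'
#' @param panel List of [transcript_record] objects with role `"nontarget"`.
#' @param track_organisms If `TRUE`, also record which organism tags contain
#'   each canonical k-mer (larger index; off by default).
#' @return An object of class `offtarget_index` with sets `k20` and `k21`,
#'   counts, and the source organism tags.
#' @export
build_offtarget_index <- function(panel, track_organisms = FALSE) {
  if (inherits(panel, "transcript_record")) panel <- list(panel)
  if (length(panel) == 0L) stop("no non-target sequences")
  stopifnot(all(vapply(panel, inherits, logical(1), "transcript_record")))
  kmers_of <- function(rec, k) canonical_kmer(enumerate_kmers(rec, k)$kmer)
  k20_by_rec <- lapply(panel, kmers_of, k = 20L)
  k21_by_rec <- lapply(panel, kmers_of, k = 21L)
  orgs <- vapply(panel, `[[`, character(1), "organism")
  org_map <- NULL
  if (isTRUE(track_organisms)) {
    per_org <- function(by_rec) {
      sp <- split(by_rec, orgs)
      lapply(sp, function(l) unique(unlist(l, use.names = FALSE)))
    }
    org_map <- list(k20 = per_org(k20_by_rec), k21 = per_org(k21_by_rec))
  }
  k20 <- unique(unlist(k20_by_rec, use.names = FALSE))
  k21 <- unique(unlist(k21_by_rec, use.names = FALSE))
  structure(list(k20 = k20, k21 = k21,
                 n_sequences = length(panel),
                 n_kmers = c(k20 = length(k20), k21 = length(k21)),
                 source_organisms = unique(orgs),
                 org_map = org_map),
            class = "offtarget_index")
}

#' @export
print.offtarget_index <- function(x, ...) {
  cat(sprintf("<offtarget_index> %d sequence(s), %d canonical 20-mers, %d canonical 21-mers\n",
              x$n_sequences, x$n_kmers[["k20"]], x$n_kmers[["k21"]]))
  if (length(x$source_organisms) && any(nzchar(x$source_organisms))) {
    cat("  organisms:", paste(x$source_organisms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Screen a target transcript against an off-target index
#'
#' A 21-mer at position `i` is flagged with `match_class` 21 when its
#' canonical form is in the panel's 21-mer set, otherwise with `match_class`
#' 20 when either of its two terminal 20-mers is in the 20-mer set. The
#' strongest evidence wins (21 beats 20).
#'
#' @param target A [transcript_record].
#' @param index An `offtarget_index` built with [build_offtarget_index()].
#' @return Data frame of hits sorted by `target_pos`, with columns
#'   `target_pos` (0-based), `kmer`, `match_class` (21 or 20), and
#'   `organisms` (comma-joined tags) when the index tracks organisms.
#' @export
screen_transcript <- function(target, index) {
  stopifnot(inherits(target, "transcript_record"),
            inherits(index, "offtarget_index"))
  km <- enumerate_kmers(target, 21L)
  if (nrow(km) == 0L) {
    return(data.frame(target_pos = integer(0), kmer = character(0),
                      match_class = integer(0)))
  }
  full <- canonical_kmer(km$kmer)
  pre <- canonical_kmer(substring(km$kmer, 1L, 20L))
  suf <- canonical_kmer(substring(km$kmer, 2L, 21L))
  hit21 <- full %in% index$k21
  hit20 <- (!hit21) & (pre %in% index$k20 | suf %in% index$k20)
  sel <- hit21 | hit20
  hits <- data.frame(target_pos = km$pos[sel], kmer = km$kmer[sel],
                     match_class = ifelse(hit21[sel], 21L, 20L))
  if (!is.null(index$org_map) && nrow(hits) > 0L) {
    hits$organisms <- vapply(which(sel), function(i) {
      if (hit21[i]) {
        orgs <- names(index$org_map$k21)[vapply(index$org_map$k21,
                 function(s) full[i] %in% s, logical(1))]
      } else {
        orgs <- names(index$org_map$k20)[vapply(index$org_map$k20,
                 function(s) pre[i] %in% s || suf[i] %in% s, logical(1))]
      }
      paste(orgs, collapse = ",")
    }, character(1))
  }
  hits[order(hits$target_pos), , drop = FALSE]
}

#' Exclusion mask from k-mer hits
#'
#' The union of the 21-nt windows of all flagged positions, merged into
#' normal form. When the target is supplied, every window containing an N
#' (never enumerated, hence never screened) is conservatively added to the
#' mask: a base that cannot be verified cannot be declared specific.
#'
#' @param hits Hit data frame from [screen_transcript()].
#' @param target_length Length of the target transcript.
#' @param target Optional [transcript_record]; when given, N-containing
#'   windows are masked too.
#' @return Normalized interval data frame (`start`, `end`).
#' @export
exclusion_mask <- function(hits, target_length, target = NULL) {
  target_length <- as.integer(target_length)
  iv <- data.frame(start = integer(0), end = integer(0))
  if (!is.null(hits) && nrow(hits) > 0L) {
    if (any(hits$target_pos < 0L | hits$target_pos + 21L > target_length)) {
      stop("hit out of bounds for target length")
    }
    iv <- data.frame(start = hits$target_pos, end = hits$target_pos + 21L)
  }
  if (!is.null(target)) {
    stopifnot(nchar(target$seq) == target_length)
    npos <- gregexpr("N", target$seq, fixed = TRUE)[[1L]]
    if (npos[1L] != -1L && target_length >= 21L) {
      for (j in as.integer(npos)) {        # 1-based N position
        lo <- max(0L, j - 21L)             # 0-based first window start
        hi <- min(j - 1L, target_length - 21L)
        if (lo <= hi) iv <- rbind(iv, data.frame(start = lo, end = hi + 21L))
      }
    }
  }
  merge_intervals(iv)
}

#' Save an off-target index as sorted text
#'
#' Format: a header line `#dsrnaforge-index v1`, then for each k a line
#' `#k <k> <count>` followed by one canonical k-mer per line, sorted.
#'
#' @param index An `offtarget_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_offtarget_index <- function(index, path) {
  stopifnot(inherits(index, "offtarget_index"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#dsrnaforge-index v1", con)
  for (k in c(20L, 21L)) {
    set <- sort(index[[paste0("k", k)]], method = "radix")
    writeLines(sprintf("#k %d %d", k, length(set)), con)
    writeLines(set, con)
  }
  invisible(path)
}

#' Load an off-target index written by [write_offtarget_index()]
#'
#' @param path Path to the index file.
#' @return An `offtarget_index` (without organism detail).
#' @export
read_offtarget_index <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1L] != "#dsrnaforge-index v1") {
    stop("not a dsrnaforge index file")
  }
  hdr <- grep("^#k ", lines)
  sets <- list()
  for (h in hdr) {
    parts <- strsplit(lines[h], " ", fixed = TRUE)[[1L]]
    k <- as.integer(parts[2L]); n <- as.integer(parts[3L])
    sets[[paste0("k", k)]] <- if (n > 0L) lines[(h + 1L):(h + n)] else character(0)
  }
  structure(list(k20 = sets$k20, k21 = sets$k21,
                 n_sequences = NA_integer_,
                 n_kmers = c(k20 = length(sets$k20), k21 = length(sets$k21)),
                 source_organisms = character(0), org_map = NULL),
            class = "offtarget_index")
}
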