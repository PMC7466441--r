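# Sequence and interval primitives shared by all modules.
# Sequences are uppercase DNA over {A,C,G,T,N}; intervals are 0-based
# half-open and, once normalized, sorted, non-overlapping and non-adjacent.

#' Create a transcript record
#'
#' A transcript record is an identified nucleotide sequence with an organism
#' tag and a role (`"target"` or `"nontarget"`). Sequences are uppercased and
#' U is mapped to T so RNA and DNA inputs are interchangeable.
#'
#' @param id Character identifier (must be non-empty).
#' @param seq Nucleotide string over A/C/G/T/U/N (case-insensitive).
#' @param organism Free-text organism tag.
#' @param role Either `"target"` or `"nontarget"`.
#' @return An object of class `transcript_record` with fields `id`, `seq`,
#'   `organism`, `role`.
#' @examples
#' transcript_record("tx1", "acgu")$seq  # "ACGT"
#' @export
transcript_record <- function(id, seq, organism = "", role = "target") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("record id must be a non-empty string")
  }
  role <- match.arg(role, c("target", "nontarget"))
  seq <- normalize_seq(seq, id = id)
  structure(list(id = id, seq = seq, organism = organism, role = role),
            class = "transcript_record")
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript_record> %s [%s, %s], %d nt\n",
              x$id, x$organism, x$role, nchar(x$seq)))
  invisible(x)
}

# Uppercase, U->T, validate alphabet; reports the first offending position.
normalize_seq <- function(seq, id = "<seq>") {
  if (!is.character(seq) || length(seq) != 1L) stop("seq must be a single string")
  seq <- chartr("u", "U", toupper(seq))
  seq <- chartr("U", "T", seq)
  if (!nzchar(seq)) stop(sprintf("record '%s': empty sequence", id))
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("record '%s': illegal character '%s' at position %d",
                 id, substr(seq, bad, bad), as.integer(bad)))
  }
  seq
}

#' Read a multi-record FASTA file
#'
#' Sequences are normalized (uppercase, U mapped to T) and validated against
#' the A/C/G/T/N alphabet. Record ids are the first whitespace-delimited
#' token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @param organism Organism tag applied to every record.
#' @param role `"target"` or `"nontarget"`, applied to every record.
#' @return List of [transcript_record] objects, in file order.
#' @export
read_fasta <- function(path, organism = "", role = "target") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("%s: no sequences", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicate record id(s): %s", path,
                 paste(unique(dup), collapse = ", ")))
  }
  seqs <- as.character(set)
  mapply(function(i, s) transcript_record(i, s, organism = organism, role = role),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write transcript records to FASTA
#'
#' @param records List of [transcript_record] objects (or a single one).
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "transcript_record")) records <- list(records)
  stopifnot(length(records) > 0L)
  seqs <- vapply(records, `[[`, character(1), "seq")
  ids <- vapply(records, `[[`, character(1), "id")
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' Vectorized reverse complement over the A/C/G/T/N alphabet.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographic minimum of a k-mer and its reverse
#' complement; indexing canonical k-mers screens both strands at once, which
#' is what a double-stranded molecule requires. Idempotent.
#'
#' @param kmer Character vector of k-mers over A/C/G/T (no N).
#' @return Character vector of canonical k-mers.
#' @examples
#' canonical_kmer("AAAAC")  # "AAAAC" (revcomp "GTTTT" is larger)
#' @export
canonical_kmer <- function(kmer) {
  if (length(kmer) == 0L) return(character(0))
  if (any(grepl("N", kmer, fixed = TRUE))) stop("ambiguous base: k-mer contains N")
  rc <- revcomp(kmer)
  ifelse(kmer <= rc, kmer, rc)
}

# ---- intervals ------------------------------------------------------------

as_interval_df <- function(intervals) {
  if (is.null(intervals) || (is.data.frame(intervals) && nrow(intervals) == 0L)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  if (is.matrix(intervals)) {
    intervals <- data.frame(start = intervals[, 1], end = intervals[, 2])
  }
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in% names(intervals)))
  data.frame(start = as.integer(intervals$start), end = as.integer(intervals$end))
}

#' Merge intervals into normal form
#'
#' Sorts 0-based half-open intervals and coalesces overlapping and abutting
#' ones; the covered position set is preserved. Idempotent.
#'
#' @param intervals Data frame (or 2-column matrix) with `start` and `end`.
#' @return Data frame with columns `start`, `end`: sorted, disjoint,
#'   non-adjacent.
#' @examples
#' merge_intervals(data.frame(start = c(0, 5), end = c(10, 15)))  # 0..15
#' @export
merge_intervals <- function(intervals) {
  iv <- as_interval_df(intervals)
  if (nrow(iv) == 0L) return(iv)
  if (any(iv$start >= iv$end)) stop("invalid interval: start must be < end")
  if (any(iv$start < 0L)) stop("invalid interval: negative start")
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- integer(0); out_e <- integer(0)
  cs <- iv$start[1L]; ce <- iv$end[1L]
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      if (iv$start[i] <= ce) {           # overlap or abutting -> extend
        ce <- max(ce, iv$end[i])
      } else {
        out_s <- c(out_s, cs); out_e <- c(out_e, ce)
        cs <- iv$start[i]; ce <- iv$end[i]
      }
    }
  }
  data.frame(start = c(out_s, cs), end = c(out_e, ce))
}

#' Complement of an interval set within a transcript
#'
#' @param iset Normalized or raw interval set (merged internally).
#' @param length Transcript length; all intervals must fit in `[0, length)`.
#' @return Interval data frame covering exactly `[0, length)` minus `iset`.
#' @export
complement_intervals <- function(iset, length) {
  length <- as.integer(length)
  stopifnot(length >= 0L)
  iv <- merge_intervals(iset)
  if (nrow(iv) > 0L && max(iv$end) > length) {
    stop("interval exceeds transcript length")
  }
  if (length == 0L) return(data.frame(start = integer(0), end = integer(0)))
  bounds_s <- c(0L, iv$end)
  bounds_e <- c(iv$start, length)
  keep <- bounds_s < bounds_e
  data.frame(start = bounds_s[keep], end = bounds_e[keep])
}

#' Write an interval set as BED3
#'
#' BED uses the same 0-based half-open convention as the package internals.
#'
#' @param iset Interval data frame.
#' @param chrom Chromosome/transcript name placed in column 1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iset, chrom, path) {
  iv <- as_interval_df(iset)
  df <- data.frame(chrom = rep(chrom, nrow(iv)), start = iv$start, end = iv$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
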