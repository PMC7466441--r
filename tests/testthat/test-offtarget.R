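test_that("enumerate_kmers covers all N-free windows", {
  r <- transcript_record("t", strrep("ACGTA", 5))   # length 25
  km <- enumerate_kmers(r, 21)
  expect_equal(km$pos, 0:4)
  expect_equal(nchar(km$kmer), rep(21L, 5))
  expect_equal(nrow(enumerate_kmers(transcript_record("t", strrep("A", 20)), 21)), 0L)

  withr::with_seed(3, {
    seq <- oracle_random_dna(60)
  })
  seq <- paste0(substr(seq, 1, 30), "N", substr(seq, 32, 60))
  km <- enumerate_kmers(transcript_record("t", seq), 21)
  # brute-force window scan
  expected <- Filter(function(i) !grepl("N", substr(seq, i + 1, i + 21), fixed = TRUE),
                     0:(60 - 21))
  expect_equal(km$pos, as.integer(expected))
  expect_equal(km$pos, c(0:9, 31:39))
})

test_that("index membership matches brute-force substring search", {
  one <- transcript_record("p", strrep("ACGTT", 4), role = "nontarget")  # 20 nt
  idx1 <- build_offtarget_index(list(one))
  expect_equal(unname(idx1$n_kmers), c(1L, 0L))
  expect_error(build_offtarget_index(list()), "no non-target")

  withr::with_seed(9, {
    pseq <- oracle_random_dna(500)
    panel <- list(transcript_record("p1", pseq, role = "nontarget"))
    idx <- build_offtarget_index(panel)
    rcp <- oracle_revcomp(pseq)
    # canonical invariance: panel plus its revcomp gives the same sets
    idx2 <- build_offtarget_index(list(panel[[1L]],
      transcript_record("p2", rcp, role = "nontarget")))
    expect_setequal(idx2$k20, idx$k20)
    expect_setequal(idx2$k21, idx$k21)
    # random probes: real 20-mers from either strand, plus random 20-mers
    probes <- c(vapply(1:300, function(i) {
      s <- sample(500 - 19, 1); substr(pseq, s, s + 19) }, character(1)),
      vapply(1:300, function(i) {
      s <- sample(500 - 19, 1); substr(rcp, s, s + 19) }, character(1)),
      vapply(1:400, function(i) oracle_random_dna(20), character(1)))
    in_idx <- canonical_kmer(probes) %in% idx$k20
    truth <- grepl_fixed_any(probes, c(pseq, rcp))
    expect_equal(in_idx, truth)
  })
})

test_that("screen flags exactly the >=20 nt exact matches", {
  withr::with_seed(21, {
    tseq <- oracle_random_dna(300)
    pseq <- oracle_random_dna(400)
  })
  # plant an exact 21-mer at target position 50 (0-based)
  q21 <- substr(tseq, 51, 71)
  panel_seq <- paste0(substr(pseq, 1, 100), q21, substr(pseq, 122, 400))
  idx <- build_offtarget_index(list(
    transcript_record("p", panel_seq, role = "nontarget")))
  hits <- screen_transcript(transcript_record("t", tseq), idx)
  h50 <- hits[hits$target_pos == 50L, ]
  expect_equal(nrow(h50), 1L)
  expect_equal(h50$match_class, 21L)

  # same 21-mer mismatched at its first base: only the suffix 20-mer matches
  mismatch_first <- function(s) {
    first <- substr(s, 1, 1)
    paste0(setdiff(c("A", "C", "G", "T"), first)[1L], substr(s, 2, nchar(s)))
  }
  panel_seq2 <- paste0(substr(pseq, 1, 100), mismatch_first(q21),
                       substr(pseq, 122, 400))
  idx2 <- build_offtarget_index(list(
    transcript_record("p", panel_seq2, role = "nontarget")))
  hits2 <- screen_transcript(transcript_record("t", tseq), idx2)
  h50 <- hits2[hits2$target_pos == 50L, ]
  expect_equal(h50$match_class, 20L)

  # internal mismatch at offset 10 -> longest exact run is 10, not flagged
  mm <- q21
  substr(mm, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(mm, 11, 11))[1L]
  panel_seq3 <- paste0(substr(pseq, 1, 100), mm, substr(pseq, 122, 400))
  idx3 <- build_offtarget_index(list(
    transcript_record("p", panel_seq3, role = "nontarget")))
  hits3 <- screen_transcript(transcript_record("t", tseq), idx3)
  flagged3 <- hits3$target_pos
  oracle3 <- oracle_flagged_positions(tseq, panel_seq3)
  expect_equal(flagged3, oracle3)
  expect_false(50L %in% flagged3)
})

test_that("screen is monotone under panel growth and strand-symmetric", {
  withr::with_seed(33, {
    tseq <- oracle_random_dna(400)
    p1 <- oracle_random_dna(600)
    p2 <- paste0(substr(tseq, 101, 120), oracle_random_dna(200))  # shares a 20-mer
  })
  t <- transcript_record("t", tseq)
  small <- build_offtarget_index(list(transcript_record("a", p1, role = "nontarget")))
  big <- build_offtarget_index(list(transcript_record("a", p1, role = "nontarget"),
                                    transcript_record("b", p2, role = "nontarget")))
  f_small <- screen_transcript(t, small)$target_pos
  f_big <- screen_transcript(t, big)$target_pos
  expect_true(all(f_small %in% f_big))
  expect_true(100L %in% f_big)   # planted 20-mer flags window at its start

  rc_panel <- build_offtarget_index(list(
    transcript_record("a", oracle_revcomp(p1), role = "nontarget"),
    transcript_record("b", oracle_revcomp(p2), role = "nontarget")))
  expect_equal(screen_transcript(t, rc_panel)$target_pos, f_big)
})

test_that("exclusion mask is the union of 21-nt windows plus N windows", {
  hits <- data.frame(target_pos = c(0L, 10L), kmer = "x", match_class = 21L)
  expect_equal(exclusion_mask(hits, 100), data.frame(start = 0L, end = 31L))
  expect_equal(nrow(exclusion_mask(NULL, 100)), 0L)
  expect_error(exclusion_mask(data.frame(target_pos = 90L), 100), "bounds")

  withr::with_seed(13, {
    for (rep in 1:10) {
      L <- 200L
      pos <- sort(sample(0:(L - 21L), sample(1:15, 1)))
      hits <- data.frame(target_pos = pos)
      m <- exclusion_mask(hits, L)
      expect_equal(oracle_positions(m),
                   sort(unique(unlist(lapply(pos, function(p) p:(p + 20L))))))
    }
  })

  # windows under an N are masked even without hits
  seq <- strrep("A", 100)
  substr(seq, 51, 51) <- "N"
  t <- transcript_record("t", seq)
  m <- exclusion_mask(NULL, 100, target = t)
  # N at 0-based 50: window starts 30..50 are unverifiable
  expect_equal(m, data.frame(start = 30L, end = 71L))
})

test_that("index text round-trip preserves the k-mer sets", {
  withr::with_seed(17, {
    panel <- list(transcript_record("p", oracle_random_dna(300), role = "nontarget"))
  })
  idx <- build_offtarget_index(panel)
  f <- withr::local_tempfile(fileext = ".idx")
  write_offtarget_index(idx, f)
  back <- read_offtarget_index(f)
  expect_setequal(back$k20, idx$k20)
  expect_setequal(back$k21, idx$k21)
  expect_error(read_offtarget_index(withr::local_tempfile(lines = "junk")),
               "not a dsrnaforge index")
})

test_that("organism tracking reports the contributing panel species", {
  withr::with_seed(19, {
    tseq <- oracle_random_dna(120)
    filler <- oracle_random_dna(100)
  })
  shared <- substr(tseq, 31, 51)        # 21-mer at 0-based position 30
  panel <- list(
    transcript_record("a", paste0(filler, shared), organism = "spA",
                      role = "nontarget"),
    transcript_record("b", oracle_revcomp(paste0(shared, filler)),
                      organism = "spB", role = "nontarget"))
  idx <- build_offtarget_index(panel, track_organisms = TRUE)
  hits <- screen_transcript(transcript_record("t", tseq), idx)
  h <- hits[hits$target_pos == 30L, ]
  expect_equal(h$match_class, 21L)
  expect_setequal(strsplit(h$organisms, ",")[[1L]], c("spA", "spB"))
})
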