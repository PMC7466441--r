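# Seeded synthetic-data generators. Each generator seeds the RNG once per
# call (restoring the caller's RNG state afterwards) so identical arguments
# give byte-identical outputs. The defaults encode the study conditions the
# rest of the package is tested under: a ~2 kb target screened against a
# small non-target panel, two-arm feeding trials with daily observation and
# a 14-day horizon, a three-location four-replicate field trial, and
# TaqMan-style Cq tables from a slope -3.3219 standard curve.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Synthetic target + non-target transcriptomes with planted shared 20-mers
#'
#' Generates a uniform-random target transcript and a panel of non-target
#' sequences, then copies `n_planted` non-overlapping 20-mers from the
#' target into random panel positions (random strand). Embedding sites get
#' mismatching flanks so a planted 20-mer cannot extend to a shared 21-mer,
#' and the construction is verified (and resampled on failure) so that the
#' canonical 20-mers shared between target and panel are exactly the
#' planted ones and no 21-mer is shared: the truth set of flagged 21-mer
#' start positions is exact, not probabilistic.
#'
#' A shared 20-mer at target position `p` makes it the terminal 20-mer of
#' the 21-mer windows starting at `p - 1` and `p`, so the truth is
#' `{p - 1, p}` intersected with the valid window range.
#'
#' @param seed Integer seed.
#' @param target_len Target length (default 2000, ≥ 100).
#' @param n_nontarget Number of panel sequences (default 3).
#' @param nontarget_len Length of each panel sequence (default 5000).
#' @param n_planted Number of planted 20-mers (default 10); must satisfy
#'   `n_planted * 21 < target_len / 2`.
#' @param out_dir Optional directory; when given, `target.fa` and
#'   `panel_<i>.fa` are written there.
#' @return List with `target` ([transcript_record]), `panel` (list of
#'   records), `truth` (sorted 0-based 21-mer start positions that a
#'   correct screen must flag), and `planted` (data frame of planted
#'   20-mer positions and strands).
#' @export
synth_transcriptomes <- function(seed, target_len = 2000L, n_nontarget = 3L,
                                 nontarget_len = 5000L, n_planted = 10L,
                                 out_dir = NULL) {
  stopifnot(target_len >= 100L)
  if (n_planted * 21L >= target_len / 2) stop("infeasible packing of planted k-mers")
  withr::with_seed(seed, {
    for (attempt in seq_len(50L)) {
      res <- synth_transcriptomes_once(target_len, n_nontarget,
                                       nontarget_len, n_planted)
      if (!is.null(res)) break
      res <- NULL
    }
    if (is.null(res)) stop("could not construct collision-free transcriptomes")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(res$target, file.path(out_dir, "target.fa"))
      for (i in seq_along(res$panel)) {
        write_fasta(res$panel[[i]], file.path(out_dir, sprintf("panel_%d.fa", i)))
      }
    }
    res
  })
}

# One construction attempt; NULL when the verification rejects it.
synth_transcriptomes_once <- function(target_len, n_nontarget,
                                      nontarget_len, n_planted) {
  target_seq <- random_dna(target_len)
  panel_chars <- lapply(seq_len(n_nontarget),
                        function(i) strsplit(random_dna(nontarget_len), "")[[1L]])
  # non-overlapping planted 20-mer starts on the target (1-based), with
  # flank room and >= 2 nt spacing so planted windows are distinct
  ok_pos <- FALSE
  for (try in seq_len(20L)) {
    p <- sort(sample(2:(target_len - 21L), n_planted))
    if (n_planted < 2L || all(diff(p) >= 22L)) { ok_pos <- TRUE; break }
  }
  if (!ok_pos) return(NULL)
  tchar <- strsplit(target_seq, "")[[1L]]
  used <- vector("list", n_nontarget)         # occupied panel intervals
  planted <- data.frame(target_pos = integer(0), panel_seq = integer(0),
                        panel_pos = integer(0), strand = character(0))
  bases <- c("A", "C", "G", "T")
  for (pp in p) {
    s20 <- tchar[pp:(pp + 19L)]
    strand <- sample(c("+", "-"), 1L)
    ins <- if (strand == "+") s20 else rev(chartr_vec(s20))
    placed <- FALSE
    for (try in seq_len(50L)) {
      r <- sample.int(n_nontarget, 1L)
      q <- sample(2:(nontarget_len - 21L), 1L)   # 1-based start in panel seq
      clash <- any(vapply(used[[r]], function(iv) q <= iv[2L] + 1L && q + 20L >= iv[1L] - 1L,
                          logical(1)))
      if (clash) next
      panel_chars[[r]][q:(q + 19L)] <- ins
      # flanks must not extend the match to 21 nt on either strand
      if (strand == "+") {
        bad_l <- tchar[pp - 1L]; bad_r <- tchar[pp + 20L]
      } else {
        bad_l <- chartr_vec(tchar[pp + 20L]); bad_r <- chartr_vec(tchar[pp - 1L])
      }
      panel_chars[[r]][q - 1L] <- sample(setdiff(bases, bad_l), 1L)
      panel_chars[[r]][q + 20L] <- sample(setdiff(bases, bad_r), 1L)
      used[[r]] <- c(used[[r]], list(c(q, q + 19L)))
      planted <- rbind(planted, data.frame(target_pos = pp - 1L, panel_seq = r,
                                           panel_pos = q - 1L, strand = strand))
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  target <- transcript_record("target_tx", target_seq,
                              organism = "target_species", role = "target")
  panel <- lapply(seq_len(n_nontarget), function(i) {
    transcript_record(sprintf("nontarget_%d", i),
                      paste(panel_chars[[i]], collapse = ""),
                      organism = sprintf("nontarget_species_%d", i),
                      role = "nontarget")
  })
  # verification: shared canonical 20-mers are exactly the planted ones,
  # each planted 20-mer occurs once in the target, and no shared 21-mer
  t20 <- canonical_kmer(enumerate_kmers(target, 20L)$kmer)
  t21 <- canonical_kmer(enumerate_kmers(target, 21L)$kmer)
  p20 <- unique(unlist(lapply(panel, function(r) canonical_kmer(enumerate_kmers(r, 20L)$kmer))))
  p21 <- unique(unlist(lapply(panel, function(r) canonical_kmer(enumerate_kmers(r, 21L)$kmer))))
  planted20 <- if (nrow(planted) == 0L) character(0) else
    canonical_kmer(substring(target_seq, planted$target_pos + 1L,
                             planted$target_pos + 20L))
  shared20 <- intersect(unique(t20), p20)
  if (!setequal(shared20, planted20)) return(NULL)
  if (length(intersect(unique(t21), p21)) > 0L) return(NULL)
  if (any(vapply(planted20, function(k) sum(t20 == k), integer(1)) != 1L)) return(NULL)
  truth <- sort(unique(c(planted$target_pos - 1L, planted$target_pos)))
  truth <- truth[truth >= 0L & truth <= target_len - 21L]
  list(target = target, panel = panel, truth = truth, planted = planted)
}

# complement of a character vector of bases
chartr_vec <- function(x) c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]

#' Simulate a two(or more)-arm feeding trial with daily observation
#'
#' Event times are drawn from per-arm exponential hazards and rounded up to
#' whole days (deliberately inducing the tied event times of daily trial
#' observation); subjects alive at `max_day` are administratively censored.
#' An arm with rate 0 yields only censored records.
#'
#' @param seed Integer seed.
#' @param n_per_arm Subjects per arm (default 40).
#' @param arms Named numeric vector of daily hazard rates; the default
#'   `c(water = 0.04, dsMESH = 0.20)` encodes a hazard ratio of 5 between
#'   a low-mortality control and an effective treatment.
#' @param max_day Administrative censoring horizon in days (default 14).
#' @param trial Trial label stored in the records.
#' @return Survival data frame (`subject_id`, `arm`, `trial`, `time`,
#'   `event`).
#' @export
simulate_survival_trial <- function(seed, n_per_arm = 40L,
                                    arms = c(water = 0.04, dsMESH = 0.20),
                                    max_day = 14L, trial = "sim") {
  stopifnot(length(arms) >= 1L, !is.null(names(arms)), all(arms >= 0))
  if (all(arms == 0) && !is.finite(max_day)) {
    stop("all hazard rates zero and no censoring horizon")
  }
  withr::with_seed(seed, {
    recs <- lapply(names(arms), function(a) {
      lam <- arms[[a]]
      t_cont <- if (lam > 0) stats::rexp(n_per_arm, rate = lam) else rep(Inf, n_per_arm)
      t_day <- ceiling(t_cont)
      event <- as.integer(t_day <= max_day)
      time <- ifelse(event == 1L, t_day, max_day)
      data.frame(subject_id = sprintf("%s_%03d", a, seq_len(n_per_arm)),
                 arm = a, trial = trial, time = time, event = event)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a multi-location field trial with known survival rates
#'
#' Per replicate plot, the pre-treatment larval count is Poisson with mean
#' `mean_infestation`, truncated to at least 15 (plots are selected for
#' infestation); the post-treatment count is binomial with the arm's true
#' survival probability. Leaf damage starts uniform in `[5, 15]`% and
#' increases by an arm-specific increment plus Gaussian noise (sd 2),
#' clipped to `[0, 100]`.
#'
#' @param seed Integer seed.
#' @param n_locations Number of locations (default 3).
#' @param reps Replicate plots per arm and location (default 4).
#' @param mean_infestation Poisson mean of the pre-count (default 20).
#' @param control_survival Survival probability on control plots
#'   (default 0.9).
#' @param treated_survival Named survival probabilities of the treated
#'   arms; the default `c(dsMESH = 0.07, spinosad = 0.02)` encodes a
#'   strongly effective dsRNA and a faster-acting reference insecticide.
#' @param dpt Assessment day recorded in the output (default 7).
#' @param damage_increment Named mean leaf-damage increases in percentage
#'   points (control named `control`).
#' @return Field-assessment data frame (`location`, `plot`, `arm`,
#'   `n_before`, `n_after`, `dpt`, `damage_before`, `damage_after`).
#' @export
simulate_field_trial <- function(seed, n_locations = 3L, reps = 4L,
                                 mean_infestation = 20,
                                 control_survival = 0.9,
                                 treated_survival = c(dsMESH = 0.07,
                                                      spinosad = 0.02),
                                 dpt = 7L,
                                 damage_increment = c(control = 25,
                                                      dsMESH = 5,
                                                      spinosad = 3)) {
  stopifnot(control_survival >= 0, control_survival <= 1,
            all(treated_survival >= 0), all(treated_survival <= 1))
  surv <- c(control = control_survival, treated_survival)
  withr::with_seed(seed, {
    rows <- list()
    for (loc in seq_len(n_locations)) {
      for (a in names(surv)) {
        for (rp in seq_len(reps)) {
          nb <- stats::rpois(1L, mean_infestation)
          while (nb < 15L) nb <- stats::rpois(1L, mean_infestation)
          na_ <- stats::rbinom(1L, nb, surv[[a]])
          db <- stats::runif(1L, 5, 15)
          da <- db + damage_increment[[a]] + stats::rnorm(1L, 0, 2)
          rows[[length(rows) + 1L]] <- data.frame(
            location = sprintf("loc%d", loc), plot = sprintf("%s_r%d", a, rp),
            arm = a, n_before = nb, n_after = na_, dpt = dpt,
            damage_before = db,
            damage_after = min(100, max(0, da)))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate standard-curve qPCR data from known copy numbers
#'
#' Standards are generated over five 10-fold serial dilutions per gene with
#' `cq = intercept + slope * log10(dilution) + N(0, sigma_cq)`; sample
#' measurements are generated at the given dilutions and replicates from
#' `cq = intercept + slope * log10(copies * dilution) + N(0, sigma_cq)`
#' (two replicates of two dilutions by default, matching the paired-
#' dilution inhibition QC design).
#'
#' @param seed Integer seed.
#' @param true_copies Data frame `sample_id,group,gene,copies` (> 0).
#' @param slope,intercept Standard-curve parameters shared by all genes
#'   (defaults −3.3219 and 20: a perfect-doubling assay).
#' @param sigma_cq Gaussian Cq noise sd in cycles (default 0.2).
#' @param dilutions Sample dilutions (default `c(1, 0.1)`).
#' @param n_replicates Replicates per dilution (default 2).
#' @param standard_dilutions Standards dilution series
#'   (default `10^(0:-4)`).
#' @param standard_replicates Replicates per standard dilution (default 2).
#' @return List with `standards` (`gene,dilution,replicate,cq`) and
#'   `samples` (`sample_id,group,gene,dilution,replicate,cq`).
#' @export
simulate_qpcr_run <- function(seed, true_copies, slope = -3.3219,
                              intercept = 20, sigma_cq = 0.2,
                              dilutions = c(1, 0.1), n_replicates = 2L,
                              standard_dilutions = 10^(0:-4),
                              standard_replicates = 2L) {
  stopifnot(is.data.frame(true_copies),
            all(c("sample_id", "group", "gene", "copies") %in% names(true_copies)),
            all(true_copies$copies > 0))
  withr::with_seed(seed, {
    genes <- unique(true_copies$gene)
    standards <- expand.grid(replicate = seq_len(standard_replicates),
                             dilution = standard_dilutions, gene = genes,
                             stringsAsFactors = FALSE)[, c("gene", "dilution", "replicate")]
    standards$cq <- intercept + slope * log10(standards$dilution) +
      stats::rnorm(nrow(standards), 0, sigma_cq)
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        dilution = dilutions,
                        row = seq_len(nrow(true_copies)))
    samples <- data.frame(sample_id = true_copies$sample_id[grid$row],
                          group = true_copies$group[grid$row],
                          gene = true_copies$gene[grid$row],
                          dilution = grid$dilution,
                          replicate = grid$replicate)
    samples$cq <- intercept +
      slope * log10(true_copies$copies[grid$row] * grid$dilution) +
      stats::rnorm(nrow(samples), 0, sigma_cq)
    list(standards = standards, samples = samples)
  })
}

#' True copy numbers for a simulated knockdown experiment
#'
#' Builds the `true_copies` table for [simulate_qpcr_run()]: a target gene
#' at `control_copies` in the control group and
#' `control_copies * (1 - knockdown)` in the treated group, plus reference
#' genes at fixed copy numbers in both groups.
#'
#' @param n_per_group Samples per group (default 4).
#' @param knockdown True fractional knockdown of the target (default 0.7).
#' @param control_copies Target copies in controls (default 100).
#' @param target_gene,ref_genes Gene labels.
#' @param ref_copies Copy numbers of the reference genes.
#' @param groups Labels of (treated, control) groups.
#' @return Data frame `sample_id,group,gene,copies`.
#' @export
knockdown_true_copies <- function(n_per_group = 4L, knockdown = 0.7,
                                  control_copies = 100,
                                  target_gene = "mesh",
                                  ref_genes = c("LdRP4", "rRNA18S", "LdSmt3"),
                                  ref_copies = c(50, 500, 80),
                                  groups = c("dsMESH", "dsEGFP")) {
  stopifnot(length(ref_genes) == length(ref_copies), length(groups) == 2L)
  rows <- list()
  for (g in groups) {
    tc <- if (g == groups[1L]) control_copies * (1 - knockdown) else control_copies
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%d", g, i)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, group = g,
        gene = c(target_gene, ref_genes),
        copies = c(tc, ref_copies))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
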