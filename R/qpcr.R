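# Standard-curve qPCR quantification. Cq is linear in log10 template
# amount; the curve slope gives the amplification efficiency
# E = 10^(-1/slope) (E = 2 is perfect doubling). Quantities are
# back-calculated by inverting the regression, corrected for the dilution
# at which the sample was run, normalized to the geometric mean of three
# endogenous control genes, and summarized as percent knockdown between
# treatment groups. The limit of quantification (LOQ) is read off the
# standard curve; sample values falling below it are flagged and excluded
# from group means by default.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(relative template amount) across a
#' serial dilution series (typically five 10-fold dilutions). The LOQ is
#' the smallest dilution whose replicates are all detected and whose mean
#' absolute residual from the fitted line is at most `loq_residual` cycles.
#'
#' @param points Data frame with columns `dilution` (> 0, relative amount)
#'   and `cq` (`NA` = not detected), one row per replicate.
#' @param gene Assay label.
#' @param loq_residual LOQ residual tolerance in cycles (default 0.5).
#' @return Object of class `standard_curve`: `gene`, `slope`, `intercept`,
#'   `efficiency`, `efficiency_pct`, `r2`, `loq`, `linear_range`,
#'   `n_points`.
#' @examples
#' pts <- data.frame(dilution = c(1, 0.1, 0.01),
#'                   cq = 20 - log10(c(1, 0.1, 0.01)) * 3.3219)
#' fit_standard_curve(pts)$efficiency  # ~2
#' @export
fit_standard_curve <- function(points, gene = "", loq_residual = 0.5) {
  stopifnot(is.data.frame(points), all(c("dilution", "cq") %in% names(points)))
  if (any(points$dilution <= 0)) stop("dilutions must be positive")
  det <- points[!is.na(points$cq), , drop = FALSE]
  if (length(unique(det$dilution)) < 3L) {
    stop("at least 3 distinct detected dilutions are required")
  }
  x <- log10(det$dilution)
  if (diff(range(x)) == 0) stop("no spread in dilution series")
  fit <- stats::lm(cq ~ x, data = data.frame(x = x, cq = det$cq))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope >= 0) stop("invalid assay: standard-curve slope must be negative")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((det$cq - mean(det$cq))^2)
  r2 <- 1 - ss_res / ss_tot
  efficiency <- 10^(-1 / slope)
  # LOQ: per-dilution criterion on the full replicate table
  resid_all <- points$cq - (intercept + slope * log10(points$dilution))
  by_dil <- split(seq_len(nrow(points)), points$dilution)
  quantifiable <- vapply(by_dil, function(i) {
    all(!is.na(points$cq[i])) && mean(abs(resid_all[i])) <= loq_residual
  }, logical(1))
  dils <- as.numeric(names(by_dil))
  ok <- dils[quantifiable]
  if (length(ok) == 0L) stop("no dilution meets the LOQ criterion")
  structure(list(gene = gene, slope = slope, intercept = intercept,
                 efficiency = efficiency,
                 efficiency_pct = (efficiency - 1) * 100,
                 r2 = r2, loq = min(ok), linear_range = range(ok),
                 n_points = nrow(det)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %s: slope %.4f, intercept %.3f, E = %.3f (%.1f%%), R2 = %.4f, LOQ = %g\n",
              if (nzchar(x$gene)) x$gene else "(unnamed)",
              x$slope, x$intercept, x$efficiency, x$efficiency_pct,
              x$r2, x$loq))
  invisible(x)
}

#' Predicted Cq for a relative template amount
#'
#' @param curve A `standard_curve`.
#' @param amount Relative template amount in the reaction (> 0).
#' @return Predicted Cq.
#' @export
predict_cq <- function(curve, amount) {
  stopifnot(inherits(curve, "standard_curve"), all(amount > 0))
  curve$intercept + curve$slope * log10(amount)
}

#' Back-calculate relative copy number from Cq
#'
#' Inverts the standard curve: the amount in the reaction is
#' `10^((cq - intercept)/slope)`; dividing by the dilution at which the
#' sample was run gives the undiluted relative copy number. A measurement
#' whose in-reaction amount falls below the curve's LOQ (or a not-detected
#' Cq, `NA`) is flagged `below_loq` with `quantity = NA`.
#'
#' @param cq Cq value(s); `NA` means not detected.
#' @param curve A `standard_curve`.
#' @param dilution Relative template dilution(s) of the measurement
#'   (default 1).
#' @return Data frame with `quantity` (dilution-corrected), `in_reaction`,
#'   and `below_loq`.
#' @export
quantify <- function(cq, curve, dilution = 1) {
  stopifnot(inherits(curve, "standard_curve"), all(dilution > 0))
  in_reaction <- 10^((cq - curve$intercept) / curve$slope)
  below <- is.na(cq) | in_reaction < curve$loq
  quantity <- ifelse(below, NA_real_, in_reaction / dilution)
  data.frame(quantity = quantity,
             in_reaction = ifelse(is.na(cq), NA_real_, in_reaction),
             below_loq = below)
}

#' Paired-dilution inhibition check
#'
#' A sample measured at two dilutions should back-calculate to the same
#' undiluted quantity; a deficit at the more concentrated dilution reveals
#' PCR inhibitors. Verdict is `"inhibited"` when the dilution-corrected
#' ratio deviates from 1 by more than `tolerance`, `"unevaluable"` when
#' either measurement is below the LOQ, `"ok"` otherwise.
#'
#' @param cq1,cq2 Cq of the two measurements (same sample and gene).
#' @param dilution1,dilution2 Their dilutions (must differ).
#' @param curve A `standard_curve` for the gene.
#' @param tolerance Allowed fractional deviation of the ratio (default 0.3).
#' @return List with `verdict` and `ratio` (q2/q1, `NA` when unevaluable).
#' @export
inhibition_qc <- function(cq1, cq2, dilution1, dilution2, curve,
                          tolerance = 0.3) {
  if (dilution1 == dilution2) stop("inhibition QC needs two different dilutions")
  q1 <- quantify(cq1, curve, dilution1)
  q2 <- quantify(cq2, curve, dilution2)
  if (q1$below_loq || q2$below_loq) {
    return(list(verdict = "unevaluable", ratio = NA_real_))
  }
  ratio <- q2$quantity / q1$quantity
  list(verdict = if (abs(ratio - 1) > tolerance) "inhibited" else "ok",
       ratio = ratio)
}

#' Normalize target expression to endogenous control genes
#'
#' Divides the target copy number by the geometric mean of the reference
#' gene copy numbers (three endogenous controls in the standard design);
#' arithmetic-mean normalization is available for sensitivity analysis.
#'
#' @param target_copies Target-gene copy number (> 0).
#' @param ref_copies Numeric vector of reference-gene copy numbers.
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return Normalized expression (scalar).
#' @examples
#' normalize_expression(10, c(1, 10, 100))  # 1
#' @export
normalize_expression <- function(target_copies, ref_copies,
                                 method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (any(is.na(ref_copies)) || any(ref_copies <= 0)) {
    stop("reference unquantifiable")
  }
  if (is.na(target_copies) || target_copies < 0) {
    stop("target copy number must be a non-negative number")
  }
  denom <- switch(method,
                  geometric = exp(mean(log(ref_copies))),
                  arithmetic = mean(ref_copies))
  target_copies / denom
}

#' Percent knockdown between treatment groups
#'
#' `100 * (1 - mean(treated) / mean(control))` on normalized expression
#' values (arithmetic group means).
#'
#' @param treated,control Numeric vectors of normalized expression values;
#'   `NA` values (below-LOQ exclusions) are dropped.
#' @return Knockdown in percent.
#' @export
knockdown_percent <- function(treated, control) {
  treated <- treated[!is.na(treated)]
  control <- control[!is.na(control)]
  if (length(treated) == 0L || length(control) == 0L) {
    stop("both groups must contain quantifiable values")
  }
  mc <- mean(control)
  if (mc <= 0) stop("control mean must be positive")
  100 * (1 - mean(treated) / mc)
}

#' Standard-curve qPCR expression pipeline
#'
#' Fits one standard curve per gene, back-calculates dilution-corrected
#' quantities for every sample measurement (averaging detected replicates
#' and dilutions per sample and gene), normalizes the target gene to the
#' geometric mean of the reference genes and reports per-group knockdown
#' against a control group.
#'
#' @param standards Data frame `gene,dilution,replicate,cq` (`NA` = ND).
#' @param samples Data frame `sample_id,group,gene,dilution,replicate,cq`.
#' @param target_gene Target assay label.
#' @param ref_genes Character vector of reference assay labels.
#' @param control_group Group used as the knockdown baseline.
#' @param loq_action `"exclude"` (default: below-LOQ measurements dropped)
#'   or `"half"` (substitute LOQ/2, dilution-corrected).
#' @return List with `curves` (per gene), `expression` (per sample:
#'   normalized value), and `knockdown` (per non-control group, percent).
#' @export
qpcr_expression <- function(standards, samples, target_gene, ref_genes,
                            control_group,
                            loq_action = c("exclude", "half")) {
  loq_action <- match.arg(loq_action)
  genes <- c(target_gene, ref_genes)
  missing_std <- setdiff(genes, unique(standards$gene))
  if (length(missing_std)) {
    stop(sprintf("no standards for gene(s): %s", paste(missing_std, collapse = ", ")))
  }
  curves <- lapply(genes, function(g) {
    fit_standard_curve(standards[standards$gene == g, c("dilution", "cq")],
                       gene = g)
  })
  names(curves) <- genes

  sample_gene_quantity <- function(sid, g) {
    m <- samples[samples$sample_id == sid & samples$gene == g, , drop = FALSE]
    if (nrow(m) == 0L) return(NA_real_)
    q <- quantify(m$cq, curves[[g]], m$dilution)
    if (loq_action == "half") {
      q$quantity[q$below_loq] <- (curves[[g]]$loq / 2) / m$dilution[q$below_loq]
    }
    vals <- q$quantity[!is.na(q$quantity)]
    if (length(vals) == 0L) NA_real_ else mean(vals)
  }

  ids <- unique(samples$sample_id)
  grp <- samples$group[match(ids, samples$sample_id)]
  expr <- vapply(ids, function(sid) {
    tq <- sample_gene_quantity(sid, target_gene)
    rq <- vapply(ref_genes, sample_gene_quantity, numeric(1), sid = sid)
    if (is.na(tq) || any(is.na(rq)) || any(rq <= 0)) return(NA_real_)
    normalize_expression(tq, rq)
  }, numeric(1))
  expression <- data.frame(sample_id = ids, group = grp, normalized = expr)

  other <- setdiff(unique(grp), control_group)
  ctrl_vals <- expr[grp == control_group]
  knockdown <- vapply(other, function(g) {
    knockdown_percent(expr[grp == g], ctrl_vals)
  }, numeric(1))
  list(curves = curves, expression = expression,
       knockdown = data.frame(group = other, knockdown_pct = unname(knockdown)))
}

#' Read a Cq table CSV (`sample_id,group,gene,dilution,replicate,cq`)
#'
#' The marker `ND` (not detected) is read as `NA`.
#'
#' @param path CSV path.
#' @return Cq data frame.
#' @export
read_cq_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cq = "character"))
  need <- c("sample_id", "group", "gene", "dilution", "replicate", "cq")
  if (!all(need %in% names(df))) {
    stop(sprintf("Cq CSV must have columns: %s", paste(need, collapse = ",")))
  }
  cq <- suppressWarnings(as.numeric(ifelse(df$cq == "ND", NA, df$cq)))
  bad <- which(!is.na(df$cq) & df$cq != "ND" & is.na(cq))
  if (length(bad)) stop(sprintf("unparseable cq at row %d", bad[1L]))
  df$cq <- cq
  if (any(df$dilution <= 0)) stop("dilutions must be positive")
  if (any(!is.na(df$cq) & df$cq <= 0)) stop("detected cq must be positive")
  df
}

#' Write a Cq table CSV (`NA` written as `ND`)
#'
#' @param df Cq data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cq_csv <- function(df, path) {
  out <- df
  out$cq <- ifelse(is.na(out$cq), "ND", format(out$cq, digits = 10))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
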