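#' Amplification efficiency from a standard-curve slope
#'
#' `E = (10^(-1/y) - 1) * 100` for slope `y` (cycles per log10
#' concentration); per-cycle fold amplification is `1 + E/100`. The
#' canonical anchor: slope `-3.3219` (= -log2(10) cycles per ten-fold
#' dilution) gives E = 100 % and fold = 2.
#'
#' @param y regression slope, must be negative.
#' @return List with `E` (percent) and `fold`.
#' @export
efficiency_from_slope <- function(y) {
  if (y >= 0) stop("slope must be negative")
  E <- (10^(-1 / y) - 1) * 100
  list(E = E, fold = 1 + E / 100)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of mean Ct (technical replicates averaged) on
#' log10 template concentration, with the derived amplification
#' efficiency.
#'
#' @param ct_table data frame with columns `ct` and `log10_conc` (and
#'   optionally `sample`, `replicate`), e.g. from
#'   [simulate_dilution_series()].
#' @return Object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `E` (percent), `fold`, `n_points`.
#' @export
fit_standard_curve <- function(ct_table) {
  stopifnot(all(c("ct", "log10_conc") %in% names(ct_table)))
  mean_ct <- tapply(ct_table$ct, ct_table$log10_conc, mean)
  x <- as.numeric(names(mean_ct))
  y <- as.numeric(mean_ct)
  if (length(x) < 3) stop("need >= 3 distinct concentrations")
  if (var(x) == 0) stop("zero variance in concentration")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) stop("positive slope: Ct must rise as template dilutes")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  eff <- efficiency_from_slope(slope)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2, E = eff$E, fold = eff$fold,
                 n_points = length(x)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: slope %.4f, intercept %.2f, R^2 %.4f, E = %.1f%%, fold %.3f\n",
    x$slope, x$intercept, x$r_squared, x$E, x$fold))
  invisible(x)
}

.mean_ct <- function(ct_table, sample, target) {
  sel <- ct_table$sample == sample & ct_table$target == target
  if (!any(sel)) stop(sprintf("no Ct for sample '%s', target '%s'",
                              sample, target))
  mean(ct_table$ct[sel])
}

#' Relative copy number by the 2^-ddCt method
#'
#' Technical replicates are averaged at the Ct level; `dCt = Ct(target) -
#' Ct(reference gene)` per sample, `ddCt = dCt(test) - dCt(calibrator)`,
#' and the relative quantity is `2^-ddCt` (the calibrator is exactly 1).
#'
#' @param ct_table Ct data frame (`sample`, `target`, `replicate`, `ct`).
#' @param target quantified target (e.g. an LTR or internal-domain
#'   amplicon).
#' @param reference_gene single-copy reference gene.
#' @param test_sample,calibrator_sample sample ids.
#' @return Data frame (class `relative_quantity`) with one row per sample
#'   (`delta_ct`, `delta_delta_ct`, `rq`, `method`, `calibrator_id`).
#' @export
copy_number_rq <- function(ct_table, target, reference_gene, test_sample,
                           calibrator_sample) {
  d_test <- .mean_ct(ct_table, test_sample, target) -
    .mean_ct(ct_table, test_sample, reference_gene)
  d_cal <- .mean_ct(ct_table, calibrator_sample, target) -
    .mean_ct(ct_table, calibrator_sample, reference_gene)
  out <- data.frame(
    sample_id = c(test_sample, calibrator_sample),
    target_id = target,
    delta_ct = c(d_test, d_cal),
    delta_delta_ct = c(d_test - d_cal, 0),
    rq = c(2^(-(d_test - d_cal)), 1),
    method = "copy_number_2ddct",
    calibrator_id = calibrator_sample,
    stringsAsFactors = FALSE)
  class(out) <- c("relative_quantity", "data.frame")
  out
}

#' Efficiency-corrected relative expression ((1+E)^-ddCt)
#'
#' Per sample, `dCt = Ct(target) - Ct(normalizer)` (technical replicates
#' averaged). The calibrator defaults to the sample with the highest
#' normalized Ct -- i.e. the lowest-expression tissue -- and gets relative
#' quantity exactly 1; every sample is reported as
#' `(1 + E)^-(dCt - dCt(calibrator))`, so more template (lower Ct) gives a
#' higher quantity.
#'
#' @param ct_table Ct data frame (`sample`, `target`, `replicate`, `ct`).
#' @param target quantified target.
#' @param normalizer stable normalizer gene (e.g. GAPDH).
#' @param efficiency amplification efficiency E as a fraction in
#'   `(0, 1.1]`; reactions below `min_efficiency` are refused.
#' @param calibrator `"auto"` (highest normalized Ct) or a sample id.
#' @param min_efficiency minimum acceptable efficiency (default 0.90).
#' @return Data frame (class `relative_quantity`), one row per sample.
#' @export
expression_rq <- function(ct_table, target, normalizer, efficiency,
                          calibrator = "auto", min_efficiency = 0.90) {
  if (efficiency <= 0 || efficiency > 1.1)
    stop("efficiency must be in (0, 1.1]")
  if (efficiency < min_efficiency)
    stop(sprintf("efficiency %.2f below the acceptance threshold %.2f",
                 efficiency, min_efficiency))
  samples <- unique(ct_table$sample[ct_table$target == target])
  if (!length(samples)) stop("no Ct rows for target")
  dct <- vapply(samples, function(s)
    .mean_ct(ct_table, s, target) - .mean_ct(ct_table, s, normalizer),
    numeric(1))
  cal <- if (identical(calibrator, "auto"))
    samples[which.max(dct)] else calibrator
  if (!cal %in% samples) stop("calibrator sample not found")
  ddct <- dct - dct[samples == cal]
  rq <- (1 + efficiency)^(-ddct)
  rq[samples == cal] <- 1
  out <- data.frame(sample_id = samples, target_id = target,
                    delta_ct = unname(dct), delta_delta_ct = unname(ddct),
                    rq = unname(rq), method = "expression_eff_ddct",
                    calibrator_id = cal, stringsAsFactors = FALSE)
  class(out) <- c("relative_quantity", "data.frame")
  out
}

#' geNorm expression-stability measure M
#'
#' For each candidate normalizer j, `M_j` is the mean over the other genes
#' k of the standard deviation across samples of `log2(x_j / x_k)`. Lower
#' M means more stable; the conventional single-gene sufficiency threshold
#' is M < 0.15.
#'
#' @param expr numeric matrix of positive expression values, genes x
#'   samples (rownames = gene ids).
#' @return Data frame with `gene_id` and `M`, ordered as the input genes.
#' @export
genorm_m <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("need >= 2 candidate genes")
  if (ncol(expr) < 2) stop("need >= 2 samples")
  if (any(expr <= 0)) stop("expression values must be positive")
  genes <- rownames(expr)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(expr)))
  lexpr <- log2(expr)
  M <- vapply(seq_len(nrow(expr)), function(j) {
    others <- setdiff(seq_len(nrow(expr)), j)
    mean(vapply(others, function(k) sd(lexpr[j, ] - lexpr[k, ]), numeric(1)))
  }, numeric(1))
  data.frame(gene_id = genes, M = M, stringsAsFactors = FALSE)
}

#' One-way ANOVA with Fisher's LSD multiple comparisons
#'
#' One-way analysis of variance on replicate relative quantities; when the
#' omnibus test is significant at `alpha`, all pairwise groups are
#' compared by Fisher's least-significant-difference t tests on the pooled
#' mean squared error, and compact letter groupings are assigned (groups
#' sharing a letter do not differ at `alpha`). When the omnibus p is not
#' below `alpha`, no pairwise tests are run and all groups share one
#' letter.
#'
#' @param values numeric response (e.g. rq replicates).
#' @param groups group/condition labels, >= 2 groups with >= 2 replicates
#'   each.
#' @param alpha significance level (default 0.05).
#' @return Object of class `anova_lsd`: list with `F`, `p`, `df`,
#'   `mse`, `groups` (data frame: group, n, mean, letters), `pairwise`
#'   (data frame of pairwise tests, or `NULL`), `degenerate` (all-equal
#'   within-group values flag).
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  n_per <- table(groups)
  if (any(n_per < 2)) stop("need >= 2 replicates per group")
  N <- length(values)
  k <- nlevels(groups)
  means <- tapply(values, groups, mean)
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) /
    (N - k)
  degenerate <- mse <= .Machine$double.eps * max(1, stats::var(values))
  if (degenerate) {
    # zero within-group variance: exact separation
    p <- if (max(means) - min(means) == 0) 1 else 0
    Fstat <- if (p == 0) Inf else 0
  } else {
    a <- anova(aov(values ~ groups))
    Fstat <- a$`F value`[1]
    p <- a$`Pr(>F)`[1]
  }
  pairwise <- NULL
  lvl <- levels(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(lvl, lvl))
  if (p < alpha) {
    pr <- combn(k, 2)
    rows <- apply(pr, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      se <- sqrt(mse * (1 / n_per[i] + 1 / n_per[j]))
      tval <- if (se == 0) {
        if (means[i] == means[j]) 0 else Inf
      } else (means[i] - means[j]) / se
      pv <- if (is.infinite(tval)) 0 else
        2 * pt(abs(tval), df = N - k, lower.tail = FALSE)
      data.frame(group_a = lvl[i], group_b = lvl[j], diff = means[i] - means[j],
                 t = tval, p = pv, significant = pv < alpha,
                 stringsAsFactors = FALSE)
    })
    pairwise <- do.call(rbind, rows)
    for (r in seq_len(nrow(pairwise)))
      sig[pairwise$group_a[r], pairwise$group_b[r]] <-
      sig[pairwise$group_b[r], pairwise$group_a[r]] <- pairwise$significant[r]
  }
  letters_vec <- .lsd_letters(means, sig)
  grp <- data.frame(group = lvl, n = as.integer(n_per),
                    mean = as.numeric(means), letters = letters_vec[lvl],
                    stringsAsFactors = FALSE)
  structure(list(F = Fstat, p = p, df = c(k - 1L, N - k), mse = mse,
                 groups = grp, pairwise = pairwise,
                 degenerate = degenerate, alpha = alpha),
            class = "anova_lsd")
}

# compact letter display: maximal runs of mutually non-different groups in
# descending-mean order
.lsd_letters <- function(means, sig) {
  lvl <- names(means)[order(-means)]
  k <- length(lvl)
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[lvl[i:(j + 1)], lvl[i:(j + 1)]])) j <- j + 1
    intervals[[i]] <- c(i, j)
  }
  # drop intervals contained in another
  keep <- vapply(seq_along(intervals), function(i)
    !any(vapply(seq_along(intervals), function(j)
      j != i && intervals[[j]][1] <= intervals[[i]][1] &&
        intervals[[j]][2] >= intervals[[i]][2], logical(1))),
    logical(1))
  intervals <- intervals[keep]
  out <- setNames(rep("", k), lvl)
  for (t in seq_along(intervals)) {
    rng <- intervals[[t]]
    out[lvl[rng[1]:rng[2]]] <- paste0(out[lvl[rng[1]:rng[2]]],
                                      letters[(t - 1) %% 26 + 1])
  }
  out
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g%s\n",
              x$df[1], x$df[2], x$F, x$p,
              if (x$degenerate) " (degenerate: zero within-group variance)"
              else ""))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Read / write Ct tables as TSV
#'
#' Columns: `sample`, `group`, `target`, `replicate`, `ct` and optionally
#' `log10_conc`.
#'
#' @param ct_table data frame to write.
#' @param path file path.
#' @return `write_ct_tsv` invisibly returns `path`; `read_ct_tsv` returns
#'   the data frame.
#' @export
write_ct_tsv <- function(ct_table, path) {
  write.table(ct_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
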