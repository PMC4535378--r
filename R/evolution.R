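#' Kimura two-parameter distance from a pairwise alignment
#'
#' Computes the transition proportion P, transversion proportion Q and the
#' K2P distance `K = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]` over gap-free
#' alignment columns (pairwise deletion; columns containing non-ACGT bases
#' are also excluded).
#'
#' When the observed proportions are outside the model domain
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the distance is saturated: `K` is
#' `NA` and `saturated` is `TRUE` -- saturated distances are reported as
#' missing, never clamped.
#'
#' @param alignment a [align_pair_global()] result, or a list with
#'   `aligned_a` / `aligned_b` gapped strings of equal length.
#' @return An object of class `divergence_estimate`: list with `sites`
#'   (usable columns), `P`, `Q`, `K`, `saturated`.
#' @export
k2p_distance <- function(alignment) {
  a <- .seq_chars(alignment$aligned_a)
  b <- .seq_chars(alignment$aligned_b)
  if (length(a) != length(b)) stop("aligned strings differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) stop("no gap-free alignment columns")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  .k2p_from_pq(P, Q, n)
}

# shared constructor: the closed-form K2P evaluation
.k2p_from_pq <- function(P, Q, sites) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- (w1 <= 0) || (w2 <= 0)
  K <- if (saturated) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  structure(list(sites = as.integer(sites), P = P, Q = Q, K = K,
                 saturated = saturated),
            class = "divergence_estimate")
}

#' Kimura two-parameter distance from observed proportions
#'
#' @param P transition proportion; `P, Q >= 0`, `P + Q <= 1`.
#' @param Q transversion proportion.
#' @param sites number of compared sites (bookkeeping only).
#' @return A `divergence_estimate`, as for [k2p_distance()].
#' @export
k2p_from_pq <- function(P, Q, sites = NA_integer_) {
  if (P < 0 || Q < 0 || P + Q > 1) stop("invalid (P, Q)")
  .k2p_from_pq(P, Q, sites)
}

#' @export
print.divergence_estimate <- function(x, ...) {
  if (x$saturated)
    cat(sprintf("K2P: saturated (P=%.3f, Q=%.3f over %s sites)\n",
                x$P, x$Q, x$sites))
  else
    cat(sprintf("K2P: K=%.5f (P=%.3f, Q=%.3f over %s sites)\n",
                x$K, x$P, x$Q, x$sites))
  invisible(x)
}

#' Insertion time from LTR divergence
#'
#' `T = K / (2 r)`: the element's two LTRs are identical at integration and
#' each accumulates substitutions at rate `r`, so their divergence K grows
#' at `2 r` per year.
#'
#' @param K inter-LTR K2P divergence (substitutions/site, >= 0). `NA`
#'   (saturated) propagates.
#' @param r substitution rate in substitutions/site/year (default
#'   `1.5e-8`).
#' @return An object of class `age_estimate`: list with `K`, `r` and `T`
#'   (years).
#' @export
insertion_time <- function(K, r = .DEFAULT_RATE) {
  if (r <= 0) stop("r must be > 0")
  if (!is.na(K) && K < 0) stop("K must be >= 0")
  structure(list(K = K, r = r, T = K / (2 * r)), class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("insertion age: T = %.3g years (K = %.5g, r = %.3g)\n",
              x$T, x$K, x$r))
  invisible(x)
}

#' Date an element copy from its two LTRs
#'
#' Applies the paper-standard intactness criterion -- a full-length copy
#' with both LTRs delimited and a detected TSD -- then aligns the 5' and 3'
#' LTR globally, estimates K2P divergence and converts it to years.
#'
#' @param copy one row of a [find_copies()] table (or any list with
#'   `status`, `tsd`, `strand`, LTR interval fields).
#' @param genome the genome DNA string the copy lives on.
#' @param r substitution rate (substitutions/site/year).
#' @return An `age_estimate` with the `divergence_estimate` attached as
#'   attribute `divergence`; `T` is `NA` when the divergence is saturated.
#' @export
date_element <- function(copy, genome, r = .DEFAULT_RATE) {
  copy <- as.list(copy)
  if (is.na(copy$tsd) || !identical(copy$status, "full_length"))
    stop("not intact: dating requires a full-length copy with a TSD")
  ltrs <- extract_ltr_sequences(copy, genome)
  aln <- align_pair_global(ltrs$ltr5, ltrs$ltr3)
  dv <- k2p_distance(aln)
  age <- insertion_time(dv$K, r)
  attr(age, "divergence") <- dv
  age
}

#' Extract oriented LTR sequences of a copy
#'
#' @param copy a copy record with `strand` and LTR interval fields in
#'   genome coordinates.
#' @param genome genome DNA string.
#' @return List with `ltr5` and `ltr3` strings, in element orientation.
#' @export
extract_ltr_sequences <- function(copy, genome) {
  copy <- as.list(copy)
  if (is.na(copy$ltr5_start) || is.na(copy$ltr3_start))
    stop("LTR intervals not set")
  s5 <- .substr_seq(genome, copy$ltr5_start, copy$ltr5_end)
  s3 <- .substr_seq(genome, copy$ltr3_start, copy$ltr3_end)
  if (identical(copy$strand, "-")) {
    s5 <- revcomp(s5); s3 <- revcomp(s3)
  }
  list(ltr5 = s5, ltr3 = s3)
}

#' Per-family LTR nucleotide diversity
#'
#' Pi is the mean over all unordered sequence pairs of the per-site
#' difference proportion (differences / gap-free compared sites, pairwise
#' deletion), with its standard deviation across pairs.
#'
#' @param ltr_seqs character vector of >= 2 LTR sequences.
#' @param family_name label carried into the result.
#' @return An object of class `diversity_stat`: list with `family_name`,
#'   `n_sequences`, `Pi`, `sd`, `n_pairs`.
#' @export
ltr_diversity <- function(ltr_seqs, family_name = NA_character_) {
  n <- length(ltr_seqs)
  if (n < 2) stop("need >= 2 sequences")
  pairs <- combn(n, 2)
  pdist <- apply(pairs, 2, function(ij) {
    aln <- align_pair_global(ltr_seqs[ij[1]], ltr_seqs[ij[2]])
    a <- .seq_chars(aln$aligned_a); b <- .seq_chars(aln$aligned_b)
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (!any(ok)) return(NA_real_)
    sum(a[ok] != b[ok]) / sum(ok)
  })
  structure(list(family_name = family_name, n_sequences = n,
                 Pi = mean(pdist, na.rm = TRUE),
                 sd = if (ncol(pairs) > 1) sd(pdist, na.rm = TRUE) else 0,
                 n_pairs = ncol(pairs)),
            class = "diversity_stat")
}

#' @export
print.diversity_stat <- function(x, ...) {
  cat(sprintf("LTR diversity %s: Pi = %.4f (sd %.4f, %d sequences)\n",
              x$family_name, x$Pi, x$sd, x$n_sequences))
  invisible(x)
}
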