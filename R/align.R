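#' Exact global pairwise alignment
#'
#' Needleman-Wunsch/Gotoh global alignment under the package scoring scheme
#' (match +1, mismatch -1, gap open -3, gap extend -1; a gap of length L
#' costs open + (L-1) x extend). Traceback ties are broken
#' deterministically, preferring the diagonal move, then a gap in `seq_a`,
#' then a gap in `seq_b`, so the returned alignment is reproducible
#' bit-exactly.
#'
#' @param seq_a,seq_b DNA strings (non-empty).
#' @return An object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `matches`,
#'   `columns` (total alignment columns), and `identity`
#'   (matches / columns, terminal gap columns excluded).
#' @export
align_pair_global <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) stop("empty sequence")
  res <- nw_align_cpp(toupper(seq_a), toupper(seq_b),
                      .SCORING$match, .SCORING$mismatch,
                      .SCORING$gap_open, .SCORING$gap_extend)
  a <- .seq_chars(res$aligned_a)
  b <- .seq_chars(res$aligned_b)
  both <- a != "-" & b != "-"
  # terminal gap columns: leading/trailing runs where either side is gapped
  inner <- which(both)
  core <- if (length(inner)) seq(min(inner), max(inner)) else integer(0)
  matches <- sum(a[core] == b[core] & both[core] &
                   a[core] %in% c("A", "C", "G", "T"))
  columns <- length(core)
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, matches = matches, columns = columns,
                 identity = if (columns > 0) matches / columns else NA_real_,
                 n_both = sum(both)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: score %d, identity %.4f over %d columns\n",
              x$score, x$identity, x$columns))
  invisible(x)
}

# Fraction of the shorter sequence covered by both-base alignment columns;
# denominator choice for the 80-80 family rule.
.alignment_coverage <- function(aln) {
  la <- sum(.seq_chars(aln$aligned_a) != "-")
  lb <- sum(.seq_chars(aln$aligned_b) != "-")
  aln$n_both / min(la, lb)
}
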