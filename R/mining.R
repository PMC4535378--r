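#' Find copies of a reference element in a genome
#'
#' Seed-and-extend discovery: exact k-mer seeds (default k = 12) are
#' located on both strands, chained by implied start position, and each
#' candidate locus is aligned to the reference by banded local alignment
#' under the package scoring scheme. Identity is matches / alignment
#' columns (internal gaps count, terminal gaps excluded); coverage is the
#' aligned fraction of the reference length. Overlapping loci are resolved
#' to the best-scoring copy (higher identity, then longer reference).
#'
#' Every candidate is structurally annotated: reference LTR boundaries are
#' projected onto the copy and refined ([delimit_ltrs()]), TG..CA termini
#' are checked ([check_termini()]) and the target site duplication is
#' searched ([detect_tsd()]). Status is `"full_length"` only when the copy
#' passes the identity and coverage thresholds and the termini check;
#' otherwise the first failing filter is recorded
#' (`rejected_identity`, `rejected_coverage`, `rejected_termini`).
#'
#' @param genome genome DNA string (non-empty).
#' @param reference a [reference_element()] (>= 100 bp).
#' @param min_identity,min_coverage acceptance thresholds (default 0.80,
#'   the 80/80 rule).
#' @param k seed k-mer length.
#' @param min_seeds minimum seeds to open a candidate locus.
#' @param genome_id id recorded on each copy.
#' @return Data frame of element copies with columns `copy_id`,
#'   `genome_id`, `family`, `start`, `end`, `strand`, `identity`,
#'   `coverage`, `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`,
#'   `termini_ok`, `tsd`, `status`. LTR intervals are genome coordinates;
#'   for minus-strand copies the 5' LTR is the genome-rightmost interval.
#' @export
find_copies <- function(genome, reference, min_identity = 0.80,
                        min_coverage = 0.80, k = 12L, min_seeds = 3L,
                        genome_id = "genome") {
  if (nchar(genome) == 0) stop("empty genome")
  if (!inherits(reference, "reference_element")) stop("reference_element required")
  reflen <- nchar(reference$sequence)
  if (reflen < 100) stop("reference shorter than 100 bp")
  if (reflen < k) stop("reference shorter than seed length")

  cands <- c(.scan_strand(genome, reference, "+", k, min_seeds),
             .scan_strand(genome, reference, "-", k, min_seeds))
  if (length(cands) == 0) return(.empty_copies())

  cands <- .resolve_overlaps(cands)
  rows <- lapply(seq_along(cands), function(i)
    .annotate_candidate(cands[[i]], genome, reference, min_identity,
                        min_coverage, genome_id,
                        copy_id = sprintf("%s_hit%03d",
                                          reference$family_name, i)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  out$copy_id <- sprintf("%s_hit%03d", reference$family_name,
                         seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

.empty_copies <- function() {
  data.frame(copy_id = character(0), genome_id = character(0),
             family = character(0), start = integer(0), end = integer(0),
             strand = character(0), identity = numeric(0),
             coverage = numeric(0), ltr5_start = integer(0),
             ltr5_end = integer(0), ltr3_start = integer(0),
             ltr3_end = integer(0), termini_ok = logical(0),
             tsd = character(0), status = character(0),
             stringsAsFactors = FALSE)
}

# seed, chain and align one strand; returns a list of candidate records in
# FORWARD genome coordinates, each keeping its oriented projection
.scan_strand <- function(genome, reference, strand, k, min_seeds) {
  L <- nchar(genome)
  go <- if (strand == "-") revcomp(genome) else genome
  hits <- kmer_hits_cpp(reference$sequence, go, as.integer(k))
  if (nrow(hits) == 0) return(list())
  implied <- hits[, "genome_pos"] - hits[, "ref_pos"] + 1L
  implied <- sort(implied)
  reflen <- nchar(reference$sequence)
  # tight diagonal chaining: seeds of one locus share an implied start up
  # to small alignment drift; distinct loci (and the spurious diagonals
  # produced by the two identical reference LTRs) sit >= an LTR length
  # apart and must not merge
  brk <- 200L
  grp <- cumsum(c(1L, as.integer(diff(implied) > brk)))
  out <- list()
  pad <- 60L
  bw <- pad + 40L
  for (g in unique(grp)) {
    members <- implied[grp == g]
    if (length(members) < min_seeds) next
    est <- as.integer(stats::median(members))
    ws <- max(1L, est - pad)
    we <- min(L, est + reflen - 1L + pad)
    win <- .substr_seq(go, ws, we)
    off <- est - ws
    res <- local_align_banded_cpp(reference$sequence, win,
                                  band_lo = off - bw, band_hi = off + bw,
                                  .SCORING$match, .SCORING$mismatch,
                                  .SCORING$gap_open, .SCORING$gap_extend)
    if (res$columns < 30 || is.na(res$ref_start)) next
    s_o <- ws + res$win_start - 1L      # oriented genome coords
    e_o <- ws + res$win_end - 1L
    proj <- res$proj
    proj[!is.na(proj)] <- proj[!is.na(proj)] + ws - 1L
    fwd <- if (strand == "-") c(L - e_o + 1L, L - s_o + 1L) else c(s_o, e_o)
    out[[length(out) + 1L]] <- list(
      strand = strand, start = fwd[1], end = fwd[2],
      o_start = s_o, o_end = e_o,
      ref_start = res$ref_start, ref_end = res$ref_end,
      identity = res$matches / res$columns,
      coverage = (res$ref_end - res$ref_start + 1L) / reflen,
      score = res$score, reflen = reflen, proj = proj, genome_len = L)
  }
  out
}

# greedy best-first overlap resolution by alignment score (so partial
# sub-alignments -- e.g. one LTR of the same locus re-seeded by the other,
# identical, reference LTR -- lose to the full-locus alignment), then
# identity, then leftmost
.resolve_overlaps <- function(cands) {
  if (length(cands) <= 1) return(cands)
  ord <- order(-vapply(cands, `[[`, 0, "score"),
               -vapply(cands, `[[`, 0, "identity"),
               vapply(cands, `[[`, 0, "start"))
  kept <- list()
  for (i in ord) {
    ci <- cands[[i]]
    clash <- any(vapply(kept, function(kj) {
      ov <- min(ci$end, kj$end) - max(ci$start, kj$start) + 1L
      ov > 0.1 * min(ci$end - ci$start, kj$end - kj$start)
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- ci
  }
  kept
}

# fill projection gaps/ends by nearest-anchor arithmetic so every reference
# position maps to an (extrapolated) oriented genome position
.fill_projection <- function(proj) {
  n <- length(proj)
  anchors <- which(!is.na(proj))
  if (length(anchors) == 0) return(proj)
  filled <- proj
  for (p in seq_len(n)) {
    if (!is.na(proj[p])) next
    # nearest anchor
    a <- anchors[which.min(abs(anchors - p))]
    filled[p] <- proj[a] + (p - a)
  }
  filled
}

.annotate_candidate <- function(cand, genome, reference, min_identity,
                                min_coverage, genome_id, copy_id) {
  L <- cand$genome_len
  go <- if (cand$strand == "-") revcomp(genome) else genome
  ltrs <- tryCatch(
    .delimit_from_proj(.fill_projection(cand$proj), reference,
                       cand$o_start, cand$o_end, go),
    error = function(e) NULL)
  if (is.null(ltrs)) {
    l5 <- l3 <- c(NA_integer_, NA_integer_)
    termini_ok <- FALSE
  } else {
    l5 <- ltrs$ltr5; l3 <- ltrs$ltr3
    termini_ok <- .termini_ok_oriented(go, l5, l3)
  }
  # map oriented LTR intervals to forward coordinates
  o2f <- function(iv) {
    if (any(is.na(iv))) return(c(NA_integer_, NA_integer_))
    if (cand$strand == "-") c(L - iv[2] + 1L, L - iv[1] + 1L) else iv
  }
  f5 <- o2f(l5); f3 <- o2f(l3)

  row <- data.frame(
    copy_id = copy_id, genome_id = genome_id,
    family = reference$family_name,
    start = cand$start, end = cand$end, strand = cand$strand,
    identity = cand$identity, coverage = cand$coverage,
    ltr5_start = f5[1], ltr5_end = f5[2],
    ltr3_start = f3[1], ltr3_end = f3[2],
    termini_ok = termini_ok, tsd = NA_character_,
    status = "full_length", stringsAsFactors = FALSE)
  row$tsd <- suppressWarnings(detect_tsd(genome, row))
  row$status <-
    if (row$identity < min_identity) "rejected_identity"
    else if (row$coverage < min_coverage) "rejected_coverage"
    else if (!termini_ok) "rejected_termini"
    else "full_length"
  row
}

# project reference LTR boundaries through a filled projection and refine
# termini within +/- 3 bp; everything in ORIENTED genome coordinates
.delimit_from_proj <- function(proj, reference, o_start, o_end, go) {
  b <- c(reference$ltr5[1], reference$ltr5[2],
         reference$ltr3[1], reference$ltr3[2])
  pp <- proj[b]
  if (any(is.na(pp))) stop("projection outside copy")
  slack <- 3L
  if (pp[1] < o_start - slack || pp[4] > o_end + slack ||
      any(pp < 1) || any(pp > nchar(go)))
    stop("projection outside copy")
  # refine outer boundaries within +/- 3 bp: score each shift by the
  # TG../..CA terminal motif plus direct-repeat agreement with the
  # projected partner LTR boundary (the two LTRs are a direct repeat, so
  # the true 5' start matches the 3' LTR start better than a chance TG in
  # the flank); ties resolve to the smallest shift, left first
  L <- nchar(go)
  kmers_match <- function(p, q, len) {
    if (p < 1 || q < 1 || p + len - 1 > L || q + len - 1 > L) return(0L)
    sum(.seq_chars(.substr_seq(go, p, p + len - 1)) ==
          .seq_chars(.substr_seq(go, q, q + len - 1)))
  }
  shifts <- c(0L, -1L, 1L, -2L, 2L, -3L, 3L)
  s0 <- pp[1]
  sc_s <- vapply(shifts, function(d) {
    s <- s0 + d
    if (s < 1 || s + 1 > L) return(-Inf)
    4 * (.substr_seq(go, s, s + 1L) == "TG") + kmers_match(s, pp[3], 8L)
  }, numeric(1))
  s <- s0 + shifts[which.max(sc_s)]
  e0 <- pp[4]
  sc_e <- vapply(shifts, function(d) {
    e <- e0 + d
    if (e - 1 < 1 || e > L) return(-Inf)
    4 * (.substr_seq(go, e - 1L, e) == "CA") +
      kmers_match(e - 7L, pp[2] - 7L, 8L)
  }, numeric(1))
  e <- e0 + shifts[which.max(sc_e)]
  list(ltr5 = c(s, pp[2] + (s - s0)), ltr3 = c(pp[3] + (e - e0), e))
}

.termini_ok_oriented <- function(go, ltr5, ltr3) {
  if (any(is.na(c(ltr5, ltr3)))) return(FALSE)
  .substr_seq(go, ltr5[1], ltr5[1] + 1L) == "TG" &&
    .substr_seq(go, ltr3[2] - 1L, ltr3[2]) == "CA"
}

#' Delimit the LTRs of a copy by reference projection
#'
#' Re-aligns the copy region to its reference (banded local alignment),
#' projects the reference LTR boundaries through the alignment onto the
#' genome and refines the outer boundaries within +/- 3 bp toward the
#' TG../..CA terminal motifs.
#'
#' @param copy one row of a [find_copies()] table (needs `start`, `end`,
#'   `strand`).
#' @param reference the copy's [reference_element()].
#' @param genome genome DNA string.
#' @return List with `ltr5` and `ltr3` integer intervals in genome
#'   coordinates (for minus-strand copies `ltr5` is genome-rightmost).
#'   Errors with "projection outside copy" when a reference LTR does not
#'   project into the aligned copy.
#' @export
delimit_ltrs <- function(copy, reference, genome) {
  copy <- as.list(copy)
  L <- nchar(genome)
  go <- if (identical(copy$strand, "-")) revcomp(genome) else genome
  o_iv <- if (identical(copy$strand, "-"))
    c(L - copy$end + 1L, L - copy$start + 1L) else c(copy$start, copy$end)
  pad <- 30L
  ws <- max(1L, o_iv[1] - pad)
  we <- min(L, o_iv[2] + pad)
  win <- .substr_seq(go, ws, we)
  off <- o_iv[1] - ws
  bw <- pad + 40L
  res <- local_align_banded_cpp(reference$sequence, win,
                                band_lo = off - bw, band_hi = off + bw,
                                .SCORING$match, .SCORING$mismatch,
                                .SCORING$gap_open, .SCORING$gap_extend)
  if (is.na(res$ref_start)) stop("projection outside copy")
  proj <- res$proj
  proj[!is.na(proj)] <- proj[!is.na(proj)] + ws - 1L
  # restrict anchors to the aligned copy: positions outside [o_start,o_end]
  # would extrapolate past the copy
  ltrs <- .delimit_from_proj(.fill_projection(proj), reference,
                             o_iv[1], o_iv[2], go)
  o2f <- function(iv) if (identical(copy$strand, "-"))
    c(L - iv[2] + 1L, L - iv[1] + 1L) else iv
  list(ltr5 = o2f(ltrs$ltr5), ltr3 = o2f(ltrs$ltr3))
}

#' Check canonical TG..CA termini
#'
#' `TRUE` iff the first two bases of the 5' LTR are `TG` and the last two
#' bases of the 3' LTR are `CA`, read in element orientation. N bases never
#' match.
#'
#' @param copy a copy record with strand and LTR intervals (genome
#'   coordinates).
#' @param genome genome DNA string.
#' @return Logical.
#' @export
check_termini <- function(copy, genome) {
  copy <- as.list(copy)
  if (any(is.na(c(copy$ltr5_start, copy$ltr3_start)))) stop("LTR intervals not set")
  ltrs <- extract_ltr_sequences(copy, genome)
  n3 <- nchar(ltrs$ltr3)
  substr(ltrs$ltr5, 1, 2) == "TG" && substr(ltrs$ltr3, n3 - 1, n3) == "CA"
}

#' Detect the target site duplication of a copy
#'
#' Compares the k-mer immediately 5' of the copy with the k-mer
#' immediately 3' of it, for k from `max_len` down to `min_len`, and
#' returns the longest exact match (N never matches). Strand-symmetric, so
#' flanks are read on the forward genome strand.
#'
#' @param genome genome DNA string.
#' @param copy a copy record with `start`/`end` genome coordinates.
#' @param min_len,max_len TSD length range searched (default 4-6 bp).
#' @return The TSD string (forward strand), or `NA` if none (with a
#'   warning when the copy sits at a contig edge).
#' @export
detect_tsd <- function(genome, copy, min_len = 4L, max_len = 6L) {
  copy <- as.list(copy)
  L <- nchar(genome)
  if (copy$start - max_len < 1 || copy$end + max_len > L) {
    warning("copy at contig edge; TSD undetectable")
    return(NA_character_)
  }
  for (k in seq(max_len, min_len)) {
    left <- .substr_seq(genome, copy$start - k, copy$start - 1L)
    right <- .substr_seq(genome, copy$end + 1L, copy$end + k)
    if (left == right && !grepl("[^ACGT]", left)) return(left)
  }
  NA_character_
}

#' Detect the polypurine tract upstream of the 3' LTR
#'
#' Scans the `window` bp immediately upstream (element orientation) of the
#' 3' LTR for the longest run of purines (A/G on the element strand) of at
#' least `min_len` bp; ties go to the run nearest the LTR.
#'
#' @param copy a copy record with strand and 3' LTR interval.
#' @param genome genome DNA string.
#' @param window search window in bp upstream of the 3' LTR.
#' @param min_len minimum run length.
#' @return Integer `c(start, end)` interval in forward genome coordinates,
#'   or `NULL` if no qualifying run.
#' @export
detect_ppt <- function(copy, genome, window = 50L, min_len = 10L) {
  copy <- as.list(copy)
  if (is.na(copy$ltr3_start)) stop("3' LTR interval not set")
  L <- nchar(genome)
  minus <- identical(copy$strand, "-")
  if (!minus) {
    rs <- max(1L, copy$ltr3_start - window)
    re <- copy$ltr3_start - 1L
    if (re < rs) return(NULL)
    region <- .substr_seq(genome, rs, re)
  } else {
    rs <- copy$ltr3_end + 1L
    re <- min(L, copy$ltr3_end + window)
    if (re < rs) return(NULL)
    region <- revcomp(.substr_seq(genome, rs, re))
  }
  ch <- .seq_chars(region)
  pur <- ch %in% c("A", "G")
  r <- rle(pur)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_len)
  if (!length(ok)) return(NULL)
  # longest run; ties -> nearest the 3' LTR (largest start in element frame)
  best <- ok[order(-r$lengths[ok], -starts[ok])][1]
  iv <- c(starts[best], ends[best])
  if (!minus) rs + iv - 1L else sort(re - iv + 1L)
}

#' Per-window counts of full-length copies
#'
#' Tabular genome-distribution summary: counts of full-length copies per
#' fixed-width window, by genome. Each copy is assigned to the window
#' containing its start.
#'
#' @param copies a [find_copies()]-style data frame.
#' @param genome_lengths named integer vector of genome lengths.
#' @param window_bp window width (> 0).
#' @return Data frame with `genome_id`, `window_start`, `window_end`,
#'   `n_copies`.
#' @export
copy_density <- function(copies, genome_lengths, window_bp) {
  stopifnot(window_bp > 0, !is.null(names(genome_lengths)))
  fl <- copies[copies$status == "full_length", , drop = FALSE]
  out <- lapply(names(genome_lengths), function(g) {
    len <- genome_lengths[[g]]
    starts <- seq(1L, len, by = window_bp)
    cnt <- integer(length(starts))
    sub <- fl[fl$genome_id == g, , drop = FALSE]
    if (nrow(sub)) {
      w <- pmin(((sub$start - 1L) %/% window_bp) + 1L, length(starts))
      t <- table(w)
      cnt[as.integer(names(t))] <- as.integer(t)
    }
    data.frame(genome_id = g, window_start = starts,
               window_end = pmin(starts + window_bp - 1L, len),
               n_copies = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write mined copies as GFF3
#'
#' @param copies a [find_copies()] data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_copies_gff3 <- function(copies, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = copies$genome_id,
    ranges = IRanges::IRanges(start = copies$start, end = copies$end),
    strand = copies$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "retrofam", type = "LTR_retrotransposon",
    ID = copies$copy_id, family = copies$family,
    identity = round(copies$identity, 4),
    coverage = round(copies$coverage, 4),
    tsd = copies$tsd, termini_ok = copies$termini_ok,
    status = copies$status)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Mine a genome against a panel of reference elements
#'
#' Runs [find_copies()] for each reference and resolves cross-reference
#' overlaps to the copy with the highest identity (ties to the longer
#' reference).
#'
#' @param genome genome DNA string.
#' @param references list of [reference_element()]s.
#' @param ... passed to [find_copies()].
#' @return Combined copies data frame (genome coordinate order).
#' @export
mine_genome <- function(genome, references, ...) {
  if (inherits(references, "reference_element")) references <- list(references)
  per_ref <- lapply(references, function(r) find_copies(genome, r, ...))
  all <- do.call(rbind, per_ref)
  if (nrow(all) <= 1) return(all)
  reflen <- setNames(vapply(references, function(r) nchar(r$sequence), 0),
                     vapply(references, `[[`, "", "family_name"))
  ord <- order(-all$identity, -reflen[all$family], all$start)
  keep <- logical(nrow(all))
  for (i in ord) {
    clash <- FALSE
    for (j in which(keep)) {
      ov <- min(all$end[i], all$end[j]) - max(all$start[i], all$start[j]) + 1L
      if (ov > 0.1 * min(all$end[i] - all$start[i],
                         all$end[j] - all$start[j])) { clash <- TRUE; break }
    }
    if (!clash) keep[i] <- TRUE
  }
  out <- all[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
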