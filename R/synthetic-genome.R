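#' Simulation configuration
#'
#' Bundles the parameters shared by the genome/insertion simulator: the
#' neutral substitution rate used to translate insertion age into expected
#' divergence, the transition/transversion rate ratio of the substitution
#' process, the target-site-duplication length and the Ct noise level for
#' simulated qPCR tables.
#'
#' @param seed integer seed; a fixed seed makes all simulator output
#'   byte-identical across runs.
#' @param genome_length background genome length in bp.
#' @param gc_content background GC fraction in `[0, 1]`.
#' @param rate substitution rate in substitutions/site/year (default
#'   `1.5e-8`, the per-lineage rate commonly applied to plant LTR
#'   retrotransposon dating).
#' @param kappa transition/transversion rate ratio (>= 0).
#' @param tsd_length target site duplication length; must be 4, 5 or 6 bp,
#'   the canonical range for LTR retrotransposons.
#' @param noise_sd_ct Gaussian noise SD, in Ct cycles, for simulated qPCR.
#' @param mutate_termini if `FALSE` (default) the two terminal bases of each
#'   LTR (the TG../..CA motif) are exempt from simulated substitution, so
#'   termini checks can be exercised independently of element age.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 5e5, gc_content = 0.5,
                       rate = 1.5e-8, kappa = 2, tsd_length = 5L,
                       noise_sd_ct = 0, mutate_termini = FALSE) {
  stopifnot(genome_length > 0, rate > 0, kappa >= 0, noise_sd_ct >= 0)
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0,1]")
  if (!tsd_length %in% 4:6) stop("tsd_length must be 4, 5 or 6")
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 gc_content = gc_content, rate = rate, kappa = kappa,
                 tsd_length = as.integer(tsd_length),
                 noise_sd_ct = noise_sd_ct, mutate_termini = mutate_termini),
            class = "sim_config")
}

#' Generate a random background genome
#'
#' Bases are drawn i.i.d. with the requested GC content (G and C
#' equiprobable, likewise A and T).
#'
#' @param length genome length in bp (> 0).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A DNA string of the requested length.
#' @export
generate_background_genome <- function(length, gc = 0.5, seed = NULL) {
  if (length <= 0) stop("length must be > 0")
  if (gc < 0 || gc > 1) stop("gc must be in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  .chars_seq(sample(names(p), length, replace = TRUE, prob = p))
}

# K80 per-site change probabilities after expected `d` substitutions/site.
# alpha = transition rate, beta = each transversion rate, alpha/beta = kappa,
# normalized so alpha + 2*beta = d.
.k80_probs <- function(d, kappa) {
  if (is.infinite(kappa)) {
    # pure-transition limit: two-state chain at rate d
    p_ts <- (1 - exp(-2 * d)) / 2
    return(c(same = 1 - p_ts, ts = p_ts, tv = 0))
  }
  beta <- d / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta)
  e2 <- exp(-2 * (alpha + beta))
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts   <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv   <- 0.25 - 0.25 * e1            # each of the two transversions
  c(same = p_same, ts = p_ts, tv = p_tv)
}

#' Evolve a sequence under the Kimura two-parameter model
#'
#' Applies the full K80 Markov substitution process (back-mutations and
#' multiple hits included) site-independently for an expected
#' `branch_length` substitutions per site. Non-ACGT bases are left
#' untouched.
#'
#' @param seq DNA string.
#' @param branch_length expected substitutions per site (>= 0).
#' @param kappa transition/transversion rate ratio; `Inf` gives the
#'   pure-transition limit.
#' @param seed optional integer seed.
#' @param mask integer vector of 1-based positions exempt from mutation.
#' @return The mutated DNA string, with attribute `n_diff` giving the number
#'   of sites that differ from the input (the realized Hamming distance).
#' @export
evolve_sequence_k2p <- function(seq, branch_length, kappa = 2, seed = NULL,
                                mask = NULL) {
  if (branch_length < 0) stop("branch_length must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ch <- .seq_chars(seq)
  n <- length(ch)
  if (branch_length == 0 || n == 0) {
    out <- .chars_seq(ch)
    attr(out, "n_diff") <- 0L
    return(out)
  }
  pr <- .k80_probs(branch_length, kappa)
  # categories: 1 stay, 2 transition, 3/4 the two transversions
  cat <- sample.int(4L, n, replace = TRUE,
                    prob = c(pr["same"], pr["ts"], pr["tv"], pr["tv"]))
  if (!is.null(mask) && length(mask)) cat[mask] <- 1L
  ts_map  <- c(A = "G", G = "A", C = "T", T = "C")
  tv1_map <- c(A = "C", G = "C", C = "A", T = "A")
  tv2_map <- c(A = "T", G = "T", C = "G", T = "G")
  acgt <- ch %in% c("A", "C", "G", "T")
  new <- ch
  i2 <- which(cat == 2L & acgt); new[i2] <- ts_map[ch[i2]]
  i3 <- which(cat == 3L & acgt); new[i3] <- tv1_map[ch[i3]]
  i4 <- which(cat == 4L & acgt); new[i4] <- tv2_map[ch[i4]]
  out <- .chars_seq(new)
  attr(out, "n_diff") <- sum(new != ch)
  out
}

#' Construct a reference element
#'
#' A reference full-length LTR retrotransposon: its sequence, superfamily,
#' lineage and the coordinates (1-based, inclusive) of its two LTRs. The
#' element must start at the 5' LTR start and end at the 3' LTR end.
#'
#' @param family_name family label, e.g. `"RLC_egAle_1"`.
#' @param superfamily `"Copia"` or `"Gypsy"`.
#' @param lineage lineage label, e.g. `"Ale"`.
#' @param sequence element DNA string.
#' @param ltr5,ltr3 integer `c(start, end)` of the 5' and 3' LTR within
#'   `sequence`.
#' @return An object of class `reference_element`.
#' @export
reference_element <- function(family_name, superfamily, lineage, sequence,
                              ltr5, ltr3) {
  n <- nchar(sequence)
  stopifnot(length(ltr5) == 2, length(ltr3) == 2)
  if (ltr5[1] != 1L || ltr3[2] != n)
    stop("element must start at the 5' LTR start and end at the 3' LTR end")
  if (ltr5[2] >= ltr3[1]) stop("LTR intervals must not overlap, 5' before 3'")
  structure(list(family_name = family_name, superfamily = superfamily,
                 lineage = lineage, sequence = sequence,
                 ltr5 = as.integer(ltr5), ltr3 = as.integer(ltr3)),
            class = "reference_element")
}

#' Simulate a reference element with identical TG..CA LTRs
#'
#' @param family_name,superfamily,lineage labels stored on the element.
#' @param ltr_length LTR length in bp (>= 50).
#' @param internal_length internal-region length in bp.
#' @param gc GC fraction of the random sequence.
#' @param seed optional integer seed.
#' @return A [reference_element()] whose 5' and 3' LTRs are byte-identical,
#'   begin with `TG` and end with `CA`.
#' @export
simulate_reference_element <- function(family_name = "RLC_egSim_1",
                                       superfamily = "Copia",
                                       lineage = "Sim",
                                       ltr_length = 1000,
                                       internal_length = 3000,
                                       gc = 0.5, seed = NULL) {
  stopifnot(ltr_length >= 50, internal_length >= 0)
  if (!is.null(seed)) set.seed(seed)
  ltr <- generate_background_genome(ltr_length, gc)
  substr(ltr, 1, 2) <- "TG"
  substr(ltr, ltr_length - 1, ltr_length) <- "CA"
  internal <- if (internal_length > 0)
    generate_background_genome(internal_length, gc) else ""
  seq <- paste0(ltr, internal, ltr)
  reference_element(family_name, superfamily, lineage, seq,
                    ltr5 = c(1L, ltr_length),
                    ltr3 = c(ltr_length + internal_length + 1L,
                             2L * ltr_length + internal_length))
}

#' Plant one element insertion into a genome
#'
#' Realizes the standard dating assumption that the two LTRs are identical
#' at integration: both LTRs are evolved independently from the reference
#' LTR with branch length `rate * age` (so their expected mutual divergence
#' is `2 * rate * age`), the internal region is evolved at the same rate,
#' and the insertion is flanked by an exact duplication of the target site
#' (`tsd_length` bp).
#'
#' @param genome background genome DNA string.
#' @param reference a [reference_element()] with identical TG..CA LTRs.
#' @param age insertion age in years (>= 0).
#' @param config a [sim_config()]; supplies rate, kappa, TSD length and the
#'   termini-masking policy.
#' @param position optional 1-based target-site start; drawn uniformly away
#'   from the contig edges when `NULL`.
#' @param copy_id identifier recorded in the truth table.
#' @return A list with elements `genome` (the genome after insertion) and
#'   `truth` (one-row data frame: copy_id, family, age_years, start/end of
#'   the inserted element, LTR intervals, TSD sequence, realized identity to
#'   the reference).
#' @export
plant_insertion <- function(genome, reference, age, config = sim_config(),
                            position = NULL, copy_id = "copy_1") {
  if (age < 0) stop("age must be >= 0")
  if (!inherits(reference, "reference_element"))
    stop("reference lacks LTR annotation")
  L <- nchar(genome)
  tsd_len <- config$tsd_length
  if (is.null(position)) {
    lo <- tsd_len + 10L
    hi <- L - 2L * tsd_len - 10L
    if (hi < lo) stop("genome too short for insertion")
    position <- sample(lo:hi, 1L)
  }
  if (position < 2 || position + tsd_len - 1 >= L)
    stop("insertion position leaves no flanking sequence")

  branch <- config$rate * age
  ltr_len5 <- reference$ltr5[2] - reference$ltr5[1] + 1L
  ltr_len3 <- reference$ltr3[2] - reference$ltr3[1] + 1L
  ltr_ref5 <- .substr_seq(reference$sequence, reference$ltr5[1], reference$ltr5[2])
  ltr_ref3 <- .substr_seq(reference$sequence, reference$ltr3[1], reference$ltr3[2])
  if (substr(ltr_ref5, 1, 2) != "TG" ||
      substr(ltr_ref3, ltr_len3 - 1, ltr_len3) != "CA")
    stop("reference LTRs must start TG and end CA")
  internal <- .substr_seq(reference$sequence, reference$ltr5[2] + 1L,
                          reference$ltr3[1] - 1L)

  mask5 <- mask3 <- NULL
  if (!config$mutate_termini) {
    mask5 <- c(1L, 2L, ltr_len5 - 1L, ltr_len5)
    mask3 <- c(1L, 2L, ltr_len3 - 1L, ltr_len3)
  }
  ltr5_new <- evolve_sequence_k2p(ltr_ref5, branch, config$kappa, mask = mask5)
  ltr3_new <- evolve_sequence_k2p(ltr_ref3, branch, config$kappa, mask = mask3)
  int_new <- if (nchar(internal) > 0)
    evolve_sequence_k2p(internal, branch, config$kappa) else ""
  element <- paste0(ltr5_new, int_new, ltr3_new)
  elen <- nchar(element)
  n_diff <- attr(ltr5_new, "n_diff") + attr(ltr3_new, "n_diff") +
    (if (nchar(internal) > 0) attr(int_new, "n_diff") else 0L)

  tsd <- .substr_seq(genome, position, position + tsd_len - 1L)
  genome_new <- paste0(.substr_seq(genome, 1L, position + tsd_len - 1L),
                       element,
                       .substr_seq(genome, position, L))
  el_start <- position + tsd_len
  truth <- data.frame(
    copy_id = copy_id, family = reference$family_name,
    age_years = age, start = el_start, end = el_start + elen - 1L,
    strand = "+",
    ltr5_start = el_start, ltr5_end = el_start + ltr_len5 - 1L,
    ltr3_start = el_start + elen - ltr_len3, ltr3_end = el_start + elen - 1L,
    tsd = tsd, realized_identity = 1 - n_diff / elen,
    stringsAsFactors = FALSE)
  list(genome = genome_new, truth = truth)
}

#' Simulate a genome with planted element copies
#'
#' Generates a random background genome and plants copies of one or more
#' reference elements at non-overlapping sites, recording full ground truth
#' for each copy.
#'
#' @param config a [sim_config()]; `config$seed` seeds the whole simulation.
#' @param references a single [reference_element()] or a list of them.
#' @param n_copies integer vector (recycled over references): copies per
#'   reference.
#' @param ages ages in years; a vector recycled over all copies, or a list
#'   parallel to `references`.
#' @return A list with `genome` (DNA string) and `truth` (data frame, one
#'   row per planted copy, in genome coordinate order).
#' @export
simulate_genome <- function(config, references, n_copies = 10L, ages = 1e6) {
  if (inherits(references, "reference_element")) references <- list(references)
  set.seed(config$seed)
  genome <- generate_background_genome(config$genome_length, config$gc_content)

  n_copies <- rep_len(n_copies, length(references))
  total <- sum(n_copies)
  ref_idx <- rep(seq_along(references), n_copies)
  if (is.list(ages)) {
    age_vec <- unlist(lapply(seq_along(references), function(i)
      rep_len(ages[[i]], n_copies[i])))
  } else age_vec <- rep_len(ages, total)

  # non-overlapping original target sites, away from contig edges
  margin <- 200L
  min_gap <- 50L
  for (try in 1:200) {
    pos <- sort(sample(seq.int(margin, config$genome_length - margin), total))
    if (total < 2 || all(diff(pos) >= min_gap)) break
    if (try == 200) stop("could not place non-overlapping insertions")
  }
  ord <- sample.int(total)   # which copy goes at which site
  truth <- vector("list", total)
  offset <- 0L
  for (s in seq_len(total)) {
    k <- ord[s]
    ref <- references[[ref_idx[k]]]
    res <- plant_insertion(genome, ref, age_vec[k], config,
                           position = pos[s] + offset,
                           copy_id = sprintf("copy_%03d", k))
    genome <- res$genome
    truth[[s]] <- res$truth
    offset <- offset + (res$truth$end - res$truth$start + 1L) +
      config$tsd_length
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

#' Write a truth table as GFF3
#'
#' @param truth truth data frame from [simulate_genome()].
#' @param genome_id sequence id to use in column 1.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_truth_gff3 <- function(truth, genome_id, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genome_id,
    ranges = IRanges::IRanges(start = truth$start, end = truth$end),
    strand = truth$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "retrofam_sim", type = "LTR_retrotransposon",
    ID = truth$copy_id, family = truth$family,
    age_years = truth$age_years, tsd = truth$tsd)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
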