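#' Simulate a qPCR Ct table
#'
#' Quantification cycles are generated from the standard exponential
#' amplification model, `Ct = baseline - log(quantity) / log(1 + E)`, with
#' optional homoscedastic Gaussian noise and a technical-replicate
#' structure.
#'
#' @param design data frame with columns `sample`, `target`, `quantity`
#'   (true relative template quantity, > 0) and optionally `efficiency`
#'   (per-target amplification efficiency E as a fraction in (0, 1.1],
#'   default 1) and `group` (condition label carried through).
#' @param baseline_ct Ct of one quantity unit at the given efficiency.
#' @param noise_sd Gaussian noise SD in cycles (>= 0).
#' @param replicates technical replicates per (sample, target).
#' @param seed optional integer seed.
#' @return Data frame with columns `sample`, `group`, `target`,
#'   `replicate`, `ct`.
#' @export
simulate_ct_table <- function(design, baseline_ct = 30, noise_sd = 0,
                              replicates = 3L, seed = NULL) {
  stopifnot(all(c("sample", "target", "quantity") %in% names(design)),
            replicates >= 1, noise_sd >= 0)
  if (any(design$quantity <= 0)) stop("quantities must be > 0")
  eff <- if ("efficiency" %in% names(design)) design$efficiency else
    rep(1, nrow(design))
  if (any(eff <= 0 | eff > 1.1)) stop("efficiencies must be in (0, 1.1]")
  if (!is.null(seed)) set.seed(seed)
  grp <- if ("group" %in% names(design)) design$group else
    rep(NA_character_, nrow(design))
  idx <- rep(seq_len(nrow(design)), each = replicates)
  ct0 <- baseline_ct - log(design$quantity[idx]) / log(1 + eff[idx])
  noise <- if (noise_sd > 0) rnorm(length(idx), 0, noise_sd) else 0
  data.frame(sample = design$sample[idx], group = grp[idx],
             target = design$target[idx],
             replicate = rep(seq_len(replicates), nrow(design)),
             ct = ct0 + noise, stringsAsFactors = FALSE)
}

#' Simulate a dilution-series Ct table for standard curves
#'
#' @param concentrations template concentrations (e.g. ng/ul); default the
#'   six-point series 5e-1 .. 5e-6.
#' @param efficiency amplification efficiency E (fraction).
#' @param baseline_ct Ct at concentration 1.
#' @param noise_sd,replicates,seed as in [simulate_ct_table()].
#' @param target target label.
#' @return Data frame with columns `sample`, `target`, `replicate`, `ct`,
#'   `log10_conc`.
#' @export
simulate_dilution_series <- function(concentrations = 5 * 10^-(1:6),
                                     efficiency = 1, baseline_ct = 12,
                                     noise_sd = 0, replicates = 3L,
                                     target = "target", seed = NULL) {
  stopifnot(length(concentrations) >= 2, all(concentrations > 0))
  design <- data.frame(sample = sprintf("dil_%02d", seq_along(concentrations)),
                       target = target, quantity = concentrations,
                       efficiency = efficiency, stringsAsFactors = FALSE)
  ct <- simulate_ct_table(design, baseline_ct = baseline_ct,
                          noise_sd = noise_sd, replicates = replicates,
                          seed = seed)
  ct$log10_conc <- log10(concentrations)[match(ct$sample, design$sample)]
  ct
}

#' Marker matrix constructor
#'
#' Individuals x loci binary band table for dominant marker systems
#' (IRAP/REMAP), with species labels per individual and primer-of-origin
#' labels per locus.
#'
#' @param bands binary matrix, rownames = individual ids (unique),
#'   colnames = locus ids.
#' @param species character vector of species labels, one per individual.
#' @param primer optional character vector of primer labels, one per locus.
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(bands, species, primer = NULL) {
  bands <- as.matrix(bands)
  if (!all(bands %in% c(0, 1))) stop("band values must be 0/1")
  if (is.null(rownames(bands)) || anyDuplicated(rownames(bands)))
    stop("individual ids must be present and unique")
  if (length(species) != nrow(bands))
    stop("one species label per individual required")
  if (is.null(primer)) primer <- rep("P1", ncol(bands))
  if (length(primer) != ncol(bands))
    stop("one primer label per locus required")
  structure(list(bands = bands,
                 species = setNames(as.character(species), rownames(bands)),
                 primer = setNames(as.character(primer), colnames(bands))),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d individuals x %d loci, %d species, %d primers\n",
              nrow(x$bands), ncol(x$bands), length(unique(x$species)),
              length(unique(x$primer))))
  invisible(x)
}

#' Simulate a species-structured binary marker matrix
#'
#' Each locus receives a species presence pattern: with probability
#' `1 - between_species_divergence` it is shared by all species, otherwise
#' each species carries it independently with probability 1/2. Individuals
#' then show a band at a species-carried locus with probability
#' `within_species_band_freq` (and never at a locus their species lacks),
#' so loci are fixed-within/variable-between at the stated rates.
#'
#' @param n_species number of species.
#' @param n_per_species individuals per species.
#' @param n_loci number of loci (bands).
#' @param within_species_band_freq band frequency within carrier species.
#' @param between_species_divergence fraction of loci with species-specific
#'   patterns.
#' @param n_primers number of primers the loci are attributed to
#'   (round-robin).
#' @param seed optional integer seed.
#' @return A [marker_matrix()].
#' @export
simulate_marker_matrix <- function(n_species = 5, n_per_species = 10,
                                   n_loci = 60,
                                   within_species_band_freq = 0.9,
                                   between_species_divergence = 0.3,
                                   n_primers = 4, seed = NULL) {
  stopifnot(n_species > 0, n_per_species > 0, n_loci > 0, n_primers > 0)
  if (within_species_band_freq < 0 || within_species_band_freq > 1 ||
      between_species_divergence < 0 || between_species_divergence > 1)
    stop("frequencies must be in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  divergent <- runif(n_loci) < between_species_divergence
  pattern <- matrix(1L, n_species, n_loci)
  if (any(divergent))
    pattern[, divergent] <- matrix(
      as.integer(runif(n_species * sum(divergent)) < 0.5),
      n_species, sum(divergent))
  sp <- rep(sprintf("sp%d", seq_len(n_species)), each = n_per_species)
  ids <- sprintf("%s_i%02d", sp, rep(seq_len(n_per_species), n_species))
  carried <- pattern[rep(seq_len(n_species), each = n_per_species), ,
                     drop = FALSE]
  bands <- carried *
    matrix(as.integer(runif(length(sp) * n_loci) < within_species_band_freq),
           length(sp), n_loci)
  rownames(bands) <- ids
  colnames(bands) <- sprintf("L%03d", seq_len(n_loci))
  primer <- sprintf("P%d", ((seq_len(n_loci) - 1L) %% n_primers) + 1L)
  marker_matrix(bands, sp, primer)
}

#' Write / read a marker matrix as TSV
#'
#' Rows are individuals with a `species` column; loci columns are prefixed
#' with their primer label (`primer.locus`).
#'
#' @param x a [marker_matrix()].
#' @param path file path.
#' @return `write_marker_tsv` invisibly returns `path`; `read_marker_tsv`
#'   returns a [marker_matrix()].
#' @export
write_marker_tsv <- function(x, path) {
  stopifnot(inherits(x, "marker_matrix"))
  df <- data.frame(individual = rownames(x$bands),
                   species = unname(x$species), x$bands,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[-(1:2)] <- paste(x$primer, colnames(x$bands), sep = ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_tsv
#' @export
read_marker_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  bands <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(bands) <- df$individual
  parts <- strsplit(colnames(bands), ".", fixed = TRUE)
  primer <- vapply(parts, `[`, character(1), 1L)
  locus <- vapply(parts, function(p) paste(p[-1], collapse = "."), character(1))
  colnames(bands) <- locus
  marker_matrix(bands, df$species, primer)
}
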