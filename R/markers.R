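#' Jaccard similarity matrix from dominant marker bands
#'
#' `GSj(i, j) = a / (a + b + c)` with `a` the shared band presences and
#' `b`, `c` the presences unique to each individual; shared absences are
#' ignored. Individuals with zero bands have undefined similarity against
#' everybody and are dropped with a warning. Pairs with `a + b + c = 0`
#' are set `NA` and flagged in the `undefined_pairs` attribute.
#'
#' @param x a [marker_matrix()] or a binary individuals x loci matrix.
#' @return Symmetric similarity matrix (class `similarity_matrix`) with
#'   unit diagonal.
#' @export
jaccard_matrix <- function(x) {
  bands <- if (inherits(x, "marker_matrix")) x$bands else as.matrix(x)
  if (!all(bands %in% c(0, 1))) stop("band values must be 0/1")
  if (nrow(bands) < 2) stop("need >= 2 individuals")
  empty <- rowSums(bands) == 0
  if (any(empty)) {
    warning("dropping individuals with zero bands: ",
            paste(rownames(bands)[empty], collapse = ", "))
    bands <- bands[!empty, , drop = FALSE]
    if (nrow(bands) < 2) stop("fewer than 2 individuals with bands")
  }
  a <- tcrossprod(bands)                       # shared presences
  pres <- rowSums(bands)
  union <- outer(pres, pres, `+`) - a          # a + b + c
  gs <- a / union
  undef <- which(union == 0 & upper.tri(union), arr.ind = TRUE)
  gs[union == 0] <- NA_real_
  diag(gs) <- 1
  structure(gs, class = c("similarity_matrix", class(gs)),
            undefined_pairs = if (nrow(undef)) {
              data.frame(a = rownames(bands)[undef[, 1]],
                         b = rownames(bands)[undef[, 2]])
            } else NULL)
}

#' UPGMA dendrogram from a distance matrix
#'
#' Textbook UPGMA (arithmetic average linkage, cluster-size-weighted merge
#' distances) producing an ultrametric rooted tree; each merge sits at
#' half the cluster distance per side. Labels are processed in
#' lexicographic order so equal-distance ties resolve to the
#' lexicographically smallest members. Distances are typically
#' `1 - jaccard_matrix(x)`.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal
#'   (labels as dimnames), or a [stats::dist] object.
#' @return An [ape::phylo] ultrametric tree, with the Newick string (child
#'   clades ordered by smallest leaf label) in attribute `newick` and the
#'   merge heights in attribute `heights`.
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  if (any(is.na(dm))) {
    idx <- which(is.na(dm) & upper.tri(dm), arr.ind = TRUE)
    stop("NA/NaN distances for pairs: ",
         paste(sprintf("(%s,%s)", rownames(dm)[idx[, 1]],
                       colnames(dm)[idx[, 2]]), collapse = " "))
  }
  if (!isSymmetric(unname(dm)) || any(dm < 0) || any(diag(dm) != 0))
    stop("need a symmetric non-negative distance matrix with zero diagonal")
  if (is.null(rownames(dm)))
    rownames(dm) <- colnames(dm) <- sprintf("t%d", seq_len(nrow(dm)))
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  hc <- stats::hclust(stats::as.dist(dm), method = "average")

  labels <- hc$labels
  n <- length(labels)
  node_newick <- character(n)      # newick of each merged cluster
  node_min <- character(n)         # smallest leaf label per cluster
  node_h <- numeric(n)
  leaf_nw <- function(lab, h) sprintf("%s:%.15g", lab, h)
  for (m in seq_len(n - 1)) {
    h <- hc$height[m] / 2
    part <- lapply(hc$merge[m, ], function(ch) {
      if (ch < 0) list(nw = leaf_nw(labels[-ch], h), min = labels[-ch])
      else list(nw = sprintf("%s:%.15g", node_newick[ch], h - node_h[ch]),
                min = node_min[ch])
    })
    if (part[[2]]$min < part[[1]]$min) part <- part[c(2, 1)]
    node_newick[m] <- sprintf("(%s,%s)", part[[1]]$nw, part[[2]]$nw)
    node_min[m] <- part[[1]]$min
    node_h[m] <- h
  }
  nw <- paste0(node_newick[n - 1], ";")
  tree <- ape::read.tree(text = nw)
  attr(tree, "newick") <- nw
  attr(tree, "heights") <- hc$height / 2
  tree
}

#' Polymorphism summaries per species and primer
#'
#' For every species x primer combination: scorable bands (loci with at
#' least one presence in that species), polymorphic bands (loci neither
#' fixed present nor fixed absent within the species) and their
#' percentage; plus per-species averages across primers. Species with a
#' single individual have undefined polymorphism and are flagged `NA`.
#'
#' @param x a [marker_matrix()] with species and primer labels.
#' @return List with `per_primer` and `per_species` data frames.
#' @export
polymorphism_stats <- function(x) {
  stopifnot(inherits(x, "marker_matrix"))
  species <- unique(x$species)
  primers <- unique(x$primer)
  rows <- list()
  for (sp in species) {
    sub <- x$bands[x$species == sp, , drop = FALSE]
    single <- nrow(sub) < 2
    for (pr in primers) {
      cols <- x$primer == pr
      m <- sub[, cols, drop = FALSE]
      scorable <- sum(colSums(m) > 0)
      if (single) {
        poly <- NA_integer_
      } else {
        poly <- sum(colSums(m) > 0 & colSums(m) < nrow(m))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, primer = pr, n_individuals = nrow(sub),
        n_loci = sum(cols), scorable = scorable, polymorphic = poly,
        pct_polymorphic = if (!is.na(poly) && scorable > 0)
          100 * poly / scorable else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  per_primer <- do.call(rbind, rows)
  per_species <- do.call(rbind, lapply(split(per_primer, per_primer$species),
    function(df) data.frame(
      species = df$species[1],
      mean_scorable = mean(df$scorable),
      mean_polymorphic = mean(df$polymorphic),
      mean_pct_polymorphic = mean(df$pct_polymorphic),
      stringsAsFactors = FALSE)))
  rownames(per_species) <- NULL
  list(per_primer = per_primer, per_species = per_species)
}

#' Build a marker matrix from per-individual fragment sizes
#'
#' Fragments from different individuals are merged into one locus when
#' their sizes agree within the relative tolerance (default +/- 2 %):
#' sorted sizes are chained into a locus while consecutive sizes differ by
#' at most `size_tolerance` of the smaller one.
#'
#' @param fragments named list: per individual, a numeric vector of
#'   fragment sizes in bp (may be empty; an empty lane gives an all-absent
#'   row).
#' @param species species label per individual (recycled).
#' @param size_tolerance relative size tolerance for locus merging.
#' @param primer primer label applied to all loci.
#' @return A [marker_matrix()]; loci are named `"<primer>_<size>"` by
#'   their median fragment size.
#' @export
read_band_calls <- function(fragments, species = "sp1",
                            size_tolerance = 0.02, primer = "P1") {
  if (is.null(names(fragments))) stop("individuals must be named")
  sizes <- unlist(fragments, use.names = FALSE)
  if (length(sizes) && any(sizes <= 0)) stop("fragment sizes must be > 0")
  species <- rep_len(species, length(fragments))
  if (!length(sizes)) {
    bands <- matrix(0L, length(fragments), 0,
                    dimnames = list(names(fragments), NULL))
    return(marker_matrix(bands, species, character(0)))
  }
  us <- sort(unique(sizes))
  brk <- c(1L, which(diff(us) > size_tolerance * us[-length(us)]) + 1L)
  locus_of <- findInterval(seq_along(us), brk)
  locus_size <- tapply(us, locus_of, stats::median)
  n_loci <- length(locus_size)
  bands <- matrix(0L, length(fragments), n_loci,
                  dimnames = list(names(fragments),
                                  sprintf("%s_%g", primer, locus_size)))
  for (i in seq_along(fragments)) {
    f <- fragments[[i]]
    if (!length(f)) next
    loc <- locus_of[match(f, us)]
    bands[i, unique(loc)] <- 1L
  }
  marker_matrix(bands, species, rep(primer, n_loci))
}
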