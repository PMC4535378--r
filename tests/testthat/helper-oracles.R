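# Independent oracles used across test files. These deliberately use naive
# algorithms or third-party implementations, never the package's own code
# path.

# O(n^3) average-linkage (UPGMA) clustering returning the cophenetic
# distance matrix: entry (i,j) is the distance at which leaves i and j are
# first merged.
naive_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labs <- rownames(d)
  clusters <- as.list(seq_len(n))
  cd <- d
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i >= j) next
      dij <- cd[active[i], active[j]]
      if (dij < bd) { bd <- dij; best <- c(active[i], active[j]) }
    }
    a <- best[1]; b <- best[2]
    for (x in clusters[[a]]) for (y in clusters[[b]]) {
      coph[x, y] <- coph[y, x] <- bd
    }
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (k in active) {
      if (k == a || k == b) next
      cd[a, k] <- cd[k, a] <- (na * cd[a, k] + nb * cd[b, k]) / (na + nb)
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    active <- setdiff(active, b)
  }
  coph
}

# brute-force all-k TSD comparison of the two flanks
brute_tsd <- function(genome, start, end, min_len = 4, max_len = 6) {
  for (k in seq(max_len, min_len)) {
    left <- substr(genome, start - k, start - 1)
    right <- substr(genome, end + 1, end + k)
    if (nchar(left) == k && nchar(right) == k && left == right &&
        !grepl("[^ACGT]", left)) return(left)
  }
  NA_character_
}

# brute-force set-based Jaccard for one pair of binary rows
brute_jaccard <- function(x, y) {
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c <- sum(x == 0 & y == 1)
  if (a + b + c == 0) return(NA_real_)
  a / (a + b + c)
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
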