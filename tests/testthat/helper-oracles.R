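# Independent brute-force oracles used to cross-check the implementation.

# Position-by-position substring scan: all (protein, start, end) occurrences.
naive_scan <- function(sequence, proteins) {
  k <- nchar(sequence)
  out <- list()
  for (p in proteins) {
    n <- nchar(p$sequence) - k + 1L
    if (n < 1L) next
    subs <- substring(p$sequence, 1:n, k:(k + n - 1L))
    pos <- which(subs == sequence)
    if (length(pos)) {
      out[[length(out) + 1L]] <- data.frame(
        protein_id = p$protein_id, start = pos, end = pos + k - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
}

# Hand-rolled tally for the terminal logo: explicit per-peptide loops.
logo_tally <- function(peptides, min_length = 5L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  counts <- matrix(0, 20, 6, dimnames = list(aa, c("N1", "N2", "N3",
                                                   "C-3", "C-2", "C-1")))
  n <- 0L
  for (pep in peptides) {
    if (nchar(pep) < min_length) next
    n <- n + 1L
    ch <- strsplit(pep, "")[[1]]
    for (j in 1:3) {
      counts[ch[j], j] <- counts[ch[j], j] + 1
      counts[ch[length(ch) - 3L + j], j + 3L] <-
        counts[ch[length(ch) - 3L + j], j + 3L] + 1
    }
  }
  counts / n
}

# O(n^3) Lance-Williams agglomeration returning the cophenetic matrix.
naive_agglomerate <- function(x, linkage = c("average", "single", "ward")) {
  linkage <- match.arg(linkage)
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))
  if (linkage == "ward") d2 <- d2^2
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  coph <- matrix(0, n, n)
  diag(d2) <- Inf
  for (step in seq_len(n - 1L)) {
    # inactive rows/cols are Inf, so the global minimum is the active minimum;
    # lowest-index pair among the minima
    idx <- which(d2 == min(d2), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    h <- if (linkage == "ward") sqrt(d2[i, j]) else d2[i, j]
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- h; coph[b, a] <- h
    }
    for (k in setdiff(active, c(i, j))) {
      dn <- switch(linkage,
        average = (sizes[i] * d2[i, k] + sizes[j] * d2[j, k]) /
          (sizes[i] + sizes[j]),
        single = min(d2[i, k], d2[j, k]),
        ward = ((sizes[i] + sizes[k]) * d2[i, k] +
                  (sizes[j] + sizes[k]) * d2[j, k] -
                  sizes[k] * d2[i, j]) / (sizes[i] + sizes[j] + sizes[k]))
      d2[i, k] <- dn; d2[k, i] <- dn
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
    d2[j, ] <- Inf; d2[, j] <- Inf
  }
  coph
}

# Minimum spanning tree edge weights (Prim), for the single-linkage identity.
mst_edges <- function(x) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1, ]
  edges <- numeric(0)
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    edges <- c(edges, best[v])
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  sort(unname(edges))
}

# Adjusted Rand index between two labelings.
rand_adjusted <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- ai * bj / choose(n, 2)
  (nij - expected) / ((ai + bj) / 2 - expected)
}
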