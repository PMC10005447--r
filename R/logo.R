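# Terminal-residue probability matrices (sequence-logo content).

LOGO_POSITIONS <- c("N1", "N2", "N3", "C-3", "C-2", "C-1")

#' Terminal-residue probability matrix
#'
#' Summarises the apparent cleavage preference of a peptide set as the
#' probability of each amino acid at the first three (N1-N3) and last three
#' (C-3..C-1) positions. Residues 1..3 of each included peptide feed the N
#' columns and residues L-2..L the C columns; for a length-5 peptide the
#' middle residue therefore contributes to both N3 and C-3. Peptides shorter
#' than `min_length` are excluded and counted. Probabilities are plain
#' frequencies (no pseudocounts, no information-content scaling): the matrix
#' itself is the product, letter-height rendering is out of scope.
#'
#' @param peptides Character vector of peptide sequences.
#' @param min_length Minimum peptide length to include; default 5, the
#'   shortest length reliably identified under typical ion-trap MS/MS
#'   conditions.
#' @return A `terminal_logo`: list with `probs` (20 x 6 matrix, amino-acid
#'   rows in alphabet order, columns `r paste(LOGO_POSITIONS, collapse=", ")`),
#'   `n_peptides` and `n_excluded`.
#' @export
terminal_logo <- function(peptides, min_length = 5L) {
  min_length <- as.integer(min_length)
  if (min_length < 5L) stop("min_length must be >= 5")
  peptides <- toupper(peptides)
  len <- nchar(peptides)
  keep <- peptides[len >= min_length]
  if (length(keep) == 0L) {
    stop("no peptides of length >= ", min_length,
         "; check the input or lower min_length")
  }
  counts <- matrix(0L, nrow = length(AA_ALPHABET), ncol = 6L,
                   dimnames = list(AA_ALPHABET, LOGO_POSITIONS))
  L <- nchar(keep)
  for (j in 1:3) {
    n_res <- substring(keep, j, j)
    c_res <- substring(keep, L - 3L + j, L - 3L + j)
    counts[, j] <- counts[, j] + as.integer(table(factor(n_res, levels = AA_ALPHABET)))
    counts[, j + 3L] <- counts[, j + 3L] +
      as.integer(table(factor(c_res, levels = AA_ALPHABET)))
  }
  structure(list(probs = counts / length(keep),
                 n_peptides = length(keep),
                 n_excluded = sum(len < min_length)),
            class = "terminal_logo")
}

#' @export
print.terminal_logo <- function(x, ...) {
  cat(sprintf("<terminal_logo> %d peptides (%d excluded as too short)\n",
              x$n_peptides, x$n_excluded))
  top <- apply(x$probs, 2, function(col) {
    i <- which.max(col)
    sprintf("%s (%.2f)", rownames(x$probs)[i], col[i])
  })
  print(top)
  invisible(x)
}

#' Most frequent terminal k-mers
#'
#' Exact k-mer counts at the chosen peptide end, ranked by descending count
#' with ties broken lexicographically (e.g. the most abundant C-terminal
#' tripeptide of a digest).
#'
#' @param peptides Character vector of peptide sequences; peptides shorter
#'   than `k` are ignored.
#' @param end `"N"` for the first k residues, `"C"` for the last k.
#' @param k k-mer length (default 3).
#' @return Data frame `kmer`, `count`, ranked; zero rows for empty input.
#' @export
top_terminal_kmer <- function(peptides, end = c("N", "C"), k = 3L) {
  end <- match.arg(end)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  peptides <- toupper(peptides)
  peptides <- peptides[nchar(peptides) >= k]
  if (length(peptides) == 0L) {
    return(data.frame(kmer = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  L <- nchar(peptides)
  kmer <- if (end == "N") substring(peptides, 1L, k)
          else substring(peptides, L - k + 1L, L)
  tab <- table(kmer)
  out <- data.frame(kmer = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
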