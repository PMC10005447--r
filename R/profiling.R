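# Per-residue coverage profiles, size distributions and count summaries.

filter_sample <- function(observations, sample_key) {
  if (is.null(sample_key)) return(observations)
  if (!is.null(sample_key$substrate)) {
    observations <- observations[observations$substrate == sample_key$substrate, ,
                                 drop = FALSE]
  }
  if (!is.null(sample_key$time_min)) {
    observations <- observations[observations$time_min == sample_key$time_min, ,
                                 drop = FALSE]
  }
  observations
}

#' Per-residue intensity or occurrence profile
#'
#' For each mature residue position p of `protein`, sums over all mapped
#' peptides overlapping p either their MS intensity (`intensity_sum`, the
#' quantity drawn as area plots along the sequence) or a weight of 1 per
#' peptide (`occurrence_count`, the appearance-frequency profile behind
#' coverage heatmaps). Peptides from all animals in the selected sample are
#' pooled by summation.
#'
#' @param observations Mapped observation data frame ([map_observations()]).
#' @param protein A [protein_record()].
#' @param mode `"intensity_sum"` or `"occurrence_count"`.
#' @param sample_key Optional list with `substrate` and/or `time_min` used to
#'   filter observations; `NULL` pools everything present.
#' @return A `residue_profile`: list with `protein_id`, `mode`, `sample_key`
#'   and `values` (numeric, one entry per mature residue).
#' @export
residue_profile <- function(observations, protein,
                            mode = c("intensity_sum", "occurrence_count"),
                            sample_key = NULL) {
  mode <- match.arg(mode)
  obs <- filter_sample(observations, sample_key)
  obs <- obs[obs$protein_id == protein$protein_id, , drop = FALSE]
  L <- nchar(protein$sequence)
  if (nrow(obs) && (any(obs$start < 1L) || any(obs$end > L) ||
                    any(obs$start > obs$end))) {
    stop("observation mapped outside the bounds of ", protein$protein_id)
  }
  values <- numeric(L)
  if (nrow(obs)) {
    w <- if (mode == "intensity_sum") obs$intensity else rep(1, nrow(obs))
    # difference-array accumulation of interval weights
    d <- numeric(L + 1L)
    for (i in seq_len(nrow(obs))) {
      d[obs$start[i]] <- d[obs$start[i]] + w[i]
      d[obs$end[i] + 1L] <- d[obs$end[i] + 1L] - w[i]
    }
    values <- cumsum(d[seq_len(L)])
  }
  structure(list(protein_id = protein$protein_id, mode = mode,
                 sample_key = sample_key, values = values),
            class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  key <- if (is.null(x$sample_key)) "pooled"
         else paste(unlist(x$sample_key), collapse = "@")
  cat(sprintf("<residue_profile> %s, %s, sample %s: %d positions, total %.4g\n",
              x$protein_id, x$mode, key, length(x$values), sum(x$values)))
  invisible(x)
}

sample_row_keys <- function(observations) {
  keys <- unique(observations[, c("substrate", "time_min")])
  keys <- keys[order(keys$substrate, keys$time_min), , drop = FALSE]
  rownames(keys) <- NULL
  keys
}

#' Matrix of residue profiles across (substrate, time) samples
#'
#' One row per (substrate, time_min) combination present in the data, in
#' substrate order then time order; columns are mature residue positions of
#' `protein`. Each row equals [residue_profile()] of the same subset, so this
#' matrix is the numeric content behind per-sample area plots (intensity
#' mode) and coverage heatmaps (occurrence mode).
#'
#' @inheritParams residue_profile
#' @param normalize If `TRUE`, divide each row by its total so rows sum to 1
#'   (rows that are all zero are left as is).
#' @return Numeric matrix, rownames `substrate@time`, colnames
#'   `protein_id:position`.
#' @export
profile_matrix <- function(observations, protein,
                           mode = c("intensity_sum", "occurrence_count"),
                           normalize = FALSE) {
  mode <- match.arg(mode)
  keys <- sample_row_keys(observations)
  L <- nchar(protein$sequence)
  m <- matrix(0, nrow = nrow(keys), ncol = L,
              dimnames = list(paste0(keys$substrate, "@", keys$time_min),
                              paste0(protein$protein_id, ":", seq_len(L))))
  for (i in seq_len(nrow(keys))) {
    pr <- residue_profile(observations, protein, mode,
                          sample_key = list(substrate = keys$substrate[i],
                                            time_min = keys$time_min[i]))
    m[i, ] <- pr$values
  }
  if (normalize) {
    tot <- rowSums(m)
    m[tot > 0, ] <- m[tot > 0, , drop = FALSE] / tot[tot > 0]
  }
  m
}

#' Peptide size distribution
#'
#' Counts unique peptide sequences per length bin within each group. Bins
#' are defined by their lower edges; the last bin is open-ended. Defaults
#' (2-5, 6-9, 10-14, >=15 residues) bracket the size classes typically
#' discussed for gastric/duodenal digests.
#'
#' @param observations Observation data frame (mapping not required).
#' @param bin_edges Strictly increasing integer lower edges of length bins.
#' @param group_by Character vector of grouping columns
#'   (default `"substrate"`; add `"time_min"` for per-time distributions).
#' @return Data frame with one row per group x bin: grouping columns, `bin`
#'   label, `count` and `percent` (percentages sum to 100 per non-empty
#'   group; an empty group reports 0).
#' @export
size_distribution <- function(observations, bin_edges = c(2L, 6L, 10L, 15L),
                              group_by = "substrate") {
  bin_edges <- as.integer(bin_edges)
  if (any(diff(bin_edges) <= 0L)) {
    stop("bin_edges must be strictly increasing (unordered or overlapping bins)")
  }
  labels <- c(paste0(bin_edges[-length(bin_edges)], "-",
                     bin_edges[-1L] - 1L),
              paste0(">=", bin_edges[length(bin_edges)]))
  stopifnot(all(group_by %in% names(observations)))

  groups <- unique(observations[, group_by, drop = FALSE])
  if (nrow(groups) == 0L) {
    return(cbind(groups, data.frame(bin = character(), count = integer(),
                                    percent = numeric())))
  }
  groups <- groups[do.call(order, groups), , drop = FALSE]
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- rep(TRUE, nrow(observations))
    for (col in group_by) sel <- sel & observations[[col]] == groups[g, col]
    seqs <- unique(observations$sequence[sel])
    len <- nchar(seqs)
    idx <- findInterval(len, c(bin_edges, Inf))
    counts <- tabulate(idx[idx >= 1L], nbins = length(labels))
    total <- sum(counts)
    pct <- if (total > 0) 100 * counts / total else rep(0, length(counts))
    cbind(groups[rep(g, length(labels)), , drop = FALSE],
          data.frame(bin = labels, count = counts, percent = pct,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-time-point peptide count summary
#'
#' For each (substrate, time point): the number of unique peptide sequences
#' seen in at least one animal (`total`) and the number seen in every one of
#' `n_animals` animals (`common`). Column totals are the arithmetic sums of
#' the per-time entries -- the convention of published per-time count tables
#' -- not deduplicated unions across time (see [dedup_union()] for those).
#'
#' @param observations Observation data frame carrying `animal_id`.
#' @param n_animals Number of animals in the design (a peptide is "common"
#'   when present in all of them).
#' @return A `count_summary`: list with `per_time` (data frame `substrate`,
#'   `time_min`, `total`, `common`) and `column_totals`.
#' @export
count_summary <- function(observations, n_animals) {
  n_animals <- as.integer(n_animals)
  if (is.na(n_animals) || n_animals < 1L) stop("n_animals must be >= 1")
  keys <- sample_row_keys(observations)
  per_time <- cbind(keys, total = 0L, common = 0L)
  for (i in seq_len(nrow(keys))) {
    sel <- observations$substrate == keys$substrate[i] &
      observations$time_min == keys$time_min[i]
    sub <- unique(observations[sel, c("sequence", "animal_id")])
    n_an <- table(sub$sequence)
    per_time$total[i] <- length(n_an)
    per_time$common[i] <- sum(n_an == n_animals)
  }
  structure(list(per_time = per_time, column_totals = count_totals(per_time),
                 n_animals = n_animals),
            class = "count_summary")
}

#' Column totals of a per-time count table
#'
#' Sums `total` and `common` over time points within each substrate; this is
#' the arithmetic that produces the "Total" row of a per-time count table.
#'
#' @param per_time Data frame with columns `substrate`, `time_min`, `total`,
#'   `common`.
#' @return Data frame with one row per substrate: `substrate`, `total`,
#'   `common`.
#' @export
count_totals <- function(per_time) {
  stopifnot(all(c("substrate", "total", "common") %in% names(per_time)))
  out <- do.call(rbind, lapply(split(per_time, per_time$substrate), function(d) {
    data.frame(substrate = d$substrate[1L], total = sum(d$total),
               common = sum(d$common), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Deduplicated union counts across time points
#'
#' Number of distinct peptide sequences per substrate over all time points
#' combined. Provided for completeness; this is deliberately NOT the
#' semantics of per-time count-table totals (see [count_summary()]).
#'
#' @param observations Observation data frame.
#' @return Data frame `substrate`, `unique_sequences`.
#' @export
dedup_union <- function(observations) {
  out <- do.call(rbind, lapply(split(observations, observations$substrate),
    function(d) data.frame(substrate = d$substrate[1L],
                           unique_sequences = length(unique(d$sequence)),
                           stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' @export
print.count_summary <- function(x, ...) {
  cat("<count_summary> unique peptides per (substrate, time); common = in all",
      x$n_animals, "animals\n")
  print(x$per_time, row.names = FALSE)
  cat("column totals (sums over time points):\n")
  print(x$column_totals, row.names = FALSE)
  invisible(x)
}

#' Published duodenal peptide counts bundled as a worked example
#'
#' Per-time-point counts of unique casein-derived peptides identified in pig
#' duodenal effluents (n = 6 animals) after intake of micellar casein or a
#' casein pepsin hydrolysate: total unique sequences and those common to all
#' six animals, at 5-150 min post-intake. Used as the worked example for
#' [count_totals()].
#'
#' @return Data frame `substrate`, `time_min`, `total`, `common`.
#' @export
duodenal_count_table <- function() {
  utils::read.table(system.file("extdata", "duodenal_peptide_counts.tsv",
                                package = "pepdigest", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
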