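# Peptide identification tables and exact-substring mapping onto references.

#' Mapping policy options
#'
#' @param equate_ile_leu Treat isoleucine and leucine as interchangeable when
#'   matching (mass spectrometry cannot distinguish them); off by default
#'   because search-engine output is already committed to one residue.
#' @param multi_match_rule `"report_all"` expands a peptide matching several
#'   loci into one mapped copy per locus, flagged ambiguous; `"unique_only"`
#'   drops ambiguous peptides.
#' @param on_unmapped `"drop_with_log"` drops unmapped peptides and counts
#'   them in the mapping report; `"error"` aborts listing them.
#' @return A `mapping_policy` list.
#' @export
mapping_policy <- function(equate_ile_leu = FALSE,
                           multi_match_rule = c("report_all", "unique_only"),
                           on_unmapped = c("drop_with_log", "error")) {
  structure(list(equate_ile_leu = isTRUE(equate_ile_leu),
                 multi_match_rule = match.arg(multi_match_rule),
                 on_unmapped = match.arg(on_unmapped)),
            class = "mapping_policy")
}

#' Read a peptide identification table
#'
#' Parses a delimited text table of identified peptides (one row per peptide
#' observation) into the unmapped observation data frame consumed by
#' [map_observations()]. The basal sample is encoded as time -15 min; the
#' string `"basal"` in the time column is converted. Rows failing validation
#' (sequence shorter than 2 residues, illegal residue characters, negative
#' intensity) are dropped with a message. Missing intensities default to 1 so
#' count-only tables flow through the same pipeline; such rows are flagged in
#' `intensity_imputed`.
#'
#' @param path Delimited text file with a header row. Tab is used for `.tsv`
#'   (and unknown extensions), comma for `.csv`; override with `sep`.
#' @param column_map Named list mapping the roles `sequence`, `intensity`,
#'   `substrate`, `time_min`, `animal_id` to column names in the file.
#' @param sep Field separator; default chosen from the file extension.
#' @return Data frame with columns `sequence`, `intensity`, `substrate`,
#'   `time_min`, `animal_id`, `intensity_imputed`.
#' @export
read_peptide_table <- function(path,
                               column_map = list(sequence = "sequence",
                                                 intensity = "intensity",
                                                 substrate = "substrate",
                                                 time_min = "time_min",
                                                 animal_id = "animal_id"),
                               sep = NULL) {
  if (!file.exists(path)) stop("peptide table not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  needed <- c("sequence", "intensity", "substrate", "time_min", "animal_id")
  for (role in needed) {
    if (is.null(column_map[[role]])) {
      stop("column_map does not name a column for role ", sQuote(role))
    }
    if (!column_map[[role]] %in% names(raw)) {
      stop("mandatory column ", sQuote(column_map[[role]]),
           " (role ", role, ") missing from ", path)
    }
  }
  raw_int <- as.character(raw[[column_map$intensity]])
  obs <- data.frame(
    sequence = toupper(as.character(raw[[column_map$sequence]])),
    intensity = suppressWarnings(as.numeric(raw_int)),
    substrate = as.character(raw[[column_map$substrate]]),
    time_raw = as.character(raw[[column_map$time_min]]),
    animal_id = as.character(raw[[column_map$animal_id]]),
    stringsAsFactors = FALSE)
  obs$time_min <- suppressWarnings(as.integer(
    ifelse(tolower(obs$time_raw) == "basal", -15L, obs$time_raw)))
  obs$time_raw <- NULL

  # missing intensity -> occurrence weight 1 (flagged); non-numeric text is a
  # row validation failure, not a missing value
  missing_int <- is.na(raw_int) | !nzchar(trimws(raw_int))
  bad_int <- is.na(obs$intensity) & !missing_int
  obs$intensity[missing_int] <- 1.0
  obs$intensity_imputed <- missing_int

  valid_seq <- nchar(obs$sequence) >= 2L &
    !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), obs$sequence)
  ok <- valid_seq & !is.na(obs$time_min) & !bad_int & obs$intensity >= 0
  if (any(!ok)) {
    message(sum(!ok), " row(s) dropped during peptide-table validation")
  }
  rownames(obs) <- NULL
  obs[ok, , drop = FALSE]
}

canon_seq <- function(x, policy) {
  if (policy$equate_ile_leu) chartr("I", "L", x) else x
}

#' Locate a peptide within reference proteins
#'
#' Exact-substring search of one peptide in every protein, returning all
#' occurrences (including overlapping ones) as mature 1-based inclusive
#' coordinates, in protein order then ascending start. Identified peptide
#' sequences are exact, so alignment here means positioning, not scoring.
#'
#' @param sequence Peptide amino-acid string.
#' @param proteins List of [protein_record()] objects.
#' @param policy A [mapping_policy()]; `equate_ile_leu` canonicalises I to L
#'   on both sides before matching.
#' @return Data frame with columns `protein_id`, `start`, `end`
#'   (zero rows if no match).
#' @export
map_peptide <- function(sequence, proteins, policy = mapping_policy()) {
  sequence <- toupper(sequence)
  stopifnot(nzchar(sequence))
  pat <- canon_seq(sequence, policy)
  # zero-width lookahead so overlapping occurrences are all reported
  re <- paste0("(?=", pat, ")")
  hits <- lapply(proteins, function(p) {
    subj <- canon_seq(p$sequence, policy)
    if (nchar(pat) > nchar(subj)) return(NULL)
    m <- gregexpr(re, subj, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(protein_id = p$protein_id, start = as.integer(m),
               end = as.integer(m) + nchar(pat) - 1L,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(protein_id = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  hits
}

#' Map peptide observations onto reference proteins
#'
#' Applies [map_peptide()] to every observation. Under
#' `multi_match_rule = "report_all"` an observation matching k > 1 loci is
#' expanded into k mapped copies with `ambiguous = TRUE`; under
#' `"unique_only"` ambiguous observations are dropped. Unmapped observations
#' are dropped (or abort, per policy). The attached mapping report conserves
#' records: `input = mapped_unique + ambiguous + unmapped` counts input rows.
#'
#' @param observations Data frame from [read_peptide_table()] (or the
#'   simulator); re-mapping previously mapped observations overwrites
#'   coordinates.
#' @param proteins List of [protein_record()] objects.
#' @param policy A [mapping_policy()].
#' @return Mapped observation data frame with added columns `protein_id`,
#'   `start`, `end`, `ambiguous`, carrying the report in
#'   `attr(, "mapping_report")` (also via [mapping_report()]).
#' @export
map_observations <- function(observations, proteins, policy = mapping_policy()) {
  observations$protein_id <- NULL
  observations$start <- NULL
  observations$end <- NULL
  observations$ambiguous <- NULL

  n_in <- nrow(observations)
  loci <- lapply(unique(observations$sequence), map_peptide,
                 proteins = proteins, policy = policy)
  names(loci) <- unique(observations$sequence)

  n_hits <- vapply(loci[observations$sequence], nrow, 0L)
  unmapped <- n_hits == 0L
  ambiguous <- n_hits > 1L
  if (any(unmapped)) {
    bad <- unique(observations$sequence[unmapped])
    if (policy$on_unmapped == "error") {
      stop("unmapped peptide sequence(s): ", paste(bad, collapse = ", "))
    }
    message(sum(unmapped), " observation(s) with unmapped sequence dropped")
  }

  keep <- !unmapped
  if (policy$multi_match_rule == "unique_only") keep <- keep & !ambiguous
  kept <- observations[keep, , drop = FALSE]
  if (nrow(kept)) {
    h <- loci[kept$sequence]
    n_loci <- vapply(h, nrow, 0L)
    mapped <- kept[rep(seq_len(nrow(kept)), n_loci), , drop = FALSE]
    mapped$protein_id <- unlist(lapply(h, `[[`, "protein_id"), use.names = FALSE)
    mapped$start <- unlist(lapply(h, `[[`, "start"), use.names = FALSE)
    mapped$end <- unlist(lapply(h, `[[`, "end"), use.names = FALSE)
    mapped$ambiguous <- rep(n_loci > 1L, n_loci)
  } else {
    mapped <- cbind(kept,
                    data.frame(protein_id = character(0), start = integer(0),
                               end = integer(0), ambiguous = logical(0)))
  }
  rownames(mapped) <- NULL
  report <- list(input = n_in,
                 mapped_unique = sum(!unmapped & !ambiguous),
                 ambiguous = sum(ambiguous & !unmapped),
                 ambiguous_dropped = if (policy$multi_match_rule == "unique_only")
                   sum(ambiguous & !unmapped) else 0L,
                 unmapped = sum(unmapped),
                 output_rows = nrow(mapped))
  attr(mapped, "mapping_report") <- report
  mapped
}

#' Retrieve the mapping report attached by [map_observations()]
#' @param x A mapped observation data frame.
#' @return Named list of record counts.
#' @export
mapping_report <- function(x) attr(x, "mapping_report")
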