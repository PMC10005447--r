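# Reference protein records with mature-protein residue numbering.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Create a reference protein record
#'
#' A `protein_record` holds one mature protein sequence (signal peptide
#' already removed) together with numbering metadata. All coordinates used
#' throughout the package are 1-based inclusive positions on the mature
#' sequence, the convention in which bioactive casein fragments are reported
#' (e.g. beta-casomorphin-7 = beta-casein 60-66).
#'
#' @param protein_id Short identifier token, e.g. `"CASB_BOVIN"`.
#' @param sequence Uppercase amino-acid string over the 20-letter alphabet.
#' @param display_name Free-text name; defaults to `protein_id`.
#' @param signal_length Number of residues removed from the precursor
#'   (metadata only; the stored sequence is already mature).
#' @param source_accession Free-text provenance note.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(protein_id, sequence, display_name = protein_id,
                           signal_length = 0L, source_accession = NA_character_) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L, nzchar(protein_id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("protein ", protein_id, ": sequence is empty")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA_ALPHABET)
  if (length(bad)) {
    stop("protein ", protein_id, ": illegal residue character(s) ",
         paste(sQuote(bad), collapse = ", "))
  }
  signal_length <- as.integer(signal_length)
  if (is.na(signal_length) || signal_length < 0L) {
    stop("protein ", protein_id, ": signal_length must be a non-negative integer")
  }
  structure(
    list(protein_id = protein_id, display_name = display_name,
         sequence = sequence, signal_length = signal_length,
         source_accession = source_accession),
    class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%s): %d aa mature, signal_length=%d\n",
              x$protein_id, x$display_name, nchar(x$sequence), x$signal_length))
  invisible(x)
}

#' @export
length.protein_record <- function(x) nchar(x$sequence)

#' Read reference proteins from FASTA
#'
#' Headers follow the dialect `>id key=value ...`; recognised keys are
#' `name` (display name, underscores allowed), `signal_length` and
#' `source_accession`. An absent `signal_length` defaults to 0. Sequences are
#' uppercased and validated against the 20-letter amino-acid alphabet.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named list of [protein_record()] objects, one per entry.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("malformed FASTA in ", path, ": no records")
  recs <- lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    fields <- strsplit(trimws(header), "[ \t]+")[[1]]
    id <- fields[1L]
    kv <- list()
    for (f in fields[-1L]) {
      m <- regmatches(f, regexec("^([A-Za-z_]+)=(.*)$", f))[[1]]
      if (length(m) == 3L) kv[[m[2L]]] <- m[3L]
    }
    protein_record(
      protein_id = id,
      sequence = as.character(set[[i]]),
      display_name = if (!is.null(kv$name)) kv$name else id,
      signal_length = if (!is.null(kv$signal_length)) as.integer(kv$signal_length) else 0L,
      source_accession = if (!is.null(kv$source_accession)) kv$source_accession else NA_character_)
  })
  names(recs) <- vapply(recs, `[[`, "", "protein_id")
  recs
}

#' Write reference proteins to FASTA
#'
#' Inverse of [load_fasta()]: the round trip is lossless for id, metadata and
#' sequence.
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- sprintf(">%s name=%s signal_length=%d", r$protein_id,
                   r$display_name, r$signal_length)
    if (!is.na(r$source_accession)) {
      hdr <- paste0(hdr, " source_accession=", r$source_accession)
    }
    writeLines(hdr, con)
    starts <- seq(1L, nchar(r$sequence), by = width)
    writeLines(substring(r$sequence, starts,
                         pmin(starts + width - 1L, nchar(r$sequence))), con)
  }
  invisible(path)
}

#' Bundled mature bovine casein references
#'
#' The four major bovine caseins (beta, alpha-s1, alpha-s2, kappa) as mature
#' sequences (signal peptides of 15, 15, 15 and 21 residues removed), one
#' canonical genetic variant each; accessions are recorded in
#' `source_accession`. Mature beta-casein is 209 residues, so its C-terminal
#' domain spans positions 193-209.
#'
#' @return Named list of four [protein_record()] objects.
#' @export
bundled_caseins <- function() {
  load_fasta(system.file("extdata", "caseins_mature.fasta",
                         package = "pepdigest", mustWork = TRUE))
}
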