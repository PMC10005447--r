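# Small in-code fixtures shared across tests.

make_obs <- function(sequence, intensity = 1, substrate = "casein",
                     time_min = 5L, animal_id = "pig1",
                     protein_id = NULL, start = NULL, end = NULL) {
  n <- length(sequence)
  out <- data.frame(sequence = sequence,
                    intensity = rep_len(intensity, n),
                    substrate = rep_len(substrate, n),
                    time_min = rep_len(as.integer(time_min), n),
                    animal_id = rep_len(animal_id, n),
                    intensity_imputed = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(protein_id)) {
    out$protein_id <- rep_len(protein_id, n)
    out$start <- rep_len(as.integer(start), n)
    out$end <- rep_len(as.integer(end), n)
    out$ambiguous <- FALSE
  }
  out
}

# Mapped-style observation table straight from simulator output (rows of
# peptides and truth align one-to-one).
truth_as_mapped <- function(sim) {
  out <- sim$peptides
  out$protein_id <- sim$truth$protein_id
  out$start <- sim$truth$start
  out$end <- sim$truth$end
  out$ambiguous <- FALSE
  out
}

write_peptide_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_peptides <- function(n, len_range = c(5L, 12L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(len_range[1]:len_range[2], 1L), replace = TRUE),
          collapse = "")
  }, "")
}

small_digest_config <- function(seed, ...) {
  digestion_config(n_animals = 2L, time_points = c(5L, 30L),
                   peptides_per_sample_target = 60L, seed = seed, ...)
}
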