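# Seeded in-silico digestion and plasma simulators.

#' Default pepsin-like cleavage propensities
#'
#' Relative propensity to cut the bond following each residue (P1
#' preference): high after the hydrophobic/aromatic residues F, L, W, Y and
#' after E (the pepsin preference), near zero after P, and a moderate
#' baseline elsewhere -- duodenal digests have also seen the broad pancreatic
#' proteases, so no bond is fully immune. The proline rule on the other side
#' of the bond (P1' = proline suppresses cleavage) is applied by the
#' simulator itself.
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
default_cleavage_weights <- function() {
  w <- stats::setNames(rep(0.2, length(AA_ALPHABET)), AA_ALPHABET)
  w[c("F", "L", "W", "Y", "E")] <- 1
  w["P"] <- 0.01
  w
}

#' Configuration for the in-silico digestion simulator
#'
#' The defaults define a casein-meal-like duodenal digest: the four bundled
#' mature caseins, pepsin-like P1 cleavage preference, a modest fraction of
#' susceptible bonds cut (intact casein empties slowly and reaches the
#' duodenum only partly degraded), an observability window of 5-40 residues
#' mimicking the MS identification floor of five residues, log-normal
#' intensities spanning decades, 6 animals and the ten duodenal sampling
#' times 5-150 min. Hydrolysate-like digests are obtained by raising
#' `hydrolysis_extent` (the pre-digestion is represented as a higher overall
#' extent, not as a second enzyme pass) and dropping region protection.
#'
#' @param proteins List of [protein_record()] substrate proteins.
#' @param cleavage_weights Named per-residue relative cleavage propensity
#'   (bond after that residue).
#' @param hydrolysis_extent Expected fraction of bonds cut, in (0, 1];
#'   per-bond cut probabilities are the weights rescaled to this mean.
#' @param protected_regions List of `list(protein_id, start, end, factor)`
#'   entries; bonds inside \[start, end\] get their weight multiplied by
#'   `factor` (e.g. 0.1 to emulate the pepsin resistance of the beta-casein
#'   C-terminal domain 193-209).
#' @param min_len,max_len Observable fragment length window (default 5-40).
#' @param intensity_logmean,intensity_logsd Log-normal parameters (natural
#'   log scale) of the per-peptide base intensity. The base intensity is
#'   drawn once per generating locus and reused whenever that fragment is
#'   emitted again: a peptide's MS response is chiefly a property of the
#'   peptide (abundance, ionisation efficiency), which is what makes
#'   intensity profiles reproducible across samples.
#' @param intensity_within_sd Log-scale SD of the per-observation noise
#'   around the base intensity (sample-to-sample variation of one peptide).
#' @param n_animals Number of animals.
#' @param time_points Integer sampling times (minutes post-intake).
#' @param peptides_per_sample_target Per (animal, time) cap on emitted
#'   fragments; larger yields are subsampled.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return A `digestion_config` list.
#' @export
digestion_config <- function(proteins = bundled_caseins(),
                             cleavage_weights = default_cleavage_weights(),
                             hydrolysis_extent = 0.15,
                             protected_regions = NULL,
                             min_len = 5L, max_len = 40L,
                             intensity_logmean = log(1e6),
                             intensity_logsd = 0.7,
                             intensity_within_sd = 0.3,
                             n_animals = 6L,
                             time_points = c(5L, 10L, 15L, 20L, 30L, 45L,
                                             60L, 90L, 120L, 150L),
                             peptides_per_sample_target = 150L,
                             seed = 1L) {
  stopifnot(hydrolysis_extent > 0, hydrolysis_extent <= 1,
            min_len >= 2L, max_len >= min_len,
            all(cleavage_weights >= 0), n_animals >= 1L)
  names(proteins) <- vapply(proteins, `[[`, "", "protein_id")
  structure(list(proteins = proteins, cleavage_weights = cleavage_weights,
                 hydrolysis_extent = hydrolysis_extent,
                 protected_regions = protected_regions,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 intensity_logmean = intensity_logmean,
                 intensity_logsd = intensity_logsd,
                 intensity_within_sd = intensity_within_sd,
                 n_animals = as.integer(n_animals),
                 time_points = as.integer(time_points),
                 peptides_per_sample_target = as.integer(peptides_per_sample_target),
                 seed = as.integer(seed)),
            class = "digestion_config")
}

# Per-bond cut probabilities for one protein: weight of the preceding
# residue, P1'-proline suppression, region protection, then rescaled so the
# pooled mean equals hydrolysis_extent (capped at 1).
bond_weights <- function(protein, config) {
  res <- strsplit(protein$sequence, "")[[1]]
  L <- length(res)
  if (L < 2L) return(numeric(0))
  w <- config$cleavage_weights[res[-L]]
  w <- w * ifelse(res[-1L] == "P", 0.05, 1)
  for (pr in config$protected_regions) {
    if (pr$protein_id != protein$protein_id) next
    idx <- seq_len(L - 1L)
    inside <- idx >= pr$start & idx <= min(pr$end, L - 1L)
    w[inside] <- w[inside] * pr$factor
  }
  unname(w)
}

#' Simulate one substrate's duodenal peptidome
#'
#' For every (animal, time) sample, each peptide bond is cut independently
#' with probability proportional to its cleavage weight, rescaled so the
#' expected cut fraction equals `hydrolysis_extent`. Fragments between
#' consecutive cuts whose length falls in the observability window are
#' emitted; yields above the per-sample target are subsampled. An emitted
#' peptide's intensity is its per-locus log-normal base intensity scaled by
#' the fragment's production probability under the cut model (abundant =
#' frequently produced), with log-normal within-sample noise. The returned truth table records each emitted peptide's
#' generating locus, so mapping round-trips are checkable.
#'
#' @param config A [digestion_config()].
#' @param substrate_label Substrate label stamped on every row.
#' @return List with `peptides` (data frame `sequence`, `intensity`,
#'   `substrate`, `time_min`, `animal_id`) and `truth` (same rows plus
#'   `protein_id`, `start`, `end`); samples that produced no observable
#'   fragment are listed in `attr(peptides, "empty_samples")` with a
#'   warning.
#' @export
simulate_digest <- function(config, substrate_label = "casein") {
  stopifnot(inherits(config, "digestion_config"))
  set.seed(config$seed)
  base_log <- new.env(parent = emptyenv())  # locus -> base log-intensity
  wlist <- lapply(config$proteins, bond_weights, config = config)
  mean_w <- mean(unlist(wlist))
  if (!is.finite(mean_w) || mean_w <= 0) stop("all cleavage weights are zero")
  plist <- lapply(wlist, function(w)
    pmin(0.995, config$hydrolysis_extent * w / mean_w))
  # per-bond log p(cut) and cumulative log p(uncut), for fragment production
  # probabilities: q = p(left cut) * p(right cut) * prod(inside uncut)
  lqlist <- lapply(plist, function(p) {
    list(logp = log(p), cum1mp = c(0, cumsum(log1p(-p))))
  })

  rows <- list()
  empty <- character(0)
  for (animal in seq_len(config$n_animals)) {
    animal_id <- paste0("pig", animal)
    for (t in config$time_points) {
      frs <- list()
      for (k in seq_along(config$proteins)) {
        p <- config$proteins[[k]]
        pr <- plist[[k]]
        cuts <- which(stats::runif(length(pr)) < pr)
        bounds <- c(0L, cuts, nchar(p$sequence))
        st <- bounds[-length(bounds)] + 1L
        en <- bounds[-1L]
        len <- en - st + 1L
        ok <- len >= config$min_len & len <= config$max_len
        if (any(ok)) {
          lq <- lqlist[[k]]
          L <- nchar(p$sequence)
          st_ok <- st[ok]
          en_ok <- en[ok]
          logq <- ifelse(st_ok > 1L, lq$logp[st_ok - 1L], 0) +
            ifelse(en_ok < L, lq$logp[en_ok], 0) +
            lq$cum1mp[en_ok] - lq$cum1mp[st_ok]
          frs[[length(frs) + 1L]] <- data.frame(
            protein_id = p$protein_id, start = st_ok, end = en_ok,
            logq = logq, stringsAsFactors = FALSE)
        }
      }
      if (length(frs) == 0L) {
        empty <- c(empty, paste0(animal_id, "@", t))
        next
      }
      fr <- do.call(rbind, frs)
      if (nrow(fr) > config$peptides_per_sample_target) {
        fr <- fr[sort(sample.int(nrow(fr), config$peptides_per_sample_target)), ,
                 drop = FALSE]
      }
      seqs <- vapply(seq_len(nrow(fr)), function(i) {
        substr(config$proteins[[fr$protein_id[i]]]$sequence,
               fr$start[i], fr$end[i])
      }, "")
      # a peptide's base intensity is a property of the locus (abundance x
      # response), drawn once and reused; the production probability scales
      # it, so resistant-region fragments dominate as they do in real digests
      keys <- paste0(fr$protein_id, ":", fr$start, "-", fr$end)
      mu <- vapply(keys, function(key) {
        if (is.null(base_log[[key]])) {
          base_log[[key]] <- stats::rnorm(1L, config$intensity_logmean,
                                          config$intensity_logsd)
        }
        base_log[[key]]
      }, 0, USE.NAMES = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seqs,
        intensity = exp(mu + fr$logq +
                          stats::rnorm(nrow(fr), 0, config$intensity_within_sd)),
        substrate = substrate_label, time_min = t, animal_id = animal_id,
        protein_id = fr$protein_id, start = fr$start, end = fr$end,
        stringsAsFactors = FALSE)
    }
  }
  all_rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(), intensity = numeric(),
               substrate = character(), time_min = integer(),
               animal_id = character(), protein_id = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  rownames(all_rows) <- NULL
  peptides <- all_rows[, c("sequence", "intensity", "substrate", "time_min",
                           "animal_id")]
  peptides$intensity_imputed <- rep(FALSE, nrow(peptides))
  if (length(empty)) {
    warning(length(empty), " sample(s) produced no observable fragment: ",
            paste(empty, collapse = ", "))
    attr(peptides, "empty_samples") <- empty
  }
  list(peptides = peptides,
       truth = all_rows[, c("sequence", "substrate", "time_min", "animal_id",
                            "protein_id", "start", "end")])
}

#' Simulate the full two-substrate digestion study
#'
#' Convenience wrapper generating a casein-like digest (default extent 0.15,
#' beta-casein C-terminal domain 193-209 protected by factor 0.1) and a
#' hydrolysate-like digest (default extent 0.45, no protection) over the
#' same animals and time grid, emulating the qualitative contrasts of such
#' studies: the hydrolysate is further degraded (fewer long peptides) and
#' lacks the protected-region enrichment.
#'
#' @param seed Integer seed (the hydrolysate arm uses `seed + 1`).
#' @param n_animals,time_points Shared design.
#' @param casein_extent,hydrolysate_extent Hydrolysis extents of the two
#'   arms.
#' @param protect_factor Protection factor for beta-casein 193-209 in the
#'   casein arm.
#' @param ... Further arguments passed to [digestion_config()] for both arms.
#' @return List with `peptides` and `truth` data frames covering both
#'   substrates.
#' @export
simulate_study <- function(seed = 1L, n_animals = 6L,
                           time_points = c(5L, 10L, 15L, 20L, 30L, 45L,
                                           60L, 90L, 120L, 150L),
                           casein_extent = 0.15, hydrolysate_extent = 0.45,
                           protect_factor = 0.1, ...) {
  cas_cfg <- digestion_config(
    hydrolysis_extent = casein_extent,
    protected_regions = list(list(protein_id = "CASB_BOVIN", start = 193L,
                                  end = 209L, factor = protect_factor)),
    n_animals = n_animals, time_points = time_points, seed = seed, ...)
  hyd_cfg <- digestion_config(
    hydrolysis_extent = hydrolysate_extent, protected_regions = NULL,
    n_animals = n_animals, time_points = time_points, seed = seed + 1L, ...)
  cas <- simulate_digest(cas_cfg, "casein")
  hyd <- simulate_digest(hyd_cfg, "hydrolysate")
  list(peptides = rbind(cas$peptides, hyd$peptides),
       truth = rbind(cas$truth, hyd$truth))
}

#' Default plasma time-course shapes
#'
#' Mean concentration curves (umol/L) on the blood sampling grid
#' (-15, 5, 20, 45, 60, 120, 180, 240, 360 min) for three representative
#' analytes. The hydrolysate curves peak earlier and higher than the casein
#' curves at short times (< 200 min) and the substrates converge by 360 min,
#' the qualitative pattern expected when a pre-hydrolysed protein is
#' absorbed faster than its intact counterpart.
#'
#' @return Named list; each element has `times`, `casein`, `hydrolysate`.
#' @export
default_plasma_spec <- function() {
  tg <- PLASMA_TIME_GRID
  list(
    methionine = list(times = tg,
                      casein = c(28, 29, 32, 38, 44, 50, 48, 42, 33),
                      hydrolysate = c(28, 33, 48, 62, 58, 46, 40, 36, 32)),
    lysine = list(times = tg,
                  casein = c(160, 165, 180, 205, 225, 240, 235, 220, 185),
                  hydrolysate = c(160, 180, 230, 270, 260, 235, 215, 200, 184)),
    valine = list(times = tg,
                  casein = c(210, 212, 220, 235, 250, 265, 268, 258, 230),
                  hydrolysate = c(210, 220, 250, 285, 290, 280, 255, 240, 229)))
}

#' Simulate plasma amino-acid time courses
#'
#' Concentration = substrate-specific mean curve + animal random offset +
#' Gaussian noise, truncated at zero (with a warning) since concentrations
#' cannot be negative. With `animal_sd = 0` and `noise_sd = 0` the emitted
#' values equal the mean curves exactly.
#'
#' @param effect_spec Per-analyte curves as in [default_plasma_spec()].
#' @param n_animals Number of animals per substrate arm.
#' @param animal_sd SD of the per-animal additive offset (umol/L).
#' @param noise_sd SD of the per-measurement Gaussian noise (umol/L).
#' @param seed Integer seed.
#' @return Long-format data frame `analyte`, `animal_id`, `substrate`,
#'   `time_min`, `concentration`.
#' @export
simulate_plasma <- function(effect_spec = default_plasma_spec(),
                            n_animals = 6L, animal_sd = 5, noise_sd = 10,
                            seed = 1L) {
  set.seed(as.integer(seed))
  rows <- list()
  for (analyte in names(effect_spec)) {
    spec <- effect_spec[[analyte]]
    for (substrate in c("casein", "hydrolysate")) {
      curve <- spec[[substrate]]
      stopifnot(length(curve) == length(spec$times))
      for (animal in seq_len(n_animals)) {
        offset <- stats::rnorm(1L, 0, animal_sd)
        conc <- curve + offset + stats::rnorm(length(curve), 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          analyte = analyte, animal_id = paste0("pig", animal),
          substrate = substrate, time_min = spec$times,
          concentration = conc, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$concentration < 0)) {
    warning(sum(out$concentration < 0),
            " negative concentration(s) truncated at 0")
    out$concentration <- pmax(0, out$concentration)
  }
  rownames(out) <- NULL
  out
}
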