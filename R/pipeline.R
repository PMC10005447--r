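# Stage runner chaining the analysis with a manifest, for scripted use.

default_run_config <- function() {
  list(
    peptide_table = NULL,        # path to TSV/CSV of identified peptides
    plasma_table = NULL,         # path to long-format plasma TSV
    fasta = NULL,                # reference FASTA; NULL = bundled caseins
    column_map = list(sequence = "sequence", intensity = "intensity",
                      substrate = "substrate", time_min = "time_min",
                      animal_id = "animal_id"),
    equate_ile_leu = FALSE,
    multi_match_rule = "report_all",
    on_unmapped = "drop_with_log",
    bin_edges = c(2L, 6L, 10L, 15L),
    min_presence = 2L,
    min_logo_length = 5L,
    pca_center = TRUE, pca_scale = FALSE,
    cluster_distance = "euclidean", cluster_linkage = "ward",
    cluster_log_transform = TRUE,
    n_animals = 6L,
    seed = 1L)
}

load_run_config <- function(config) {
  base <- default_run_config()
  if (is.null(config)) return(base)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(base, config)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Run pipeline stages and write their artifacts
#'
#' Subcommand-style entry point: `stage = "all"` chains
#' map, profile, sizes, logo, counts, pca and cluster on one peptide table;
#' individual stages run alone; `"simulate"` generates a synthetic study
#' (digest + plasma tables) to analyse; `"plasma"` runs the ANOVA on a
#' plasma table. Every run writes a `manifest.json` recording inputs,
#' parameters, seed, package version and the MD5 of every artifact, so two
#' runs with the same config and seed are verifiably identical.
#'
#' @param stage One of `"simulate"`, `"map"`, `"profile"`, `"sizes"`,
#'   `"logo"`, `"counts"`, `"pca"`, `"cluster"`, `"plasma"`, `"all"`.
#' @param config Named list of options, or path to a YAML file with the same
#'   keys (unknown keys are rejected); `NULL` uses defaults. Keys: input
#'   paths (`peptide_table`, `plasma_table`, `fasta`), `column_map`, mapping
#'   policy fields, `bin_edges`, `min_presence`, `min_logo_length`, PCA and
#'   clustering options, `n_animals`, `seed`.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "map", "profile",
                                   "sizes", "logo", "counts", "pca",
                                   "cluster", "plasma"),
                         config = NULL, outdir = "pepdigest-out") {
  stage <- match.arg(stage)
  cfg <- load_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  add <- function(path) artifacts[[length(artifacts) + 1L]] <<- path

  proteins <- if (is.null(cfg$fasta)) bundled_caseins() else load_fasta(cfg$fasta)
  policy <- mapping_policy(cfg$equate_ile_leu, cfg$multi_match_rule,
                           cfg$on_unmapped)

  if (stage == "simulate") {
    study <- simulate_study(seed = cfg$seed, n_animals = cfg$n_animals)
    plasma <- simulate_plasma(seed = cfg$seed, n_animals = cfg$n_animals)
    add(write_tsv(study$peptides, file.path(outdir, "simulated_peptides.tsv")))
    add(write_tsv(study$truth, file.path(outdir, "simulated_truth.tsv")))
    add(write_tsv(plasma, file.path(outdir, "simulated_plasma.tsv")))
  }

  if (stage %in% c("map", "profile", "sizes", "logo", "counts", "pca",
                   "cluster", "all")) {
    if (is.null(cfg$peptide_table)) {
      stop("config key 'peptide_table' is required for stage ", sQuote(stage))
    }
    obs <- read_peptide_table(cfg$peptide_table, cfg$column_map)
    mapped <- map_observations(obs, proteins, policy)

    if (stage %in% c("map", "all")) {
      add(write_tsv(mapped, file.path(outdir, "mapped_peptides.tsv")))
      jsonlite::write_json(mapping_report(mapped),
                           file.path(outdir, "mapping_report.json"),
                           auto_unbox = TRUE)
      add(file.path(outdir, "mapping_report.json"))
    }
    if (stage %in% c("profile", "all")) {
      for (p in proteins) {
        for (mode in c("intensity_sum", "occurrence_count")) {
          m <- profile_matrix(mapped, p, mode)
          add(write_matrix_tsv(m, file.path(
            outdir, sprintf("profile_%s_%s.tsv", p$protein_id, mode))))
        }
      }
    }
    if (stage %in% c("sizes", "all")) {
      add(write_tsv(size_distribution(mapped, cfg$bin_edges),
                    file.path(outdir, "size_distribution.tsv")))
    }
    if (stage %in% c("logo", "all")) {
      for (s in unique(mapped$substrate)) {
        seqs <- mapped$sequence[mapped$substrate == s]
        lg <- terminal_logo(seqs, cfg$min_logo_length)
        add(write_matrix_tsv(lg$probs,
                             file.path(outdir, sprintf("logo_%s.tsv", s))))
        add(write_tsv(top_terminal_kmer(seqs, "C"),
                      file.path(outdir, sprintf("cterm_kmers_%s.tsv", s))))
      }
    }
    if (stage %in% c("counts", "all")) {
      cs <- count_summary(mapped, cfg$n_animals)
      add(write_tsv(cs$per_time, file.path(outdir, "counts_per_time.tsv")))
      add(write_tsv(cs$column_totals, file.path(outdir, "counts_totals.tsv")))
    }
    if (stage %in% c("pca", "all")) {
      fm <- residue_feature_matrix(mapped, proteins)
      pc <- peptidome_pca(fm, center = cfg$pca_center, scale. = cfg$pca_scale)
      add(write_matrix_tsv(pc$scores, file.path(outdir, "pca_scores.tsv")))
      add(write_matrix_tsv(pc$loadings, file.path(outdir, "pca_loadings.tsv")))
      add(write_tsv(data.frame(component = seq_along(pc$explained_ratio),
                               explained_ratio = pc$explained_ratio),
                    file.path(outdir, "pca_explained.tsv")))
    }
    if (stage %in% c("cluster", "all")) {
      pm <- peptide_feature_matrix(mapped, cfg$min_presence)
      cl <- cluster_samples(pm, cfg$cluster_distance, cfg$cluster_linkage,
                            cfg$cluster_log_transform)
      as_newick(cl, file.path(outdir, "sample_dendrogram.nwk"))
      add(file.path(outdir, "sample_dendrogram.nwk"))
      add(write_tsv(data.frame(order = seq_along(cl$leaf_order),
                               sample = cl$labels[cl$leaf_order]),
                    file.path(outdir, "cluster_leaf_order.tsv")))
    }
  }

  if (stage == "plasma") {
    if (is.null(cfg$plasma_table)) {
      stop("config key 'plasma_table' is required for stage 'plasma'")
    }
    plasma <- utils::read.table(cfg$plasma_table, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    rep <- plasma_anova(plasma)
    add(write_tsv(rep$effects, file.path(outdir, "plasma_anova_effects.tsv")))
    add(write_tsv(rep$per_time, file.path(outdir, "plasma_anova_per_time.tsv")))
    add(write_tsv(summarize_series(plasma),
                  file.path(outdir, "plasma_summary.tsv")))
  }

  manifest <- list(
    stage = stage,
    parameters = cfg[!vapply(cfg, is.null, TRUE)],
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("pepdigest")),
    artifacts = lapply(artifacts, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
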