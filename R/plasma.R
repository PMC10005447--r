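# Plasma amino-acid time-course comparison between substrates.

PLASMA_TIME_GRID <- c(-15L, 5L, 20L, 45L, 60L, 120L, 180L, 240L, 360L)

split_analytes <- function(data) {
  if (!"analyte" %in% names(data)) data$analyte <- "analyte"
  split(data, data$analyte)
}

#' Two-way ANOVA of plasma concentrations with per-time Bonferroni contrasts
#'
#' For each analyte, fits a fixed-effects two-way ANOVA
#' (substrate x time, both crossed factors, balanced design required) and
#' then compares the two substrates at every sampled time point with t
#' statistics on the pooled error term. Raw per-time p values are Bonferroni
#' adjusted within the analyte, the family being the sampled time points
#' (basal included), and annotated with significance stars at 0.05 (*) and
#' 0.01 (**). Although the underlying feeding design is a crossover (each
#' animal receives both substrates), animal is deliberately not modelled:
#' the procedure is the plain two-substrate-by-time ANOVA conventionally
#' reported for such curves; see the vignette for the caveat.
#'
#' @param data Long-format data frame with columns `substrate`, `time_min`,
#'   `animal_id`, `concentration` and optionally `analyte` (one ANOVA per
#'   analyte).
#' @return A `plasma_anova`: list with `effects` (per analyte and term:
#'   `df`, `sum_sq`, `mean_sq`, `F`, `p`) and `per_time` (per analyte and
#'   time: substrate means, `diff` = second substrate minus first in sorted
#'   label order, `t`, `raw_p`, `adj_p`, `stars`).
#' @export
plasma_anova <- function(data) {
  stopifnot(all(c("substrate", "time_min", "animal_id", "concentration") %in%
                  names(data)))
  reports <- lapply(split_analytes(data), plasma_anova_one)
  structure(list(
    effects = do.call(rbind, lapply(reports, `[[`, "effects")),
    per_time = do.call(rbind, lapply(reports, `[[`, "per_time"))),
    class = "plasma_anova")
}

plasma_anova_one <- function(d) {
  subs <- sort(unique(d$substrate))
  times <- sort(unique(d$time_min))
  if (length(subs) < 2L) stop("need at least 2 substrates")
  if (length(times) < 2L) stop("need at least 2 time points")
  cells <- table(d$substrate, d$time_min)
  if (any(cells == 0L)) {
    i <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop("empty design cell: substrate ", rownames(cells)[i[1L]],
         ", time ", colnames(cells)[i[2L]])
  }
  if (length(unique(as.vector(cells))) != 1L) {
    stop("unbalanced design: per-cell replicate counts differ")
  }
  n_rep <- as.vector(cells)[1L]
  if (n_rep < 2L) stop("need at least 2 replicates per (substrate, time) cell")

  d$substrate_f <- factor(d$substrate, levels = subs)
  d$time_f <- factor(d$time_min, levels = times)
  fit <- stats::aov(concentration ~ substrate_f * time_f, data = d)
  tab <- summary(fit)[[1L]]
  terms <- c("substrate", "time", "interaction", "residual")
  effects <- data.frame(
    analyte = d$analyte[1L], term = terms,
    df = tab[["Df"]], sum_sq = tab[["Sum Sq"]], mean_sq = tab[["Mean Sq"]],
    F = tab[["F value"]], p = tab[["Pr(>F)"]],
    stringsAsFactors = FALSE)
  mse <- tab[["Mean Sq"]][4L]
  df_e <- tab[["Df"]][4L]

  per_time <- do.call(rbind, lapply(times, function(t) {
    a <- d$concentration[d$substrate == subs[1L] & d$time_min == t]
    b <- d$concentration[d$substrate == subs[2L] & d$time_min == t]
    diff <- mean(b) - mean(a)
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    tstat <- if (se > 0) diff / se else 0
    raw_p <- if (se > 0) 2 * stats::pt(-abs(tstat), df_e) else 1
    data.frame(analyte = d$analyte[1L], time_min = t,
               mean_1 = mean(a), mean_2 = mean(b), diff = diff,
               t = tstat, raw_p = raw_p, stringsAsFactors = FALSE)
  }))
  per_time$adj_p <- pmin(1, per_time$raw_p * length(times))
  per_time$stars <- ifelse(per_time$adj_p < 0.01, "**",
                           ifelse(per_time$adj_p < 0.05, "*", ""))
  attr(per_time, "substrate_order") <- subs
  list(effects = effects, per_time = per_time)
}

#' @export
print.plasma_anova <- function(x, ...) {
  cat("<plasma_anova> two-way substrate x time ANOVA,",
      "Bonferroni per-time contrasts\n")
  main <- x$effects[x$effects$term != "residual", ]
  print(main, row.names = FALSE, digits = 4)
  sig <- x$per_time[x$per_time$stars != "", , drop = FALSE]
  if (nrow(sig)) {
    cat("significant per-time differences (Bonferroni):\n")
    print(sig[, c("analyte", "time_min", "diff", "adj_p", "stars")],
          row.names = FALSE, digits = 4)
  } else cat("no significant per-time differences\n")
  invisible(x)
}

#' Per-cell means and standard errors of plasma series
#'
#' Arithmetic mean and standard error of the mean per (analyte, substrate,
#' time) cell. A single-observation cell has no defined SE; it is reported
#' as 0 with `se_undefined = TRUE`.
#'
#' @param data Long-format plasma data frame (as for [plasma_anova()]).
#' @return Data frame `analyte`, `substrate`, `time_min`, `n`, `mean`, `se`,
#'   `se_undefined`.
#' @export
summarize_series <- function(data) {
  if (!"analyte" %in% names(data)) data$analyte <- "analyte"
  key <- interaction(data$analyte, data$substrate, data$time_min, drop = TRUE)
  out <- do.call(rbind, lapply(split(data, key), function(d) {
    n <- nrow(d)
    se <- if (n > 1L) stats::sd(d$concentration) / sqrt(n) else 0
    data.frame(analyte = d$analyte[1L], substrate = d$substrate[1L],
               time_min = d$time_min[1L], n = n,
               mean = mean(d$concentration), se = se,
               se_undefined = n == 1L, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$analyte, out$substrate, out$time_min), ]
  rownames(out) <- NULL
  out
}
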