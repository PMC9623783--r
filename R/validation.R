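## Validation layer: regression of benchmark GEBV on IGP, absolute
## difference summaries, genetic trend, trend correlations, and the
## backsolve subset-size sweep.

group_vector <- function(n, groups) {
  if (is.null(groups)) rep("all", n) else as.character(groups)
}

#' Regression of benchmark GEBV on IGP
#'
#' Ordinary least squares GEBV = b0 + b1 * IGP per trait (and per group,
#' e.g. sex).  R^2 is the squared Pearson correlation.  b0 is additionally
#' reported in genetic-SD units when `genetic_sd` is given (b1 and R^2 are
#' scale-free and never standardized).
#'
#' @param gebv,igp aligned matrices (animals x traits).
#' @param groups optional per-animal grouping (e.g. sex), default one group.
#' @param genetic_sd optional per-trait genetic SD for standardizing b0.
#' @return data frame `trait, group, b0, b1, r2, n, degenerate` (plus
#'   `b0_std` when `genetic_sd` is given); `degenerate` flags zero IGP
#'   variance (undefined slope).
#' @export
regress_gebv_on_igp <- function(gebv, igp, groups = NULL, genetic_sd = NULL) {
  gebv <- as.matrix(gebv); igp <- as.matrix(igp)
  stopifnot(all(dim(gebv) == dim(igp)))
  g <- group_vector(nrow(gebv), groups)
  out <- list()
  for (grp in unique(g)) {
    rows <- g == grp
    if (sum(rows) < 3L)
      stop(sprintf("fewer than 3 paired animals in group '%s'", grp))
    for (j in seq_len(ncol(gebv))) {
      x <- igp[rows, j]; y <- gebv[rows, j]
      if (var(x) == 0) {
        out[[length(out) + 1L]] <- data.frame(trait = j, group = grp,
                                              b0 = NA_real_, b1 = NA_real_,
                                              r2 = NA_real_, n = sum(rows),
                                              degenerate = TRUE)
        next
      }
      b1 <- cov(x, y) / var(x)
      b0 <- mean(y) - b1 * mean(x)
      out[[length(out) + 1L]] <- data.frame(trait = j, group = grp, b0 = b0,
                                            b1 = b1, r2 = cor(x, y)^2,
                                            n = sum(rows), degenerate = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(genetic_sd)) res$b0_std <- res$b0 / genetic_sd[res$trait]
  res
}

#' Mean and maximum absolute differences between GEBV and IGP
#'
#' MEAN = mean |GEBV - IGP| / sigma_a and MAX = max |GEBV - IGP| / sigma_a
#' per trait and group, in genetic-SD units.
#'
#' @inheritParams regress_gebv_on_igp
#' @param genetic_sd per-trait genetic SD (default 1 = trait units).
#' @return data frame `trait, group, mean_abs, max_abs`.
#' @export
abs_diff_stats <- function(gebv, igp, genetic_sd = NULL, groups = NULL) {
  gebv <- as.matrix(gebv); igp <- as.matrix(igp)
  stopifnot(all(dim(gebv) == dim(igp)))
  if (is.null(genetic_sd)) genetic_sd <- rep(1, ncol(gebv))
  g <- group_vector(nrow(gebv), groups)
  out <- list()
  for (grp in unique(g)) {
    rows <- g == grp
    d <- abs(gebv[rows, , drop = FALSE] - igp[rows, , drop = FALSE])
    out[[length(out) + 1L]] <- data.frame(
      trait = seq_len(ncol(gebv)), group = grp,
      mean_abs = colMeans(d) / genetic_sd,
      max_abs = apply(d, 2L, max) / genetic_sd)
  }
  do.call(rbind, out)
}

#' Standardized genetic trend
#'
#' Slope of cohort-mean (true or estimated) breeding value on birth year
#' over the evaluation window, divided by the genetic SD: genetic progress
#' per year in genetic-SD units.
#'
#' @param values matrix (animals x traits) with animal ids as rownames.
#' @param ped an `igp_pedigree` supplying birth years.
#' @param genetic_sd per-trait genetic SD (default 1).
#' @param window optional `c(first, last)` birth-year window.
#' @return per-trait trend vector (genetic SDs per year).
#' @export
genetic_trend <- function(values, ped, genetic_sd = NULL, window = NULL) {
  values <- as.matrix(values)
  if (is.null(genetic_sd)) genetic_sd <- rep(1, ncol(values))
  by <- ped$birth_year[match(rownames(values), as.character(ped$id))]
  if (anyNA(by)) stop("animals in values absent from pedigree")
  keep <- if (is.null(window)) rep(TRUE, length(by))
          else by >= window[1] & by <= window[2]
  by <- by[keep]; values <- values[keep, , drop = FALSE]
  years <- sort(unique(by))
  if (length(years) < 2L) stop("genetic trend requires at least 2 cohorts")
  cm <- vapply(years, function(yr) colMeans(values[by == yr, , drop = FALSE]),
               numeric(ncol(values)))
  cm <- matrix(cm, nrow = ncol(values))  # traits x years
  slopes <- apply(cm, 1L, function(v) cov(years, v) / var(years))
  slopes / genetic_sd
}

#' Correlations of validation statistics with the genetic trend
#'
#' Pearson correlations, across traits, of the standardized genetic trend
#' with each supplied per-trait statistic (b0, b1, R^2, MEAN, MAX, ...).
#'
#' @param dg per-trait genetic trend.
#' @param stats data frame or matrix of per-trait statistics (one row per
#'   trait, aligned with `dg`).
#' @param digits rounding for reporting (default 2); `NULL` to disable.
#' @return named vector of correlations; a zero-variance statistic yields
#'   `NA` with a warning.
#' @export
correlate_with_trend <- function(dg, stats, digits = 2) {
  stats <- as.data.frame(stats)
  if (length(dg) < 3L) stop("at least 3 traits are required")
  out <- vapply(stats, function(col) {
    if (sd(col) == 0 || sd(dg) == 0) NA_real_ else cor(dg, col)
  }, numeric(1))
  if (anyNA(out)) warning("zero-variance statistic: correlation undefined")
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Backsolve subset-size sweep
#'
#' For each subset size and seed: draw a random backsolving subset of the
#' GEBV animals, backsolve SNP effects, predict IGP for the target animals
#' and regress the benchmark GEBV on IGP.  Reports per-size averages of b1
#' and R^2 over traits and seeds.
#'
#' @param ctx list with `Z_gebv` (centered genotypes of GEBV animals),
#'   `gebv` (their GEBV matrix, rows aligned), `Z_targets`,
#'   `benchmark_targets` (benchmark GEBV of the target animals), `freqs`,
#'   and optionally `blend_beta` (default 0.05).
#' @param sizes subset sizes to test.
#' @param seeds seeds; each (size, seed) pair is one replicate.
#' @return list with `summary` (data frame `size, mean_b1, mean_r2`) and
#'   `replicates` (per size/seed/trait results).
#' @export
subset_size_sweep <- function(ctx, sizes, seeds = 1:5) {
  beta <- if (is.null(ctx$blend_beta)) 0.05 else ctx$blend_beta
  ids <- rownames(ctx$Z_gebv)
  reps <- list()
  for (size in sizes) {
    for (seed in seeds) {
      sub <- select_backsolve_subset(ids, size, seed = seed)
      pos <- match(sub, ids)
      eff <- backsolve_snp_effects(ctx$Z_gebv[pos, , drop = FALSE],
                                   ctx$gebv[pos, , drop = FALSE],
                                   ctx$freqs, blend_beta = beta)
      pred <- predict_igp(ctx$Z_targets, eff)
      reg <- regress_gebv_on_igp(ctx$benchmark_targets, pred$igp)
      reg$size <- size; reg$seed <- seed
      reps[[length(reps) + 1L]] <- reg
    }
  }
  reps <- do.call(rbind, reps)
  summary <- do.call(rbind, lapply(sizes, function(s) {
    rows <- reps$size == s
    data.frame(size = s, mean_b1 = mean(reps$b1[rows]),
               mean_r2 = mean(reps$r2[rows]))
  }))
  list(summary = summary, replicates = reps)
}
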