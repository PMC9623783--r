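## End-to-end pipeline: benchmark ssGBLUP -> partitioned ssGBLUP ->
## SNP backsolving -> IGP -> base adjustment -> validation.

#' Assemble a dataset from files
#'
#' Reads pedigree, genotype and phenotype files into the structure used by
#' [run_pipeline()] and partitions the animals.
#'
#' @param pedigree_file,genotype_file,phenotype_file input paths (see
#'   [read_pedigree()], [read_genotypes()], [read_phenotypes()]).
#' @param vc trait variance components (`Sa`, `Spe` or `NULL`, `Se`).
#' @param cutoff_year IGP start date; default the youngest cohort.
#' @return dataset list as produced by [simulate_dataset()] (without
#'   `truth`).
#' @export
read_dataset <- function(pedigree_file, genotype_file, phenotype_file, vc,
                         cutoff_year = NULL) {
  ped <- read_pedigree(pedigree_file)
  geno <- read_genotypes(genotype_file)
  phen <- read_phenotypes(phenotype_file)
  bad <- setdiff(unique(as.character(phen$id)), as.character(ped$id))
  if (length(bad))
    stop("phenotyped animals absent from pedigree: ",
         paste(head(bad), collapse = ", "))
  if (is.null(cutoff_year)) cutoff_year <- max(ped$birth_year)
  part <- partition_animals(ped, phen, geno, cutoff_year)
  list(pedigree = ped, genotypes = geno, phenotypes = phen, partition = part,
       vc = vc, genetic_sd = sqrt(diag(vc$Sa)), config = NULL, truth = NULL)
}

#' Run the full indirect-genomic-prediction pipeline
#'
#' Four steps mirroring a production evaluation: (1) benchmark ssGBLUP
#' with every genotyped animal in G; (2) ssGBLUP with only the GEBV set
#' (genotyped animals with phenotypes or progeny) in G; (3) SNP-effect
#' backsolving from a random subset of the GEBV set; (4) IGP = Z u-hat for
#' the target animals, genetic-base adjustment, and validation of IGP
#' against the benchmark GEBV.  Allele frequencies are computed once from
#' the full genotyped pool and reused at every stage so Z is consistent.
#'
#' @param data dataset from [simulate_dataset()] or [read_dataset()].
#' @param backsolve_n backsolving subset size; `NULL` uses the whole GEBV
#'   set.
#' @param backsolve_seed seed of the random subset draw.
#' @param apy_core APY core specification for the ssGBLUP runs (`NULL` =
#'   direct inversion; integer; `"eigen98"`/`"eigen99"`).
#' @param core_seed seed of the random core draw.
#' @param blend_beta G blending fraction.
#' @param adjust_mode genetic-base adjustment, `"mean_difference"` (default)
#'   or `"intercept"`; `"none"` skips it.
#' @param tol,max_iter PCG controls.
#' @param out_dir optional output directory; when given, GEBV, SNP-effect,
#'   IGP and validation tables plus a YAML run manifest are written there.
#' @return list with `benchmark`, `partitioned` (both `igp_gblup`),
#'   `effects`, `igp` (adjusted `igp_result` for the target animals),
#'   `validation` (regression, absolute differences, genetic trend, trend
#'   correlations when 3+ traits), `subset_ids`, `manifest`.
#' @export
run_pipeline <- function(data, backsolve_n = NULL, backsolve_seed = 1L,
                         apy_core = NULL, core_seed = 1L, blend_beta = 0.05,
                         adjust_mode = "mean_difference",
                         tol = 1e-12, max_iter = 1000L, out_dir = NULL) {
  ped <- data$pedigree
  part <- data$partition
  freqs <- allele_frequencies(data$genotypes)
  benchmark <- run_ssgblup(ped, data$genotypes, data$phenotypes, data$vc,
                           apy_core = apy_core, core_seed = core_seed,
                           blend_beta = blend_beta, freqs = freqs,
                           tol = tol, max_iter = max_iter)
  geno_gebv <- data$genotypes[part$gebv_ids, , drop = FALSE]
  partitioned <- run_ssgblup(ped, geno_gebv, data$phenotypes, data$vc,
                             apy_core = apy_core, core_seed = core_seed,
                             blend_beta = blend_beta, freqs = freqs,
                             tol = tol, max_iter = max_iter)
  if (is.null(backsolve_n)) backsolve_n <- length(part$gebv_ids)
  subset_ids <- select_backsolve_subset(part$gebv_ids, backsolve_n,
                                        seed = backsolve_seed)
  Z_subset <- center_genotypes(data$genotypes, freqs, subset_ids)
  gebv_subset <- partitioned$ebv[subset_ids, , drop = FALSE]
  effects <- backsolve_snp_effects(Z_subset, gebv_subset, freqs,
                                   blend_beta = blend_beta)
  Z_targets <- center_genotypes(data$genotypes, freqs, part$igp_ids)
  igp <- predict_igp(Z_targets, effects)
  fitted_subset <- Z_subset %*% effects$u
  if (!identical(adjust_mode, "none"))
    igp <- adjust_genetic_base(igp, gebv_subset, fitted_subset,
                               mode = adjust_mode)
  bench_targets <- benchmark$ebv[part$igp_ids, , drop = FALSE]
  sex <- ped$sex[match(part$igp_ids, as.character(ped$id))]
  regression <- regress_gebv_on_igp(bench_targets, igp$igp, groups = sex,
                                    genetic_sd = data$genetic_sd)
  absdiff <- abs_diff_stats(bench_targets, igp$igp,
                            genetic_sd = data$genetic_sd, groups = sex)
  trend <- genetic_trend(benchmark$ebv, ped, genetic_sd = data$genetic_sd)
  correlations <- NULL
  if (ncol(bench_targets) >= 3L) {
    per_trait <- regression[regression$group == regression$group[1], ]
    correlations <- correlate_with_trend(
      trend, data.frame(b0 = per_trait$b0_std, b1 = per_trait$b1,
                        r2 = per_trait$r2))
  }
  manifest <- list(
    seeds = list(simulation = if (!is.null(data$config)) data$config$seed,
                 backsolve = backsolve_seed, core = core_seed),
    sizes = list(pedigree = nrow(ped),
                 genotyped = nrow(data$genotypes),
                 gebv_set = length(part$gebv_ids),
                 igp_set = length(part$igp_ids),
                 backsolve_subset = length(subset_ids),
                 markers = ncol(data$genotypes)),
    blend_beta = blend_beta, apy_core = apy_core,
    adjust_mode = adjust_mode, pcg_tol = tol,
    iterations = list(benchmark = benchmark$iterations,
                      partitioned = partitioned$iterations),
    criterion = list(benchmark = benchmark$criterion,
                     partitioned = partitioned$criterion),
    package_version = as.character(utils::packageVersion("igpred")))
  out <- list(benchmark = benchmark, partitioned = partitioned,
              effects = effects, igp = igp,
              validation = list(regression = regression, abs_diff = absdiff,
                                trend = trend, correlations = correlations),
              subset_ids = subset_ids, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, data, out_dir)
  out
}

write_pipeline_outputs <- function(out, data, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ebv_long <- function(m, source) {
    data.frame(id = rep(rownames(m), times = ncol(m)),
               trait = rep(seq_len(ncol(m)), each = nrow(m)),
               value = as.vector(m), source = source)
  }
  write.csv(rbind(ebv_long(out$benchmark$ebv, "benchmark_gebv"),
                  ebv_long(out$partitioned$ebv, "gebv")),
            file.path(out_dir, "gebv.csv"), row.names = FALSE, quote = FALSE)
  write_snp_effects(out$effects, file.path(out_dir, "snp_effects.csv"))
  write.csv(ebv_long(out$igp$igp, "igp"), file.path(out_dir, "igp.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(out$validation$regression, file.path(out_dir, "validation.csv"),
            row.names = FALSE, quote = FALSE)
  yaml::write_yaml(out$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
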