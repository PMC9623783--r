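## Synthetic population generator: multi-generation pedigree under
## truncation selection on true breeding values, gene-dropped genotypes,
## multi-trait phenotypes with repeated records, and the GEBV/IGP/
## nongenotyped partition of animals.

#' Simulation configuration
#'
#' Defines the synthetic population: pedigree structure, marker panel,
#' trait architecture and selection regime.  Phenotypic variance is 1 per
#' trait, so the additive variance equals the heritability and the
#' permanent-environment variance equals repeatability minus heritability.
#'
#' @param n_founders founder animals (generation 1).
#' @param n_generations total generations including the founders.
#' @param offspring_per_dam litter size per selected dam.
#' @param n_markers biallelic SNP count.
#' @param founder_maf_range interval in (0, 0.5] for founder allele
#'   frequencies (drawn uniformly per marker).
#' @param n_traits number of traits.
#' @param heritabilities per-trait narrow-sense heritability in (0, 1).
#' @param genetic_correlations scalar (constant off-diagonal) or full
#'   correlation matrix of breeding values across traits.
#' @param repeatability per-trait repeatability in `[h2, 1)`; repeatability
#'   equal to h2 means no permanent-environment effect.
#' @param selection_intensity fraction of each sex kept as parents, in (0, 1].
#' @param selection_weights per-trait index weights for truncation selection
#'   on true breeding values; all zero means random selection.
#' @param prop_genotyped fraction of animals genotyped.
#' @param prop_phenotyped_females probability that a female (not in the
#'   youngest cohort) has phenotype records.
#' @param records_per_animal repeated records per phenotyped animal.
#' @param missing_rate genotype missing-code injection rate (default 0).
#' @param fixed_effect_sd SD of contemporary-group (birth year x sex) effects.
#' @param start_year birth year of the founders.
#' @param seed integer seed driving every random stage.
#' @return validated list of class `igp_config`.
#' @export
simulation_config <- function(n_founders = 120,
                              n_generations = 5,
                              offspring_per_dam = 8,
                              n_markers = 1000,
                              founder_maf_range = c(0.05, 0.5),
                              n_traits = 2,
                              heritabilities = rep(0.3, n_traits),
                              genetic_correlations = 0.3,
                              repeatability = pmax(heritabilities,
                                                   pmin(heritabilities + 0.15, 0.95)),
                              selection_intensity = 0.25,
                              selection_weights = c(1, rep(0, n_traits - 1)),
                              prop_genotyped = 0.6,
                              prop_phenotyped_females = 0.8,
                              records_per_animal = 2,
                              missing_rate = 0,
                              fixed_effect_sd = 0.5,
                              start_year = 2000,
                              seed = 1) {
  t <- as.integer(n_traits)
  if (t < 1) stop("n_traits must be at least 1")
  if (length(heritabilities) == 1L) heritabilities <- rep(heritabilities, t)
  if (length(repeatability) == 1L) repeatability <- rep(repeatability, t)
  if (length(selection_weights) == 1L && t > 1L)
    selection_weights <- c(selection_weights, rep(0, t - 1L))
  stopifnot(length(heritabilities) == t, length(repeatability) == t,
            length(selection_weights) == t)
  if (any(heritabilities <= 0 | heritabilities > 1))
    stop("heritabilities must be in (0, 1]")
  if (any(repeatability < heritabilities) || any(repeatability > 1))
    stop("repeatability must be in [h2, 1] per trait")
  if (selection_intensity <= 0 || selection_intensity > 1)
    stop("selection_intensity must be in (0, 1]")
  if (length(founder_maf_range) != 2L || founder_maf_range[1] <= 0 ||
      founder_maf_range[2] > 0.5 || diff(founder_maf_range) < 0)
    stop("founder_maf_range must be an interval within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (is.matrix(genetic_correlations)) {
    Rg <- genetic_correlations
  } else {
    Rg <- matrix(genetic_correlations, t, t); diag(Rg) <- 1
  }
  if (!isSymmetric(unname(Rg)) ||
      min(eigen(Rg, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("genetic correlation matrix must be symmetric positive semi-definite")
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              offspring_per_dam = as.integer(offspring_per_dam),
              n_markers = as.integer(n_markers),
              founder_maf_range = founder_maf_range,
              n_traits = t, heritabilities = heritabilities,
              genetic_correlations = Rg, repeatability = repeatability,
              selection_intensity = selection_intensity,
              selection_weights = selection_weights,
              prop_genotyped = prop_genotyped,
              prop_phenotyped_females = prop_phenotyped_females,
              records_per_animal = as.integer(records_per_animal),
              missing_rate = missing_rate,
              fixed_effect_sd = fixed_effect_sd,
              start_year = as.integer(start_year), seed = as.integer(seed))
  class(cfg) <- "igp_config"
  cfg
}

#' Trait (co)variance components implied by a simulation configuration
#'
#' @param config an `igp_config`.
#' @return list with additive (`Sa`), permanent-environment (`Spe`, `NULL`
#'   if all zero) and residual (`Se`) covariance matrices.
#' @export
variance_components <- function(config) {
  sa <- sqrt(config$heritabilities)
  Sa <- outer(sa, sa) * config$genetic_correlations
  pe <- config$repeatability - config$heritabilities
  Spe <- if (all(pe <= 0)) NULL else diag(pe, config$n_traits)
  Se <- diag(1 - config$repeatability, config$n_traits)
  list(Sa = Sa, Spe = Spe, Se = Se)
}

#' Simulate a pedigree under truncation selection on true breeding values
#'
#' Founders get multivariate-normal true breeding values (TBV) with the
#' configured additive covariance; each later generation is bred from the
#' top `selection_intensity` fraction of each sex of the previous cohort,
#' ranked on the weighted TBV index (random parents when all weights are
#' zero).  Offspring TBV follow the infinitesimal recursion
#' tbv = (tbv_sire + tbv_dam)/2 + Mendelian deviation with covariance
#' (0.5 - 0.25 (F_s + F_d)) Sa.  Offspring sexes alternate
#' deterministically so both sexes exist in every cohort.
#'
#' @param config an `igp_config`.
#' @return list with `pedigree` (an `igp_pedigree`) and `truth` (list of
#'   `tbv` matrix, `pe` matrix of permanent-environment deviations, `F`
#'   inbreeding vector), both in pedigree order.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "igp_config"))
  set.seed(config$seed)
  t <- config$n_traits
  vc <- variance_components(config)
  cha <- chol(vc$Sa + diag(1e-12, t))
  nf <- config$n_founders
  id <- seq_len(nf)
  sire <- dam <- rep(0L, nf)
  sex <- rep(c("M", "F"), length.out = nf)
  birth_year <- rep(config$start_year, nf)
  tbv <- matrix(rnorm(nf * t), nf, t) %*% cha
  F <- rep(0, nf)
  A_cohort <- diag(nf)
  cohort <- list(pos = id, tbv = tbv, sex = sex)
  next_id <- nf + 1L
  if (config$n_generations > 1L) {
    for (g in 2:config$n_generations) {
      idx <- if (all(config$selection_weights == 0)) {
        runif(nrow(cohort$tbv))
      } else {
        as.vector(cohort$tbv %*% config$selection_weights)
      }
      males <- which(cohort$sex == "M"); females <- which(cohort$sex == "F")
      n_s <- floor(config$selection_intensity * length(males))
      n_d <- floor(config$selection_intensity * length(females))
      if (n_s < 1L || n_d < 1L)
        stop(sprintf("no parents left for generation %d (selection_intensity %.3g)",
                     g, config$selection_intensity))
      sires <- males[order(idx[males], decreasing = TRUE)[seq_len(n_s)]]
      dams <- females[order(idx[females], decreasing = TRUE)[seq_len(n_d)]]
      dam_vec <- rep(dams, each = config$offspring_per_dam)
      sire_vec <- rep(sires[sample.int(n_s, n_d, replace = TRUE)],
                      each = config$offspring_per_dam)
      nk <- length(dam_vec)
      Fk <- 0.5 * A_cohort[cbind(sire_vec, dam_vec)]
      msd <- sqrt(pmax(0.5 - 0.25 * (F[cohort$pos[sire_vec]] +
                                       F[cohort$pos[dam_vec]]), 0))
      eps <- (matrix(rnorm(nk * t), nk, t) %*% cha) * msd
      tbv_k <- 0.5 * (cohort$tbv[sire_vec, , drop = FALSE] +
                        cohort$tbv[dam_vec, , drop = FALSE]) + eps
      ## cohort relationship recursion: off-diagonals from the parent
      ## cohort, diagonal 1 + F
      S <- matrix(0, nk, nrow(A_cohort))
      S[cbind(seq_len(nk), sire_vec)] <- 0.5
      S[cbind(seq_len(nk), dam_vec)] <- S[cbind(seq_len(nk), dam_vec)] + 0.5
      A_new <- S %*% A_cohort %*% t(S)
      diag(A_new) <- 1 + Fk
      ids_k <- next_id + seq_len(nk) - 1L
      id <- c(id, ids_k)
      sire <- c(sire, cohort$pos[sire_vec])
      dam <- c(dam, cohort$pos[dam_vec])
      sex_k <- rep(c("M", "F"), length.out = nk)
      sex <- c(sex, sex_k)
      birth_year <- c(birth_year, rep(config$start_year + g - 1L, nk))
      tbv <- rbind(tbv, tbv_k)
      F <- c(F, Fk)
      A_cohort <- A_new
      cohort <- list(pos = ids_k, tbv = tbv_k, sex = sex_k)
      next_id <- next_id + nk
    }
  }
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    birth_year = birth_year, sex = sex)
  ped <- as_pedigree(ped)
  rownames(tbv) <- id
  pe <- matrix(0, length(id), t, dimnames = list(id, NULL))
  if (!is.null(vc$Spe))
    pe <- matrix(rnorm(length(id) * t), length(id), t) %*%
      chol(vc$Spe + diag(1e-12, t))
  rownames(pe) <- id
  ord <- as.character(ped$id)
  list(pedigree = ped,
       truth = list(tbv = tbv[ord, , drop = FALSE],
                    pe = pe[ord, , drop = FALSE],
                    F = setNames(F, id)[ord]))
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder allele frequencies are drawn uniformly on `founder_maf_range`
#' per marker; every animal receives one allele per parent per marker,
#' independently across markers (no linkage).  An unknown parent's gamete
#' is drawn from the founder frequencies.  Missing codes are injected at
#' `missing_rate` if configured.
#'
#' @param ped an `igp_pedigree`.
#' @param config an `igp_config`.
#' @return integer matrix animals x markers with codes 0/1/2 (`NA` missing),
#'   animal ids as rownames.
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(config, "igp_config"))
  ped <- if (inherits(ped, "igp_pedigree")) ped else as_pedigree(ped)
  set.seed(config$seed + 1L)
  m <- config$n_markers
  n <- nrow(ped)
  p0 <- runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  idx <- ped_index(ped)
  geno <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- idx$sire[i]; d <- idx$dam[i]
    from_s <- if (s > 0L) rbinom(m, 1L, geno[s, ] / 2) else rbinom(m, 1L, p0)
    from_d <- if (d > 0L) rbinom(m, 1L, geno[d, ] / 2) else rbinom(m, 1L, p0)
    geno[i, ] <- from_s + from_d
  }
  if (config$missing_rate > 0) {
    drop <- runif(length(geno)) < config$missing_rate
    geno[drop] <- NA_integer_
  }
  dimnames(geno) <- list(ped$id, sprintf("M%d", seq_len(m)))
  attr(geno, "founder_freq") <- p0
  geno
}

#' Simulate phenotype records under the repeatability animal model
#'
#' y = contemporary-group effect + TBV + permanent-environment deviation +
#' residual, per trait, with the variance fractions implied by the
#' configuration.  Contemporary groups are birth year x sex.  Females not
#' in the youngest cohort are phenotyped with probability
#' `prop_phenotyped_females`; males and youngest-cohort animals carry no
#' records (they enter the evaluation through relatives only).
#'
#' @param ped an `igp_pedigree`.
#' @param truth true values from [simulate_pedigree()].
#' @param config an `igp_config`.
#' @return data frame `id, trait, value, fixed_level, record_no`.
#' @export
simulate_phenotypes <- function(ped, truth, config) {
  stopifnot(inherits(config, "igp_config"))
  ped <- if (inherits(ped, "igp_pedigree")) ped else as_pedigree(ped)
  set.seed(config$seed + 2L)
  t <- config$n_traits
  vc <- variance_components(config)
  young <- if (config$n_generations > 1L)
    ped$birth_year == max(ped$birth_year) else rep(FALSE, nrow(ped))
  eligible <- ped$sex == "F" & !young
  phenotyped <- eligible & runif(nrow(ped)) < config$prop_phenotyped_females
  if (!any(phenotyped))
    return(data.frame(id = integer(0), trait = integer(0), value = numeric(0),
                      fixed_level = character(0), record_no = integer(0)))
  cg <- paste(ped$birth_year, ped$sex, sep = "_")
  levels_cg <- sort(unique(cg[phenotyped]))
  cg_eff <- matrix(rnorm(length(levels_cg) * t, sd = config$fixed_effect_sd),
                   length(levels_cg), t, dimnames = list(levels_cg, NULL))
  who <- which(phenotyped)
  nrec <- config$records_per_animal
  rows_id <- rep(ped$id[who], each = nrec)
  rows_cg <- rep(cg[who], each = nrec)
  rows_rec <- rep(seq_len(nrec), times = length(who))
  nr <- length(rows_id)
  se_chol <- chol(vc$Se + diag(1e-12, t))
  resid <- matrix(rnorm(nr * t), nr, t) %*% se_chol
  tbv <- truth$tbv[as.character(rows_id), , drop = FALSE]
  pe <- truth$pe[as.character(rows_id), , drop = FALSE]
  y <- cg_eff[rows_cg, , drop = FALSE] + tbv + pe + resid
  data.frame(id = rep(rows_id, times = t),
             trait = rep(seq_len(t), each = nr),
             value = as.vector(y),
             fixed_level = rep(rows_cg, times = t),
             record_no = rep(rows_rec, times = t))
}

#' Sample the genotyped subset of a pedigree
#'
#' Each animal is genotyped independently with probability
#' `prop_genotyped` (deterministic given the configuration seed).
#'
#' @param ped an `igp_pedigree`.
#' @param config an `igp_config`.
#' @return vector of genotyped animal ids in pedigree order.
#' @export
sample_genotyped <- function(ped, config) {
  set.seed(config$seed + 3L)
  keep <- runif(nrow(ped)) < config$prop_genotyped
  if (!any(keep)) stop("no animals genotyped; increase prop_genotyped")
  ped$id[keep]
}

#' Partition animals into GEBV, IGP and nongenotyped sets
#'
#' Genotyped animals with phenotype records or progeny obtain GEBV from the
#' ssGBLUP; genotyped animals with neither, born at or after the cutoff
#' year, are the indirect-prediction (IGP) targets.  Genotyped animals with
#' neither phenotypes nor progeny but born before the cutoff remain in the
#' GEBV set, so the two sets are disjoint and exhaust the genotyped pool.
#'
#' @param ped an `igp_pedigree`.
#' @param phen phenotype records (`id` column used).
#' @param geno genotype matrix; its rownames define the genotyped set.
#' @param cutoff_year birth-year start date for IGP eligibility.
#' @return list of class `igp_partition` with `gebv_ids`, `igp_ids`,
#'   `nongenotyped_ids`, `cutoff_year` and `shares` (percent of genotyped
#'   animals in the GEBV and IGP sets, rounded to integers).
#' @export
partition_animals <- function(ped, phen, geno, cutoff_year) {
  ped <- if (inherits(ped, "igp_pedigree")) ped else as_pedigree(ped)
  gids <- rownames(geno)
  pos <- match(gids, as.character(ped$id))
  if (anyNA(pos))
    stop("genotyped animals absent from pedigree: ",
         paste(head(gids[is.na(pos)]), collapse = ", "))
  has_phen <- gids %in% as.character(unique(phen$id))
  parents <- unique(c(ped$sire, ped$dam))
  has_prog <- gids %in% as.character(parents[parents != 0L])
  born_after <- ped$birth_year[pos] >= cutoff_year
  igp <- !has_phen & !has_prog & born_after
  out <- list(gebv_ids = gids[!igp], igp_ids = gids[igp],
              nongenotyped_ids = as.character(setdiff(ped$id, as.integer(gids))),
              cutoff_year = cutoff_year,
              shares = partition_shares(sum(!igp), sum(igp)))
  class(out) <- "igp_partition"
  out
}

#' GEBV/IGP shares of the genotyped pool
#'
#' @param n_gebv genotyped animals obtaining GEBV directly.
#' @param n_igp genotyped animals obtaining IGP.
#' @return named vector of integer-rounded percentages.
#' @export
partition_shares <- function(n_gebv, n_igp) {
  total <- n_gebv + n_igp
  c(gebv = round(100 * n_gebv / total), igp = round(100 * n_igp / total))
}

#' Simulate a complete evaluation dataset
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genotypes()], [sample_genotyped()], [simulate_phenotypes()]
#' and [partition_animals()].  The partition cutoff defaults to the
#' youngest cohort's birth year.
#'
#' @param config an `igp_config`.
#' @param cutoff_year IGP start date; default the last generation.
#' @return list with `config`, `pedigree`, `truth`, `genotypes` (genotyped
#'   animals only), `phenotypes`, `partition`, `vc`, `genetic_sd`.
#' @export
simulate_dataset <- function(config, cutoff_year = NULL) {
  sim <- simulate_pedigree(config)
  geno_all <- simulate_genotypes(sim$pedigree, config)
  gids <- sample_genotyped(sim$pedigree, config)
  geno <- geno_all[as.character(gids), , drop = FALSE]
  phen <- simulate_phenotypes(sim$pedigree, sim$truth, config)
  if (is.null(cutoff_year)) cutoff_year <- max(sim$pedigree$birth_year)
  part <- partition_animals(sim$pedigree, phen, geno, cutoff_year)
  vc <- variance_components(config)
  list(config = config, pedigree = sim$pedigree, truth = sim$truth,
       genotypes = geno, phenotypes = phen, partition = part, vc = vc,
       genetic_sd = sqrt(diag(vc$Sa)))
}
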