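test_that("a one-generation configuration yields founders only", {
  cfg <- simulation_config(n_founders = 10, n_generations = 1, n_traits = 1)
  sim <- simulate_pedigree(cfg)
  expect_equal(nrow(sim$pedigree), 10L)
  expect_true(all(sim$pedigree$sire == 0 & sim$pedigree$dam == 0))
  expect_setequal(unique(sim$pedigree$sex), c("M", "F"))
})

test_that("simulation is bit-identical under the same configuration", {
  cfg <- small_config(seed = 21)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})

test_that("without selection the genetic trend vanishes", {
  cfg <- simulation_config(n_founders = 1200, n_generations = 6,
                           offspring_per_dam = 8, selection_intensity = 0.25,
                           selection_weights = 0, n_traits = 1, seed = 22)
  sim <- simulate_pedigree(cfg)
  tr <- genetic_trend(sim$truth$tbv, sim$pedigree,
                      genetic_sd = sqrt(cfg$heritabilities))
  # cohort-mean SE ~ sigma_a/sqrt(1200); 3-SE band on the fitted slope
  expect_lt(abs(tr), 0.03 / sqrt(cfg$heritabilities))
})

test_that("truncation selection delivers the breeder's-equation response", {
  p <- 0.2
  i <- dnorm(qnorm(1 - p)) / p   # selection intensity for proportion p
  gains <- sapply(1:10, function(s) {
    cfg <- simulation_config(n_founders = 500, n_generations = 5,
                             offspring_per_dam = 10, selection_intensity = p,
                             n_traits = 1, heritabilities = 0.3, seed = 100 + s)
    sim <- simulate_pedigree(cfg)
    genetic_trend(sim$truth$tbv, sim$pedigree,
                  genetic_sd = sqrt(0.3))
  })
  # selection acts on true breeding values (accuracy 1): expected gain is
  # i * sigma_a per generation, eroded by finite-pool order statistics,
  # family co-selection and inbreeding
  expect_gt(mean(gains), 0)
  expect_lt(abs(mean(gains) - i) / i, 0.25)
})

test_that("selection so strong that no parents remain is reported", {
  cfg <- simulation_config(n_founders = 10, n_generations = 3,
                           selection_intensity = 0.05, n_traits = 1)
  expect_error(simulate_pedigree(cfg), "generation")
})

test_that("gene dropping respects Mendelian inheritance and expectations", {
  cfg0 <- simulation_config(n_founders = 10, n_generations = 1,
                            n_markers = 0, n_traits = 1)
  sim0 <- simulate_pedigree(cfg0)
  expect_equal(ncol(simulate_genotypes(sim0$pedigree, cfg0)), 0L)
  # founder frequency fixed at 0.5: mean code 1 within 3 binomial SEs
  cfg <- simulation_config(n_founders = 200, n_generations = 1,
                           n_markers = 1000, founder_maf_range = c(0.5, 0.5),
                           n_traits = 1, seed = 23)
  sim <- simulate_pedigree(cfg)
  g <- simulate_genotypes(sim$pedigree, cfg)
  se <- sqrt(2 * 0.5 * 0.5 / (200 * 1000))
  expect_lt(abs(mean(g) - 1), 3 * se)
  # both parents homozygous 0 at a marker -> all offspring 0
  cfg2 <- small_config(seed = 24)
  sim2 <- simulate_pedigree(cfg2)
  g2 <- simulate_genotypes(sim2$pedigree, cfg2)
  ped2 <- as.data.frame(sim2$pedigree)
  kids <- which(ped2$sire != 0)
  si <- match(ped2$sire[kids], ped2$id)
  di <- match(ped2$dam[kids], ped2$id)
  zero_parents <- g2[si, ] == 0L & g2[di, ] == 0L
  expect_true(all(g2[kids, ][zero_parents] == 0L))
})

test_that("gene-drop frequencies are preserved in expectation", {
  cfg <- simulation_config(n_founders = 80, n_generations = 3,
                           offspring_per_dam = 8, selection_weights = 0,
                           n_markers = 200, founder_maf_range = c(0.3, 0.3),
                           n_traits = 1, seed = 30)
  sim <- simulate_pedigree(cfg)
  freqs <- sapply(1:20, function(k) {
    cfg_k <- simulation_config(n_founders = 80, n_generations = 3,
                               offspring_per_dam = 8, selection_weights = 0,
                               n_markers = 200, founder_maf_range = c(0.3, 0.3),
                               n_traits = 1, seed = 1000 + k)
    mean(simulate_genotypes(sim$pedigree, cfg_k)) / 2
  })
  se <- sd(freqs) / sqrt(20)
  expect_lt(abs(mean(freqs) - 0.3), 3 * se)
})

test_that("missing genotype injection produces valid missing codes", {
  cfg <- small_config(seed = 25, missing_rate = 0.1)
  sim <- simulate_pedigree(cfg)
  g <- simulate_genotypes(sim$pedigree, cfg)
  expect_gt(mean(is.na(g)), 0.05)
  expect_true(all(g[!is.na(g)] %in% 0:2))
})

test_that("phenotype variance components are recovered", {
  # degenerate: heritability 1, no residual, no permanent environment
  cfg1 <- simulation_config(n_founders = 60, n_generations = 3,
                            heritabilities = 1, repeatability = 1,
                            records_per_animal = 1, fixed_effect_sd = 0,
                            n_traits = 1, seed = 26)
  sim1 <- simulate_pedigree(cfg1)
  ph1 <- simulate_phenotypes(sim1$pedigree, sim1$truth, cfg1)
  tbv1 <- sim1$truth$tbv[as.character(ph1$id), 1]
  expect_equal(ph1$value, unname(tbv1), tolerance = 1e-6)
  # repeatability = h2: repeated records differ only by residual noise
  cfg2 <- simulation_config(n_founders = 400, n_generations = 3,
                            heritabilities = 0.3, repeatability = 0.3,
                            records_per_animal = 2, n_traits = 1, seed = 27)
  sim2 <- simulate_pedigree(cfg2)
  ph2 <- simulate_phenotypes(sim2$pedigree, sim2$truth, cfg2)
  expect_null(variance_components(cfg2)$Spe)
  w <- reshape(ph2[ph2$trait == 1, c("id", "record_no", "value")],
               direction = "wide", idvar = "id", timevar = "record_no")
  dev <- w$value.1 - w$value.2
  # ~3 Monte-Carlo SEs of a variance estimate on ~300 animals
  expect_equal(var(dev), 2 * 0.7, tolerance = 0.25)
  # h2 = 0.3: var(TBV)/var(y) ~ 0.3 averaged over seeds
  ratios <- sapply(1:10, function(s) {
    cfg <- simulation_config(n_founders = 800, n_generations = 3,
                             selection_weights = 0, heritabilities = 0.3,
                             repeatability = 0.3, records_per_animal = 1,
                             fixed_effect_sd = 0, n_markers = 0,
                             prop_phenotyped_females = 1, n_traits = 1,
                             seed = 200 + s)
    sim <- simulate_pedigree(cfg)
    ph <- simulate_phenotypes(sim$pedigree, sim$truth, cfg)
    var(sim$truth$tbv[as.character(ph$id), 1]) / var(ph$value)
  })
  expect_equal(mean(ratios), 0.3, tolerance = 0.05)
})

test_that("animal partition follows the phenotype/progeny/cutoff rule", {
  ped <- as_pedigree(data.frame(
    id = 1:8,
    sire = c(0, 0, 0, 0, 1, 1, 1, 1),
    dam = c(0, 0, 0, 0, 2, 2, 3, 3),
    birth_year = c(2000, 2000, 2000, 2000, 2005, 2005, 2005, 2005),
    sex = c("M", "F", "F", "F", "M", "F", "M", "F")))
  phen <- data.frame(id = c(2, 3, 6), trait = 1, value = 0,
                     fixed_level = "cg", record_no = 1)
  geno <- matrix(1L, 5, 2, dimnames = list(c(2, 3, 6, 7, 8), c("M1", "M2")))
  part <- partition_animals(ped, phen, geno, cutoff_year = 2005)
  # 3 genotyped with phenotypes, 2 genotyped young without -> 60% / 40%
  expect_setequal(part$gebv_ids, c("2", "3", "6"))
  expect_setequal(part$igp_ids, c("7", "8"))
  expect_equal(unname(part$shares), c(60, 40))
  # a genotyped sire with progeny but no phenotypes belongs to the GEBV set
  geno2 <- rbind(geno, matrix(1L, 1, 2, dimnames = list("1", NULL)))
  part2 <- partition_animals(ped, phen, geno2, cutoff_year = 2005)
  expect_true("1" %in% part2$gebv_ids)
  expect_error(partition_animals(ped, phen,
                                 rbind(geno, matrix(1L, 1, 2,
                                                    dimnames = list("99", NULL))),
                                 2005), "99")
})

test_that("partition shares reproduce the published Holstein counts", {
  expect_equal(unname(partition_shares(886176, 1448775)), c(38, 62))
  expect_equal(unname(partition_shares(2054690, 280261)["gebv"]), 88,
               ignore_attr = TRUE)
})

test_that("partition is exhaustive and disjoint on simulated data", {
  d <- simulate_dataset(small_config(seed = 28))
  part <- d$partition
  expect_length(intersect(part$gebv_ids, part$igp_ids), 0)
  expect_setequal(c(part$gebv_ids, part$igp_ids), rownames(d$genotypes))
  expect_setequal(c(part$gebv_ids, part$igp_ids, part$nongenotyped_ids),
                  as.character(d$pedigree$id))
  # IGP members: born at/after cutoff, no progeny, no phenotypes
  ped <- as.data.frame(d$pedigree)
  pos <- match(part$igp_ids, as.character(ped$id))
  expect_true(all(ped$birth_year[pos] >= part$cutoff_year))
  parents <- as.character(c(ped$sire, ped$dam))
  expect_length(intersect(part$igp_ids, parents), 0)
  expect_length(intersect(part$igp_ids, as.character(d$phenotypes$id)), 0)
})
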