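test_that("H-inverse reduces to A-inverse without genotypes and when G = A22", {
  cfg <- small_config(seed = 31)
  d <- simulate_dataset(cfg)
  Ainv <- build_A_inverse(d$pedigree)
  H0 <- assemble_H_inverse(Ainv)
  set.seed(1)
  v <- matrix(rnorm(nrow(d$pedigree) * 2), nrow(d$pedigree))
  expect_equal(H0$multiply(v), as.matrix(Ainv %*% v), ignore_attr = TRUE)
  # G := A22 makes the genomic correction cancel exactly
  A22 <- build_A(d$pedigree, rownames(d$genotypes))
  A22inv <- invert_dense_psd(A22)
  H1 <- assemble_H_inverse(Ainv, A22inv, A22inv, rownames(d$genotypes))
  expect_lt(max(abs(H1$multiply(v) - as.matrix(Ainv %*% v))), 1e-8)
})

test_that("H-inverse matvec matches the densely assembled H-inverse", {
  cfg <- simulation_config(n_founders = 40, n_generations = 3,
                           offspring_per_dam = 8, n_markers = 400,
                           n_traits = 1, prop_genotyped = 0.5, seed = 32)
  d <- simulate_dataset(cfg)
  n <- nrow(d$pedigree)
  gids <- rownames(d$genotypes)
  Ainv <- build_A_inverse(d$pedigree)
  A22inv <- invert_dense_psd(build_A(d$pedigree, gids))
  fr <- allele_frequencies(d$genotypes)
  G <- build_G(center_genotypes(d$genotypes, fr), fr,
               A22 = build_A(d$pedigree, gids))
  Ginv <- invert_dense_psd(G$G)
  H <- assemble_H_inverse(Ainv, Ginv, A22inv, gids)
  Hdense <- as.matrix(Ainv)
  pos <- match(gids, as.character(d$pedigree$id))
  Hdense[pos, pos] <- Hdense[pos, pos] + Ginv - A22inv
  set.seed(2)
  v <- matrix(rnorm(n * 2), n)
  expect_lt(max(abs(H$multiply(v) - Hdense %*% v)), 1e-8)
  expect_lt(max(abs(H$diagonal() - diag(Hdense))), 1e-8)
  # APY-represented G-inverse agrees with its own dense form inside H
  set.seed(3)
  apy <- apy_inverse(G, sample(gids, 20))
  Hapy <- assemble_H_inverse(Ainv, apy, A22inv, gids)
  Gapy_dense <- matrix(0, length(gids), length(gids))
  perm <- match(apy$ids, gids)
  Gapy_dense[perm, perm] <- apy$multiply(diag(length(gids)))
  Hdense2 <- as.matrix(Ainv)
  Hdense2[pos, pos] <- Hdense2[pos, pos] + Gapy_dense - A22inv
  expect_lt(max(abs(Hapy$multiply(v) - Hdense2 %*% v)), 1e-8)
})

test_that("the MME solution equals the closed-form shrunken mean", {
  # one animal, one record, one fixed level: 2x2 system solved by hand
  ped <- as_pedigree(data.frame(id = 1, sire = 0, dam = 0,
                                birth_year = 2000, sex = "F"))
  vc <- list(Sa = matrix(0.4), Spe = NULL, Se = matrix(0.6))
  y <- 2.5
  phen <- data.frame(id = 1, trait = 1, value = y, fixed_level = "cg",
                     record_no = 1)
  fit <- run_ssgblup(ped, NULL, phen, vc, genomic = FALSE)
  C <- matrix(c(1, 1, 1, 1 + 0.6 / 0.4), 2) / 0.6
  sol <- solve(C, c(y, y) / 0.6)
  expect_equal(unname(fit$fixed[1, 1]), sol[1], tolerance = 1e-8)
  expect_equal(unname(fit$ebv[1, 1]), sol[2], tolerance = 1e-8)
})

test_that("all-zero phenotypes give all-zero breeding values", {
  cfg <- small_config(seed = 33)
  d <- simulate_dataset(cfg)
  phen0 <- d$phenotypes
  phen0$value <- 0
  fit <- run_ssgblup(d$pedigree, NULL, phen0, d$vc, genomic = FALSE)
  expect_equal(max(abs(fit$ebv)), 0)
})

test_that("uncorrelated two-trait solves separate into single-trait solves", {
  cfg <- simulation_config(n_founders = 30, n_generations = 3,
                           n_markers = 200, n_traits = 2,
                           genetic_correlations = 0, seed = 34)
  d <- simulate_dataset(cfg)
  both <- run_ssgblup(d$pedigree, d$genotypes, d$phenotypes, d$vc,
                      tol = 1e-16, max_iter = 3000)
  for (j in 1:2) {
    vcj <- list(Sa = d$vc$Sa[j, j, drop = FALSE],
                Spe = d$vc$Spe[j, j, drop = FALSE],
                Se = d$vc$Se[j, j, drop = FALSE])
    phenj <- d$phenotypes[d$phenotypes$trait == j, ]
    phenj$trait <- 1
    single <- run_ssgblup(d$pedigree, d$genotypes, phenj, vcj,
                          tol = 1e-16, max_iter = 3000)
    expect_lt(max(abs(both$ebv[, j] - single$ebv[, 1])), 1e-7)
  }
})

test_that("PCG solves the identity in one iteration and is monotone in tol", {
  b <- matrix(c(1, -2, 3), 3)
  sys <- list(matvec = identity, rhs = b, precondition = identity)
  sol <- pcg_solve(sys)
  expect_equal(sol$x, b)
  expect_equal(sol$iterations, 1L)
  cfg <- small_config(seed = 35)
  d <- simulate_dataset(cfg)
  H <- assemble_H_inverse(build_A_inverse(d$pedigree))
  sys2 <- build_mme(d$phenotypes, d$vc, H)
  loose <- pcg_solve(sys2, tol = 1e-4)
  tight <- pcg_solve(sys2, tol = 1e-12)
  expect_lte(loose$iterations, tight$iterations)
  expect_true(tight$converged)
})

test_that("PCG matches a dense factorization of the assembled equations", {
  cfg <- simulation_config(n_founders = 24, n_generations = 3,
                           n_markers = 150, n_traits = 2, seed = 36)
  d <- simulate_dataset(cfg)
  fr <- allele_frequencies(d$genotypes)
  gids <- rownames(d$genotypes)
  Ainv <- build_A_inverse(d$pedigree)
  A22 <- build_A(d$pedigree, gids)
  A22inv <- invert_dense_psd(A22)
  G <- build_G(center_genotypes(d$genotypes, fr), fr, A22 = A22)
  H <- assemble_H_inverse(Ainv, invert_dense_psd(G$G), A22inv, gids)
  sys <- build_mme(d$phenotypes, d$vc, H)
  L <- nrow(sys$rhs); t <- ncol(sys$rhs)
  expect_lte(L * t, 500)
  C <- matrix(0, L * t, L * t)
  for (j in seq_len(L * t)) {
    e <- matrix(0, L, t); e[j] <- 1
    C[, j] <- as.vector(sys$matvec(e))
  }
  expect_true(isSymmetric(C, tol = 1e-8))
  dense <- matrix(solve(C, as.vector(sys$rhs)), L, t)
  sol <- pcg_solve(sys, tol = 1e-16, max_iter = 5000)
  expect_lt(max(abs(sol$x - dense)), 1e-6 * max(abs(dense)))
})

test_that("repeated solves are bit-identical and reductions hold end-to-end", {
  cfg <- small_config(seed = 37)
  d <- simulate_dataset(cfg)
  r1 <- run_ssgblup(d$pedigree, d$genotypes, d$phenotypes, d$vc)
  r2 <- run_ssgblup(d$pedigree, d$genotypes, d$phenotypes, d$vc)
  expect_identical(r1$ebv, r2$ebv)
  # pedigree BLUP vs ssGBLUP with G := A22: identical evaluations
  ped_blup <- run_ssgblup(d$pedigree, NULL, d$phenotypes, d$vc,
                          genomic = FALSE)
  a22 <- run_ssgblup(d$pedigree, d$genotypes, d$phenotypes, d$vc,
                     G_matrix = build_A(d$pedigree, rownames(d$genotypes)))
  expect_lt(max(abs(ped_blup$ebv - a22$ebv)), 1e-6)
  # APY with the full genotyped set as core reproduces the direct inverse
  full_core <- run_ssgblup(d$pedigree, d$genotypes, d$phenotypes, d$vc,
                           apy_core = nrow(d$genotypes))
  expect_lt(max(abs(r1$ebv - full_core$ebv)),
            1e-4 * sqrt(d$vc$Sa[1, 1]))
  # the genomic and pedigree evaluations agree closely for phenotyped animals
  ok <- unique(as.character(d$phenotypes$id))
  expect_gt(cor(r1$ebv[ok, 1], ped_blup$ebv[ok, 1]), 0.9)
})
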