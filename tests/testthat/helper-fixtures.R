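# Shared fixtures, all built in code.

# sire/dam trio: two unrelated founders and their offspring
trio_pedigree <- function() {
  as_pedigree(data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2),
                         birth_year = c(2000, 2000, 2001),
                         sex = c("M", "F", "M")))
}

# two founders, two full sibs, and an offspring of the sib mating
fullsib_pedigree <- function() {
  as_pedigree(data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3),
                         dam = c(0, 0, 2, 2, 4),
                         birth_year = c(2000, 2000, 2001, 2001, 2002),
                         sex = c("M", "F", "M", "F", "M")))
}

# a selected multi-generation population small enough for dense oracles
small_config <- function(seed = 1, ...) {
  simulation_config(n_founders = 40, n_generations = 4, n_markers = 300,
                    n_traits = 1, heritabilities = 0.3, seed = seed, ...)
}

random_spd <- function(n, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n)
  crossprod(M) / n + diag(n)
}

# allele-frequency object with known frequencies (bypasses estimation)
known_freqs <- function(p, ids = character(0)) {
  structure(list(p = p, monomorphic = p <= 0 | p >= 1, ids = ids),
            class = "igp_freqs")
}
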