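## SNP-effect backsolving: u-hat = lambda D Z' G^-1 a-hat, with D = I and
## lambda = sigma_u^2 / sigma_a^2 = 1/k under VanRaden method 1.

#' Random subset of GEBV animals for backsolving
#'
#' Uniform sample without replacement, deterministic given the seed.
#'
#' @param gebv_ids ids of genotyped animals with GEBV.
#' @param n subset size; `n == length(gebv_ids)` returns the full set.
#' @param seed integer seed.
#' @return vector of selected ids.
#' @export
select_backsolve_subset <- function(gebv_ids, n, seed = 1L) {
  if (n > length(gebv_ids))
    stop(sprintf("requested subset of %d exceeds the %d available GEBV animals",
                 n, length(gebv_ids)))
  if (n == length(gebv_ids)) return(gebv_ids)
  set.seed(seed)
  sort(sample(gebv_ids, n))
}

#' Backsolve SNP marker effects from GEBV
#'
#' u-hat = lambda D Z' G^-1 a-hat per trait, with D = I and
#' lambda = 1/k where k = 2 sum p(1-p) is the VanRaden scaling used to
#' build G = ZZ'/k from the same allele frequencies.  The subset's G is
#' blended toward the identity by `blend_beta` and inverted directly (no
#' APY is needed at backsolving scale).  At `blend_beta = 0` and full rank,
#' Z u-hat reproduces the subset GEBV exactly.
#'
#' @param Z_subset centered genotypes of the backsolving animals (rows
#'   aligned with `gebv_subset`).
#' @param gebv_subset GEBV matrix (animals x traits) with matching rownames.
#' @param freqs the allele frequencies used to center `Z_subset`.
#' @param blend_beta blending fraction toward the identity, default 0.05.
#' @return list of class `igp_snp_effects`: `u` (markers x traits),
#'   `freqs`, `lambda`, `k`, `beta`, `ids`.
#' @export
backsolve_snp_effects <- function(Z_subset, gebv_subset, freqs,
                                  blend_beta = 0.05) {
  Z_subset <- as.matrix(Z_subset)
  gebv_subset <- as.matrix(gebv_subset)
  if (nrow(Z_subset) != nrow(gebv_subset))
    stop("genotype rows and GEBV rows differ in count")
  if (!is.null(rownames(Z_subset)) && !is.null(rownames(gebv_subset)) &&
      !identical(rownames(Z_subset), rownames(gebv_subset)))
    stop("genotype and GEBV rows are not aligned")
  G <- build_G(Z_subset, freqs, blend_beta = blend_beta, A22 = NULL)
  Ginv <- tryCatch(invert_dense_psd(G$G), error = function(e)
    stop("subset G is not invertible even after blending: ",
         conditionMessage(e)))
  lambda <- 1 / G$k
  u <- lambda * crossprod(Z_subset, Ginv %*% gebv_subset)
  rownames(u) <- colnames(Z_subset)
  structure(list(u = u, freqs = freqs, lambda = lambda, k = G$k,
                 beta = blend_beta, ids = rownames(Z_subset)),
            class = "igp_snp_effects")
}
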