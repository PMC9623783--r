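## Indirect genomic prediction IGP = Z u-hat and genetic-base adjustment.

#' Indirect genomic prediction of target animals
#'
#' IGP = Z_targets u-hat per trait.  Missing genotypes were replaced by
#' their expectation during centering, so they contribute 0.
#'
#' @param Z_targets centered genotypes of the target animals, on the same
#'   marker panel (and the same allele frequencies) as the backsolve.
#' @param effects SNP effects from [backsolve_snp_effects()].
#' @return list of class `igp_result`: `igp` (targets x traits matrix),
#'   `adjustment` (per-trait, 0 until [adjust_genetic_base()]), `effects_ids`
#'   (the backsolving animal set).
#' @export
predict_igp <- function(Z_targets, effects) {
  Z_targets <- as.matrix(Z_targets)
  if (ncol(Z_targets) != nrow(effects$u))
    stop(sprintf("marker mismatch: targets have %d markers, effects %d",
                 ncol(Z_targets), nrow(effects$u)))
  igp <- Z_targets %*% effects$u
  structure(list(igp = igp, adjustment = rep(0, ncol(igp)),
                 effects_ids = effects$ids),
            class = "igp_result")
}

#' Genetic-base adjustment of IGP
#'
#' GEBV and IGP sit on different genetic bases; on a reference set with
#' both values the offset is removed either by the per-trait mean
#' difference (adds mean(GEBV) - mean(IGP)) or by applying the validation
#' regression b0 + b1 * IGP.
#'
#' @param igp an `igp_result`.
#' @param reference_gebv GEBV matrix of the reference animals.
#' @param reference_igp IGP (or fitted Z u-hat) matrix of the same animals,
#'   rows aligned with `reference_gebv`.
#' @param mode `"mean_difference"` or `"intercept"`.
#' @return the adjusted `igp_result`; `adjustment` records the per-trait
#'   additive shift (mean-difference mode) or intercepts (intercept mode).
#' @export
adjust_genetic_base <- function(igp, reference_gebv, reference_igp,
                                mode = c("mean_difference", "intercept")) {
  mode <- match.arg(mode)
  reference_gebv <- as.matrix(reference_gebv)
  reference_igp <- as.matrix(reference_igp)
  if (nrow(reference_gebv) == 0L) stop("empty reference set")
  if (!all(dim(reference_gebv) == dim(reference_igp)))
    stop("reference GEBV and IGP dimensions differ")
  t <- ncol(igp$igp)
  if (mode == "mean_difference") {
    shift <- colMeans(reference_gebv) - colMeans(reference_igp)
    igp$igp <- sweep(igp$igp, 2L, shift, `+`)
    igp$adjustment <- igp$adjustment + shift
  } else {
    for (j in seq_len(t)) {
      fit <- lm(reference_gebv[, j] ~ reference_igp[, j])
      b <- coef(fit)
      igp$igp[, j] <- b[1] + b[2] * igp$igp[, j]
      igp$adjustment[j] <- b[1]
    }
  }
  igp
}
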