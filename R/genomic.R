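## Genomic relationship machinery: allele frequencies, centering, VanRaden G
## with blending, direct and APY inversion, spectral core-size estimation.

#' Allele frequencies of the counted allele
#'
#' Frequency of the counted allele per marker, computed from the 0/1/2
#' dosage codes of the given animals, excluding missing entries.
#' Monomorphic markers (p of 0 or 1) are flagged, not dropped.
#'
#' @param geno genotype matrix (animals x markers, codes 0/1/2, `NA` missing)
#'   with animal ids as rownames.
#' @param ids animals to compute from; default all rows.
#' @return list with `p` (named frequency vector), `monomorphic` (logical),
#'   `ids` (source animal set), class `igp_freqs`.
#' @export
allele_frequencies <- function(geno, ids = rownames(geno)) {
  pos <- match(ids, rownames(geno))
  if (anyNA(pos))
    stop("ids absent from genotype matrix: ",
         paste(head(ids[is.na(pos)]), collapse = ", "))
  m <- geno[pos, , drop = FALSE]
  nobs <- colSums(!is.na(m))
  if (any(nobs == 0L))
    stop("markers with all genotypes missing: ",
         paste(head(colnames(m)[nobs == 0L]), collapse = ", "))
  p <- colSums(m, na.rm = TRUE) / (2 * nobs)
  structure(list(p = p, monomorphic = p <= 0 | p >= 1, ids = ids),
            class = "igp_freqs")
}

#' Centered genotype matrix Z
#'
#' z_ij = m_ij - 2 p_j; a missing code is replaced by its expectation 2 p_j
#' so that it contributes 0 after centering.
#'
#' @param geno genotype matrix (animals x markers).
#' @param freqs allele frequencies from [allele_frequencies()].
#' @param ids rows to center; default all.
#' @return dense numeric matrix Z with the same dimnames subset.
#' @export
center_genotypes <- function(geno, freqs, ids = rownames(geno)) {
  pos <- match(ids, rownames(geno))
  if (anyNA(pos))
    stop("ids absent from genotype matrix: ",
         paste(head(ids[is.na(pos)]), collapse = ", "))
  if (ncol(geno) != length(freqs$p))
    stop("marker count of genotypes and frequencies differ")
  Z <- geno[pos, , drop = FALSE]
  Z[is.na(Z)] <- NA  # keep NA; replaced after centering
  Z <- sweep(Z, 2L, 2 * freqs$p, `-`)
  Z[is.na(Z)] <- 0
  Z
}

#' VanRaden genomic relationship matrix
#'
#' G_raw = Z Z' / k with k = 2 * sum_j p_j (1 - p_j) (VanRaden method 1),
#' then blended as G = (1 - beta) G_raw + beta A22 for invertibility; the
#' identity is used when no A22 is supplied.
#'
#' @param Z centered genotypes from [center_genotypes()].
#' @param freqs allele frequencies used to center Z.
#' @param blend_beta blending fraction in `[0, 1)`, default 0.05.
#' @param A22 optional pedigree relationship matrix of the same animals.
#' @return list with `G`, `ids`, `k`, `beta`, class `igp_grm`.
#' @export
build_G <- function(Z, freqs, blend_beta = 0.05, A22 = NULL) {
  k <- 2 * sum(freqs$p * (1 - freqs$p))
  if (k <= 0)
    stop("all markers monomorphic: scaling constant k = 2*sum p(1-p) is zero")
  G <- tcrossprod(Z) / k
  if (blend_beta > 0) {
    G <- (1 - blend_beta) * G
    if (is.null(A22)) {
      diag(G) <- diag(G) + blend_beta
    } else {
      A22 <- as.matrix(A22)
      if (!all(dim(A22) == dim(G)))
        stop("A22 dimension does not match the animal set")
      G <- G + blend_beta * A22
    }
  }
  structure(list(G = G, ids = rownames(Z), k = k, beta = blend_beta),
            class = "igp_grm")
}

#' APY sparse inverse of the genomic relationship matrix
#'
#' Algorithm of proven and young: the inverse is represented by the direct
#' inverse of the core block G_cc, the coupling P = G_nc G_cc^-1, and the
#' diagonal of noncore conditional (Mendelian-sampling-like) variances
#' m_ii = g_ii - g_ic G_cc^-1 g_ci.  The implied inverse
#' \deqn{G_{APY}^{-1} = [[G_{cc}^{-1} + P'M^{-1}P, -P'M^{-1}],
#'                       [-M^{-1}P, M^{-1}]]}
#' has zero entries between distinct noncore animals and is applied
#' matrix-free, never forming the dense noncore block.
#'
#' @param G an `igp_grm` (or plain symmetric matrix with dimnames).
#' @param core_ids animal ids to use as the core.
#' @return object of class `igp_apy` with elements `core_ids`, `noncore_ids`,
#'   `Gcc_inv`, `P`, `m`, `multiply(v)` (matrix-free matvec, `v` a vector or
#'   column matrix in the order `c(core_ids, noncore_ids)`), `diagonal()`,
#'   and `ids` (the operator's animal order).
#' @export
apy_inverse <- function(G, core_ids) {
  if (inherits(G, "igp_grm")) { ids <- G$ids; Gm <- G$G } else {
    Gm <- as.matrix(G); ids <- rownames(Gm)
  }
  if (length(core_ids) == 0L) stop("core set is empty")
  cpos <- match(as.character(core_ids), ids)
  if (anyNA(cpos))
    stop("core ids absent from G: ",
         paste(head(core_ids[is.na(cpos)]), collapse = ", "))
  npos <- setdiff(seq_along(ids), cpos)
  Gcc_inv <- invert_dense_psd(Gm[cpos, cpos, drop = FALSE])
  noncore_ids <- ids[npos]
  if (length(npos)) {
    Gnc <- Gm[npos, cpos, drop = FALSE]
    P <- Gnc %*% Gcc_inv                      # noncore x core
    m <- diag(Gm)[npos] - rowSums(P * Gnc)    # conditional variances
    if (any(m <= 1e-8))
      stop("noncore animals fully explained by the core (duplicate genotypes?): ",
           paste(head(noncore_ids[m <= 1e-8]), collapse = ", "))
  } else {
    P <- matrix(0, 0, length(cpos)); m <- numeric(0)
  }
  nc <- length(cpos); nn <- length(npos)
  op_ids <- c(ids[cpos], noncore_ids)
  multiply <- function(v) {
    v <- as.matrix(v)
    if (nrow(v) != nc + nn) stop("dimension mismatch in APY matvec")
    vc <- v[seq_len(nc), , drop = FALSE]
    out <- matrix(0, nc + nn, ncol(v))
    if (nn) {
      vn <- v[nc + seq_len(nn), , drop = FALSE]
      w <- (P %*% vc - vn) / m
      out[seq_len(nc), ] <- Gcc_inv %*% vc + crossprod(P, w)
      out[nc + seq_len(nn), ] <- -w
    } else {
      out[seq_len(nc), ] <- Gcc_inv %*% vc
    }
    rownames(out) <- op_ids
    out
  }
  diagonal <- function() {
    dc <- diag(Gcc_inv)
    if (nn) dc <- dc + as.vector(crossprod(P^2, 1 / m))
    setNames(c(dc, if (nn) 1 / m else numeric(0)), op_ids)
  }
  structure(list(core_ids = ids[cpos], noncore_ids = noncore_ids,
                 Gcc_inv = Gcc_inv, P = P, m = m, ids = op_ids,
                 multiply = multiply, diagonal = diagonal),
            class = "igp_apy")
}

#' Spectral estimate of the APY core size
#'
#' Smallest number k of top eigenvalues of G whose sum reaches
#' `threshold` of trace(G) — the number of (approximately) independent
#' chromosome segments the core should span.
#'
#' @param G an `igp_grm` or symmetric matrix.
#' @param threshold fraction of the variation in G to explain, in (0, 1].
#' @return integer core size.
#' @export
estimate_core_size <- function(G, threshold = 0.98) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  Gm <- if (inherits(G, "igp_grm")) G$G else as.matrix(G)
  ev <- eigen(Gm, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  total <- sum(ev)
  if (total <= 0) return(0L)
  as.integer(which(cumsum(ev) >= threshold * total - 1e-12)[1])
}
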