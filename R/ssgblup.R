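## Single-step GBLUP: H-inverse operator, mixed model equations for a
## multi-trait repeatability animal model, matrix-free PCG solver, and the
## orchestrating run_ssgblup().

#' Matrix-free H-inverse operator
#'
#' H^-1 combines the sparse pedigree inverse A^-1 over all animals with the
#' genomic correction (G^-1 - A22^-1) scattered into the genotyped block:
#' H^-1 v = A^-1 v + scatter(G^-1 v22 - A22^-1 v22).  The operator is never
#' formed densely; `Ginv` may be a dense inverse or an APY operator from
#' [apy_inverse()].
#'
#' @param Ainv sparse A-inverse with animal ids as dimnames.
#' @param Ginv dense G-inverse (dimnames required) or an `igp_apy`; `NULL`
#'   for pedigree-only BLUP.
#' @param A22inv dense inverse of the genotyped-animal block of A.
#' @param geno_ids genotyped animal ids in the order of `A22inv`.
#' @return list with `multiply(v)` (v an animals x traits matrix in
#'   pedigree order), `diagonal()`, `ids`; class `igp_hinv`.
#' @export
assemble_H_inverse <- function(Ainv, Ginv = NULL, A22inv = NULL,
                               geno_ids = NULL) {
  ped_ids <- rownames(Ainv)
  genomic <- !is.null(Ginv)
  if (genomic) {
    if (is.null(A22inv) || is.null(geno_ids))
      stop("A22inv and geno_ids are required with a genomic term")
    geno_ids <- as.character(geno_ids)
    gpos <- match(geno_ids, ped_ids)
    if (anyNA(gpos))
      stop("genotyped ids absent from pedigree: ",
           paste(head(geno_ids[is.na(gpos)]), collapse = ", "))
    if (inherits(Ginv, "igp_apy")) {
      if (length(Ginv$ids) != length(geno_ids))
        stop("dimension mismatch between G inverse and genotyped count")
      p_op <- match(Ginv$ids, geno_ids)
      gmult <- function(v22) {
        out <- matrix(0, nrow(v22), ncol(v22))
        out[p_op, ] <- Ginv$multiply(v22[p_op, , drop = FALSE])
        out
      }
      gdiag <- function() {
        d <- numeric(length(geno_ids)); d[p_op] <- Ginv$diagonal(); d
      }
    } else {
      Gi <- as.matrix(Ginv)
      if (nrow(Gi) != length(geno_ids))
        stop("dimension mismatch between G inverse and genotyped count")
      gmult <- function(v22) Gi %*% v22
      gdiag <- function() diag(Gi)
    }
    if (nrow(A22inv) != length(geno_ids))
      stop("dimension mismatch between A22 inverse and genotyped count")
  }
  multiply <- function(v) {
    v <- as.matrix(v)
    r <- as.matrix(Ainv %*% v)
    if (genomic) {
      v22 <- v[gpos, , drop = FALSE]
      r[gpos, ] <- r[gpos, ] + gmult(v22) - A22inv %*% v22
    }
    rownames(r) <- ped_ids
    r
  }
  diagonal <- function() {
    d <- Matrix::diag(Ainv)
    if (genomic) d[gpos] <- d[gpos] + gdiag() - diag(A22inv)
    setNames(d, ped_ids)
  }
  structure(list(multiply = multiply, diagonal = diagonal, ids = ped_ids),
            class = "igp_hinv")
}

#' Assemble the mixed model equations as a matrix-free system
#'
#' Multi-trait repeatability animal model: one fixed contemporary-group
#' factor, additive genetic effect with (co)variance Sa and relationship
#' operator H^-1 (or A^-1), and an optional permanent-environment effect
#' for phenotyped animals.  Solutions are laid out as an L x t matrix
#' (levels by traits); records with missing traits are handled by
#' residual-covariance subsetting per missingness pattern.
#'
#' @param phen phenotype records (`id, trait, value, fixed_level, record_no`).
#' @param vc variance components (`Sa`, `Spe` or `NULL`, `Se`).
#' @param Hinv relationship operator from [assemble_H_inverse()].
#' @return list of class `igp_mme` with `matvec(x)`, `rhs`,
#'   `precondition(r)` (block-diagonal by level, trait blocks), and
#'   `layout` (row spans of the fixed, animal, pe blocks).
#' @export
build_mme <- function(phen, vc, Hinv) {
  t <- nrow(vc$Sa)
  animals <- Hinv$ids
  bad <- setdiff(unique(as.character(phen$id)), animals)
  if (length(bad))
    stop("phenotyped animals absent from pedigree: ",
         paste(head(bad), collapse = ", "))
  use_pe <- !is.null(vc$Spe)
  ## one row per (animal, record) with a t-vector of observations
  key <- paste(phen$id, phen$record_no, sep = "\r")
  rec_keys <- unique(key)
  ri <- match(key, rec_keys)
  Y <- matrix(NA_real_, length(rec_keys), t)
  Y[cbind(ri, phen$trait)] <- phen$value
  rec_id <- as.character(phen$id[match(seq_along(rec_keys), ri)])
  rec_cg <- as.character(phen$fixed_level[match(seq_along(rec_keys), ri)])
  fixed_levels <- sort(unique(rec_cg))
  pe_ids <- if (use_pe) unique(rec_id) else character(0)
  nF <- length(fixed_levels); nA <- length(animals); nP <- length(pe_ids)
  L <- nF + nA + nP
  arows <- nF + seq_len(nA)
  prows <- if (nP) nF + nA + seq_len(nP) else integer(0)
  col_f <- match(rec_cg, fixed_levels)
  col_a <- nF + match(rec_id, animals)
  col_p <- if (nP) nF + nA + match(rec_id, pe_ids) else NULL
  nrec <- nrow(Y)
  ii <- c(seq_len(nrec), seq_len(nrec), if (nP) seq_len(nrec))
  jj <- c(col_f, col_a, col_p)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nrec, L))
  ## residual inverse per missingness pattern, zero-padded to t x t
  obs <- !is.na(Y)
  pat <- apply(obs, 1L, paste, collapse = "")
  pats <- unique(pat)
  Y0 <- Y; Y0[!obs] <- 0
  pieces <- lapply(pats, function(p) {
    rows <- which(pat == p)
    o <- obs[rows[1], ]
    if (!any(o)) return(NULL)
    Rinv <- matrix(0, t, t)
    Rinv[o, o] <- solve(vc$Se[o, o, drop = FALSE])
    Mp <- M[rows, , drop = FALSE]
    list(MtM = Matrix::crossprod(Mp),
         rhs = as.matrix(Matrix::crossprod(Mp, Y0[rows, , drop = FALSE] %*% Rinv)),
         Rinv = Rinv)
  })
  pieces <- Filter(Negate(is.null), pieces)
  Sa_inv <- solve(vc$Sa)
  Spe_inv <- if (use_pe) solve(vc$Spe) else NULL
  rhs <- matrix(0, L, t)
  for (p in pieces) rhs <- rhs + p$rhs
  matvec <- function(x) {
    x <- as.matrix(x)
    out <- matrix(0, L, t)
    for (p in pieces) out <- out + as.matrix(p$MtM %*% x) %*% p$Rinv
    out[arows, ] <- out[arows, ] +
      Hinv$multiply(x[arows, , drop = FALSE]) %*% Sa_inv
    if (nP) out[prows, ] <- out[prows, ] + x[prows, , drop = FALSE] %*% Spe_inv
    out
  }
  ## block-diagonal preconditioner: one t x t block per level
  dataDiag <- lapply(pieces, function(p) Matrix::diag(p$MtM))
  hdiag <- Hinv$diagonal()
  Pinv <- array(0, c(L, t, t))
  for (l in seq_len(L)) {
    B <- matrix(0, t, t)
    for (k in seq_along(pieces)) B <- B + dataDiag[[k]][l] * pieces[[k]]$Rinv
    if (l > nF && l <= nF + nA) B <- B + hdiag[l - nF] * Sa_inv
    if (nP && l > nF + nA) B <- B + Spe_inv
    Pinv[l, , ] <- solve(B)
  }
  precondition <- function(r) {
    out <- matrix(0, L, t)
    for (i in seq_len(t))
      for (j in seq_len(t))
        out[, i] <- out[, i] + Pinv[, i, j] * r[, j]
    out
  }
  structure(list(matvec = matvec, rhs = rhs, precondition = precondition,
                 n_traits = t,
                 layout = list(fixed_levels = fixed_levels, animals = animals,
                               pe_ids = pe_ids, arows = arows, prows = prows,
                               frows = seq_len(nF))),
            class = "igp_mme")
}

#' Preconditioned conjugate gradients for the mixed model equations
#'
#' Deterministic PCG with a zero start vector.  The convergence statistic
#' is the squared residual norm relative to the squared right-hand-side
#' norm, c = ||b - C x||^2 / ||b||^2.
#'
#' @param system an `igp_mme` (any list with `matvec`, `rhs`,
#'   `precondition`).
#' @param tol convergence tolerance on c (default 1e-12).
#' @param max_iter iteration cap.
#' @return list with `x` (solutions, levels x traits), `iterations`,
#'   `converged`, `criterion`.
#' @export
pcg_solve <- function(system, tol = 1e-12, max_iter = 1000L) {
  b <- system$rhs
  bnorm <- sum(b * b)
  x <- matrix(0, nrow(b), ncol(b))
  if (bnorm == 0)
    return(list(x = x, iterations = 0L, converged = TRUE, criterion = 0))
  r <- b
  z <- system$precondition(r)
  p <- z
  rz <- sum(r * z)
  crit <- sum(r * r) / bnorm
  iter <- 0L
  while (crit > tol && iter < max_iter) {
    iter <- iter + 1L
    q <- system$matvec(p)
    alpha <- rz / sum(p * q)
    x <- x + alpha * p
    r <- r - alpha * q
    crit <- sum(r * r) / bnorm
    if (crit <= tol) break
    z <- system$precondition(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterations = iter, converged = crit <= tol, criterion = crit)
}

#' Run a (single-step) genomic BLUP evaluation
#'
#' Orchestrates the whole solve: pedigree inverse, genotyped-block A22 and
#' its inverse, VanRaden G (blended toward A22), direct or APY inversion,
#' the H-inverse operator, MME assembly, and PCG.  With `genomic = FALSE`
#' (or no genotypes) the evaluation is ordinary pedigree BLUP.
#'
#' @param ped an `igp_pedigree`.
#' @param geno genotype matrix of the animals entering G (rownames = ids);
#'   may be `NULL`.
#' @param phen phenotype records.
#' @param vc variance components (`Sa`, `Spe`, `Se`).
#' @param genomic include the genomic term (default `TRUE` when genotypes
#'   are given).
#' @param apy_core `NULL` for direct inversion of G, an integer core size,
#'   or `"eigen98"`/`"eigen99"` to size the core from the eigenvalues of G.
#' @param core_seed seed for the random core draw.
#' @param blend_beta blending fraction of G toward A22.
#' @param freqs allele frequencies to center with; computed from `geno`
#'   when `NULL`.  Pass the full-pool frequencies to keep Z consistent
#'   across pipeline stages.
#' @param G_matrix optional replacement for G (testing aid, e.g. G = A22).
#' @param tol,max_iter PCG controls.
#' @return list of class `igp_gblup`: `ebv` (animals x traits, pedigree
#'   order), `fixed`, `pe`, `iterations`, `converged`, `criterion`,
#'   `core_ids`, `freqs`, `G`.
#' @export
run_ssgblup <- function(ped, geno, phen, vc, genomic = !is.null(geno),
                        apy_core = NULL, core_seed = 1L, blend_beta = 0.05,
                        freqs = NULL, G_matrix = NULL,
                        tol = 1e-12, max_iter = 1000L) {
  ped <- if (inherits(ped, "igp_pedigree")) ped else as_pedigree(ped)
  F <- compute_inbreeding(ped)
  Ainv <- build_A_inverse(ped, F)
  Ginv <- NULL; A22inv <- NULL; geno_ids <- NULL
  G <- NULL; core_ids <- NULL
  if (genomic && !is.null(geno) && nrow(geno) > 0L) {
    geno_ids <- rownames(geno)
    A22 <- build_A(ped, geno_ids)
    A22inv <- invert_dense_psd(A22)
    if (is.null(freqs)) freqs <- allele_frequencies(geno)
    if (is.null(G_matrix)) {
      Z <- center_genotypes(geno, freqs)
      G <- build_G(Z, freqs, blend_beta = blend_beta, A22 = A22)
    } else {
      G <- structure(list(G = as.matrix(G_matrix), ids = geno_ids, k = NA_real_,
                          beta = blend_beta), class = "igp_grm")
    }
    if (!is.null(apy_core)) {
      k <- if (identical(apy_core, "eigen98")) estimate_core_size(G, 0.98)
           else if (identical(apy_core, "eigen99")) estimate_core_size(G, 0.99)
           else as.integer(apy_core)
      if (k >= length(geno_ids)) {
        core_ids <- geno_ids
      } else {
        set.seed(core_seed)
        core_ids <- sort(sample(geno_ids, k))
      }
      Ginv <- apy_inverse(G, core_ids)
    } else {
      Ginv <- invert_dense_psd(G$G)
      dimnames(Ginv) <- list(geno_ids, geno_ids)
    }
  }
  Hinv <- assemble_H_inverse(Ainv, Ginv, A22inv, geno_ids)
  system <- build_mme(phen, vc, Hinv)
  sol <- pcg_solve(system, tol = tol, max_iter = max_iter)
  if (!sol$converged)
    warning(sprintf("PCG stopped at %d iterations, criterion %.3e",
                    sol$iterations, sol$criterion))
  lay <- system$layout
  ebv <- sol$x[lay$arows, , drop = FALSE]
  rownames(ebv) <- lay$animals
  fixed <- sol$x[lay$frows, , drop = FALSE]
  rownames(fixed) <- lay$fixed_levels
  pe <- if (length(lay$prows)) {
    m <- sol$x[lay$prows, , drop = FALSE]; rownames(m) <- lay$pe_ids; m
  } else NULL
  structure(list(ebv = ebv, fixed = fixed, pe = pe,
                 iterations = sol$iterations, converged = sol$converged,
                 criterion = sol$criterion, core_ids = core_ids,
                 freqs = freqs, G = G),
            class = "igp_gblup")
}
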