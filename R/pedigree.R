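## Pedigree container and pedigree-based relationship machinery.

#' Validate and normalise a pedigree table
#'
#' A pedigree is a data frame with columns `id`, `sire`, `dam`,
#' `birth_year`, `sex`.  Parent code 0 (or `NA`) means unknown.  Rows are
#' reordered so that parents precede offspring; original ids are kept and a
#' positional index is attached for internal use.
#'
#' @param df data frame with columns `id`, `sire`, `dam`, `birth_year`, `sex`.
#' @return the pedigree, class `igp_pedigree`, sorted parents-first.
#' @export
as_pedigree <- function(df) {
  required <- c("id", "sire", "dam", "birth_year", "sex")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  ped <- as.data.frame(df)[required]
  ped$id <- as.integer(ped$id)
  ped$sire <- as.integer(ifelse(is.na(ped$sire), 0L, ped$sire))
  ped$dam <- as.integer(ifelse(is.na(ped$dam), 0L, ped$dam))
  if (anyDuplicated(ped$id))
    stop("duplicated animal ids: ", paste(head(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (any(ped$id <= 0L)) stop("animal ids must be positive integers")
  if (any(ped$sire == ped$id) || any(ped$dam == ped$id))
    stop("animal listed as its own parent: ",
         ped$id[which(ped$sire == ped$id | ped$dam == ped$id)[1]])
  bad <- setdiff(c(ped$sire, ped$dam), c(0L, ped$id))
  if (length(bad))
    stop("parent ids absent from pedigree: ", paste(head(bad), collapse = ", "))
  ped <- ped_toposort(ped)
  class(ped) <- c("igp_pedigree", "data.frame")
  ped
}

## Kahn topological sort, erroring on cycles with the offending ids.
ped_toposort <- function(ped) {
  n <- nrow(ped)
  pos <- match(seq_len(n), seq_len(n))  # placeholder
  sire_i <- match(ped$sire, ped$id, nomatch = 0L)
  dam_i <- match(ped$dam, ped$id, nomatch = 0L)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_i[i], dam_i[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    ## stable order: founders and released animals in birth-year, id order
    ready <- ready[order(ped$birth_year[ready], ped$id[ready])]
    i <- ready[1]; ready <- ready[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) < n) {
    cyc <- setdiff(seq_len(n), order)
    stop("cyclic pedigree involving ids: ", paste(head(ped$id[cyc]), collapse = ", "))
  }
  ped[order, , drop = FALSE]
}

## 1-based positional sire/dam indices (0 = unknown) of a sorted pedigree.
ped_index <- function(ped) {
  list(sire = match(ped$sire, ped$id, nomatch = 0L),
       dam = match(ped$dam, ped$id, nomatch = 0L))
}

#' Inbreeding coefficients
#'
#' Computes per-animal inbreeding coefficients F (half the additive
#' relationship between the parents) by the Meuwissen-Luo traversal of the
#' L'DL decomposition of the numerator relationship matrix A.  Animals with
#' an unknown parent are treated as non-inbred members of an unrelated base
#' population (F = 0).
#'
#' @param ped an `igp_pedigree` (or coercible data frame).
#' @return named numeric vector of F, one entry per animal, in pedigree order.
#' @export
compute_inbreeding <- function(ped) {
  ped <- if (inherits(ped, "igp_pedigree")) ped else as_pedigree(ped)
  idx <- ped_index(ped)
  F <- ml_inbreeding(idx$sire, idx$dam)
  names(F) <- ped$id
  F
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A with the tabular
#' recursion a_ij = (a_i,sire(j) + a_i,dam(j)) / 2, a_ii = 1 + F_i.  When
#' `subset` is given, the full recursion is run and the requested rows and
#' columns (e.g. the genotyped animals, giving A22) are returned.
#'
#' @param ped an `igp_pedigree`.
#' @param subset optional vector of animal ids to restrict to (A22).
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
build_A <- function(ped, subset = NULL) {
  ped <- if (inherits(ped, "igp_pedigree")) ped else as_pedigree(ped)
  idx <- ped_index(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- idx$sire[i]; d <- idx$dam[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[prev, s]
      if (d > 0L) row <- row + 0.5 * A[prev, d]
      A[prev, i] <- row
      A[i, prev] <- row
    }
    A[i, i] <- if (s > 0L && d > 0L) 1 + 0.5 * A[s, d] else 1
  }
  dimnames(A) <- list(ped$id, ped$id)
  if (!is.null(subset)) {
    pos <- match(subset, ped$id)
    if (anyNA(pos))
      stop("subset ids absent from pedigree: ",
           paste(head(subset[is.na(pos)]), collapse = ", "))
    A <- A[pos, pos, drop = FALSE]
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' d_i to (i,i), -d_i/2 to (i,parent) and d_i/4 to each parent pair, where
#' 1/d_i is the Mendelian sampling variance fraction
#' (0.5 - 0.25(F_s + F_d) with both parents known, 0.75 - 0.25 F_p with
#' one, 1 with none).
#'
#' @param ped an `igp_pedigree`.
#' @param F inbreeding vector from [compute_inbreeding()]; computed if missing.
#' @return sparse symmetric matrix (`dsCMatrix`) in pedigree order.
#' @export
build_A_inverse <- function(ped, F = NULL) {
  ped <- if (inherits(ped, "igp_pedigree")) ped else as_pedigree(ped)
  if (is.null(F)) F <- compute_inbreeding(ped)
  if (length(F) != nrow(ped))
    stop("inbreeding vector length does not match pedigree")
  idx <- ped_index(ped)
  n <- nrow(ped)
  Fs <- ifelse(idx$sire > 0L, F[pmax(idx$sire, 1L)], -1)
  Fd <- ifelse(idx$dam > 0L, F[pmax(idx$dam, 1L)], -1)
  d <- 1 / (0.5 - 0.25 * (Fs + Fd))
  ii <- seq_len(n)
  rows <- ii; cols <- ii; vals <- d
  for (p in list(idx$sire, idx$dam)) {
    known <- p > 0L
    rows <- c(rows, ii[known], p[known], p[known])
    cols <- c(cols, p[known], ii[known], p[known])
    vals <- c(vals, -d[known] / 2, -d[known] / 2, d[known] / 4)
  }
  both <- idx$sire > 0L & idx$dam > 0L
  rows <- c(rows, idx$sire[both], idx$dam[both])
  cols <- c(cols, idx$dam[both], idx$sire[both])
  vals <- c(vals, d[both] / 4, d[both] / 4)
  Ainv <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  Ainv <- Matrix::forceSymmetric(Ainv, uplo = "L")
  dimnames(Ainv) <- list(ped$id, ped$id)
  Ainv
}

#' Invert a dense symmetric positive-definite matrix
#'
#' Cholesky-based inversion with an informative error (smallest eigenvalue,
#' blending advice) when the matrix is not positive definite.  Symmetry of
#' the result is enforced.
#'
#' @param m dense symmetric matrix.
#' @return dense symmetric inverse.
#' @export
invert_dense_psd <- function(m) {
  m <- as.matrix(m)
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(paste0("matrix is not positive definite (smallest eigenvalue ",
                        "%.3e); consider blending toward A22 or the identity"), ev))
  }
  inv <- chol2inv(ch)
  inv <- (inv + t(inv)) / 2
  dimnames(inv) <- dimnames(m)
  inv
}
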