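## File formats: pedigree/phenotype CSV, BLUPF90-style genotype text
## (id + contiguous 0/1/2 digit string, 5 = missing), SNP-effect tables.

#' Read and write pedigree files
#'
#' CSV with header `id,sire,dam,birth_year,sex`; 0 codes an unknown parent.
#'
#' @param path file path.
#' @return [read_pedigree()] returns an `igp_pedigree`.
#' @export
read_pedigree <- function(path) {
  as_pedigree(read.csv(path))
}

#' @rdname read_pedigree
#' @param ped pedigree to write.
#' @export
write_pedigree <- function(ped, path) {
  write.csv(as.data.frame(ped)[c("id", "sire", "dam", "birth_year", "sex")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write genotype files
#'
#' BLUPF90-style text: one animal per line, the id, whitespace, then a
#' contiguous digit string of per-marker codes (0/1/2, 5 = missing).
#' All lines must have the same marker count.
#'
#' @param path file path.
#' @return [read_genotypes()] returns an integer matrix (`NA` = missing)
#'   with animal ids as rownames.
#' @export
read_genotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genotype file: ", path)
  parts <- regmatches(lines, regexpr("^\\s*(\\S+)\\s+", lines))
  ids <- trimws(parts)
  codes <- mapply(function(l, p) substring(l, nchar(p) + 1L), lines, parts,
                  USE.NAMES = FALSE)
  codes <- gsub("\\s+$", "", codes)
  bad <- grepl("[^0125]", codes)
  if (any(bad))
    stop("invalid genotype codes (allowed 0/1/2, 5 = missing) on line(s): ",
         paste(head(which(bad)), collapse = ", "))
  width <- unique(nchar(codes))
  if (length(width) != 1L)
    stop("genotype string length differs on line(s): ",
         paste(head(which(nchar(codes) != nchar(codes[1]))), collapse = ", "))
  geno <- matrix(as.integer(unlist(strsplit(codes, ""), use.names = FALSE)),
                 nrow = length(ids), ncol = width, byrow = TRUE)
  geno[geno == 5L] <- NA_integer_
  dimnames(geno) <- list(ids, sprintf("M%d", seq_len(width)))
  geno
}

#' @rdname read_genotypes
#' @param geno genotype matrix to write (rownames = ids, `NA` = missing).
#' @export
write_genotypes <- function(geno, path) {
  g <- geno
  g[is.na(g)] <- 5L
  strings <- apply(g, 1L, paste, collapse = "")
  writeLines(paste(rownames(geno), strings), path)
  invisible(path)
}

#' Read and write phenotype files
#'
#' CSV with header `id,trait,value,fixed_level,record_no`.
#'
#' @param path file path.
#' @return [read_phenotypes()] returns the records data frame.
#' @export
read_phenotypes <- function(path) {
  phen <- read.csv(path)
  required <- c("id", "trait", "value", "fixed_level", "record_no")
  missing_cols <- setdiff(required, names(phen))
  if (length(missing_cols))
    stop("phenotype file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  phen[required]
}

#' @rdname read_phenotypes
#' @param phen records to write.
#' @export
write_phenotypes <- function(phen, path) {
  write.csv(phen, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write backsolved SNP effects
#'
#' CSV with header `marker,trait,effect,freq`.
#'
#' @param effects an `igp_snp_effects`.
#' @param path file path.
#' @export
write_snp_effects <- function(effects, path) {
  t <- ncol(effects$u)
  df <- data.frame(marker = rep(rownames(effects$u), times = t),
                   trait = rep(seq_len(t), each = nrow(effects$u)),
                   effect = as.vector(effects$u),
                   freq = rep(unname(effects$freqs$p), times = t))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
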