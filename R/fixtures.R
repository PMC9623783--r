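## Published per-trait validation summaries from a national US Holstein
## type-trait genomic evaluation, shipped as plain-text reference data.

#' Published Holstein type-trait IGP validation summary
#'
#' Per-trait validation statistics reported for 18 linear type traits in a
#' national US Holstein genomic evaluation in which SNP effects were
#' backsolved from 30K randomly selected genotyped animals: standardized
#' genetic trend (`dg`), intercept `b0`, slope `b1` and `r2` of the
#' regression of GEBV on IGP, and mean/maximum absolute GEBV-IGP
#' differences, split by sex.  `dg`, `b0`, `mean` and `max` are in
#' genetic-SD units; `b1` and `r2` are scale-free.
#'
#' @return data frame, one row per trait.
#' @export
holstein_igp_summary <- function() {
  read.csv(system.file("extdata", "holstein_igp_summary.csv",
                       package = "igpred"), check.names = TRUE)
}

#' Published Holstein genotyped-animal partition counts
#'
#' Numbers of genotyped US Holsteins obtaining GEBV directly versus IGP,
#' per birth-year start date of the IGP-eligible group (five nested year
#' groups, 2.33 million genotyped animals in total).
#'
#' @return data frame with columns `year_group`, `n_igp_male`,
#'   `n_igp_female`, `n_igp`, `n_gebv`.
#' @export
holstein_partition_counts <- function() {
  read.csv(system.file("extdata", "holstein_partition_counts.csv",
                       package = "igpred"), check.names = TRUE)
}
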