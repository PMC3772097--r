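# Bundled desk-scale reference datasets: published per-origin EMSA
# measurements and genome-wide ACS match counts.  These are inputs to the
# threshold-classification and motif-density arithmetic, not outputs of
# this package.

#' Published EMSA survey of 40 yeast origins
#'
#' Origin-specific apparent Kds (nM; `NA` means "ND", binding too weak to
#' determine) and orc2-1/ORC2 ChIP peak-area ratios for the
#' proof-of-principle panel: origins drawn from the lowest
#' (`ratio <= 0.3`) and highest (`ratio >= 0.8`) in-vivo affinity groups
#' plus ARS416 (ARS1) representing the moderate group.  ARS317, the
#' high-affinity silencer origin used as the internal standard of every
#' assay, is included (apparent Kd 7.223 nM).
#'
#' @return Data frame `origin`, `ratio`, `kd`, `kd_se`, `acs_status`.
#' @export
emsa_origin_survey <- function() {
  read_result_table(system.file("extdata", "emsa_origin_survey.csv",
                                package = "oriclass"))
}

#' Published panel of gEMSA-derived chromatin-dependent origins
#'
#' The twenty high in-vivo affinity origins that fell in the weak
#' in-vitro (gEMSA) cluster.  `group` records how each origin entered the
#' panel: previously classified by origin-specific EMSA
#' (`prior_chromatin_dependent`, `prior_complex`, `prior_dna_dependent`),
#' newly identified with a confirmed ORC binding site and EMSA-tested
#' (`new_tested`; `kd` is `NA`/"ND" when above the assay range), or newly
#' identified but untested (`new_untested`, empty `kd`).
#'
#' @return Data frame `origin`, `ratio`, `kd`, `kd_se`, `group`.
#' @export
gemsa_chromatin_origins <- function() {
  df <- utils::read.table(
    system.file("extdata", "gemsa_chromatin_origins.csv",
                package = "oriclass"),
    header = TRUE, sep = ",", stringsAsFactors = FALSE, na.strings = "")
  df$censored <- !is.na(df$kd) & df$kd == "ND"
  df$kd <- suppressWarnings(as.numeric(ifelse(df$kd == "ND", NA, df$kd)))
  df
}

#' Published ACS match counts per dataset
#'
#' Number of 11 bp ACS motif matches (70% LOD cutoff) and total base
#' pairs for the whole genome, the origin-database region set, and the
#' three gEMSA peak sets.
#'
#' @return Data frame `dataset`, `matches`, `bp`.
#' @export
acs_match_counts <- function() {
  utils::read.table(system.file("extdata", "acs_match_counts.csv",
                                package = "oriclass"),
                    header = TRUE, sep = ",", stringsAsFactors = FALSE)
}
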