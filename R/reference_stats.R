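#' Published library statistics of the Serratia CRISPR-array screens
#'
#' The reported unique-insertion totals of the two CRISPR-array reporter
#' libraries in *Serratia* sp. ATCC 39006 (chromosome CP025085.1), together
#' with the chromosome size. The genome size is the published value to
#' three significant figures (the package ships no sequence data); dividing
#' it by the library sizes reproduces the reported mean insertion spacings
#' of ~18 and ~19 nt after rounding.
#'
#' @return A data frame with one row per library: `library`,
#'   `n_insertions`, `genome_length`, `reported_spacing_nt`.
#' @export
serratia_library_stats <- function() {
  data.frame(
    library = c("CRISPR3", "CRISPR4"),
    n_insertions = c(278000, 262000),
    genome_length = serratia_chromosome_length,
    reported_spacing_nt = c(18, 19),
    stringsAsFactors = FALSE
  )
}

#' Approximate chromosome length of Serratia sp. ATCC 39006 (CP025085.1),
#' in nt, to three significant figures.
#' @export
serratia_chromosome_length <- 4.94e6
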