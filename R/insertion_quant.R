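#' Reduce a per-base profile to unique insertion sites
#'
#' A unique insertion site is a distinct `(position, strand)` at which at
#' least one junction read maps; it is the count unit of the enrichment
#' test. With `collapse_strands = TRUE` the plus- and minus-strand entries
#' at the same position are merged into one site (strand `"*"`, reads
#' summed) for sensitivity analysis; the default keeps strands separate,
#' the rawest defensible definition given that plot files record strands
#' separately.
#'
#' @param profile An [insertion_profile()].
#' @param collapse_strands Merge opposite-strand sites at the same position.
#'
#' @return A data frame of class `site_table` with columns `position`,
#'   `strand`, `reads`, ordered by position then strand, and attribute
#'   `sample_id`.
#' @export
profile_to_sites <- function(profile, collapse_strands = FALSE) {
  stopifnot(inherits(profile, "insertion_profile"))
  if (collapse_strands) {
    tot <- profile$forward + profile$reverse
    pos <- which(tot > 0L)
    st <- data.frame(position = pos, strand = rep("*", length(pos)),
                     reads = tot[pos], stringsAsFactors = FALSE)
  } else {
    fpos <- which(profile$forward > 0L)
    rpos <- which(profile$reverse > 0L)
    st <- data.frame(
      position = c(fpos, rpos),
      strand = c(rep("+", length(fpos)), rep("-", length(rpos))),
      reads = c(profile$forward[fpos], profile$reverse[rpos]),
      stringsAsFactors = FALSE
    )
    st <- st[order(st$position, st$strand), , drop = FALSE]
    rownames(st) <- NULL
  }
  attr(st, "sample_id") <- profile$sample_id
  class(st) <- c("site_table", "data.frame")
  st
}

#' Rebuild a per-base profile from a site table
#'
#' Inverse of [profile_to_sites()] (strand-aware tables only):
#' `sites_to_profile(profile_to_sites(p), length(p)) == p`.
#'
#' @param sites A `site_table` with strands `+`/`-`.
#' @param genome_length Genome length in nt.
#' @param sample_id Sample identifier; defaults to the table's attribute.
#' @return An [insertion_profile()].
#' @export
sites_to_profile <- function(sites, genome_length,
                             sample_id = attr(sites, "sample_id")) {
  stopifnot(is.data.frame(sites), genome_length >= 1)
  if (any(sites$strand == "*"))
    stop("strand-collapsed site tables cannot be converted back to a profile")
  if (nrow(sites) > 0L && any(sites$position > genome_length))
    stop("site position beyond genome length")
  fwd <- integer(genome_length)
  rev <- integer(genome_length)
  f <- sites$strand == "+"
  fwd[sites$position[f]] <- sites$reads[f]
  rev[sites$position[!f]] <- sites$reads[!f]
  if (is.null(sample_id)) sample_id <- "sample"
  insertion_profile(sample_id, fwd, rev)
}

#' Build the gene + intergenic feature universe
#'
#' Every maximal gap of at least 1 nt not covered by any gene span — before
#' the first gene, between consecutive gene spans, and after the last gene —
#' becomes an intergenic feature named after its flanking genes. Together
#' genes and intergenic features cover every genome position, so every
#' insertion is assignable and regulatory regions between genes are testable
#' on the same footing as genes.
#'
#' @param genes A [feature_set()] of genes.
#' @param genome A [genome_ref()].
#' @return A [feature_set()] of genes plus intergenic features, ordered by
#'   start position (stable for ties).
#' @export
build_feature_universe <- function(genes, genome) {
  stopifnot(inherits(genes, "feature_set"), inherits(genome, "genome_ref"))
  if (any(genes$kind != "gene"))
    stop("feature universe must be built from gene features only")
  if (nrow(genes) > 0L && any(genes$end > genome$length))
    stop("gene extends beyond genome length")
  if (nrow(genes) == 0L) {
    ig <- feature_set("ig_start_end", "intergenic", 1L, genome$length, ".")
    return(ig)
  }
  gr <- IRanges::IRanges(start = genes$start, end = genes$end)
  gaps <- IRanges::gaps(gr, start = 1L, end = genome$length)
  ord <- order(genes$start, genes$end)
  gstart <- genes$start[ord]
  gend <- genes$end[ord]
  gid <- genes$feature_id[ord]
  ig <- NULL
  if (length(gaps) > 0L) {
    gap_start <- IRanges::start(gaps)
    gap_end <- IRanges::end(gaps)
    left <- vapply(gap_start, function(s) {
      i <- which(gend < s)
      if (length(i) == 0L) "start" else gid[max(i)]
    }, character(1L))
    right <- vapply(gap_end, function(e) {
      i <- which(gstart > e)
      if (length(i) == 0L) "end" else gid[min(i)]
    }, character(1L))
    ig_id <- sprintf("ig_%s_%s", left, right)
    # flanking-gene pairs can repeat when genes overlap; disambiguate
    if (anyDuplicated(ig_id))
      ig_id <- make.unique(ig_id, sep = "_")
    ig <- data.frame(feature_id = ig_id, kind = "intergenic",
                     start = gap_start, end = gap_end, strand = ".",
                     name = NA_character_, stringsAsFactors = FALSE)
  }
  uni <- rbind(as.data.frame(genes), ig)
  uni <- uni[order(uni$start, uni$end), , drop = FALSE]
  rownames(uni) <- NULL
  feature_set(uni$feature_id, uni$kind, uni$start, uni$end, uni$strand,
              uni$name, genome_length = genome$length)
}

#' Count unique insertion sites per feature for one sample
#'
#' Each site increments every feature whose span contains its position; the
#' site's strand is ignored for assignment, since a transposon insertion
#' disrupts a locus regardless of the sequenced strand. The sample's library
#' size is its total number of unique sites; when genes overlap, the sum of
#' per-feature counts can exceed it (each overlapping feature is
#' incremented), which is flagged on the result.
#'
#' @param sites A `site_table` from [profile_to_sites()].
#' @param universe A [feature_set()] covering the genome (from
#'   [build_feature_universe()]).
#'
#' @return An integer vector of counts named by `feature_id`, with
#'   attributes `library_size` (total unique sites) and `inflated`
#'   (`TRUE` when total assignments exceed the library size).
#' @export
count_sites_per_feature <- function(sites, universe) {
  stopifnot(is.data.frame(sites), inherits(universe, "feature_set"))
  fr <- IRanges::IRanges(start = universe$start, end = universe$end)
  sr <- IRanges::IRanges(start = sites$position, width = 1L)
  hits <- IRanges::findOverlaps(sr, fr)
  if (nrow(sites) > 0L &&
      length(unique(S4Vectors::queryHits(hits))) < nrow(sites))
    stop("site outside every feature: the universe does not cover the genome")
  counts <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(universe))
  names(counts) <- universe$feature_id
  attr(counts, "library_size") <- nrow(sites)
  attr(counts, "inflated") <- length(hits) > nrow(sites)
  counts
}

#' Build a feature-by-sample count matrix of unique insertions
#'
#' @param profiles A named list of [insertion_profile()] objects (names are
#'   sample ids; unnamed lists use each profile's own `sample_id`).
#' @param universe A [feature_set()] from [build_feature_universe()].
#' @param collapse_strands Passed to [profile_to_sites()].
#'
#' @return An object of class `count_matrix`: a list with `counts`
#'   (integer matrix, features x samples), `library_size` (named vector of
#'   per-sample total unique sites) and `inflated` (named logical, per
#'   sample, `TRUE` when overlapping features made assignments exceed the
#'   library size).
#' @export
build_count_matrix <- function(profiles, universe, collapse_strands = FALSE) {
  stopifnot(is.list(profiles), length(profiles) > 0L,
            inherits(universe, "feature_set"))
  ids <- names(profiles)
  if (is.null(ids))
    ids <- vapply(profiles, function(p) p$sample_id, character(1L))
  counts <- matrix(0L, nrow = nrow(universe), ncol = length(profiles),
                   dimnames = list(universe$feature_id, ids))
  lib <- integer(length(profiles))
  infl <- logical(length(profiles))
  for (j in seq_along(profiles)) {
    st <- profile_to_sites(profiles[[j]], collapse_strands = collapse_strands)
    cj <- count_sites_per_feature(st, universe)
    counts[, j] <- cj
    lib[j] <- attr(cj, "library_size")
    infl[j] <- attr(cj, "inflated")
  }
  names(lib) <- ids
  names(infl) <- ids
  structure(list(counts = counts, library_size = lib, inflated = infl),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples; library sizes %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$library_size, collapse = ", ")))
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' The TSV layout is one header row, a `feature_id` first column and one
#' column per sample. Library sizes are not stored in the file; on reading
#' they must be supplied, or they default to column sums (exact only for
#' non-overlapping universes).
#'
#' @param cm A `count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @param library_size Optional named per-sample library sizes; defaults to
#'   column sums.
#' @export
read_count_matrix <- function(path, library_size = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df[[1L]]
  if (is.null(library_size))
    library_size <- colSums(counts)
  structure(list(counts = counts,
                 library_size = library_size[colnames(counts)],
                 inflated = stats::setNames(rep(NA, ncol(counts)),
                                            colnames(counts))),
            class = "count_matrix")
}
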