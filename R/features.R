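#' Feature set constructor
#'
#' A feature set is a data frame of genomic features (genes and, after
#' [build_feature_universe()], intergenic regions) with 1-based inclusive
#' coordinates. Intergenic features carry strand `"."`.
#'
#' @param feature_id Character vector of unique identifiers (locus-tag style).
#' @param kind `"gene"` or `"intergenic"` per feature.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand One of `"+"`, `"-"`, `"."` per feature.
#' @param name Optional display names (`NA` allowed).
#' @param genome_length Optional; when given, features must lie within
#'   `[1, genome_length]`.
#'
#' @return A data frame of class `feature_set`.
#' @export
feature_set <- function(feature_id, kind, start, end, strand,
                        name = NA_character_, genome_length = NULL) {
  n <- length(feature_id)
  fs <- data.frame(
    feature_id = as.character(feature_id),
    kind = as.character(kind),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    name = rep_len(as.character(name), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(fs$feature_id))
    stop("duplicate feature_id: ",
         fs$feature_id[duplicated(fs$feature_id)][1L])
  if (!all(fs$kind %in% c("gene", "intergenic")))
    stop("feature kind must be 'gene' or 'intergenic'")
  if (!all(fs$strand %in% c("+", "-", ".")))
    stop("feature strand must be one of '+', '-', '.'")
  if (any(fs$strand[fs$kind == "intergenic"] != "."))
    stop("intergenic features must have strand '.'")
  if (n > 0L && (any(fs$start < 1L) || any(fs$end < fs$start)))
    stop("feature coordinates must satisfy 1 <= start <= end")
  if (!is.null(genome_length) && n > 0L && any(fs$end > genome_length))
    stop("feature extends beyond genome length: ",
         fs$feature_id[fs$end > genome_length][1L])
  class(fs) <- c("feature_set", "data.frame")
  fs
}

empty_feature_set <- function() {
  feature_set(character(), character(), integer(), integer(), character())
}

#' Read gene features from a GFF3 annotation
#'
#' Imports gene-level records (`type == "gene"`) for the genome's sequence id.
#' Coordinates are taken as 1-based inclusive per the GFF3 standard, and the
#' record order of the file is preserved. The feature id is the `locus_tag`
#' attribute when present, else `ID`, else `Name`.
#'
#' @param path Path to a GFF3 file.
#' @param genome A [genome_ref()]; records on other sequence ids are an
#'   error, and records outside `[1, genome$length]` are rejected.
#'
#' @return A [feature_set()] of genes only.
#' @export
read_annotation <- function(path, genome) {
  stopifnot(inherits(genome, "genome_ref"))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  if (length(gr) == 0L)
    return(empty_feature_set())
  seqids <- as.character(GenomicRanges::seqnames(gr))
  if (!all(seqids == genome$genome_id))
    stop("annotation sequence id(s) ",
         paste(unique(setdiff(seqids, genome$genome_id)), collapse = ", "),
         " do not match genome '", genome$genome_id, "'")
  md <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% colnames(md)) as.character(md[[col]])
                        else rep(NA_character_, length(gr))
  ids <- pick("locus_tag")
  ids <- ifelse(is.na(ids), pick("ID"), ids)
  ids <- ifelse(is.na(ids), pick("Name"), ids)
  if (anyNA(ids))
    stop("gene record without locus_tag/ID/Name in ", path)
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  if (any(starts < 1L) || any(ends > genome$length))
    stop("gene record outside [1, ", genome$length, "]: ",
         ids[starts < 1L | ends > genome$length][1L])
  feature_set(
    feature_id = ids, kind = "gene", start = starts, end = ends,
    strand = as.character(GenomicRanges::strand(gr)),
    name = pick("Name"), genome_length = genome$length
  )
}

#' Write gene features as GFF3
#'
#' Serializes the gene records of a feature set (intergenic features are a
#' derived construct and are not written) as a GFF3 file with `locus_tag`
#' attributes, suitable for re-reading with [read_annotation()].
#'
#' @param features A [feature_set()].
#' @param genome A [genome_ref()] supplying the sequence id and length.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(features, genome, path) {
  stopifnot(inherits(features, "feature_set"), inherits(genome, "genome_ref"))
  genes <- features[features$kind == "gene", , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = genome$genome_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = ifelse(genes$strand == ".", "*", genes$strand)
  )
  gr$type <- "gene"
  gr$source <- "sortnscreen"
  gr$ID <- genes$feature_id
  gr$locus_tag <- genes$feature_id
  if (!all(is.na(genes$name))) gr$Name <- genes$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
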