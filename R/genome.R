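#' Reference genome container
#'
#' A minimal container for a single-replicon reference sequence. All genome
#' positions in the package are 1-based and resolved against this object.
#'
#' @param genome_id Sequence identifier (used as the GFF3/FASTA sequence id).
#' @param sequence Character scalar over the alphabet `A`, `C`, `G`, `T`, `N`.
#'
#' @return An object of class `genome_ref` with fields `genome_id`,
#'   `sequence` and `length` (nt).
#' @export
genome_ref <- function(genome_id, sequence) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  structure(
    list(genome_id = genome_id, sequence = sequence,
         length = nchar(sequence)),
    class = "genome_ref"
  )
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("<genome_ref> %s, %d nt\n", x$genome_id, x$length))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Reads the first (and expected only) record of a FASTA file. Multi-replicon
#' files are rejected: profiles and features in this package are keyed to a
#' single replicon, matching the single-chromosome design of the screens it
#' analyses.
#'
#' @param path Path to a FASTA file.
#' @return A [genome_ref()].
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L)
    stop("no sequences in FASTA file: ", path)
  if (length(seqs) > 1L)
    stop("expected a single-replicon FASTA, found ", length(seqs),
         " records in ", path)
  id <- sub("\\s.*$", "", names(seqs)[1L])
  genome_ref(id, as.character(seqs[[1L]]))
}

#' Write a genome to a FASTA file
#'
#' @param genome A [genome_ref()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_ref"))
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$genome_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
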