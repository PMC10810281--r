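#' Verify the transposon tag at the start of reads
#'
#' Sequencing from the transposon junction leaves a fixed 12-nt transposon
#' tag at the 5' end of every genuine junction read. A read passes when the
#' Hamming distance between its prefix and the tag is at most `max_mismatch`;
#' `N` bases are counted as mismatches. Passing reads have the tag prefix
#' removed. Reads shorter than the tag fail with `mismatches = NA` rather
#' than erroring.
#'
#' @param reads Character vector of read sequences.
#' @param tag The transposon tag sequence (default the Tn5 mosaic-end derived
#'   12-mer `TATAAGAGACAG`).
#' @param max_mismatch Maximum tolerated mismatches (default 2).
#'
#' @return A data frame with one row per read: `tag_ok`, `mismatches`
#'   (`NA` when the read is shorter than the tag) and `trimmed` (the read
#'   with the tag removed when `tag_ok`, otherwise the unchanged read).
#' @export
verify_tag <- function(reads, tag = "TATAAGAGACAG", max_mismatch = 2L) {
  stopifnot(is.character(reads), is.character(tag), length(tag) == 1L,
            nchar(tag) >= 1L, max_mismatch >= 0L)
  tag <- toupper(tag)
  tlen <- nchar(tag)
  tchars <- strsplit(tag, "", fixed = TRUE)[[1L]]
  reads_up <- toupper(reads)
  too_short <- nchar(reads_up) < tlen
  mismatches <- rep(NA_integer_, length(reads))
  ok_idx <- which(!too_short)
  if (length(ok_idx) > 0L) {
    prefixes <- substr(reads_up[ok_idx], 1L, tlen)
    pm <- matrix(unlist(strsplit(prefixes, "", fixed = TRUE)),
                 nrow = tlen)
    mm <- colSums(pm != tchars | pm == "N" |
                    matrix(tchars == "N", nrow = tlen, ncol = ncol(pm)))
    mismatches[ok_idx] <- as.integer(mm)
  }
  tag_ok <- !too_short & !is.na(mismatches) & mismatches <= max_mismatch
  trimmed <- ifelse(tag_ok, substr(reads, tlen + 1L, nchar(reads)), reads)
  data.frame(tag_ok = tag_ok, mismatches = mismatches, trimmed = trimmed,
             stringsAsFactors = FALSE)
}

#' Trim reads from the 3' end to a fixed length
#'
#' Reads longer than `target_length` keep their first `target_length` bases;
#' shorter reads are returned unchanged.
#'
#' @param reads Character vector of read sequences.
#' @param target_length Target read length in nt (default 50).
#' @return Character vector of trimmed reads.
#' @export
trim_3prime <- function(reads, target_length = 50L) {
  stopifnot(target_length >= 1L)
  ifelse(nchar(reads) > target_length,
         substr(reads, 1L, target_length), reads)
}

#' Place a read on the genome by exact match
#'
#' Finds exact occurrences of the read on both strands of the reference and
#' reports the insertion point: the genome coordinate of the read's first
#' sequenced base on the read's strand. A forward match starting at `s`
#' yields `(s, "+")`; a reverse-complement match spanning `[s, e]` yields
#' `(e, "-")`, the first sequenced base being the rightmost genome
#' coordinate. Reads matching nowhere return status `no_hit`; reads matching
#' more than once (across both strands combined) return `ambiguous` rather
#' than an arbitrary choice.
#'
#' @param read A single read sequence (character scalar).
#' @param genome A [genome_ref()].
#' @param min_length Minimum read length to attempt placement (default 20).
#'
#' @return A list with `status` (`"unique"`, `"no_hit"`, `"ambiguous"`,
#'   `"too_short"`), and for unique hits `position` and `strand`.
#' @export
place_read <- function(read, genome, min_length = 20L) {
  stopifnot(is.character(read), length(read) == 1L,
            inherits(genome, "genome_ref"))
  if (nchar(read) < min_length)
    return(list(status = "too_short", position = NA_integer_,
                strand = NA_character_))
  subject <- Biostrings::DNAString(genome$sequence)
  pat <- Biostrings::DNAString(toupper(read))
  fwd <- Biostrings::matchPattern(pat, subject)
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subject)
  nhits <- length(fwd) + length(rev)
  if (nhits == 0L)
    return(list(status = "no_hit", position = NA_integer_,
                strand = NA_character_))
  if (nhits > 1L)
    return(list(status = "ambiguous", position = NA_integer_,
                strand = NA_character_))
  if (length(fwd) == 1L)
    list(status = "unique", position = Biostrings::start(fwd)[1L],
         strand = "+")
  else
    list(status = "unique", position = Biostrings::end(rev)[1L],
         strand = "-")
}

#' Prepare tagged reads and place them on the genome
#'
#' End-to-end read preparation for synthetic or small real FASTQ inputs:
#' verify the transposon tag (tag first, then length trimming), trim the
#' tag-stripped reads from the 3' end, and place each surviving read on the
#' genome by exact match. Real screens mapped with a dedicated aligner should
#' instead supply per-base plot files directly to [read_plot_file()].
#'
#' @param fastq Path to a single-end FASTQ file.
#' @param genome A [genome_ref()].
#' @param tag,max_mismatch Passed to [verify_tag()].
#' @param target_length Passed to [trim_3prime()].
#' @param min_length Passed to [place_read()].
#'
#' @return A data frame with one row per read: `read_id`, `status`
#'   (placement status, or `"tag_fail"`), `position`, `strand`.
#' @export
prep_reads <- function(fastq, genome, tag = "TATAAGAGACAG",
                       max_mismatch = 2L, target_length = 50L,
                       min_length = 20L) {
  seqs <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  ids <- sub("\\s.*$", "", names(seqs))
  reads <- as.character(seqs)
  tg <- verify_tag(reads, tag = tag, max_mismatch = max_mismatch)
  trimmed <- trim_3prime(tg$trimmed, target_length)
  out <- data.frame(read_id = ids, status = "tag_fail",
                    position = NA_integer_, strand = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in which(tg$tag_ok)) {
    hit <- place_read(trimmed[i], genome, min_length = min_length)
    out$status[i] <- hit$status
    out$position[i] <- hit$position
    out$strand[i] <- hit$strand
  }
  out
}

#' Build an insertion profile from placed reads
#'
#' Tabulates uniquely placed reads into a per-base [insertion_profile()].
#'
#' @param placed Data frame as returned by [prep_reads()].
#' @param genome A [genome_ref()].
#' @param sample_id Sample identifier for the profile.
#' @return An [insertion_profile()].
#' @export
placed_reads_to_profile <- function(placed, genome, sample_id) {
  stopifnot(inherits(genome, "genome_ref"))
  ok <- placed[placed$status == "unique", , drop = FALSE]
  fwd <- tabulate(ok$position[ok$strand == "+"], nbins = genome$length)
  rev <- tabulate(ok$position[ok$strand == "-"], nbins = genome$length)
  insertion_profile(sample_id, fwd, rev)
}
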