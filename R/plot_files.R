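#' Per-base insertion profile
#'
#' Holds the per-position read counts of transposon junction reads on the
#' plus and minus strands of the reference, the content of a TraDIS-style
#' `.insert_site_plot` file. Position `i` of each vector corresponds to
#' genome position `i` (1-based).
#'
#' @param sample_id Sample identifier.
#' @param forward,reverse Integer vectors of non-negative per-position read
#'   counts; both must have exactly genome-length entries.
#'
#' @return An object of class `insertion_profile`.
#' @export
insertion_profile <- function(sample_id, forward, reverse) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  forward <- as.integer(forward)
  reverse <- as.integer(reverse)
  if (length(forward) != length(reverse))
    stop("forward and reverse strand vectors differ in length")
  if (length(forward) == 0L)
    stop("profile must cover at least one position")
  if (anyNA(forward) || anyNA(reverse))
    stop("profile contains missing counts")
  if (any(forward < 0L) || any(reverse < 0L))
    stop("profile contains negative counts")
  structure(
    list(sample_id = sample_id, forward = forward, reverse = reverse),
    class = "insertion_profile"
  )
}

#' @export
print.insertion_profile <- function(x, ...) {
  cat(sprintf(
    "<insertion_profile> %s: %d positions, %d fwd / %d rev reads\n",
    x$sample_id, length(x$forward), sum(x$forward), sum(x$reverse)))
  invisible(x)
}

#' Read a per-base insertion plot file
#'
#' Plot files tabulate the number of transposon junction reads at each
#' nucleotide position of the reference, one line per position, with two
#' whitespace-separated non-negative integer columns: plus-strand reads and
#' minus-strand reads. Line `i` is genome position `i`. Gzip-compressed files
#' (`.gz`) are accepted.
#'
#' @param path Path to the plot file.
#' @param genome_length Expected number of data lines (the genome length).
#' @param sample_id Sample identifier to attach; defaults to the file name
#'   stripped of `.insert_site_plot`/`.gz` suffixes.
#'
#' @return An [insertion_profile()].
#' @export
read_plot_file <- function(path, genome_length,
                           sample_id = plot_file_sample_id(path)) {
  stopifnot(length(genome_length) == 1L, genome_length >= 1)
  fread_args <- list(header = FALSE, colClasses = "character", sep = " ",
                     strip.white = TRUE, fill = TRUE,
                     blank.lines.skip = FALSE)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    lines <- readLines(con)
    close(con)
    dt <- do.call(data.table::fread,
                  c(list(text = paste(lines, collapse = "\n")), fread_args))
  } else {
    dt <- do.call(data.table::fread, c(list(file = path), fread_args))
  }
  if (ncol(dt) != 2L) {
    bad <- which(apply(is.na(dt) | dt == "", 1L, any))[1L]
    stop(sprintf("plot file %s: expected 2 fields per line (line %d)",
                 path, if (is.na(bad)) 1L else bad))
  }
  if (nrow(dt) != genome_length)
    stop(sprintf(
      "plot file %s has %d data lines but genome length is %d",
      path, nrow(dt), as.integer(genome_length)))
  fwd <- suppressWarnings(as.numeric(dt[[1L]]))
  rev <- suppressWarnings(as.numeric(dt[[2L]]))
  bad <- which(is.na(fwd) | is.na(rev) | fwd < 0 | rev < 0 |
                 fwd != floor(fwd) | rev != floor(rev))
  if (length(bad) > 0L)
    stop(sprintf(
      "plot file %s: non-integer or negative field at line %d",
      path, bad[1L]))
  insertion_profile(sample_id, fwd, rev)
}

#' Write a per-base insertion plot file
#'
#' Serializes an [insertion_profile()] in the two-column per-position layout
#' read by [read_plot_file()]. Writing then re-reading reproduces the profile
#' exactly. Paths ending in `.gz` are gzip-compressed.
#'
#' @param profile An [insertion_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plot_file <- function(profile, path) {
  stopifnot(inherits(profile, "insertion_profile"))
  lines <- paste(profile$forward, profile$reverse)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

plot_file_sample_id <- function(path) {
  sub("\\.(insert_site_plot|txt|tsv)(\\.gz)?$", "", basename(path))
}
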