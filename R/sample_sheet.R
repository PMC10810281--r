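#' Sample sheet constructor and validator
#'
#' The sample sheet maps sequenced samples to their screen, sorted bin and
#' replicate. Each screen sorts cells into three fluorescence bins per
#' replicate: `high` and `low` (the tails) and `depleted` (the central mass,
#' the control group of the enrichment test). Every screen must therefore
#' contain at least one `depleted` sample, and `(screen_id, bin, replicate)`
#' must be unique.
#'
#' @param df A data frame with columns `sample_id`, `screen_id`, `bin`,
#'   `replicate`.
#'
#' @return The validated data frame with class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  required <- c("sample_id", "screen_id", "bin", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$sample_id <- as.character(df$sample_id)
  df$screen_id <- as.character(df$screen_id)
  df$bin <- as.character(df$bin)
  df$replicate <- as.integer(df$replicate)
  bad_bin <- setdiff(unique(df$bin), c("high", "low", "depleted"))
  if (length(bad_bin) > 0L)
    stop("unknown bin label(s): ", paste(bad_bin, collapse = ", "),
         " (expected high, low, depleted)")
  if (anyNA(df$replicate) || any(df$replicate < 1L))
    stop("replicate must be a positive integer")
  key <- paste(df$screen_id, df$bin, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (screen_id, bin, replicate) row: ",
         gsub("\r", "/", key[duplicated(key)][1L]))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  no_ctrl <- setdiff(unique(df$screen_id),
                     unique(df$screen_id[df$bin == "depleted"]))
  if (length(no_ctrl) > 0L)
    stop("screen(s) without a depleted control sample: ",
         paste(no_ctrl, collapse = ", "))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from TSV
#'
#' @param path Path to a tab-separated file with header columns `sample_id`,
#'   `screen_id`, `bin`, `replicate`.
#' @return A validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  sample_sheet(df)
}

#' Write a sample sheet to TSV
#'
#' @param sheet A [sample_sheet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(inherits(sheet, "sample_sheet"))
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
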