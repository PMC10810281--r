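#' Pipeline configuration
#'
#' Collects the paths and thresholds of a screen analysis run. Plot files
#' are looked up in `plot_dir` as `<sample_id>.insert_site_plot` (a `.gz`
#' variant is accepted).
#'
#' @param genome_fasta Path to the reference FASTA.
#' @param annotation_gff3 Path to the gene annotation GFF3.
#' @param sample_sheet_tsv Path to the sample sheet TSV.
#' @param plot_dir Directory holding one plot file per sample.
#' @param out_dir Output directory for result tables and the manifest.
#' @param fdr_max,lfc_min Enrichment thresholds (defaults 0.05, 0.5).
#' @param pseudo Fold-change pseudo-count (default 0.5).
#' @param phi Optional dispersion override (default: estimated per screen).
#' @param collapse_strands Merge opposite-strand sites at one position.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, annotation_gff3, sample_sheet_tsv,
                            plot_dir, out_dir, fdr_max = 0.05,
                            lfc_min = 0.5, pseudo = 0.5, phi = NULL,
                            collapse_strands = FALSE) {
  stopifnot(fdr_max > 0, fdr_max < 1, lfc_min >= 0, pseudo >= 0)
  for (p in c(genome_fasta, annotation_gff3, sample_sheet_tsv, plot_dir))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(list(genome_fasta = genome_fasta,
                 annotation_gff3 = annotation_gff3,
                 sample_sheet_tsv = sample_sheet_tsv,
                 plot_dir = plot_dir, out_dir = out_dir,
                 fdr_max = fdr_max, lfc_min = lfc_min, pseudo = pseudo,
                 phi = phi, collapse_strands = collapse_strands),
            class = "pipeline_config")
}

find_plot_file <- function(plot_dir, sample_id) {
  for (suffix in c(".insert_site_plot", ".insert_site_plot.gz")) {
    p <- file.path(plot_dir, paste0(sample_id, suffix))
    if (file.exists(p)) return(p)
  }
  stop("no plot file for sample ", sample_id, " in ", plot_dir)
}

#' Run the screen analysis pipeline
#'
#' Quantifies unique insertions per feature from plot files, tests bin
#' enrichment against the depleted control per screen, classifies regulator
#' calls, writes all intermediate and final tables to the output directory,
#' and records a manifest (config, input/output checksums, package version)
#' so a rerun on identical inputs is bit-identical. The analysis path
#' contains no randomness.
#'
#' @param config A [pipeline_config()].
#' @return A results bundle: list with `universe`, `counts`
#'   (a `count_matrix`), `results` (per-contrast enrichment), `calls`
#'   (regulator calls, all screens), `sheet` and `manifest`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  genome <- read_genome_fasta(config$genome_fasta)
  genes <- read_annotation(config$annotation_gff3, genome)
  sheet <- read_sample_sheet(config$sample_sheet_tsv)  # checks depleted
  universe <- build_feature_universe(genes, genome)
  profiles <- lapply(stats::setNames(sheet$sample_id, sheet$sample_id),
                     function(sid)
    read_plot_file(find_plot_file(config$plot_dir, sid), genome$length,
                   sample_id = sid))
  cm <- build_count_matrix(profiles, universe,
                           collapse_strands = config$collapse_strands)
  results <- list()
  calls <- list()
  for (sc in unique(sheet$screen_id)) {
    res <- enrich_screen(cm, sheet, screen_id = sc, phi = config$phi,
                         fdr_max = config$fdr_max,
                         lfc_min = config$lfc_min, pseudo = config$pseudo)
    results[[sc]] <- res
    calls[[sc]] <- call_regulators(res)
  }
  results <- do.call(rbind, c(results, make.row.names = FALSE))
  calls <- do.call(rbind, c(calls, make.row.names = FALSE))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(cm, file.path(config$out_dir, "counts.tsv"))
  utils::write.table(results, file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls, file.path(config$out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- pipeline_manifest(config)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(universe = universe, counts = cm, results = results, calls = calls,
       sheet = sheet, manifest = manifest)
}

pipeline_manifest <- function(config) {
  inputs <- c(config$genome_fasta, config$annotation_gff3,
              config$sample_sheet_tsv)
  outputs <- file.path(config$out_dir,
                       c("counts.tsv", "enrichment.tsv", "calls.tsv"))
  md5 <- function(paths) {
    h <- tools::md5sum(paths[file.exists(paths)])
    as.list(stats::setNames(unname(h), basename(names(h))))
  }
  cfg <- unclass(config)
  cfg$phi <- if (is.null(cfg$phi)) "estimated" else cfg$phi
  list(package = "sortnscreen",
       version = as.character(utils::packageVersion("sortnscreen")),
       config = cfg,
       input_md5 = md5(inputs),
       output_md5 = md5(outputs))
}

#' Compare regulator calls across screen result bundles
#'
#' Takes two or more bundles from [run_screen()] (or from an in-memory
#' analysis), checks they share a feature universe, and computes the
#' cross-screen overlap of significant loci (features called `up_in_high`
#' or `up_in_low`; set `include_ambiguous = TRUE` to count ambiguous calls
#' as significant too).
#'
#' @param bundles Named list of results bundles (or of `regulator_calls`
#'   data frames).
#' @param include_ambiguous Count ambiguous features as significant.
#' @return The overlap structure of [compare_screens()].
#' @export
run_comparison <- function(bundles, include_ambiguous = FALSE) {
  stopifnot(is.list(bundles), length(bundles) >= 2L, !is.null(names(bundles)))
  get_calls <- function(b) if (is.data.frame(b)) b else b$calls
  universes <- lapply(bundles, function(b) sort(get_calls(b)$feature_id))
  for (i in seq_along(universes)[-1L]) {
    if (!identical(universes[[1L]], universes[[i]])) {
      diff <- c(setdiff(universes[[1L]], universes[[i]]),
                setdiff(universes[[i]], universes[[1L]]))
      stop("feature universe mismatch between bundles '",
           names(bundles)[1L], "' and '", names(bundles)[i], "': ",
           paste(utils::head(diff, 10L), collapse = ", "))
    }
  }
  keep <- c("up_in_high", "up_in_low",
            if (include_ambiguous) "ambiguous")
  sets <- lapply(bundles, function(b) {
    calls <- get_calls(b)
    calls$feature_id[calls$call %in% keep]
  })
  compare_screens(sets)
}
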