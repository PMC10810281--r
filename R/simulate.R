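#' Configuration of a synthetic sorted transposon screen
#'
#' The generator emulates the stages of a sorted transposon-library reporter
#' screen: a dense mutant pool over a genome (about one insertion per 18 nt
#' by default), per-cell reporter fluorescence with multiplicative effects
#' for insertions in regulator features plus lognormal noise, quantile
#' gating of the sorted cells into low/high/depleted bins at 5/5/90 percent,
#' triplicate sorts, and per-bin sequencing with overdispersed sampling
#' noise.
#'
#' @param genome_length Genome length in nt (>= 1000).
#' @param n_genes Number of genes to tile onto the genome.
#' @param n_insertions Number of unique `(position, strand)` insertion
#'   sites in the pool; the default `round(genome_length / 18)` reproduces
#'   the observed density of about one insertion every 18 nt.
#' @param gate_fractions Named fractions `(low, high, depleted)` of sorted
#'   cells per bin, summing to 1; default `c(0.05, 0.05, 0.90)`.
#' @param cells_sorted Cells sorted per replicate experiment (default
#'   `2e7`, the scale of the real sorts; reduce for desk-scale runs).
#' @param n_replicates Independent sort replicates (default 3).
#' @param reads_per_sample Sequencing reads per (bin, replicate) library
#'   (default 5000 at the default desk genome scale, giving partial
#'   unique-site recovery in the depleted bin as in real libraries).
#' @param effect_map Named numeric vector mapping `feature_id` to a
#'   fluorescence multiplier (1 = neutral; > 1 means disrupting the feature
#'   raises reporter output, i.e. the feature represses the reporter;
#'   < 1 means the feature activates it).
#' @param n_repressors,n_activators Convenience counts of planted
#'   regulators; that many genes, evenly spaced along the genome, are added
#'   to the effect map with `repressor_effect` / `activator_effect`.
#' @param repressor_effect,activator_effect Effect sizes for planted
#'   regulators (defaults 10 and 0.1).
#' @param noise_sd Lognormal sigma (natural-log units) of per-cell
#'   fluorescence noise (default 0.35).
#' @param phi_seq Sequencing overdispersion: squared coefficient of
#'   variation of the gamma read-rate weights, giving per-site counts an
#'   approximately negative-binomial dispersion of `phi_seq` (default
#'   0.05; 0 gives plain multinomial reads).
#' @param abundance_conc Dirichlet concentration of per-mutant pool
#'   abundances around uniform (default 5; larger is more even).
#' @param screen_id Identifier used in sample names (default "screen1").
#' @param seed Integer seed; all stages derive their own sub-seed from it,
#'   so a config is reproducible end to end.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e5,
                       n_genes = 80,
                       n_insertions = round(genome_length / 18),
                       gate_fractions = c(low = 0.05, high = 0.05,
                                          depleted = 0.90),
                       cells_sorted = 2e7,
                       n_replicates = 3,
                       reads_per_sample = 5000,
                       effect_map = numeric(0),
                       n_repressors = 0,
                       n_activators = 0,
                       repressor_effect = 10,
                       activator_effect = 0.1,
                       noise_sd = 0.35,
                       phi_seq = 0.05,
                       abundance_conc = 5,
                       screen_id = "screen1",
                       seed = 1L) {
  stopifnot(genome_length >= 1000, n_genes >= 1,
            n_insertions >= 0, n_insertions <= 2 * genome_length,
            cells_sorted >= 1, n_replicates >= 1, reads_per_sample >= 1,
            noise_sd >= 0, phi_seq >= 0, abundance_conc > 0,
            repressor_effect > 0, activator_effect > 0,
            n_repressors >= 0, n_activators >= 0)
  if (length(gate_fractions) != 3L)
    stop("gate_fractions must have three entries (low, high, depleted)")
  if (is.null(names(gate_fractions)) || !all(nzchar(names(gate_fractions))))
    names(gate_fractions) <- c("low", "high", "depleted")
  gate_fractions <- gate_fractions[c("low", "high", "depleted")]
  if (any(gate_fractions <= 0) || abs(sum(gate_fractions) - 1) > 1e-9)
    stop("gate fractions must be positive and sum to 1")
  if (length(effect_map) > 0L &&
      (is.null(names(effect_map)) || any(effect_map <= 0)))
    stop("effect_map must be a named vector of positive multipliers")
  structure(
    list(genome_length = as.integer(genome_length),
         n_genes = as.integer(n_genes),
         n_insertions = as.integer(n_insertions),
         gate_fractions = gate_fractions,
         cells_sorted = as.integer(cells_sorted),
         n_replicates = as.integer(n_replicates),
         reads_per_sample = as.integer(reads_per_sample),
         effect_map = effect_map,
         n_repressors = as.integer(n_repressors),
         n_activators = as.integer(n_activators),
         repressor_effect = repressor_effect,
         activator_effect = activator_effect,
         noise_sd = noise_sd,
         phi_seq = phi_seq,
         abundance_conc = abundance_conc,
         screen_id = screen_id,
         seed = as.integer(seed)),
    class = "sim_config")
}

# deterministic per-stage sub-seed, kept below 2^31
derive_seed <- function(seed, stage) {
  as.integer(((seed %% 48611) * 44257 + stage * 7919) %% 2147483629)
}

#' Simulate a genome and its gene annotation
#'
#' Generates a random (hence non-repetitive with overwhelming probability)
#' sequence and tiles `n_genes` genes onto it with gaps on both sides of
#' every gene, so intergenic features always exist. Deterministic under the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a [genome_ref()]) and `features`
#'   (a [feature_set()] of genes).
#' @export
simulate_genome_and_features <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  L <- config$genome_length
  n <- config$n_genes
  unit <- L / n
  if (unit < 60)
    stop("infeasible tiling: fewer than 60 nt per gene slot")
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  genome <- genome_ref(sprintf("simchr_%d", config$seed), seq)
  # each gene occupies 60-85% of its slot, randomly offset, leaving gaps
  frac <- stats::runif(n, 0.60, 0.85)
  glen <- pmax(30L, as.integer(round(unit * frac)))
  slot_start <- as.integer(round((seq_len(n) - 1L) * unit)) + 1L
  slot_end <- as.integer(round(seq_len(n) * unit))
  slack <- (slot_end - slot_start + 1L) - glen - 2L  # >= 1 nt gap each side
  if (any(slack < 0))
    stop("infeasible tiling: gene longer than its slot")
  offset <- 1L + as.integer(floor(stats::runif(n) * (slack + 1L)))
  start <- slot_start + offset
  end <- start + glen - 1L
  features <- feature_set(
    feature_id = sprintf("gene_%03d", seq_len(n)),
    kind = "gene", start = start, end = end,
    strand = sample(c("+", "-"), n, replace = TRUE),
    genome_length = L)
  list(genome = genome, features = features)
}

#' Simulate the transposon mutant pool
#'
#' Draws `n_insertions` unique `(position, strand)` sites uniformly over the
#' genome and assigns each mutant a relative abundance from a symmetric
#' Dirichlet around uniform (concentration `abundance_conc`), emulating
#' outgrowth variation of the library. Mean inter-site spacing is
#' `genome_length / n_insertions` by construction.
#'
#' @param config A [sim_config()].
#' @param genome A [genome_ref()].
#' @return A data frame of class `mutant_pool`: `position`, `strand`,
#'   `abundance` (summing to 1).
#' @export
simulate_mutant_pool <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_ref"))
  if (config$n_insertions > 2L * genome$length)
    stop("n_insertions exceeds the number of (position, strand) sites")
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_insertions
  if (n == 0L) {
    pool <- data.frame(position = integer(), strand = character(),
                       abundance = numeric(), stringsAsFactors = FALSE)
    class(pool) <- c("mutant_pool", "data.frame")
    return(pool)
  }
  slots <- sample.int(2L * genome$length, n)  # site = position x strand
  position <- ((slots - 1L) %/% 2L) + 1L
  strand <- ifelse(slots %% 2L == 1L, "+", "-")
  w <- stats::rgamma(n, shape = config$abundance_conc)
  pool <- data.frame(position = position, strand = strand,
                     abundance = w / sum(w), stringsAsFactors = FALSE)
  pool <- pool[order(pool$position, pool$strand), , drop = FALSE]
  rownames(pool) <- NULL
  class(pool) <- c("mutant_pool", "data.frame")
  pool
}

# multiplicative fluorescence effect of each pool site: product over the
# effect-map features whose span contains the site position
site_effects <- function(pool, features, effect_map) {
  eff <- rep(1, nrow(pool))
  if (length(effect_map) == 0L || nrow(pool) == 0L) return(eff)
  idx <- match(names(effect_map), features$feature_id)
  if (anyNA(idx))
    stop("effect_map names absent from the feature set: ",
         paste(names(effect_map)[is.na(idx)], collapse = ", "))
  fr <- IRanges::IRanges(start = features$start[idx],
                         end = features$end[idx])
  sr <- IRanges::IRanges(start = pool$position, width = 1L)
  hits <- IRanges::findOverlaps(sr, fr)
  for (k in seq_along(hits)) {
    q <- S4Vectors::queryHits(hits)[k]
    eff[q] <- eff[q] * effect_map[S4Vectors::subjectHits(hits)[k]]
  }
  eff
}

#' Sort a pool of mutant cells into fluorescence bins
#'
#' Simulates one replicate sort. Each sorted cell carries a single insertion
#' (drawn multinomially from the pool abundances); its log-fluorescence is
#' the log effect of the feature(s) its insertion disrupts plus
#' `Normal(0, noise_sd)` noise. Cells are gated by empirical quantiles of
#' the realized fluorescence: the lowest `round(n * low)` cells form the
#' `low` bin, the highest `round(n * high)` the `high` bin, and the central
#' mass the `depleted` bin, so realized bin fractions equal the gate
#' fractions up to rounding. Fluorescence ties are broken by stable cell
#' order.
#'
#' @param pool A `mutant_pool` from [simulate_mutant_pool()].
#' @param effects Per-site fluorescence multipliers (numeric vector aligned
#'   with `pool` rows), e.g. from the config's effect map.
#' @param config A [sim_config()].
#' @param replicate Replicate number (selects the sub-seed).
#'
#' @return A list with one integer vector per bin (`low`, `high`,
#'   `depleted`), each of length `nrow(pool)`, giving the number of sorted
#'   cells per pool site in that bin.
#' @export
sort_pool <- function(pool, effects, config, replicate = 1L) {
  stopifnot(inherits(pool, "mutant_pool"), nrow(pool) > 0L,
            length(effects) == nrow(pool))
  set.seed(derive_seed(config$seed, 10L + replicate))
  n <- config$cells_sorted
  cell_site <- sample.int(nrow(pool), n, replace = TRUE,
                          prob = pool$abundance)
  logf <- log(effects)[cell_site] +
    stats::rnorm(n, mean = 0, sd = config$noise_sd)
  r <- data.table::frank(logf, ties.method = "first")
  n_low <- round(n * config$gate_fractions[["low"]])
  n_high <- round(n * config$gate_fractions[["high"]])
  bin <- rep("depleted", n)
  bin[r <= n_low] <- "low"
  bin[r > n - n_high] <- "high"
  lapply(c(low = "low", high = "high", depleted = "depleted"), function(b)
    tabulate(cell_site[bin == b], nbins = nrow(pool)))
}

#' Sequence the cells of one sorted bin
#'
#' Draws `reads_per_sample` junction reads over the bin's cells with
#' gamma-weight (normalized-gamma) overdispersion `phi_seq` — per-site read
#' counts are approximately negative-binomial with dispersion `phi_seq`;
#' plain multinomial when `phi_seq = 0` — and tabulates them into a
#' per-base [insertion_profile()].
#' An empty bin yields an all-zero profile with a warning.
#'
#' @param bin_cells Integer vector of sorted cells per pool site (one
#'   element of the [sort_pool()] result).
#' @param pool The `mutant_pool`.
#' @param config A [sim_config()].
#' @param genome A [genome_ref()].
#' @param sample_id Sample identifier for the profile.
#' @param stage_seed Sub-seed index for this library.
#'
#' @return An [insertion_profile()].
#' @export
sequence_bin <- function(bin_cells, pool, config, genome, sample_id,
                         stage_seed) {
  stopifnot(length(bin_cells) == nrow(pool))
  set.seed(derive_seed(config$seed, stage_seed))
  present <- which(bin_cells > 0L)
  if (length(present) == 0L) {
    warning("empty bin for sample ", sample_id)
    return(insertion_profile(sample_id, integer(genome$length),
                             integer(genome$length)))
  }
  w <- bin_cells[present] / sum(bin_cells[present])
  if (config$phi_seq > 0) {
    # gamma-weight overdispersion: per-site rate Gamma(1/phi, w*phi) has
    # mean w and squared CV phi_seq, so site counts are approximately
    # negative-binomial with var = mu + phi_seq * mu^2
    g <- stats::rgamma(length(w), shape = 1 / config$phi_seq,
                       scale = w * config$phi_seq)
    if (sum(g) == 0) g <- w
    w <- g / sum(g)
  }
  reads <- as.integer(stats::rmultinom(1L, config$reads_per_sample, w))
  fwd <- integer(genome$length)
  rev <- integer(genome$length)
  pos <- pool$position[present]
  plus <- pool$strand[present] == "+"
  fwd[pos[plus]] <- reads[plus]
  rev[pos[!plus]] <- reads[!plus]
  insertion_profile(sample_id, fwd, rev)
}

#' Simulate a complete sorted transposon screen
#'
#' Runs the full generative model — genome and annotation, mutant pool,
#' planted regulator effects, replicate sorts, per-bin sequencing — and
#' returns (optionally writes) everything the analysis pipeline consumes,
#' together with the ground-truth regulator set.
#'
#' Planted regulators come from the config: explicit `effect_map` entries
#' plus `n_repressors` / `n_activators` genes chosen evenly spaced along
#' the genome. The output is bit-deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes genome FASTA,
#'   annotation GFF3, one plot file per (bin, replicate), the sample sheet,
#'   the truth-set TSV and the config as YAML.
#'
#' @return A list with `genome`, `features`, `universe`, `pool`, `truth`
#'   (data frame `feature_id`, `direction`, `effect`), `profiles` (named
#'   list of [insertion_profile()]), `sheet` (a [sample_sheet()]) and
#'   `config`.
#' @export
simulate_screen <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  gf <- simulate_genome_and_features(config)
  pool <- simulate_mutant_pool(config, gf$genome)
  effect_map <- config$effect_map
  n_plant <- config$n_repressors + config$n_activators
  if (n_plant > 0L) {
    if (n_plant > config$n_genes)
      stop("more planted regulators than genes")
    picks <- unique(as.integer(round(
      seq(1L, config$n_genes, length.out = n_plant))))
    ids <- gf$features$feature_id[gf$features$kind == "gene"][picks]
    planted <- c(rep(config$repressor_effect, config$n_repressors),
                 rep(config$activator_effect, config$n_activators))
    names(planted) <- ids
    planted <- planted[!names(planted) %in% names(effect_map)]
    effect_map <- c(effect_map, planted)
  }
  truth <- data.frame(
    feature_id = names(effect_map),
    direction = ifelse(effect_map > 1, "repressor",
                ifelse(effect_map < 1, "activator", "neutral")),
    effect = unname(effect_map),
    stringsAsFactors = FALSE)
  eff <- site_effects(pool, gf$features, effect_map)
  profiles <- list()
  sheet_rows <- list()
  for (r in seq_len(config$n_replicates)) {
    bins <- sort_pool(pool, eff, config, replicate = r)
    for (b in names(bins)) {
      sid <- sprintf("%s_%s_r%d", config$screen_id, b, r)
      stage <- 100L + 10L * r + match(b, c("low", "high", "depleted"))
      profiles[[sid]] <- sequence_bin(bins[[b]], pool, config, gf$genome,
                                      sid, stage)
      sheet_rows[[sid]] <- data.frame(
        sample_id = sid, screen_id = config$screen_id, bin = b,
        replicate = r, stringsAsFactors = FALSE)
    }
  }
  sheet <- sample_sheet(do.call(rbind, sheet_rows))
  universe <- build_feature_universe(gf$features, gf$genome)
  out <- list(genome = gf$genome, features = gf$features,
              universe = universe, pool = pool, truth = truth,
              profiles = profiles, sheet = sheet, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(gf$genome, file.path(dir, "genome.fasta"))
    write_annotation(gf$features, gf$genome,
                     file.path(dir, "annotation.gff3"))
    for (sid in names(profiles))
      write_plot_file(profiles[[sid]],
                      file.path(dir, paste0(sid, ".insert_site_plot")))
    write_sample_sheet(sheet, file.path(dir, "samples.tsv"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- config
    class(cfg) <- NULL
    cfg$effect_map <- as.list(cfg$effect_map)
    cfg$gate_fractions <- as.list(cfg$gate_fractions)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  out
}

#' Mean insertion spacing of a library
#'
#' The average distance between transposon insertions: genome length
#' divided by the number of unique insertion sites.
#'
#' @param genome_length Genome length in nt.
#' @param n_insertions Number of unique insertion sites.
#' @return Mean spacing in nt.
#' @export
mean_insertion_spacing <- function(genome_length, n_insertions) {
  stopifnot(genome_length > 0, n_insertions > 0)
  genome_length / n_insertions
}
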