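# Independent oracles and small fixture builders used across the suite.

# Brute-force conditional-binomial two-sided p-value (minimum-likelihood
# rule), written from the binomial pmf via lchoose so it shares no code
# with the package's exact test.
binom_exact_oracle <- function(a, b, n_a, n_b) {
  t <- a + b
  if (t == 0) return(1)
  pa <- n_a / (n_a + n_b)
  x <- 0:t
  logp <- lchoose(t, x) + x * log(pa) + (t - x) * log(1 - pa)
  probs <- exp(logp)
  obs <- probs[a + 1]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Independent Benjamini-Hochberg step-up, written as the literal formula:
# fdr_(i) = min_{j >= i} m * p_(j) / j in sorted order, mapped back.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  running <- Inf
  for (j in rev(seq_len(m))) {
    running <- min(running, m / j * sorted[j])
    adj[j] <- min(1, running)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Random insertion profile for round-trip properties.
random_profile <- function(n, sample_id = "s", max_reads = 50) {
  insertion_profile(
    sample_id,
    forward = rbinom(n, max_reads, 0.1),
    reverse = rbinom(n, max_reads, 0.1)
  )
}

# A tiny two-gene universe on a 1000-nt genome.
toy_universe <- function() {
  genome <- genome_ref("toy", strrep("ACGT", 250))
  genes <- feature_set(c("geneA", "geneB"), "gene",
                       start = c(1L, 501L), end = c(300L, 800L),
                       strand = c("+", "-"), genome_length = 1000L)
  list(genome = genome, genes = genes,
       universe = build_feature_universe(genes, genome))
}

# Desk-scale simulator config shared by pipeline-level tests: ~200-feature
# universe, triplicate sorts, partial unique-site recovery per library.
desk_config <- function(seed, ...) {
  sim_config(genome_length = 120000, n_genes = 100, cells_sorted = 2e5,
             seed = seed, ...)
}
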