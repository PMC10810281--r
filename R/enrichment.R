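#' Equalize library sizes by deterministic rescaling
#'
#' The conditional exact test compares group sums and therefore requires
#' comparable library sizes across samples. Counts are rescaled to the
#' geometric mean of the per-sample library sizes and rounded half-to-even
#' to integers, so the test path contains no hidden randomness (as
#' stochastic thinning would). Effective library sizes are equal across
#' samples afterwards.
#'
#' @param cm A `count_matrix` from [build_count_matrix()].
#' @return A `count_matrix` with rescaled integer counts, all library sizes
#'   set to the rounded geometric mean, and the per-sample rescaling
#'   factors recorded in the `scaling` element.
#' @export
equalize_libraries <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- cm$library_size
  if (any(lib <= 0))
    stop("zero library size for sample(s): ",
         paste(names(lib)[lib <= 0], collapse = ", "))
  gm <- exp(mean(log(lib)))
  fac <- gm / lib
  counts <- round(sweep(cm$counts, 2L, fac, `*`))  # round half-to-even
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 library_size = stats::setNames(rep(round(gm), length(lib)),
                                                names(lib)),
                 inflated = cm$inflated,
                 scaling = fac),
            class = "count_matrix")
}

#' Estimate a common count dispersion
#'
#' Per-feature method-of-moments estimates of the squared-CV overdispersion
#' `phi` (`var = mu + phi * mu^2`) are computed within replicate groups on
#' library-equalized counts, pooled across groups by degrees of freedom, and
#' aggregated across features by a 30\%-trimmed mean over features with
#' total count of at least `min_total`. Negative estimates are floored at
#' zero; `phi = 0` recovers the Poisson/binomial limit of the exact test.
#' This is a transparent, enumeration-testable estimator rather than a
#' likelihood-based one; its moderate downward bias at small replicate
#' numbers is documented in the methods vignette.
#'
#' @param counts Integer matrix (features x samples) of equalized counts, or
#'   a `count_matrix`.
#' @param groups Group label per sample (replicate groups); dispersion is
#'   estimated within groups having at least two samples.
#' @param trim Trim fraction of the across-feature trimmed mean.
#' @param min_total Minimum per-feature total count for inclusion.
#'
#' @return An object of class `dispersion_estimate`: a list with `phi`,
#'   `n_features` (features used) and `single_replicate` (`TRUE` when no
#'   group had two or more samples, in which case `phi = 0` with a warning).
#' @export
estimate_common_dispersion <- function(counts, groups, trim = 0.3,
                                       min_total = 5L) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  stopifnot(is.matrix(counts), length(groups) == ncol(counts))
  groups <- as.character(groups)
  reps <- table(groups)
  if (!any(reps >= 2L)) {
    warning("no replicate group with >= 2 samples; returning phi = 0")
    return(structure(list(phi = 0, n_features = 0L,
                          single_replicate = TRUE),
                     class = "dispersion_estimate"))
  }
  keep <- rowSums(counts) >= min_total
  sub <- counts[keep, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(structure(list(phi = 0, n_features = 0L,
                          single_replicate = FALSE),
                     class = "dispersion_estimate"))
  glev <- names(reps)[reps >= 2L]
  num <- rep(0, nrow(sub))
  den <- rep(0, nrow(sub))
  for (g in glev) {
    yg <- sub[, groups == g, drop = FALSE]
    m <- rowMeans(yg)
    v <- apply(yg, 1L, stats::var)
    df <- ncol(yg) - 1L
    ok <- m > 0
    num[ok] <- num[ok] + df * (v[ok] - m[ok]) / m[ok]^2
    den[ok] <- den[ok] + df
  }
  phis <- ifelse(den > 0, num / den, NA_real_)
  phi <- mean(phis, trim = trim, na.rm = TRUE)
  structure(list(phi = max(0, phi), n_features = sum(!is.na(phis)),
                 single_replicate = FALSE),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("<dispersion_estimate> phi = %.4g (from %d features)\n",
              x$phi, x$n_features))
  invisible(x)
}

#' Conditional split probabilities of the exact test
#'
#' Under a negative-binomial count model with per-sample mean `mu` and
#' common dispersion `phi`, the sum of `n` replicate counts is
#' negative-binomial with mean `n * mu` and dispersion `phi / n`.
#' Conditional on the total `t = a + b` of the two group sums, the
#' probability of each split `(x, t - x)` is the normalized product of the
#' two group-sum masses; because both groups share the same negative-binomial
#' success probability, the conditional distribution is free of `mu` and
#' depends only on `phi` and the group sizes. At `phi = 0` it reduces
#' exactly to Binomial(`t`, `n_a / (n_a + n_b)`).
#'
#' @param t Non-negative integer total.
#' @param n_a,n_b Group sizes (numbers of replicates).
#' @param phi Common dispersion (>= 0).
#' @return Numeric vector of length `t + 1`: probabilities of splits
#'   `x = 0..t`, summing to 1.
#' @export
nb_split_probs <- function(t, n_a, n_b, phi = 0) {
  stopifnot(t >= 0, n_a >= 1, n_b >= 1, phi >= 0)
  x <- 0:t
  if (phi == 0) {
    lp <- stats::dbinom(x, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    ra <- n_a / phi
    rb <- n_b / phi
    lp <- lgamma(x + ra) - lgamma(x + 1) - lgamma(ra) +
      lgamma(t - x + rb) - lgamma(t - x + 1) - lgamma(rb)
  }
  m <- max(lp)
  lp <- lp - (m + log(sum(exp(lp - m))))
  exp(lp)
}

#' Conditional negative-binomial exact test for two groups of counts
#'
#' Tests whether a feature's unique-insertion counts differ between two
#' groups of library-equalized samples (a sorted bin versus the depleted
#' control). The two-sided p-value uses the minimum-likelihood rule: the sum
#' of the probabilities of all splits of the conditional distribution (see
#' [nb_split_probs()]) no more probable than the observed split. The
#' log2 fold-change is `log2((a + pseudo) / n_a) - log2((b + pseudo) / n_b)`
#' with a pseudo-count (default 0.5) so zero-count features remain finite,
#' reported in the a-over-b orientation.
#'
#' @param group_a_counts,group_b_counts Non-negative integer vectors of
#'   per-sample counts (libraries already equalized).
#' @param phi Common dispersion, or a `dispersion_estimate`.
#' @param pseudo Pseudo-count for the fold-change (default 0.5).
#'
#' @return A list with `p`, `log2FC`, the group sums `a` and `b`, and the
#'   total `t`. A total of zero returns `p = 1` and `log2FC = 0` by
#'   convention.
#' @export
exact_test <- function(group_a_counts, group_b_counts, phi = 0,
                       pseudo = 0.5) {
  if (inherits(phi, "dispersion_estimate")) phi <- phi$phi
  stopifnot(all(group_a_counts >= 0), all(group_b_counts >= 0),
            length(group_a_counts) >= 1L, length(group_b_counts) >= 1L,
            phi >= 0)
  a <- sum(group_a_counts)
  b <- sum(group_b_counts)
  n_a <- length(group_a_counts)
  n_b <- length(group_b_counts)
  t <- a + b
  if (t == 0)
    return(list(p = 1, log2FC = 0, a = a, b = b, t = t))
  lfc <- log2((a + pseudo) / n_a) - log2((b + pseudo) / n_b)
  probs <- nb_split_probs(t, n_a, n_b, phi)
  obs <- probs[a + 1L]
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
  list(p = p, log2FC = lfc, a = a, b = b, t = t)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment:
#' `fdr_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1, returned in the
#' input order. A validated front-end to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values (same order as input).
#' @export
adjust_bh <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Test feature enrichment of sorted bins against the depleted control
#'
#' Runs the full per-screen statistical workflow: equalize libraries across
#' the screen's samples, estimate a common dispersion from the depleted
#' replicates (unless overridden), run the conditional exact test of each
#' bin (`high`, `low`) against `depleted` for every feature, adjust p-values
#' within each contrast by Benjamini-Hochberg, and flag features enriched in
#' the bin (adjusted p below `fdr_max` and signed log2 fold-change above
#' `lfc_min`).
#'
#' @param cm A `count_matrix` whose columns are the screen's samples.
#' @param sheet A [sample_sheet()] covering those samples.
#' @param screen_id Screen to test (default: the sheet's only screen).
#' @param phi Dispersion override; `NULL` (default) estimates it from the
#'   depleted replicates.
#' @param fdr_max,lfc_min Enrichment thresholds (defaults 0.05 and 0.5).
#' @param pseudo Fold-change pseudo-count (default 0.5).
#'
#' @return A data frame of class `enrichment_result` with one row per
#'   feature per contrast: `feature_id`, `screen_id`, `bin`, `sum_bin`,
#'   `sum_control`, `log2FC`, `p`, `fdr`, `enriched`; the dispersion used is
#'   attached as attribute `phi`.
#' @export
enrich_screen <- function(cm, sheet, screen_id = NULL, phi = NULL,
                          fdr_max = 0.05, lfc_min = 0.5, pseudo = 0.5) {
  stopifnot(inherits(cm, "count_matrix"), inherits(sheet, "sample_sheet"))
  if (is.null(screen_id)) {
    screen_id <- unique(sheet$screen_id)
    if (length(screen_id) != 1L)
      stop("sheet covers several screens; specify screen_id")
  }
  sheet <- sheet[sheet$screen_id == screen_id, , drop = FALSE]
  missing <- setdiff(sheet$sample_id, colnames(cm$counts))
  if (length(missing) > 0L)
    stop("count matrix lacks sample(s): ", paste(missing, collapse = ", "))
  sub <- structure(
    list(counts = cm$counts[, sheet$sample_id, drop = FALSE],
         library_size = cm$library_size[sheet$sample_id],
         inflated = cm$inflated[sheet$sample_id]),
    class = "count_matrix")
  eq <- equalize_libraries(sub)
  dep <- sheet$sample_id[sheet$bin == "depleted"]
  if (length(dep) == 0L)
    stop("screen ", screen_id, " has no depleted control samples")
  if (is.null(phi)) {
    disp <- estimate_common_dispersion(
      eq$counts[, dep, drop = FALSE],
      groups = rep("depleted", length(dep)))
    phi <- disp$phi
  } else if (inherits(phi, "dispersion_estimate")) {
    phi <- phi$phi
  }
  out <- list()
  for (bin in intersect(c("high", "low"), unique(sheet$bin))) {
    bsamp <- sheet$sample_id[sheet$bin == bin]
    res <- lapply(seq_len(nrow(eq$counts)), function(i) {
      exact_test(eq$counts[i, bsamp], eq$counts[i, dep],
                 phi = phi, pseudo = pseudo)
    })
    df <- data.frame(
      feature_id = rownames(eq$counts),
      screen_id = screen_id,
      bin = bin,
      sum_bin = vapply(res, `[[`, numeric(1L), "a"),
      sum_control = vapply(res, `[[`, numeric(1L), "b"),
      log2FC = vapply(res, `[[`, numeric(1L), "log2FC"),
      p = vapply(res, `[[`, numeric(1L), "p"),
      stringsAsFactors = FALSE
    )
    df$fdr <- adjust_bh(df$p)
    df$enriched <- df$fdr < fdr_max & df$log2FC > lfc_min
    out[[bin]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "phi") <- phi
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Classify features into regulator calls
#'
#' A feature enriched only in the `high` bin is called `up_in_high`
#' (disrupting it raises reporter output: the locus represses the reporter);
#' only in `low`, `up_in_low` (the locus activates the reporter); in both
#' bins of the same screen, `ambiguous` (excluded from downstream analysis,
#' as opposite effects of insertion positioning cannot be separated);
#' otherwise `ns`.
#'
#' @param results An `enrichment_result` from [enrich_screen()] containing
#'   both contrasts, or `high_results` / `low_results` given separately.
#' @param low_results Optional second data frame when the two contrasts are
#'   supplied separately.
#'
#' @return A data frame of class `regulator_calls`: `feature_id`,
#'   `screen_id`, `call`.
#' @export
call_regulators <- function(results, low_results = NULL) {
  if (!is.null(low_results)) {
    results <- rbind(as.data.frame(results), as.data.frame(low_results))
  }
  high <- results[results$bin == "high", , drop = FALSE]
  low <- results[results$bin == "low", , drop = FALSE]
  if (!setequal(high$feature_id, low$feature_id) ||
      nrow(high) != nrow(low))
    stop("high and low contrasts cover different feature universes")
  low <- low[match(high$feature_id, low$feature_id), , drop = FALSE]
  call <- ifelse(high$enriched & low$enriched, "ambiguous",
          ifelse(high$enriched, "up_in_high",
          ifelse(low$enriched, "up_in_low", "ns")))
  out <- data.frame(feature_id = high$feature_id,
                    screen_id = high$screen_id,
                    call = call, stringsAsFactors = FALSE)
  class(out) <- c("regulator_calls", "data.frame")
  out
}

#' Compare significant loci across screens
#'
#' Computes, for every non-empty subset of screens, the number of features
#' significant in exactly that subset, plus the percentage of all
#' significant loci (the union across screens) shared by all screens.
#'
#' @param sets A named list (one element per screen, >= 2 screens) of
#'   character vectors of significant feature ids.
#'
#' @return A list with `membership` (data frame: `feature_id`, one logical
#'   column per screen, and `subset`, the `+`-joined names of the screens
#'   containing the feature), `subset_counts` (data frame `subset`, `n`,
#'   `pct_of_union`), `n_union`, `n_shared_all` and `pct_shared_all`.
#' @export
compare_screens <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)),
            all(nzchar(names(sets))))
  union_ids <- sort(unique(unlist(sets, use.names = FALSE)))
  mem <- data.frame(feature_id = union_ids, stringsAsFactors = FALSE)
  for (s in names(sets)) mem[[s]] <- mem$feature_id %in% sets[[s]]
  flags <- as.matrix(mem[names(sets)])
  mem$subset <- apply(flags, 1L, function(z)
    paste(names(sets)[z], collapse = "+"))
  counts <- as.data.frame(table(subset = mem$subset),
                          stringsAsFactors = FALSE)
  names(counts)[2L] <- "n"
  counts$pct_of_union <- 100 * counts$n / max(1L, length(union_ids))
  shared_all <- sum(rowSums(flags) == length(sets))
  list(membership = mem,
       subset_counts = counts[order(-counts$n), , drop = FALSE],
       n_union = length(union_ids),
       n_shared_all = shared_all,
       pct_shared_all = if (length(union_ids) == 0L) 0
                        else 100 * shared_all / length(union_ids))
}
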