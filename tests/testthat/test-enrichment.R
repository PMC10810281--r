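test_that("library equalization rescales to the geometric mean", {
  counts <- matrix(c(10L, 0L, 40L, 5L), nrow = 2,
                   dimnames = list(c("f1", "f2"), c("s1", "s2")))
  cm <- structure(list(counts = counts,
                       library_size = c(s1 = 500, s2 = 2000),
                       inflated = c(s1 = FALSE, s2 = FALSE)),
                  class = "count_matrix")
  eq <- equalize_libraries(cm)
  expect_equal(unname(eq$library_size), c(1000, 1000))  # geometric mean
  expect_equal(unname(eq$counts["f1", ]), c(20L, 20L))  # 10*2, 40*0.5
  expect_equal(unname(eq$counts["f2", ]), c(0L, 2L))    # 0*2, 5*0.5 -> 2.5 -> 2

  same <- structure(list(counts = counts,
                         library_size = c(s1 = 1000, s2 = 1000),
                         inflated = c(s1 = FALSE, s2 = FALSE)),
                    class = "count_matrix")
  expect_equal(equalize_libraries(same)$counts, counts)

  zero <- structure(list(counts = counts,
                         library_size = c(s1 = 0, s2 = 10),
                         inflated = c(s1 = FALSE, s2 = FALSE)),
                    class = "count_matrix")
  expect_error(equalize_libraries(zero), "s1")
})

test_that("common dispersion recovers generating values and floors at zero", {
  set.seed(501)
  groups <- rep(c("a", "b"), each = 3)
  nb <- matrix(rnbinom(500 * 6, mu = 50, size = 1 / 0.2), 500, 6)
  est <- estimate_common_dispersion(nb, groups)
  expect_gte(est$phi, 0.1)
  expect_lte(est$phi, 0.3)

  pois <- matrix(rpois(500 * 6, 50), 500, 6)
  est0 <- estimate_common_dispersion(pois, groups)
  expect_lte(est0$phi, 0.05)

  ident <- matrix(rep(c(5L, 5L, 5L, 9L, 9L, 9L), each = 20), 20, 6)
  expect_equal(estimate_common_dispersion(ident, groups)$phi, 0)

  expect_warning(
    single <- estimate_common_dispersion(nb[, c(1, 4)], c("a", "b")),
    "replicate")
  expect_equal(single$phi, 0)
  expect_true(single$single_replicate)
})

test_that("conditional split distribution is normalized and mu-free", {
  for (phi in c(0, 0.1, 0.5)) {
    for (t in c(1, 17, 200)) {
      pr <- nb_split_probs(t, 3, 2, phi)
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      if (phi > 0) {
        # independent oracle: normalized product of group-sum NB masses,
        # via dnbinom at two arbitrary mean scales (mu must cancel)
        for (m in c(0.7, 13)) {
          x <- 0:t
          ora <- dnbinom(x, size = 3 / phi, mu = 3 * m) *
            dnbinom(t - x, size = 2 / phi, mu = 2 * m)
          ora <- ora / sum(ora)
          expect_equal(pr, ora, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("exact test reproduces its worked examples", {
  r <- exact_test(0L, 10L, phi = 0)
  expect_equal(r$p, 2 / 1024)

  expect_equal(exact_test(5L, 5L, phi = 0)$p, 1)

  lfc0 <- exact_test(40L, 10L, phi = 0, pseudo = 0)$log2FC
  expect_equal(lfc0, 2)
  lfc05 <- exact_test(40L, 10L, phi = 0, pseudo = 0.5)$log2FC
  expect_equal(lfc05, log2(40.5 / 10.5), tolerance = 1e-12)

  zero <- exact_test(c(0L, 0L), c(0L, 0L, 0L), phi = 0.3)
  expect_equal(zero$p, 1)
  expect_equal(zero$log2FC, 0)
})

test_that("exact test equals brute-force conditional binomial at phi = 0", {
  worst <- 0
  for (n_a in 1:3) for (n_b in 1:3) for (t in 0:30) for (a in 0:t) {
    p <- exact_test(c(a, integer(n_a - 1)), c(t - a, integer(n_b - 1)),
                    phi = 0)$p
    worst <- max(worst, abs(p - binom_exact_oracle(a, t - a, n_a, n_b)))
  }
  expect_lt(worst, 1e-9)
})

test_that("exact test is symmetric and monotone away from expectation", {
  set.seed(521)
  for (i in 1:20) {
    a <- rpois(3, 20); b <- rpois(2, 35); phi <- runif(1, 0, 0.4)
    ab <- exact_test(a, b, phi = phi)
    ba <- exact_test(b, a, phi = phi)
    expect_equal(ab$p, ba$p, tolerance = 1e-9)
    expect_equal(ab$log2FC, -ba$log2FC, tolerance = 1e-12)
  }
  # holding b fixed, p shrinks as a moves away from the conditional mean
  b <- 20L
  up <- vapply(seq(20L, 80L, by = 4L), function(a)
    exact_test(a, b, phi = 0.1)$p, numeric(1))
  expect_true(all(diff(up) <= 1e-9))
  down <- vapply(seq(20L, 0L, by = -2L), function(a)
    exact_test(a, b, phi = 0.1)$p, numeric(1))
  expect_true(all(diff(down) <= 1e-9))
})

test_that("exact test agrees with edgeR's classic exact test", {
  skip_if_not_installed("edgeR")
  set.seed(531)
  phi <- 0.15
  y <- matrix(rnbinom(150 * 6, mu = 40, size = 1 / phi), 150, 6)
  d <- edgeR::DGEList(counts = y, group = rep(c("ctl", "bin"), each = 3))
  d$samples$lib.size <- rep(round(mean(colSums(y))), 6)
  d$common.dispersion <- phi
  et <- edgeR::exactTest(d, pair = c("ctl", "bin"),
                         rejection.region = "smallp")
  mine <- vapply(seq_len(nrow(y)), function(i)
    exact_test(y[i, 4:6], y[i, 1:3], phi = phi)$p, numeric(1))
  expect_equal(mine, et$table$PValue, tolerance = 1e-8)
})

test_that("p-values are calibrated under the null at the true dispersion", {
  set.seed(541)
  phi <- 0.2
  pv <- vapply(seq_len(2500), function(i) {
    exact_test(rnbinom(3, mu = 50, size = 1 / phi),
               rnbinom(3, mu = 50, size = 1 / phi), phi = phi)$p
  }, numeric(1))
  frac <- mean(pv < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.42), 0.42)
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(551)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    fdr <- adjust_bh(p)
    expect_identical(fdr, bh_stepup_oracle(p))
    expect_true(all(fdr >= p))
    expect_true(all(diff(fdr[order(p)]) >= 0))
  }
})

test_that("regulator calls apply both thresholds and the ambiguity rule", {
  mk <- function(bin, fdr, lfc) data.frame(
    feature_id = c("f1", "f2", "f3", "f4"), screen_id = "s", bin = bin,
    sum_bin = 0, sum_control = 0, log2FC = lfc, p = fdr / 2, fdr = fdr,
    enriched = fdr < 0.05 & lfc > 0.5)
  high <- mk("high", fdr = c(0.01, 0.01, 0.80, 0.06),
             lfc = c(1.2, 1.0, 0.1, 2.0))
  low <- mk("low", fdr = c(0.80, 0.02, 0.01, 0.50),
            lfc = c(0.0, 2.0, 1.5, 0.0))
  calls <- call_regulators(rbind(high, low))
  expect_equal(calls$call, c("up_in_high", "ambiguous", "up_in_low", "ns"))

  mismatched <- low
  mismatched$feature_id[1] <- "other"
  expect_error(call_regulators(rbind(high, mismatched)), "universe")
})

test_that("screen overlap counts exact subsets and the shared fraction", {
  sets <- list(csm = c("A", "B", "C"), c3 = c("B", "C"), c4 = "C")
  ov <- compare_screens(sets)
  expect_equal(ov$n_union, 3L)
  expect_equal(ov$n_shared_all, 1L)
  expect_equal(ov$pct_shared_all, 100 / 3, tolerance = 1e-12)
  expect_equal(ov$membership$subset[ov$membership$feature_id == "C"],
               "csm+c3+c4")
  expect_equal(ov$membership$subset[ov$membership$feature_id == "A"], "csm")

  same <- compare_screens(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(same$pct_shared_all, 100)
  disj <- compare_screens(list(a = "x", b = "y"))
  expect_equal(disj$pct_shared_all, 0)
})
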