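test_that("profiles reduce to unique sites per strand", {
  fwd <- integer(300); rev <- integer(300)
  fwd[c(100, 250)] <- c(5L, 1L)
  rev[100] <- 3L
  p <- insertion_profile("s1", fwd, rev)
  st <- profile_to_sites(p)
  expect_equal(nrow(st), 3L)
  expect_equal(st$position, c(100L, 100L, 250L))
  expect_equal(st$strand, c("+", "-", "+"))
  expect_equal(st$reads, c(5L, 3L, 1L))

  empty <- profile_to_sites(insertion_profile("s0", integer(10), integer(10)))
  expect_equal(nrow(empty), 0L)

  merged <- profile_to_sites(p, collapse_strands = TRUE)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$reads, c(8L, 1L))
})

test_that("profile and site-table conversions are mutually inverse", {
  set.seed(301)
  for (i in 1:10) {
    p <- random_profile(150)
    st <- profile_to_sites(p)
    expect_equal(nrow(st), sum(p$forward > 0) + sum(p$reverse > 0))
    back <- sites_to_profile(st, 150)
    expect_identical(back$forward, p$forward)
    expect_identical(back$reverse, p$reverse)
    # and the reverse composition is the identity on site tables
    st2 <- profile_to_sites(back)
    expect_equal(st2$position, st$position)
    expect_equal(st2$reads, st$reads)
  }
})

test_that("feature universe fills every gap, named by flanking genes", {
  g <- genome_ref("g", strrep("A", 1000))
  genes <- feature_set(c("g1", "g2"), "gene", c(1L, 501L), c(300L, 800L),
                       c("+", "+"))
  uni <- build_feature_universe(genes, g)
  ig <- uni[uni$kind == "intergenic", ]
  expect_equal(ig$start, c(301L, 801L))
  expect_equal(ig$end, c(500L, 1000L))
  expect_equal(ig$feature_id, c("ig_g1_g2", "ig_g2_end"))
  expect_true(all(ig$strand == "."))
  # full coverage: every position in exactly >= 1 feature
  cov <- integer(1000)
  for (i in seq_len(nrow(uni)))
    cov[uni$start[i]:uni$end[i]] <- cov[uni$start[i]:uni$end[i]] + 1L
  expect_true(all(cov >= 1L))

  # adjacent genes leave no gap between them
  adj <- feature_set(c("a", "b"), "gene", c(1L, 301L), c(300L, 600L),
                     c("+", "+"))
  uni2 <- build_feature_universe(adj, g)
  expect_false(any(uni2$kind == "intergenic" & uni2$start > 1 &
                     uni2$end < 601))

  # overlapping genes: both retained, no intergenic inside the overlap
  ovl <- feature_set(c("a", "b"), "gene", c(1L, 200L), c(300L, 400L),
                     c("+", "+"))
  uni3 <- build_feature_universe(ovl, g)
  expect_equal(sum(uni3$kind == "gene"), 2L)
  expect_equal(uni3$start[uni3$kind == "intergenic"], 401L)
})

test_that("site counting assigns by position, ignoring strand", {
  uni <- toy_universe()$universe
  st <- data.frame(position = c(150L, 150L, 600L),
                   strand = c("+", "-", "+"),
                   reads = c(2L, 1L, 4L))
  counts <- count_sites_per_feature(st, uni)
  expect_equal(unname(counts["geneA"]), 2L)
  expect_equal(unname(counts["geneB"]), 1L)
  expect_equal(attr(counts, "library_size"), 3L)
  expect_false(attr(counts, "inflated"))

  st2 <- data.frame(position = 400L, strand = "+", reads = 1L)
  c2 <- count_sites_per_feature(st2, uni)
  expect_equal(unname(c2["ig_geneA_geneB"]), 1L)
})

test_that("overlapping genes inflate assignments and are flagged", {
  g <- genome_ref("g", strrep("A", 1000))
  ovl <- feature_set(c("a", "b"), "gene", c(1L, 200L), c(300L, 400L),
                     c("+", "+"))
  uni <- build_feature_universe(ovl, g)
  st <- data.frame(position = 250L, strand = "+", reads = 1L)
  counts <- count_sites_per_feature(st, uni)
  expect_equal(unname(counts[c("a", "b")]), c(1L, 1L))
  expect_equal(attr(counts, "library_size"), 1L)
  expect_true(attr(counts, "inflated"))
})

test_that("counts conserve the library size on non-overlapping universes", {
  set.seed(311)
  uni <- toy_universe()
  for (i in 1:5) {
    p <- random_profile(1000)
    st <- profile_to_sites(p)
    counts <- count_sites_per_feature(st, uni$universe)
    expect_equal(sum(counts), attr(counts, "library_size"))
    expect_equal(sum(counts), nrow(st))
  }
})

test_that("counts are invariant to site order and matrices round trip", {
  uni <- toy_universe()
  set.seed(321)
  p <- random_profile(1000, sample_id = "sampA")
  st <- profile_to_sites(p)
  shuffled <- st[sample(nrow(st)), ]
  expect_equal(count_sites_per_feature(st, uni$universe),
               count_sites_per_feature(shuffled, uni$universe))

  cm <- build_count_matrix(list(sampA = p, sampB = p), uni$universe)
  expect_equal(dim(cm$counts), c(nrow(uni$universe), 2L))
  expect_equal(unname(cm$library_size), rep(nrow(st), 2L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, f)
  back <- read_count_matrix(f)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$library_size, cm$library_size)
})
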