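# level-range fixture: ranges chosen by hand on a 6-level scale
hand_levels <- function() {
  ev <- data.frame(
    rank = 1:8,
    taxon = c("a", "b", "a", "c", "b", "d", "c", "d"),
    kind = c("FAD", "FAD", "LAD", "FAD", "LAD", "FAD", "LAD", "LAD"),
    level = c(1, 2, 3, 3, 4, 5, 5, 6))
  structure(list(events = ev, n_levels = 6, assign = ev$level),
            class = "composite_levels")
}

hand_ds <- function() {
  make_ds(list(S = list(levels = 1:4,
                        occ = data.frame(taxon = c("a", "b", "c", "d"),
                                         level = 1:4))),
          taxa_extra = data.frame(taxon = c("a", "b", "c", "d"),
                                  genus = c("G1", "G1", "G2", "G2"),
                                  group = c("PF", "PF", "SBF", "SBF")))
}

test_that("unbinned richness counts taxa whose range spans each level", {
  r <- unbinned_richness(hand_levels(), hand_ds())
  # level 1: a; 2: a,b; 3: a,b,c; 4: b,c; 5: c,d; 6: d
  expect_equal(r$richness, c(1, 2, 3, 2, 2, 1))
  # group filter
  pf <- unbinned_richness(hand_levels(), hand_ds(), group = "PF")
  expect_equal(pf$richness, c(1, 2, 2, 1, 0, 0))
  # genus collapse: G1 spans 1-4, G2 spans 3-6
  g <- unbinned_richness(hand_levels(), hand_ds(), rank = "genus")
  expect_equal(g$richness, c(1, 1, 2, 2, 1, 1))
  ratio <- species_genus_ratio(hand_levels(), hand_ds())
  expect_equal(ratio$ratio, c(1, 2, 1.5, 1, 2, 1))
})

test_that("richness obeys the running-sum identity on random composites", {
  set.seed(12)
  for (rep in seq_len(25)) {
    k <- sample(5:25, 1)
    n_tx <- sample(3:12, 1)
    fad <- sample.int(k, n_tx, replace = TRUE)
    lad <- pmin(k, fad + sample(0:5, n_tx, replace = TRUE))
    # independent oracle: direct span count per level
    direct <- vapply(seq_len(k), function(l)
      sum(fad <= l & lad >= l), integer(1))
    # running-sum identity: FADs at <= k minus LADs at < k
    running <- vapply(seq_len(k), function(l)
      sum(fad <= l) - sum(lad < l), integer(1))
    expect_equal(conopr:::range_richness(fad, lad, k), direct)
    expect_equal(direct, running)
  }
})

test_that("binned rates follow the per-lineage-per-Myr arithmetic", {
  # 10 taxa standing in one 0.2-Myr bin, 2 originations
  ranges <- data.frame(
    taxon = sprintf("t%02d", 1:10),
    fad_age = c(30.15, 30.12, rep(30.5, 8)),
    lad_age = c(rep(29.9, 2), rep(29.9, 8)))
  rs <- binned_rates(ranges, bin_width = 0.2)
  b <- rs[rs$age_lo == 30.0, ]
  expect_equal(b$n_range, 10)
  expect_equal(b$n_fad, 2)
  expect_equal(b$origination, 2 / (10 * 0.2))  # 1.0 /Lmyr
  # bin fully inside every range: no events, rates zero
  mid <- rs[rs$age_lo == 30.2, ]
  expect_equal(mid$n_fad, 0)
  expect_equal(mid$origination, 0)
  expect_equal(mid$turnover, 0)
  # identities
  ok <- !is.na(rs$origination)
  expect_equal(rs$turnover[ok], rs$origination[ok] + rs$extinction[ok])
  expect_equal(rs$net[ok], rs$origination[ok] - rs$extinction[ok])
  expect_error(binned_rates(ranges, bin_width = 0), "positive")
})

test_that("FAD counts over bins add up to the taxa originating in the
           window", {
  set.seed(3)
  ranges <- data.frame(taxon = sprintf("t%02d", 1:40),
                       fad_age = runif(40, 20, 48))
  ranges$lad_age <- pmax(20, ranges$fad_age - rexp(40, 0.3))
  rs <- binned_rates(ranges, bin_width = 0.2)
  expect_equal(sum(rs$n_fad), 40)
  expect_equal(sum(rs$n_lad), 40)
})

test_that("rarefaction matches the hypergeometric closed form and its
           degenerate cases", {
  counts <- c(12, 7, 3, 1, 1)
  full <- rarefy_richness(counts, sum(counts), iters = 200, seed = 1)
  expect_equal(full$mean, 5)           # n = N returns every taxon
  expect_equal(full$hi - full$lo, 0)
  one <- rarefy_richness(counts, 1, iters = 200, seed = 1)
  expect_equal(one$mean, 1)
  expect_warning(big <- rarefy_richness(counts, 100), "exceeds")
  expect_true(is.na(big$mean))

  set.seed(42)
  for (rep in seq_len(20)) {
    s <- sample(3:10, 1)
    counts <- sample(1:20, s, replace = TRUE)
    n <- sample.int(sum(counts) - 1, 1)
    it <- 400
    r <- rarefy_richness(counts, n, iters = it)
    exp_s <- expected_rarefaction(counts, n)
    mc_se <- max(r$sd / sqrt(it), 1e-3)
    expect_lt(abs(r$mean - exp_s), 3 * mc_se + 1e-9)
  }
})

test_that("rarefied means rise with subsample size and never exceed observed
           richness", {
  set.seed(9)
  counts <- sample(1:15, 8, replace = TRUE)
  ns <- round(seq(2, sum(counts), length.out = 6))
  means <- vapply(ns, function(n)
    rarefy_richness(counts, n, iters = 500)$mean, numeric(1))
  expect_true(all(diff(means) >= -0.1))   # monotone up to MC noise
  expect_true(all(means <= length(counts) + 1e-9))
})

test_that("series envelopes collapse without marker noise and bracket the
           point estimate", {
  k <- 12
  lv <- structure(list(
    events = data.frame(rank = 1:8,
                        taxon = c("a", "b", "a", "c", "b", "d", "c", "d"),
                        kind = c("FAD", "FAD", "LAD", "FAD", "LAD", "FAD",
                                 "LAD", "LAD"),
                        level = c(1, 3, 5, 5, 7, 9, 10, 12)),
    n_levels = k, assign = 1:12), class = "composite_levels")
  mk <- data.frame(kind = "FAD", name = c("a", "b", "c", "d"),
                   age_ma = c(48, 44, 40, 32))
  am <- bootstrap_age_model(lv, mk, hand_ds(), n_boot = 60, seed = 2)
  env <- bootstrap_richness(lv, hand_ds(), am, grid_step = 1)
  expect_true(all(env$lo <= env$value + 1e-9, na.rm = TRUE))
  expect_true(all(env$hi >= env$value - 1e-9, na.rm = TRUE))
})

test_that("max-min normalisation maps extremes to 0/1 and is affine
           invariant", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- rnorm(20)
  expect_equal(minmax_normalize(3 * x + 7), minmax_normalize(x))
  expect_equal(min(minmax_normalize(x)), 0)
  expect_equal(max(minmax_normalize(x)), 1)
  expect_error(minmax_normalize(rep(1, 5)), "constant")
})
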