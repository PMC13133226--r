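# Fixture: heights 1..4, taxon A at levels 1-2, B at levels 3-4.
ab_dataset <- function() {
  make_ds(list(S = list(levels = c(1, 2, 3, 4),
                        occ = data.frame(taxon = c("A", "A", "B", "B"),
                                         level = c(1, 2, 3, 4)))))
}

seq_of <- function(ds, ...) {
  ev <- do.call(rbind, lapply(list(...), function(x)
    data.frame(taxon = x[2], kind = x[1], stringsAsFactors = FALSE)))
  composite_sequence(ev, ds)
}

test_that("feasibility enforces FAD-before-LAD and observed coexistence", {
  one <- make_ds(list(S = list(levels = 1:2,
                               occ = data.frame(taxon = c("a", "a"),
                                                level = 1:2))))
  expect_true(is_feasible(seq_of(one, c("FAD", "a"), c("LAD", "a")), one))
  bad <- is_feasible(seq_of(one, c("LAD", "a"), c("FAD", "a")), one)
  expect_false(isTRUE(bad))
  expect_match(attr(bad, "violation"), "FAD a")

  # two taxa overlapping at every level of one section: separating their
  # ranges in the composite breaks the coexistence rule
  co <- make_ds(list(S = list(levels = 1:2,
                              occ = data.frame(taxon = c("a", "b", "a", "b"),
                                               level = c(1, 1, 2, 2)))))
  sep <- seq_of(co, c("FAD", "a"), c("LAD", "a"), c("FAD", "b"), c("LAD", "b"))
  expect_false(isTRUE(is_feasible(sep, co)))
  inter <- seq_of(co, c("FAD", "a"), c("FAD", "b"), c("LAD", "a"),
                  c("LAD", "b"))
  expect_true(is_feasible(inter, co))
})

test_that("section penalty matches hand-computed minimal extension", {
  ds <- ab_dataset()
  agree <- seq_of(ds, c("FAD", "A"), c("LAD", "A"), c("FAD", "B"),
                  c("LAD", "B"))
  expect_equal(total_penalty(agree, ds), 0)
  pl <- section_penalty(agree, ds, "S")
  expect_equal(pl$events$extension, rep(0, 4))

  # interleaved order forces either FAD_B down to 2 or LAD_A up to 3
  inter <- seq_of(ds, c("FAD", "A"), c("FAD", "B"), c("LAD", "A"),
                  c("LAD", "B"))
  expect_equal(section_penalty(inter, ds, "S")$section_penalty, 1)

  # placements are monotone, extension-only, on grid heights
  ev <- section_penalty(inter, ds, "S")$events
  expect_true(all(diff(ev$placed_height) >= 0))
  expect_true(all(ev$placed_height[ev$kind == "FAD"] <=
                    ev$observed_height[ev$kind == "FAD"]))
  expect_true(all(ev$placed_height[ev$kind == "LAD"] >=
                    ev$observed_height[ev$kind == "LAD"]))
})

test_that("section weight scales the penalty linearly", {
  ds1 <- ab_dataset()
  ds2 <- make_ds(list(S = list(levels = c(1, 2, 3, 4),
                               occ = data.frame(taxon = c("A", "A", "B", "B"),
                                                level = c(1, 2, 3, 4)),
                               weight = 2)))
  inter1 <- seq_of(ds1, c("FAD", "A"), c("FAD", "B"), c("LAD", "A"),
                   c("LAD", "B"))
  inter2 <- seq_of(ds2, c("FAD", "A"), c("FAD", "B"), c("LAD", "A"),
                   c("LAD", "B"))
  expect_equal(section_penalty(inter2, ds2, "S")$section_penalty,
               2 * section_penalty(inter1, ds1, "S")$section_penalty)
})

test_that("total penalty is additive over duplicated sections", {
  spec <- list(levels = c(1, 2, 3, 4),
               occ = data.frame(taxon = c("A", "A", "B", "B"),
                                level = c(1, 2, 3, 4)))
  ds2 <- make_ds(list(S1 = spec, S2 = spec))
  inter <- seq_of(ds2, c("FAD", "A"), c("FAD", "B"), c("LAD", "A"),
                  c("LAD", "B"))
  expect_equal(total_penalty(inter, ds2),
               2 * section_penalty(inter, ds2, "S1")$section_penalty)
})

test_that("dynamic programme equals brute-force minimum on random instances", {
  set.seed(404)
  for (rep in seq_len(250)) {
    m <- sample(1:6, 1)
    L <- sample(2:6, 1)
    grid <- sort(stats::runif(L, 0, 10))
    isfad <- stats::runif(m) < 0.5
    # observed heights on the grid (as real data would be)
    obs <- grid[sample.int(L, m, replace = TRUE)]
    dp <- conopr:::cpp_section_penalty(obs, isfad, grid)
    bf <- brute_section_penalty(obs, isfad, grid)
    if (is.infinite(bf)) {
      expect_equal(dp, -1)
    } else {
      expect_equal(dp, bf, tolerance = 1e-12)
    }
  }
})

test_that("total penalty equals the sum of per-section penalties", {
  set.seed(11)
  for (rep in seq_len(20)) {
    w <- simulate_world(n_taxa = 8, n_sections = 4, levels_per_section = 6,
                        sampling_prob = 0.6, seed = 100 + rep)
    es <- conopr:::event_system(w$dataset)
    s <- seq_from_order(random_feasible_order(es), w$dataset)
    per_sec <- vapply(names(w$dataset$sections), function(id)
      section_penalty(s, w$dataset, id)$section_penalty, numeric(1))
    expect_equal(total_penalty(s, w$dataset), sum(per_sec))
  }
})

test_that("delta evaluation agrees exactly with full recomputation", {
  w <- simulate_world(seed = 5)   # 20 taxa, 8 sections
  ds <- w$dataset
  es <- conopr:::event_system(ds)
  set.seed(99)
  s <- seq_from_order(random_feasible_order(es), ds)
  base <- total_penalty(s, ds)
  n_checked <- 0
  while (n_checked < 300) {
    off <- if (stats::runif(1) < 0.5) mutate_small(s, ds)
           else mutate_large(s, ds)
    if (is.null(off)) next
    d <- delta_penalty(s, off, ds)
    full <- total_penalty(off, ds)
    expect_equal(base + d, full, tolerance = 1e-12)
    s <- off; base <- full
    n_checked <- n_checked + 1
  }
  # locality: a move touching taxa absent from a section leaves it unchanged
  expect_equal(delta_penalty(s, s, ds), 0)  # identity move
})

test_that("composite ranges index each taxon's FAD before its LAD", {
  co <- make_ds(list(S = list(levels = 1:2,
                              occ = data.frame(taxon = c("a", "b", "a", "b"),
                                               level = c(1, 1, 2, 2)))))
  s <- seq_of(co, c("FAD", "a"), c("FAD", "b"), c("LAD", "a"), c("LAD", "b"))
  r <- composite_ranges(s)
  expect_equal(r$fad_rank[r$taxon == "a"], 1)
  expect_equal(r$lad_rank[r$taxon == "a"], 3)
  expect_equal(r$fad_rank[r$taxon == "b"], 2)
  expect_equal(r$lad_rank[r$taxon == "b"], 4)
  expect_setequal(c(r$fad_rank, r$lad_rank), 1:4)
  expect_true(all(r$fad_rank < r$lad_rank))
})

test_that("penalty is invariant under taxon relabeling and section order", {
  w <- simulate_world(n_taxa = 8, n_sections = 4, seed = 21)
  ds <- w$dataset
  es <- conopr:::event_system(ds)
  set.seed(7)
  s <- seq_from_order(random_feasible_order(es), ds)
  p0 <- total_penalty(s, ds)
  # reverse the section list
  ds2 <- ds; ds2$sections <- rev(ds2$sections)
  s2 <- composite_sequence(s$events[, c("taxon", "kind")], ds2)
  expect_equal(total_penalty(s2, ds2), p0)
  # relabel taxa (prefix) consistently everywhere
  ds3 <- ds
  ds3$taxa$taxon <- paste0("x_", ds3$taxa$taxon)
  ds3$sections <- lapply(ds3$sections, function(sc) {
    sc$occurrences$taxon <- paste0("x_", sc$occurrences$taxon); sc })
  ev3 <- s$events[, c("taxon", "kind")]
  ev3$taxon <- paste0("x_", ev3$taxon)
  s3 <- composite_sequence(ev3, ds3)
  expect_equal(total_penalty(s3, ds3), p0)
})

test_that("composite CSV round-trips through read and write", {
  w <- simulate_world(n_taxa = 8, n_sections = 4, seed = 31)
  es <- conopr:::event_system(w$dataset)
  set.seed(3)
  s <- seq_from_order(random_feasible_order(es), w$dataset)
  tmp <- tempfile(fileext = ".csv")
  write_composite(s, tmp)
  s2 <- read_composite(tmp, w$dataset)
  expect_equal(s2$events, s$events)
  unlink(tmp)
})
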