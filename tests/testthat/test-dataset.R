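test_that("reading a section table derives counts, ranges and events", {
  ds <- toy_dataset()
  expect_s3_class(ds, "strat_dataset")
  expect_equal(nrow(ds$taxa), 3)
  expect_equal(length(ds$sections), 2)
  s <- dataset_summary(ds)
  expect_equal(s$n_events, 6)
  lr <- local_ranges(ds)
  expect_equal(lr$fad_level[lr$section_id == "S1" & lr$taxon == "a"], 1L)
  expect_equal(lr$lad_level[lr$section_id == "S1" & lr$taxon == "a"], 2L)
})

test_that("non-increasing heights and malformed rows are rejected", {
  bad <- toy_table()
  bad$height[bad$section_id == "S1"] <- c(3, 3, 2, 1)
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_sections(tmp), "S1")
  mal <- toy_table()
  mal$height[5] <- NA
  utils::write.csv(mal, tmp, row.names = FALSE)
  expect_error(read_sections(tmp), "line")
  unlink(tmp)
})

test_that("duplicate occurrence rows collapse to the same dataset", {
  tab <- toy_table()
  tmp1 <- tempfile(fileext = ".csv"); tmp2 <- tempfile(fileext = ".csv")
  utils::write.csv(tab, tmp1, row.names = FALSE)
  utils::write.csv(rbind(tab, tab[3, ]), tmp2, row.names = FALSE)
  ds1 <- read_sections(tmp1)
  expect_warning(ds2 <- read_sections(tmp2), "duplicate")
  k1 <- with(ds1$sections$S1$occurrences, sort(paste(taxon, level_index)))
  k2 <- with(ds2$sections$S1$occurrences, sort(paste(taxon, level_index)))
  expect_equal(k1, k2)
  unlink(c(tmp1, tmp2))
})

test_that("read-write-read round-trips the dataset", {
  w <- simulate_world(n_taxa = 12, n_sections = 5, seed = 11)
  tmp <- tempfile(fileext = ".csv")
  write_sections(w$dataset, tmp)
  ds2 <- read_sections(tmp)
  write_sections(ds2, sub("csv$", "2.csv", tmp))
  ds3 <- read_sections(sub("csv$", "2.csv", tmp))
  expect_equal(sort(ds2$taxa$taxon), sort(w$dataset$taxa$taxon))
  expect_equal(ds2$taxa, ds3$taxa)
  expect_equal(ds2$sections, ds3$sections)
  for (id in names(w$dataset$sections)) {
    a <- w$dataset$sections[[id]]$occurrences
    b <- ds2$sections[[id]]$occurrences
    expect_setequal(paste(a$taxon, a$level_index), paste(b$taxon, b$level_index))
  }
  unlink(c(tmp, sub("csv$", "2.csv", tmp)))
})

test_that("event-count screening keeps sections strictly above threshold", {
  mk_sec <- function(n_taxa) {
    taxa <- sprintf("t%02d", seq_len(n_taxa))
    list(levels = seq_len(n_taxa), occ = data.frame(taxon = taxa,
                                                    level = seq_len(n_taxa)))
  }
  ds <- make_ds(list(A = mk_sec(14), B = mk_sec(16)))
  # connect A and B through a shared taxon so the fixture is coherent
  kept <- filter_sections(ds, 30)
  expect_equal(names(kept$sections), "B")       # 28 <= 30 < 32
  expect_equal(nrow(kept$taxa), 16)             # orphaned taxa dropped
  expect_equal(filter_sections(ds, 0)$sections, ds$sections)  # identity
  # idempotence at fixed threshold
  expect_equal(filter_sections(kept, 30)$sections, kept$sections)
  expect_error(filter_sections(ds, 100), "no section")
})

test_that("connectivity partitions sections by shared taxa", {
  ds1 <- make_ds(list(
    S1 = list(levels = 1:2, occ = data.frame(taxon = c("a", "b"), level = 1:2)),
    S2 = list(levels = 1:2, occ = data.frame(taxon = c("b", "c"), level = 1:2))))
  c1 <- section_connectivity(ds1)
  expect_equal(c1$n_components, 1)
  expect_true(c1$correlatable)

  ds2 <- make_ds(list(
    S1 = list(levels = 1:2, occ = data.frame(taxon = c("a", "a"), level = 1:2)),
    S2 = list(levels = 1:2, occ = data.frame(taxon = c("b", "b"), level = 1:2))))
  expect_equal(section_connectivity(ds2)$n_components, 2)

  ds3 <- make_ds(list(
    S1 = list(levels = 1:2, occ = data.frame(taxon = c("a", "b"), level = 1:2)),
    S2 = list(levels = 1:2, occ = data.frame(taxon = c("b", "c"), level = 1:2)),
    S3 = list(levels = 1:2, occ = data.frame(taxon = c("c", "d"), level = 1:2))))
  expect_equal(section_connectivity(ds3)$n_components, 1)  # transitivity

  # invariant under reordering of sections
  ds3r <- make_ds(list(
    S3 = list(levels = 1:2, occ = data.frame(taxon = c("c", "d"), level = 1:2)),
    S1 = list(levels = 1:2, occ = data.frame(taxon = c("a", "b"), level = 1:2)),
    S2 = list(levels = 1:2, occ = data.frame(taxon = c("b", "c"), level = 1:2))))
  expect_equal(section_connectivity(ds3r)$n_components, 1)
})

test_that("section ranking counts dataset-wide occurrences of shared taxa", {
  # a occurs 3x in total (2 in S1, 1 in S2) and is the only shared taxon;
  # b stays private to S1
  ds <- make_ds(list(
    S1 = list(levels = 1:3, occ = data.frame(taxon = c("a", "a", "b", "b"),
                                             level = c(1, 2, 2, 3))),
    S2 = list(levels = 1:2, occ = data.frame(taxon = "a", level = 1))))
  r <- rank_sections(ds)
  expect_equal(r$score, c(3, 3))
  expect_equal(r$section_id, c("S1", "S2"))  # tie broken lexically

  one <- make_ds(list(S1 = list(levels = 1:2,
                                occ = data.frame(taxon = c("x", "y"),
                                                 level = 1:2))))
  expect_equal(rank_sections(one)$score, 0)

  # doubling a shared taxon's occurrences doubles its contribution
  ds2 <- make_ds(list(
    S1 = list(levels = 1:4, occ = data.frame(taxon = c("a", "a", "a", "a", "b"),
                                             level = c(1, 2, 3, 4, 2))),
    S2 = list(levels = 1:2, occ = data.frame(taxon = c("a", "a"),
                                             level = 1:2))))
  expect_equal(rank_sections(ds2)$score, c(6, 6))
})

test_that("independent bioevents per section follow the co-occurrence rule", {
  disjoint <- make_ds(list(
    S = list(levels = 1:4, occ = data.frame(taxon = c("a", "a", "b", "b"),
                                            level = c(1, 2, 3, 4)))))
  expect_equal(independent_event_resolution(disjoint), 4)

  shared <- make_ds(list(
    S = list(levels = 1:2, occ = data.frame(taxon = c("a", "b", "a", "b"),
                                            level = c(1, 1, 2, 2)))))
  expect_equal(independent_event_resolution(shared), 0)

  both <- make_ds(list(
    S1 = list(levels = 1:4, occ = data.frame(taxon = c("a", "a", "b", "b"),
                                             level = c(1, 2, 3, 4))),
    S2 = list(levels = 1:2, occ = data.frame(taxon = c("a", "b", "a", "b"),
                                             level = c(1, 1, 2, 2)))))
  expect_equal(independent_event_resolution(both), 2)
})
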