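# Fixture builders and independent oracles shared across the test files.

# Two-section, three-taxon toy table (counts known by hand).
toy_table <- function() {
  data.frame(
    section_id = c("S1", "S1", "S1", "S1", "S2", "S2", "S2", "S2"),
    level_index = c(1L, 1L, 2L, 3L, 1L, 2L, 2L, 3L),
    height = c(0, 0, 1, 2, 10, 20, 20, 30),
    taxon = c("a", "b", "a", "b", "b", "b", "c", "c"),
    stringsAsFactors = FALSE)
}

toy_dataset <- function() {
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(toy_table(), tmp, row.names = FALSE)
  on.exit(unlink(tmp))
  read_sections(tmp)
}

# dataset from a compact spec: list(section_id = list(levels = heights,
# occ = data.frame(taxon, level)))
make_ds <- function(secs, taxa_extra = NULL) {
  sections <- lapply(names(secs), function(id) {
    s <- secs[[id]]
    list(section_id = id,
         levels = data.frame(level_index = seq_along(s$levels),
                             height = s$levels),
         occurrences = data.frame(taxon = s$occ$taxon,
                                  level_index = s$occ$level),
         weight = if (is.null(s$weight)) 1 else s$weight)
  })
  names(sections) <- names(secs)
  taxa <- data.frame(taxon = unique(unlist(lapply(sections, function(s)
    s$occurrences$taxon))), stringsAsFactors = FALSE)
  if (!is.null(taxa_extra)) taxa <- merge(taxa, taxa_extra, all.x = TRUE)
  strat_dataset(taxa, sections)
}

# a world whose sections all share one integer-age level grid, so that no
# discretisation conflict exists: the true order has penalty exactly 0
grid_world <- function(n_taxa = 10, n_sections = 5, span = c(40, 20),
                       seed = 1) {
  set.seed(seed)
  ages_grid <- seq(span[1], span[2])
  repeat {
    ev_ages <- sample(ages_grid, 2 * n_taxa)  # distinct integer event ages
    fad <- lad <- numeric(n_taxa)
    for (t in seq_len(n_taxa)) {
      two <- sort(ev_ages[c(2 * t - 1, 2 * t)], decreasing = TRUE)
      fad[t] <- two[1]; lad[t] <- two[2]
    }
    if (all(fad > lad)) break
  }
  ranges <- data.frame(taxon = sprintf("sp%02d", seq_len(n_taxa)),
                       genus = sprintf("gen%02d", ceiling(seq_len(n_taxa) / 3)),
                       group = "other", fad_age = fad, lad_age = lad,
                       stringsAsFactors = FALSE)
  sections <- list()
  for (si in seq_len(n_sections)) {
    w <- sort(sample(ages_grid, 2))
    lv_ages <- seq(w[2], w[1])  # old -> young handled below
    lv_ages <- sort(lv_ages, decreasing = TRUE)
    if (length(lv_ages) < 3) next
    occ <- list()
    for (l in seq_along(lv_ages)) {
      extant <- which(fad >= lv_ages[l] & lad <= lv_ages[l])
      if (length(extant))
        occ[[length(occ) + 1L]] <- data.frame(taxon = ranges$taxon[extant],
                                              level = l)
    }
    if (!length(occ)) next
    id <- sprintf("g%02d", si)
    sections[[id]] <- list(levels = max(lv_ages) - lv_ages + si * 0,
                           occ = do.call(rbind, occ))
    # heights 0,1,2,... strictly increasing upward
  }
  ds <- make_ds(sections)
  truth <- data.frame(taxon = rep(ranges$taxon, 2),
                      kind = rep(c("FAD", "LAD"), each = n_taxa),
                      age = c(fad, lad))
  truth <- truth[order(-truth$age), ]
  truth <- truth[truth$taxon %in% ds$taxa$taxon, ]
  list(dataset = ds, ranges = ranges, truth = truth)
}

# brute-force minimal extension-only monotone placement cost (oracle for
# the DP): enumerate all non-decreasing level assignments
brute_section_penalty <- function(obs, isfad, grid) {
  m <- length(obs)
  if (m == 0) return(0)
  L <- length(grid)
  best <- Inf
  assign <- integer(m)
  recurse <- function(i, minlev, acc) {
    if (acc >= best) return()
    if (i > m) { best <<- acc; return() }
    for (l in minlev:L) {
      h <- grid[l]
      ok <- if (isfad[i]) h <= obs[i] else h >= obs[i]
      if (ok) recurse(i + 1L, l, acc + abs(h - obs[i]))
    }
  }
  recurse(1L, 1L, 0)
  best
}

# closed-form expected rarefied richness (hypergeometric)
expected_rarefaction <- function(counts, n) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

# random feasible composite order via randomised topological sort of the
# constraint graph (independent of the package's search machinery)
random_feasible_order <- function(es) {
  n <- es$n
  indeg <- colSums(es$precede)
  placed <- logical(n)
  out <- integer(n)
  for (k in seq_len(n)) {
    avail <- which(!placed & indeg == 0)
    e <- if (length(avail) == 1L) avail else sample(avail, 1L)
    out[k] <- e
    placed[e] <- TRUE
    succ <- which(es$precede[e, ])
    indeg[succ] <- indeg[succ] - 1L
  }
  out
}

seq_from_order <- function(ord, ds) {
  es <- conopr:::event_system(ds)
  conopr:::new_composite(ord, es)
}
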