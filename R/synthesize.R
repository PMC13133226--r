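#' Simulate true taxon ranges
#'
#' Constant-rate birth--death stand-in for a real fauna: origination ages
#' fall uniformly in the study span (the constant-rate assumption
#' conditioned on the taxon count), durations are exponential with rate
#' `ext_rate` (mean duration 1/ext_rate Myr) and extinction ages are clipped
#' to the young end of the span.  When `n_taxa` is `NULL` the count is drawn
#' as Poisson(`orig_rate` x span).
#'
#' @param n_taxa number of taxa (or `NULL` to draw from `orig_rate`).
#' @param span `c(old, young)` ages in Ma.
#' @param orig_rate origination rate (taxa per Myr), used only when
#'   `n_taxa` is `NULL`.
#' @param ext_rate extinction rate (per lineage per Myr, > 0).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param n_groups number of species per genus used when labelling genera.
#' @return data frame `taxon, genus, group, fad_age, lad_age` with
#'   `fad_age > lad_age` for every taxon.
#' @export
simulate_ranges <- function(n_taxa = 20, span = c(48, 20), orig_rate = 1,
                            ext_rate = 0.15, seed = NULL, n_groups = 3) {
  stopifnot(ext_rate > 0, span[1] > span[2])
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_taxa)) {
    n_taxa <- stats::rpois(1, orig_rate * diff(rev(span)))
    if (n_taxa < 1) {
      warning("no taxa drawn; regenerating")
      while (n_taxa < 1) n_taxa <- stats::rpois(1, orig_rate * diff(rev(span)))
    }
  }
  fad <- stats::runif(n_taxa, span[2], span[1])
  dur <- stats::rexp(n_taxa, rate = ext_rate)
  lad <- pmax(fad - dur, span[2])
  # keep durations strictly positive after clipping
  lad <- pmin(lad, fad - 1e-6)
  data.frame(taxon = sprintf("sp%02d", seq_len(n_taxa)),
             genus = sprintf("gen%02d", ceiling(seq_len(n_taxa) / n_groups)),
             group = sample(c("PF", "LBF", "SBF"), n_taxa, replace = TRUE),
             fad_age = fad, lad_age = lad, stringsAsFactors = FALSE)
}

#' Simulate stratigraphic sections sampling a known world
#'
#' Each section samples a random time window of the span: level ages are
#' stratified-uniform within the window, heights accumulate with a random
#' per-section rate (younger upward), and a taxon extant at a level is
#' recorded with probability `sampling_prob`.  Every observed local range is
#' therefore contained in the taxon's true range -- the premise that makes
#' the extension-only penalty meaningful.
#'
#' @param ranges true ranges from [simulate_ranges()].
#' @param n_sections number of sections.
#' @param levels_per_section levels per section.
#' @param sampling_prob per taxon-level preservation probability in (0, 1].
#' @param span `c(old, young)` ages in Ma.
#' @param min_window minimum window duration (Myr); default one third of the
#'   span.
#' @param seed optional integer seed.
#' @return A [strat_dataset()] (taxa never observed are dropped) with an
#'   attribute `level_ages`: per section, the true age of each level.
#' @export
simulate_sections <- function(ranges, n_sections = 8, levels_per_section = 12,
                              sampling_prob = 0.5, span = c(48, 20),
                              min_window = NULL, seed = NULL) {
  stopifnot(sampling_prob > 0, sampling_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(min_window)) min_window <- (span[1] - span[2]) / 3
  sections <- list()
  level_ages <- list()
  for (si in seq_len(n_sections)) {
    w_old <- stats::runif(1, span[2] + min_window, span[1])
    w_young <- stats::runif(1, span[2], w_old - min_window)
    edges <- seq(w_old, w_young, length.out = levels_per_section + 1)
    ages <- vapply(seq_len(levels_per_section), function(l)
      stats::runif(1, edges[l + 1], edges[l]), numeric(1))  # old -> young
    rate <- stats::runif(1, 0.5, 2)
    heights <- (w_old - ages) * rate
    occ <- list()
    for (l in seq_len(levels_per_section)) {
      extant <- which(ranges$fad_age >= ages[l] & ranges$lad_age <= ages[l])
      hit <- extant[stats::runif(length(extant)) < sampling_prob]
      if (length(hit))
        occ[[length(occ) + 1L]] <- data.frame(taxon = ranges$taxon[hit],
                                              level_index = l)
    }
    if (!length(occ)) next
    id <- sprintf("sec%02d", si)
    sections[[id]] <- list(
      section_id = id,
      levels = data.frame(level_index = seq_len(levels_per_section),
                          height = heights),
      occurrences = do.call(rbind, occ), weight = 1)
    level_ages[[id]] <- ages
  }
  if (!length(sections))
    stop("no occurrences sampled; increase sampling_prob")
  seen <- unique(unlist(lapply(sections, function(s) s$occurrences$taxon)))
  taxa <- ranges[ranges$taxon %in% seen,
                 c("taxon", "genus", "group"), drop = FALSE]
  ds <- strat_dataset(taxa, sections)
  attr(ds, "level_ages") <- level_ages
  ds
}

#' Simulate an environmental proxy coupled to true richness
#'
#' Proxy value = `coupling` x max-min normalised true richness + AR(1)
#' noise, on a regular age grid across the span.
#'
#' @param ranges true ranges from [simulate_ranges()].
#' @param coupling strength of the richness signal in the proxy.
#' @param ar_coefficient AR(1) coefficient of the noise (|phi| < 1).
#' @param noise_sd stationary standard deviation of the noise.
#' @param span `c(old, young)` ages in Ma.
#' @param grid_step grid step in Myr.
#' @param seed optional integer seed.
#' @return data frame `age_ma, value`.
#' @export
simulate_proxy <- function(ranges, coupling = 1, ar_coefficient = 0.5,
                           noise_sd = 0.1, span = c(48, 20),
                           grid_step = 0.2, seed = NULL) {
  stopifnot(abs(ar_coefficient) < 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(span[2], span[1], by = grid_step)
  rich <- vapply(grid, function(a)
    sum(ranges$fad_age >= a & ranges$lad_age <= a), numeric(1))
  signal <- if (diff(range(rich)) > 0) minmax_normalize(rich)
            else rep(0, length(rich))
  n <- length(grid)
  eps <- numeric(n)
  innov_sd <- noise_sd * sqrt(1 - ar_coefficient^2)
  eps[1] <- stats::rnorm(1, sd = noise_sd)
  for (i in seq_len(n - 1L))
    eps[i + 1L] <- ar_coefficient * eps[i] + stats::rnorm(1, sd = innov_sd)
  data.frame(age_ma = grid, value = coupling * signal + eps)
}

#' True richness of a simulated world on an age grid
#'
#' @param ranges true ranges from [simulate_ranges()].
#' @param grid ages (Ma) at which to count standing taxa.
#' @return data frame `age_ma, richness`.
#' @export
true_richness <- function(ranges, grid) {
  data.frame(age_ma = grid,
             richness = vapply(grid, function(a)
               sum(ranges$fad_age >= a & ranges$lad_age <= a), numeric(1)))
}

#' Generate a complete synthetic world with known truth
#'
#' Bundles [simulate_ranges()], [simulate_sections()], a marker subset (the
#' taxa with most occurrences, mimicking index-species choice, with their
#' true FAD/LAD ages) and [simulate_proxy()] into one reproducible object.
#' The true composite event order (all FADs and LADs sorted by true age)
#' gives every downstream module a closed-loop target.
#'
#' @inheritParams simulate_ranges
#' @inheritParams simulate_sections
#' @param n_markers number of index taxa whose true ages become markers.
#' @param coupling,ar_coefficient,noise_sd proxy parameters (see
#'   [simulate_proxy()]).
#' @param seed integer seed; the whole world regenerates bit-for-bit from
#'   it.
#' @return An object of class `synthetic_world`: `ranges`, `dataset`,
#'   `markers`, `proxy`, `true_order` (data frame `taxon, kind, age`,
#'   oldest first) and `params`.
#' @export
simulate_world <- function(n_taxa = 20, n_sections = 8,
                           levels_per_section = 12, sampling_prob = 0.5,
                           span = c(48, 20), ext_rate = 0.15,
                           n_markers = 6, coupling = 1,
                           ar_coefficient = 0.5, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  ranges <- simulate_ranges(n_taxa = n_taxa, span = span,
                            ext_rate = ext_rate)
  ds <- simulate_sections(ranges, n_sections = n_sections,
                          levels_per_section = levels_per_section,
                          sampling_prob = sampling_prob, span = span)
  ranges <- ranges[ranges$taxon %in% ds$taxa$taxon, , drop = FALSE]
  occ_n <- table(unlist(lapply(ds$sections, function(s) s$occurrences$taxon)))
  idx <- names(sort(occ_n, decreasing = TRUE))[seq_len(min(n_markers,
                                                           length(occ_n)))]
  markers <- do.call(rbind, lapply(idx, function(tx) {
    r <- ranges[ranges$taxon == tx, ]
    data.frame(kind = c("FAD", "LAD"), name = tx,
               age_ma = c(r$fad_age, r$lad_age), stringsAsFactors = FALSE)
  }))
  proxy <- simulate_proxy(ranges, coupling = coupling,
                          ar_coefficient = ar_coefficient,
                          noise_sd = noise_sd, span = span)
  ev <- data.frame(taxon = rep(ranges$taxon, 2),
                   kind = rep(c("FAD", "LAD"), each = nrow(ranges)),
                   age = c(ranges$fad_age, ranges$lad_age),
                   stringsAsFactors = FALSE)
  ev <- ev[order(-ev$age), ]
  rownames(ev) <- NULL
  structure(list(ranges = ranges, dataset = ds, markers = markers,
                 proxy = proxy, true_order = ev,
                 params = list(n_taxa = n_taxa, n_sections = n_sections,
                               levels_per_section = levels_per_section,
                               sampling_prob = sampling_prob, span = span,
                               ext_rate = ext_rate, n_markers = n_markers,
                               coupling = coupling,
                               ar_coefficient = ar_coefficient,
                               noise_sd = noise_sd, seed = seed)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", nrow(x$ranges), " taxa, ",
      length(x$dataset$sections), " sections, ",
      nrow(x$markers), " markers, seed ", x$params$seed, "\n", sep = "")
  invisible(x)
}

#' Rank correlation between a fitted composite and the true event order
#'
#' Spearman correlation between each event's position in the recovered
#' composite and its position in the simulated true order.
#'
#' @param seq a [composite_sequence()] (or `conop_fit`).
#' @param world a [simulate_world()] result.
#' @return Spearman correlation coefficient.
#' @export
order_recovery <- function(seq, world) {
  if (inherits(seq, "conop_fit")) seq <- seq$sequence
  ev <- seq$events
  key <- paste(ev$taxon, ev$kind)
  truth <- world$true_order
  tkey <- paste(truth$taxon, truth$kind)
  pos_true <- match(key, tkey)
  keep <- !is.na(pos_true)
  stats::cor(ev$rank[keep], pos_true[keep], method = "spearman")
}
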