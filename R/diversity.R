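#' Unbinned richness through the composite
#'
#' Standing richness at each composite level: the number of taxa whose
#' composite range (FAD level to LAD level, inclusive) spans the level.
#' Equivalently a running sum, richness at level k = (FADs at levels <= k)
#' minus (LADs at levels < k).  Genus richness collapses congeners to one
#' range from the earliest congeneric FAD to the latest LAD.  Marker
#' pseudo-taxa are excluded.
#'
#' @param levels a [cluster_levels()] result.
#' @param ds the [strat_dataset()].
#' @param group optional group filter (`"PF"`, `"LBF"`, `"SBF"`).
#' @param rank `"species"` (default) or `"genus"`.
#' @param ages optional [fit_age_model()] result; adds an `age_ma` column.
#' @return data frame `level[, age_ma], richness`.
#' @export
unbinned_richness <- function(levels, ds, group = NULL,
                              rank = c("species", "genus"), ages = NULL) {
  rank <- match.arg(rank)
  r <- taxon_level_ranges(levels, ds)
  r <- r[!r$pseudo, , drop = FALSE]
  if (!is.null(group)) r <- r[r$group %in% group, , drop = FALSE]
  if (rank == "genus") {
    drop <- is.na(r$genus) | r$genus == ""
    if (any(drop))
      message(sum(drop), " taxa without genus excluded from genus series")
    r <- r[!drop, , drop = FALSE]
    if (nrow(r)) {
      fad <- tapply(r$fad_level, r$genus, min)
      lad <- tapply(r$lad_level, r$genus, max)
      r <- data.frame(taxon = names(fad), fad_level = as.integer(fad),
                      lad_level = as.integer(lad))
    }
  }
  k <- levels$n_levels
  richness <- range_richness(r$fad_level, r$lad_level, k)
  out <- data.frame(level = seq_len(k), richness = richness)
  if (!is.null(ages)) {
    out$age_ma <- ages$level_ages
    out <- out[, c("level", "age_ma", "richness")]
  }
  out
}

# standing count per level from level ranges (running-sum form)
range_richness <- function(fad, lad, k) {
  if (!length(fad)) return(integer(k))
  cum_fad <- cumsum(tabulate(fad, nbins = k))
  cum_lad <- cumsum(tabulate(lad, nbins = k))
  as.integer(cum_fad - c(0L, cum_lad[-k]))
}

#' Species/genus ratio per composite level
#'
#' @inheritParams unbinned_richness
#' @return data frame `level[, age_ma], species, genera, ratio` (`NA` where
#'   genus richness is zero).
#' @export
species_genus_ratio <- function(levels, ds, group = NULL, ages = NULL) {
  sp <- unbinned_richness(levels, ds, group = group, ages = ages)
  ge <- suppressMessages(
    unbinned_richness(levels, ds, group = group, rank = "genus"))
  out <- sp
  names(out)[names(out) == "richness"] <- "species"
  out$genera <- ge$richness
  out$ratio <- ifelse(out$genera > 0, out$species / out$genera, NA_real_)
  out
}

#' Binned proportional origination and extinction rates
#'
#' Partitions the calibrated span into bins of `bin_width` Myr.  Per bin,
#' with D the number of taxa whose age range intersects the bin, O the FADs
#' and E the LADs dated inside it: origination = O/(D * width) and
#' extinction = E/(D * width), in species per lineage per Myr (/Lmyr);
#' turnover is their sum, net diversification their difference.  Bins with
#' no standing taxa yield missing rates.
#'
#' @param ranges data frame `taxon, fad_age, lad_age` (Ma; `fad_age >=
#'   lad_age`), e.g. from [taxon_age_ranges()].
#' @param bin_width bin width in Myr (> 0), default 0.2.
#' @return data frame `age_lo, age_hi, age_mid, n_range, n_fad, n_lad,
#'   origination, extinction, turnover, net`.
#' @export
binned_rates <- function(ranges, bin_width = 0.2) {
  if (bin_width <= 0) stop("bin_width must be positive")
  lo <- floor(min(ranges$lad_age) / bin_width) * bin_width
  hi <- ceiling(max(ranges$fad_age) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (length(breaks) < 2) breaks <- c(lo, lo + bin_width)
  nb <- length(breaks) - 1L
  out <- data.frame(age_lo = breaks[-length(breaks)], age_hi = breaks[-1])
  out$age_mid <- (out$age_lo + out$age_hi) / 2
  top <- out$age_hi[nb]
  out$n_range <- vapply(seq_len(nb), function(b) {
    hib <- if (b == nb) top + 1e-9 else out$age_hi[b]
    sum(ranges$lad_age < hib & ranges$fad_age >= out$age_lo[b])
  }, numeric(1))
  out$n_fad <- vapply(seq_len(nb), function(b) {
    hib <- if (b == nb) top + 1e-9 else out$age_hi[b]
    sum(ranges$fad_age >= out$age_lo[b] & ranges$fad_age < hib)
  }, numeric(1))
  out$n_lad <- vapply(seq_len(nb), function(b) {
    hib <- if (b == nb) top + 1e-9 else out$age_hi[b]
    sum(ranges$lad_age >= out$age_lo[b] & ranges$lad_age < hib)
  }, numeric(1))
  denom <- out$n_range * bin_width
  out$origination <- ifelse(out$n_range > 0, out$n_fad / denom, NA_real_)
  out$extinction <- ifelse(out$n_range > 0, out$n_lad / denom, NA_real_)
  out$turnover <- out$origination + out$extinction
  out$net <- out$origination - out$extinction
  out
}

#' Taxon age ranges from a calibrated composite
#'
#' @param levels a [cluster_levels()] result.
#' @param ds the [strat_dataset()].
#' @param ages an [fit_age_model()] result (or any vector of level ages).
#' @param group optional group filter.
#' @return data frame `taxon, fad_age, lad_age` excluding pseudo-taxa.
#' @export
taxon_age_ranges <- function(levels, ds, ages, group = NULL) {
  la <- if (inherits(ages, "age_model")) ages$level_ages else ages
  r <- taxon_level_ranges(levels, ds)
  r <- r[!r$pseudo, , drop = FALSE]
  if (!is.null(group)) r <- r[r$group %in% group, , drop = FALSE]
  data.frame(taxon = r$taxon, fad_age = la[r$fad_level],
             lad_age = la[r$lad_level], stringsAsFactors = FALSE)
}

#' Individual-based rarefaction of a bin's occurrences
#'
#' Draws `n` occurrences without replacement from the bin's pooled
#' occurrences `iters` times and reports the mean and percentile interval of
#' the distinct-taxon count.  When `n` exceeds the pool size the estimate is
#' missing (with a warning).
#'
#' @param counts integer vector of occurrence counts per taxon.
#' @param n subsample size.
#' @param iters number of rarefaction draws.
#' @param seed optional integer seed.
#' @param probs interval percentiles.
#' @return list `mean, sd, lo, hi, n, n_occurrences, s_observed`.
#' @export
rarefy_richness <- function(counts, n, iters = 1000, seed = NULL,
                            probs = c(0.025, 0.975)) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (n > total) {
    warning("subsample size ", n, " exceeds pool of ", total, " occurrences")
    return(list(mean = NA_real_, sd = NA_real_, lo = NA_real_, hi = NA_real_,
                n = n, n_occurrences = total, s_observed = length(counts)))
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- rep.int(seq_along(counts), counts)
  s <- vapply(seq_len(iters), function(i)
    length(unique(pool[sample.int(total, n)])), numeric(1))
  q <- stats::quantile(s, probs = probs, names = FALSE)
  list(mean = mean(s), sd = stats::sd(s), lo = q[1], hi = q[2], n = n,
       n_occurrences = total, s_observed = length(counts))
}

# value of a level step-series at arbitrary grid ages: the value of the
# youngest level whose age is >= the grid age; NA outside the level span
series_on_grid <- function(level_ages, values, grid) {
  idx <- findInterval(-grid, -level_ages)
  out <- rep(NA_real_, length(grid))
  ok <- idx >= 1L & grid >= min(level_ages)
  out[ok] <- values[idx[ok]]
  out
}

#' Bootstrap envelopes for richness (and rate) series
#'
#' Propagates age-model uncertainty: for every bootstrap replicate of the
#' level ages the richness series is re-expressed on a common age grid, and
#' pointwise percentile envelopes are returned.
#'
#' @param levels a [cluster_levels()] result.
#' @param ds the [strat_dataset()].
#' @param ages a [bootstrap_age_model()] result (must carry `boot`).
#' @param grid_step age grid step in Myr.
#' @param group optional group filter.
#' @param probs envelope percentiles.
#' @return data frame `age_ma, value, lo, hi`.
#' @export
bootstrap_richness <- function(levels, ds, ages, grid_step = 0.2,
                               group = NULL, probs = c(0.025, 0.975)) {
  if (is.null(ages$boot))
    stop("`ages` must come from bootstrap_age_model()")
  rich <- unbinned_richness(levels, ds, group = group)$richness
  la <- ages$level_ages
  grid <- seq(min(la), max(la), by = grid_step)
  point <- series_on_grid(la, rich, grid)
  reps <- apply(ages$boot, 2, function(col) series_on_grid(col, rich, grid))
  qs <- apply(reps, 1, stats::quantile, probs = probs, na.rm = TRUE)
  data.frame(age_ma = grid, value = point,
             lo = pmin(qs[1, ], point), hi = pmax(qs[2, ], point))
}

#' @rdname bootstrap_richness
#' @param bin_width rate bin width in Myr.
#' @param what which rate column to envelope.
#' @export
bootstrap_rates <- function(levels, ds, ages, bin_width = 0.2, group = NULL,
                            what = c("origination", "extinction", "turnover",
                                     "net"),
                            probs = c(0.025, 0.975)) {
  what <- match.arg(what)
  if (is.null(ages$boot))
    stop("`ages` must come from bootstrap_age_model()")
  point <- binned_rates(taxon_age_ranges(levels, ds, ages, group = group),
                        bin_width = bin_width)
  r <- taxon_level_ranges(levels, ds)
  r <- r[!r$pseudo, , drop = FALSE]
  if (!is.null(group)) r <- r[r$group %in% group, , drop = FALSE]
  mids <- point$age_mid
  reps <- apply(ages$boot, 2, function(col) {
    rr <- binned_rates(data.frame(taxon = r$taxon,
                                  fad_age = col[r$fad_level],
                                  lad_age = col[r$lad_level]),
                       bin_width = bin_width)
    rr[[what]][match(floor(mids / bin_width), floor(rr$age_mid / bin_width))]
  })
  qs <- apply(reps, 1, stats::quantile, probs = probs, na.rm = TRUE)
  out <- point[, c("age_mid", what)]
  names(out) <- c("age_ma", "value")
  out$lo <- pmin(qs[1, ], out$value)
  out$hi <- pmax(qs[2, ], out$value)
  out
}

#' Max-min normalisation to [0, 1]
#'
#' @param x numeric vector with at least two distinct values.
#' @return `(x - min) / (max - min)`.
#' @export
minmax_normalize <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) stop("cannot normalise a constant series")
  (x - rng[1]) / diff(rng)
}
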