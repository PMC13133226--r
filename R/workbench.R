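#' Run the full correlation-to-diversity pipeline
#'
#' Executes the analysis end to end: (1) validation, optional event-count
#' screening and the connectivity check; (2) construction of the weighted
#' virtual marker section; (3) the evolutionary search, optionally as
#' independent seeded restarts merged through [init_from_sequences()];
#' (4) level clustering and spline age calibration with bootstrap; then
#' richness, proportional rates, optional rarefaction, and proxy
#' correlations.  The pipeline is a pure function of its inputs and
#' configuration: identical inputs give identical outputs.
#'
#' @param sections a [strat_dataset()] or path to a section CSV.
#' @param markers marker data frame (`kind,name,age_ma`) or path, or `NULL`
#'   to skip calibration and everything downstream of it.
#' @param proxies named list of proxy data frames (`age_ma,value`) or paths.
#' @param config an [ea_config()].
#' @param min_events screen sections with [filter_sections()] when > 0.
#' @param marker_weight weight of the virtual marker section.
#' @param restarts number of independent seeded searches merged into a
#'   final run (1 = single run).
#' @param bin_width rate bin width (Myr).
#' @param grid_step common age grid step (Myr) for series alignment.
#' @param n_boot bootstrap replicates for the age model envelope.
#' @param cor_boot bootstrap iterations for correlation intervals.
#' @param rarefy_n optional vector of rarefaction subsample sizes.
#' @param detrend also correlate linearly detrended series?
#' @param group optional group filter for the richness series used in
#'   correlations.
#' @param out_dir optional directory; when given, composite, series and
#'   manifest files are written there.
#' @return An object of class `conop_pipeline` with elements `manifest`,
#'   `fit`, `levels`, `age_model`, `richness`, `ratio`, `rates`,
#'   `rarefaction`, `correlations` and `vif`.
#' @export
run_pipeline <- function(sections, markers = NULL, proxies = NULL,
                         config = ea_config(), min_events = 0,
                         marker_weight = 10, restarts = 1, bin_width = 0.2,
                         grid_step = 0.2, n_boot = 1000, cor_boot = 10000,
                         rarefy_n = NULL, detrend = TRUE, group = NULL,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  ds <- stage("validate", {
    d <- if (is.character(sections)) read_sections(sections) else sections
    stopifnot(inherits(d, "strat_dataset"))
    if (min_events > 0) d <- filter_sections(d, min_events)
    conn <- section_connectivity(d)
    if (!conn$correlatable)
      stop("sections form ", conn$n_components, " components: ",
           paste(vapply(conn$components, paste, character(1),
                        collapse = "+"), collapse = " | "))
    d
  })

  mk <- stage("markers", {
    if (is.null(markers)) NULL
    else if (is.character(markers)) read_markers(markers)
    else markers
  })
  ds_run <- stage("markers", {
    if (is.null(mk)) ds
    else {
      vs <- marker_virtual_section(mk, weight = marker_weight)
      if (is.null(vs$section)) ds
      else {
        taxa <- ds$taxa
        if (length(vs$pseudo_taxa))
          taxa <- rbind(taxa, data.frame(taxon = vs$pseudo_taxa,
                                         genus = NA_character_,
                                         group = "other", pseudo = TRUE))
        secs <- c(ds$sections, list(vs$section))
        strat_dataset(taxa, secs)
      }
    }
  })

  fit <- stage("optimize", {
    if (restarts > 1) {
      seqs <- lapply(seq_len(restarts) - 1L, function(k) {
        cfg <- config; cfg$seed <- config$seed + k
        conop(ds_run, cfg)$sequence
      })
      cfg <- config; cfg$seed <- config$seed + restarts
      conop(ds_run, cfg, init = seqs)
    } else conop(ds_run, config)
  })

  levels <- stage("calibrate", cluster_levels(fit$sequence, ds_run))
  am <- NULL
  if (!is.null(mk))
    am <- stage("calibrate",
                bootstrap_age_model(levels, mk, ds_run, n_boot = n_boot,
                                    seed = config$seed))

  richness <- stage("diversity",
                    unbinned_richness(levels, ds_run, group = group,
                                      ages = am))
  ratio <- stage("diversity", species_genus_ratio(levels, ds_run,
                                                  group = group, ages = am))
  rates <- rar <- NULL
  if (!is.null(am)) {
    rates <- stage("diversity",
                   binned_rates(taxon_age_ranges(levels, ds_run, am,
                                                 group = group),
                                bin_width = bin_width))
    if (!is.null(rarefy_n))
      rar <- stage("diversity",
                   rarefaction_by_bin(fit$sequence, ds_run, levels, am,
                                      n_sizes = rarefy_n,
                                      bin_width = bin_width,
                                      seed = config$seed))
  }

  correlations <- vif <- NULL
  if (!is.null(proxies) && !is.null(am)) {
    correlations <- stage("correlate", {
      px <- lapply(proxies, function(p)
        if (is.character(p)) read_proxy(p) else p)
      rich_series <- data.frame(age_ma = richness$age_ma,
                                value = richness$richness)
      if (length(px) >= 2) {
        grids <- lapply(px, function(p)
          align_series(rich_series, p, grid_step = grid_step))
        common <- Reduce(intersect, lapply(grids, `[[`, "age_ma"))
        mat <- sapply(seq_along(px), function(i)
          grids[[i]]$y[match(common, grids[[i]]$age_ma)])
        colnames(mat) <- names(px)
        vif <- vif_screen(mat)
      }
      do.call(rbind, lapply(names(px), function(nm) {
        al <- align_series(rich_series, px[[nm]], grid_step = grid_step)
        raw <- spearman_cor(al$x, al$y, n_boot = cor_boot,
                            seed = config$seed)
        rows <- data.frame(proxy = nm, detrended = FALSE, rho = raw$rho,
                           p = raw$p, p_floored = raw$p_floored,
                           ci_lo = raw$ci_lo, ci_hi = raw$ci_hi, n = raw$n)
        if (detrend) {
          xd <- detrend_linear(data.frame(age_ma = al$age_ma, value = al$x))
          yd <- detrend_linear(data.frame(age_ma = al$age_ma, value = al$y))
          det <- spearman_cor(xd$value, yd$value, n_boot = cor_boot,
                              seed = config$seed)
          rows <- rbind(rows,
                        data.frame(proxy = nm, detrended = TRUE,
                                   rho = det$rho, p = det$p,
                                   p_floored = det$p_floored,
                                   ci_lo = det$ci_lo, ci_hi = det$ci_hi,
                                   n = det$n))
        }
        rows
      }))
    })
  }

  manifest <- list(
    package = as.character(utils::packageVersion("conopr")),
    seed = config$seed,
    config = unclass(config),
    config_hash = config_hash(config),
    n_taxa = sum(!ds_run$taxa$pseudo),
    n_sections = length(ds$sections),
    penalty = fit$penalty,
    trials_done = fit$trials_done,
    n_levels = levels$n_levels,
    span_myr = if (!is.null(am)) max(am$level_ages) - min(am$level_ages)
               else NA_real_,
    resolution_kyr = if (!is.null(am))
      imputed_resolution(max(am$level_ages) - min(am$level_ages),
                         levels$n_levels) else NA_real_)

  out <- structure(list(manifest = manifest, fit = fit, levels = levels,
                        age_model = am, richness = richness, ratio = ratio,
                        rates = rates, rarefaction = rar,
                        correlations = correlations, vif = vif),
                   class = "conop_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, ds_run)
  out
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(x, out_dir, ds) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  extra <- data.frame(level = x$levels$assign)
  if (!is.null(x$age_model)) {
    extra$age_ma <- x$age_model$level_ages[x$levels$assign]
    extra$age_lo <- x$age_model$envelope$lo[x$levels$assign]
    extra$age_hi <- x$age_model$envelope$hi[x$levels$assign]
  }
  write_composite(x$fit$sequence, file.path(out_dir, "composite.csv"),
                  extra = extra)
  utils::write.csv(x$richness, file.path(out_dir, "richness.csv"),
                   row.names = FALSE)
  if (!is.null(x$rates))
    utils::write.csv(x$rates, file.path(out_dir, "rates.csv"),
                     row.names = FALSE)
  if (!is.null(x$correlations))
    utils::write.csv(x$correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  utils::write.csv(x$fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(x$manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' @export
print.conop_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("CONOP pipeline run\n")
  cat("  penalty:    ", format(m$penalty), "\n", sep = "")
  cat("  levels:     ", m$n_levels, "\n", sep = "")
  if (!is.na(m$span_myr))
    cat("  span:       ", format(m$span_myr, digits = 4), " Myr (",
        format(m$resolution_kyr, digits = 4), " Kyr/level)\n", sep = "")
  if (!is.null(x$correlations)) {
    cat("  correlations:\n")
    print(x$correlations, digits = 3)
  }
  invisible(x)
}

#' Map occurrences to ages through a fitted composite
#'
#' Each section gets a monotone height-to-age map from the placed heights
#' of its events (the penalty's placement witness) against their composite
#' level ages; occurrence ages are interpolated through it.
#'
#' @param seq the fitted [composite_sequence()].
#' @param ds the [strat_dataset()].
#' @param levels a [cluster_levels()] result.
#' @param ages an [fit_age_model()] result.
#' @return data frame `section_id, taxon, level_index, age_ma`.
#' @export
occurrence_ages <- function(seq, ds, levels, ages) {
  ev <- levels$events
  ev_age <- ages$level_ages[ev$level]
  key <- paste(ev$taxon, ev$kind)
  out <- lapply(ds$sections, function(s) {
    pl <- section_penalty(seq, ds, s$section_id)
    pk <- paste(pl$events$taxon, pl$events$kind)
    pe_age <- ev_age[match(pk, key)]
    h2a <- function(h) stats::approx(pl$events$placed_height, pe_age,
                                     xout = h, ties = mean, rule = 2)$y
    occ <- s$occurrences
    hh <- s$levels$height[match(occ$level_index, s$levels$level_index)]
    data.frame(section_id = s$section_id, taxon = occ$taxon,
               level_index = occ$level_index, age_ma = h2a(hh),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rarefied richness per time bin
#'
#' Pools occurrence ages (via [occurrence_ages()]) into bins of `bin_width`
#' Myr and rarefies each bin at the requested subsample sizes.
#'
#' @inheritParams occurrence_ages
#' @param n_sizes rarefaction subsample sizes.
#' @param bin_width pooling window (Myr).
#' @param iters rarefaction iterations per bin.
#' @param seed integer seed.
#' @return data frame `age_mid, n, mean, lo, hi, n_occurrences`.
#' @export
rarefaction_by_bin <- function(seq, ds, levels, ages, n_sizes = c(300, 500),
                               bin_width = 0.2, iters = 1000, seed = 1) {
  occ <- occurrence_ages(seq, ds, levels, ages)
  occ <- occ[!ds$taxa$pseudo[match(occ$taxon, ds$taxa$taxon)], , drop = FALSE]
  lo <- floor(min(occ$age_ma) / bin_width) * bin_width
  occ$bin <- floor((occ$age_ma - lo) / bin_width)
  set.seed(seed)
  out <- list()
  for (b in sort(unique(occ$bin))) {
    counts <- table(occ$taxon[occ$bin == b])
    for (n in n_sizes) {
      r <- if (n > sum(counts)) {
        list(mean = NA_real_, lo = NA_real_, hi = NA_real_,
             n_occurrences = sum(counts))
      } else rarefy_richness(as.integer(counts), n, iters = iters)
      out[[length(out) + 1L]] <-
        data.frame(age_mid = lo + (b + 0.5) * bin_width, n = n,
                   mean = r$mean, lo = r$lo, hi = r$hi,
                   n_occurrences = r$n_occurrences)
    }
  }
  do.call(rbind, out)
}
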