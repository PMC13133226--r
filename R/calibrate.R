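#' Cluster a composite sequence into discrete temporal levels
#'
#' Adjacent events whose order the data do not resolve -- swapping them is
#' feasible and changes the total penalty by exactly zero -- are merged into
#' one composite level (transitively along adjacency).  Levels are the unit
#' of the imputed temporal resolution; a taxon's FAD and LAD are never
#' merged.
#'
#' @param seq a feasible [composite_sequence()].
#' @param ds the [strat_dataset()].
#' @param merge `"zero-swap"` (default) or `"none"` (one level per event).
#' @return An object of class `composite_levels`: `events` (the ordered
#'   event table with a `level` column), `n_levels`, and `assign` (level id
#'   per composite rank, oldest level = 1).
#' @export
cluster_levels <- function(seq, ds, merge = c("zero-swap", "none")) {
  merge <- match.arg(merge)
  es <- event_system(ds)
  check_events_match(seq, es)
  feas <- order_feasible(seq$order, es)
  if (!isTRUE(feas)) stop("infeasible sequence: ", attr(feas, "violation"))
  ord <- seq$order
  n <- length(ord)
  boundary <- rep(TRUE, n - 1L)
  if (merge == "zero-swap") {
    pos <- integer(es$n); pos[ord] <- seq_len(n)
    for (i in seq_len(n - 1L)) {
      a <- ord[i]; b <- ord[i + 1L]
      if (es$precede[a, b]) next
      secs <- unique(unlist(es$taxon_sections[unique(es$ev_taxon[c(a, b)])]))
      if (!length(secs)) { boundary[i] <- FALSE; next }
      pos2 <- pos; pos2[a] <- i + 1L; pos2[b] <- i
      d <- sum(vapply(es$sections[secs], sec_penalty_raw, numeric(1),
                      pos = pos2)) -
           sum(vapply(es$sections[secs], sec_penalty_raw, numeric(1),
                      pos = pos))
      if (d == 0) boundary[i] <- FALSE
    }
  }
  assign <- cumsum(c(TRUE, boundary))
  events <- seq$events
  events$level <- assign
  structure(list(events = events, n_levels = max(assign), assign = assign),
            class = "composite_levels")
}

#' @export
print.composite_levels <- function(x, ...) {
  cat("<composite_levels> ", nrow(x$events), " events in ", x$n_levels,
      " levels\n", sep = "")
  invisible(x)
}

#' Per-taxon level ranges
#'
#' @param levels a [cluster_levels()] result.
#' @param ds the [strat_dataset()] (for genus/group annotation).
#' @return data frame `taxon, genus, group, pseudo, fad_level, lad_level`.
#' @export
taxon_level_ranges <- function(levels, ds) {
  ev <- levels$events
  fad <- ev[ev$kind == "FAD", ]
  lad <- ev[ev$kind == "LAD", ]
  i <- match(fad$taxon, ds$taxa$taxon)
  out <- data.frame(taxon = fad$taxon,
                    genus = ds$taxa$genus[i], group = ds$taxa$group[i],
                    pseudo = ds$taxa$pseudo[i],
                    fad_level = fad$level,
                    lad_level = lad$level[match(fad$taxon, lad$taxon)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

marker_levels <- function(markers, levels, ds) {
  ev <- levels$events
  lev <- vapply(seq_len(nrow(markers)), function(i) {
    kind <- markers$kind[i]
    if (kind == "chron") {
      hit <- which(ev$taxon == markers$name[i] & ev$kind == "FAD")
    } else {
      hit <- which(ev$taxon == markers$name[i] & ev$kind == kind)
    }
    if (!length(hit)) NA_real_ else as.numeric(ev$level[hit[1]])
  }, numeric(1))
  if (anyNA(lev))
    stop("marker(s) reference events absent from the composite: ",
         paste(markers$name[is.na(lev)], collapse = ", "))
  lev
}

#' Calibrate composite levels to numeric ages
#'
#' Fits a cubic smoothing spline of marker age against composite level rank,
#' choosing the smoothing parameter by leave-one-out cross-validation over
#' `spar_grid`, then projects the fitted curve onto monotone non-increasing
#' ages (isotonic adjustment), since a cross-validated spline is not
#' intrinsically monotone.  Beyond the first and last marker the natural
#' spline extrapolates linearly from the boundary slope; such levels are
#' flagged.
#'
#' @param levels a [cluster_levels()] result.
#' @param markers data frame `kind` (`"FAD"`, `"LAD"` or `"chron"`), `name`
#'   (taxon or chron id) and `age_ma`; must reference events in at least 4
#'   distinct levels.
#' @param ds the [strat_dataset()].
#' @param spar_grid smoothing parameters searched by leave-one-out CV.
#' @param tol tolerance (Myr) beyond which markers out of monotone order
#'   trigger a warning.
#' @return An object of class `age_model`: `level_ages` (Ma per level, non-
#'   increasing), `spar`, `cv` (the CV table), `markers` (with their level
#'   ranks), `extrapolated` flags and `n_levels`.
#' @export
fit_age_model <- function(levels, markers, ds,
                          spar_grid = seq(0.2, 1.4, by = 0.1), tol = 0.5) {
  stopifnot(all(c("kind", "name", "age_ma") %in% names(markers)),
            all(markers$age_ma > 0))
  x <- marker_levels(markers, levels, ds)
  y <- markers$age_ma
  if (length(unique(x)) < 4)
    stop("markers must reference events in at least 4 distinct levels (got ",
         length(unique(x)), ")")
  o <- order(x)
  viol <- which(diff(y[o]) > tol)
  if (length(viol))
    warning("marker(s) out of monotone age order beyond tolerance: ",
            paste(markers$name[o][viol + 1L], collapse = ", "))
  cv <- vapply(spar_grid, function(sp) loo_mse(x, y, sp), numeric(1))
  spar <- spar_grid[which.min(cv)]
  fit <- stats::smooth.spline(x, y, spar = spar)
  k <- levels$n_levels
  pred <- stats::predict(fit, seq_len(k))$y
  ages <- monotone_nonincreasing(pred)
  structure(list(level_ages = ages, spar = spar,
                 cv = data.frame(spar = spar_grid, loo_mse = cv),
                 markers = data.frame(markers, level = x),
                 extrapolated = seq_len(k) < min(x) | seq_len(k) > max(x),
                 n_levels = k),
            class = "age_model")
}

loo_mse <- function(x, y, spar) {
  err <- vapply(seq_along(x), function(i) {
    f <- tryCatch(stats::smooth.spline(x[-i], y[-i], spar = spar),
                  error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    (stats::predict(f, x[i])$y - y[i])^2
  }, numeric(1))
  if (all(is.na(err))) Inf else mean(err, na.rm = TRUE)
}

# isotonic projection onto non-increasing sequences (least squares)
monotone_nonincreasing <- function(y) {
  -stats::isoreg(seq_along(y), -y)$yf
}

#' @export
print.age_model <- function(x, ...) {
  cat("<age_model> ", x$n_levels, " levels, ",
      format(max(x$level_ages), digits = 4), "-",
      format(min(x$level_ages), digits = 4), " Ma, spar = ", x$spar,
      if (!is.null(x$envelope)) paste0(", ", ncol(x$boot), " bootstrap reps"),
      "\n", sep = "")
  invisible(x)
}

#' @export
predict.age_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$level_ages)
  stats::approx(seq_len(object$n_levels), object$level_ages, xout = newdata,
                rule = 2)$y
}

#' Bootstrap uncertainty of the age model
#'
#' Resamples markers with replacement, refits the spline (each replicate
#' re-selects its smoothing by generalised cross-validation, so that
#' smoothing-parameter variability propagates into the envelope) and stores
#' per-level 2.5th/97.5th percentile ages.  Degenerate resamples
#' referencing fewer than 4 distinct levels are redrawn and counted.
#'
#' @inheritParams fit_age_model
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param probs envelope percentiles.
#' @return An `age_model` with additional elements `boot` (levels x
#'   replicates matrix), `envelope` (data frame `lo, hi`, clamped to bracket
#'   the point estimate) and `n_redraws`.
#' @export
bootstrap_age_model <- function(levels, markers, ds, n_boot = 1000,
                                seed = 1, probs = c(0.025, 0.975), ...) {
  am <- fit_age_model(levels, markers, ds, ...)
  x <- am$markers$level
  y <- markers$age_ma
  k <- am$n_levels
  set.seed(seed)
  boot <- matrix(NA_real_, k, n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    for (try in seq_len(100L)) {
      idx <- sample.int(length(x), replace = TRUE)
      if (length(unique(x[idx])) >= 4) break
      redraws <- redraws + 1L
    }
    f <- tryCatch(suppressWarnings(stats::smooth.spline(x[idx], y[idx])),
                  error = function(e)
                    tryCatch(stats::smooth.spline(x[idx], y[idx],
                                                  spar = am$spar),
                             error = function(e2) NULL))
    if (is.null(f)) { boot[, b] <- am$level_ages; next }
    boot[, b] <- monotone_nonincreasing(stats::predict(f, seq_len(k))$y)
  }
  qs <- apply(boot, 1, stats::quantile, probs = probs)
  am$boot <- boot
  am$envelope <- data.frame(lo = pmin(qs[1, ], am$level_ages),
                            hi = pmax(qs[2, ], am$level_ages))
  am$n_redraws <- redraws
  if (redraws > 0) message(redraws, " degenerate bootstrap resample(s) redrawn")
  am
}

#' Imputed temporal resolution of a composite
#'
#' The time span divided by the number of discrete composite levels, in Kyr
#' per level: e.g. a 28-Myr span resolved into 962 levels gives about
#' 29.11 Kyr.
#'
#' @param span_myr time span in Myr (> 0).
#' @param n_levels number of composite levels (>= 1).
#' @return Kyr per level.
#' @export
imputed_resolution <- function(span_myr, n_levels) {
  stopifnot(span_myr > 0)
  if (n_levels < 1) stop("n_levels must be at least 1")
  span_myr * 1000 / n_levels
}

#' Read a marker file
#'
#' CSV dialect `kind,name,age_ma` with `kind` one of `FAD`, `LAD`, `chron`.
#'
#' @param path CSV path.
#' @return data frame of markers.
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "name", "age_ma") %in% names(df)))
  if (!all(df$kind %in% c("FAD", "LAD", "chron")))
    stop("marker kind must be FAD, LAD or chron")
  df
}

#' Build a weighted virtual section from dated markers
#'
#' Index taxa with both a FAD and a LAD marker enter as ranges (occurrences
#' at both dated levels); chron boundaries enter as point-range pseudo-taxa
#' (FAD and LAD at the same level).  A taxon with only one dated event is
#' used for age calibration only and is skipped here, because a single-level
#' occurrence would wrongly pin its other datum to that level.  The section
#' is heavily weighted so the search respects the marker order.
#'
#' @param markers data frame `kind, name, age_ma`.
#' @param weight section weight (default 10).
#' @param section_id id of the virtual section.
#' @return list with `section` (a section list, or `NULL` if fewer than two
#'   usable entries), `pseudo_taxa` (character) and `skipped` (taxa with an
#'   unpaired marker).
#' @export
marker_virtual_section <- function(markers, weight = 10,
                                   section_id = "virtual_markers") {
  rows <- list(); skipped <- character(0); pseudo <- character(0)
  for (nm in unique(markers$name[markers$kind != "chron"])) {
    fad <- markers$age_ma[markers$name == nm & markers$kind == "FAD"]
    lad <- markers$age_ma[markers$name == nm & markers$kind == "LAD"]
    if (length(fad) == 1 && length(lad) == 1) {
      rows[[length(rows) + 1L]] <- data.frame(taxon = nm,
                                              age = c(fad, lad))
    } else skipped <- c(skipped, nm)
  }
  for (i in which(markers$kind == "chron")) {
    nm <- markers$name[i]
    rows[[length(rows) + 1L]] <- data.frame(taxon = nm,
                                            age = markers$age_ma[i])
    pseudo <- c(pseudo, nm)
  }
  if (length(rows) < 2)
    return(list(section = NULL, pseudo_taxa = pseudo, skipped = skipped))
  occ <- do.call(rbind, rows)
  ages <- sort(unique(occ$age), decreasing = TRUE)
  levels <- data.frame(level_index = seq_along(ages),
                       height = max(ages) - ages)
  occ$level_index <- match(occ$age, ages)
  section <- list(section_id = section_id, levels = levels,
                  occurrences = unique(occ[, c("taxon", "level_index")]),
                  weight = weight)
  list(section = section, pseudo_taxa = pseudo, skipped = skipped)
}
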