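#' Stratigraphic occurrence datasets
#'
#' A `strat_dataset` holds a collection of measured sections, each an ordered
#' list of levels (heights strictly increasing upward, i.e. younger) with
#' taxon occurrence records, plus a taxon table.  Local first- and
#' last-appearance datums (FAD/LAD) are derived per taxon per section as the
#' lowest and highest occupied level.
#'
#' @param taxa data frame with columns `taxon` and optionally `genus`,
#'   `group` (one of `"PF"`, `"LBF"`, `"SBF"`, `"other"`) and `pseudo`
#'   (logical; marker pseudo-taxa that are not biological species).
#' @param sections list of sections, each a list with elements `section_id`,
#'   `levels` (data frame `level_index`, `height`), `occurrences` (data frame
#'   `taxon`, `level_index`) and `weight` (positive scalar, default 1).
#' @return An object of class `strat_dataset`.
#' @seealso [read_sections()], [filter_sections()], [section_connectivity()],
#'   [rank_sections()]
#' @export
strat_dataset <- function(taxa, sections) {
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  stopifnot("taxon" %in% names(taxa))
  taxa$taxon <- as.character(taxa$taxon)
  if (is.null(taxa$genus)) taxa$genus <- NA_character_
  if (is.null(taxa$group)) taxa$group <- "other"
  taxa$group[is.na(taxa$group) | !taxa$group %in% c("PF", "LBF", "SBF")] <- "other"
  if (is.null(taxa$pseudo)) taxa$pseudo <- FALSE
  names(sections) <- vapply(sections, function(s) as.character(s$section_id),
                            character(1))
  sections <- lapply(sections, function(s) {
    s$levels <- as.data.frame(s$levels)
    s$occurrences <- unique(as.data.frame(s$occurrences))
    if (is.null(s$weight)) s$weight <- 1
    s
  })
  ds <- structure(list(taxa = taxa, sections = sections),
                  class = "strat_dataset")
  validate_strat_dataset(ds)
  ds
}

validate_strat_dataset <- function(ds) {
  if (anyDuplicated(ds$taxa$taxon))
    stop("duplicate taxon ids: ",
         paste(unique(ds$taxa$taxon[duplicated(ds$taxa$taxon)]), collapse = ", "))
  if (anyDuplicated(names(ds$sections)))
    stop("duplicate section ids")
  occ_taxa <- unique(unlist(lapply(ds$sections, function(s) s$occurrences$taxon)))
  orphans <- setdiff(ds$taxa$taxon, occ_taxa)
  if (length(orphans))
    stop("taxa with zero occurrences: ", paste(orphans, collapse = ", "))
  unknown <- setdiff(occ_taxa, ds$taxa$taxon)
  if (length(unknown))
    stop("occurrences of unlisted taxa: ", paste(unknown, collapse = ", "))
  for (s in ds$sections) {
    h <- s$levels$height[order(s$levels$level_index)]
    if (any(diff(h) <= 0))
      stop("section '", s$section_id,
           "': heights must increase strictly with level_index")
    if (!all(s$occurrences$level_index %in% s$levels$level_index))
      stop("section '", s$section_id, "': occurrence at unknown level")
    if (!is.numeric(s$weight) || length(s$weight) != 1 || s$weight <= 0)
      stop("section '", s$section_id, "': weight must be a positive scalar")
  }
  invisible(ds)
}

#' Read a section occurrence table
#'
#' Reads the CSV dialect `section_id,level_index,height,taxon[,genus,group,
#' weight]`, one row per occurrence.  Duplicate occurrence rows are collapsed
#' with a warning; heights must increase strictly with `level_index` within a
#' section.
#'
#' @param path path to a CSV file.
#' @return A [strat_dataset()].
#' @export
read_sections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("section_id", "level_index", "height", "taxon")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("section file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(df$section_id) | is.na(df$taxon) |
                 is.na(suppressWarnings(as.numeric(df$level_index))) |
                 is.na(suppressWarnings(as.numeric(df$height))))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  df$level_index <- as.integer(df$level_index)
  df$height <- as.numeric(df$height)
  strat_dataset_from_table(df)
}

strat_dataset_from_table <- function(df) {
  keep <- c("section_id", "level_index", "height", "taxon")
  ndup <- sum(duplicated(df[, c("section_id", "level_index", "taxon")]))
  if (ndup > 0)
    warning(ndup, " duplicate occurrence row(s) collapsed")
  taxa <- unique(data.frame(
    taxon = df$taxon,
    genus = if (is.null(df$genus)) NA_character_ else df$genus,
    group = if (is.null(df$group)) "other" else df$group,
    stringsAsFactors = FALSE))
  taxa <- taxa[!duplicated(taxa$taxon), , drop = FALSE]
  rownames(taxa) <- NULL
  sections <- lapply(split(df, df$section_id), function(sd) {
    levels <- unique(sd[, c("level_index", "height")])
    levels <- levels[order(levels$level_index), , drop = FALSE]
    if (anyDuplicated(levels$level_index))
      stop("section '", sd$section_id[1],
           "': level_index mapped to conflicting heights")
    rownames(levels) <- NULL
    w <- if (!is.null(sd$weight)) sd$weight[1] else 1
    list(section_id = sd$section_id[1],
         levels = levels,
         occurrences = unique(sd[, c("taxon", "level_index")]),
         weight = as.numeric(w))
  })
  strat_dataset(taxa, sections)
}

#' Write a dataset back to the section CSV dialect
#'
#' @param ds a [strat_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sections <- function(ds, path) {
  rows <- do.call(rbind, lapply(ds$sections, function(s) {
    occ <- s$occurrences
    h <- s$levels$height[match(occ$level_index, s$levels$level_index)]
    data.frame(section_id = s$section_id, level_index = occ$level_index,
               height = h, taxon = occ$taxon,
               genus = ds$taxa$genus[match(occ$taxon, ds$taxa$taxon)],
               group = ds$taxa$group[match(occ$taxon, ds$taxa$taxon)],
               weight = s$weight, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Local taxon ranges within each section
#'
#' The local first-appearance level of a taxon is the lowest level at which
#' it occurs, the local last appearance the highest.
#'
#' @param ds a [strat_dataset()].
#' @return data frame `section_id, taxon, fad_level, lad_level, fad_height,
#'   lad_height`.
#' @export
local_ranges <- function(ds) {
  out <- do.call(rbind, lapply(ds$sections, function(s) {
    sp <- split(s$occurrences$level_index, s$occurrences$taxon)
    fad <- vapply(sp, min, numeric(1))
    lad <- vapply(sp, max, numeric(1))
    data.frame(section_id = s$section_id, taxon = names(sp),
               fad_level = as.integer(fad), lad_level = as.integer(lad),
               fad_height = s$levels$height[match(fad, s$levels$level_index)],
               lad_height = s$levels$height[match(lad, s$levels$level_index)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Screen sections by biostratigraphic event count
#'
#' Retains sections whose number of local FAD+LAD datums (two per locally
#' observed taxon) strictly exceeds `min_events`; taxa left without any
#' section are dropped.  The default threshold of 30 events mirrors common
#' practice of excluding data-poor sections to limit sampling bias.
#'
#' @param ds a [strat_dataset()].
#' @param min_events nonnegative integer; keep sections with more than this
#'   many local datums.
#' @return The filtered [strat_dataset()].
#' @export
filter_sections <- function(ds, min_events = 30) {
  stopifnot(min_events >= 0)
  keep <- vapply(ds$sections, function(s)
    2L * length(unique(s$occurrences$taxon)) > min_events, logical(1))
  if (!any(keep))
    stop("no section has more than ", min_events, " biostratigraphic events")
  sections <- ds$sections[keep]
  left <- unique(unlist(lapply(sections, function(s) s$occurrences$taxon)))
  taxa <- ds$taxa[ds$taxa$taxon %in% left, , drop = FALSE]
  rownames(taxa) <- NULL
  strat_dataset(taxa, sections)
}

#' Section connectivity through shared taxa
#'
#' Builds the graph whose nodes are sections, with an edge wherever two
#' sections share at least one taxon, and reports its connected components.
#' A dataset is correlatable into a single composite only when this graph
#' has one component.
#'
#' @param ds a [strat_dataset()].
#' @return list with `n_components`, `components` (list of section-id
#'   vectors) and `correlatable` (logical).
#' @export
section_connectivity <- function(ds) {
  ids <- names(ds$sections)
  occ <- lapply(ds$sections, function(s) unique(s$occurrences$taxon))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(ids) > 1) {
    edges <- list()
    for (i in seq_len(length(ids) - 1))
      for (j in seq(i + 1, length(ids)))
        if (length(intersect(occ[[i]], occ[[j]])) > 0)
          edges[[length(edges) + 1L]] <- c(i, j)
    if (length(edges))
      g <- igraph::add_edges(g, unlist(edges))
  }
  comp <- igraph::components(g)
  components <- split(ids, comp$membership)
  names(components) <- NULL
  list(n_components = comp$no, components = components,
       correlatable = comp$no == 1L)
}

#' Rank sections by shared-taxon occurrence weight
#'
#' Scores each section by the summed dataset-wide occurrence counts of its
#' taxa that also occur in at least one other section, so that densely
#' sampled, well-connected sections rank first.  The top-ranked section
#' seeds composite initialisation.
#'
#' @param ds a [strat_dataset()].
#' @return data frame `section_id, score`, sorted by decreasing score with
#'   ties broken by section id.
#' @export
rank_sections <- function(ds) {
  stopifnot(length(ds$sections) >= 1)
  occ_all <- do.call(rbind, lapply(ds$sections, function(s)
    data.frame(section_id = s$section_id, taxon = unique(s$occurrences$taxon),
               n_occ = as.vector(table(s$occurrences$taxon)[unique(s$occurrences$taxon)]),
               stringsAsFactors = FALSE)))
  total_occ <- tapply(occ_all$n_occ, occ_all$taxon, sum)
  n_sec <- tapply(occ_all$section_id, occ_all$taxon, function(x) length(unique(x)))
  shared <- names(n_sec)[n_sec >= 2]
  score <- vapply(ds$sections, function(s) {
    tx <- intersect(unique(s$occurrences$taxon), shared)
    sum(total_occ[tx])
  }, numeric(1))
  out <- data.frame(section_id = names(ds$sections), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$section_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean independent bioevents per section
#'
#' An event (local FAD or LAD) is independent when its level hosts
#' occurrences of no other taxon; the mean count across sections measures
#' the temporal resolution the data can support.
#'
#' @param ds a [strat_dataset()].
#' @return mean number of independent datums per section.
#' @export
independent_event_resolution <- function(ds) {
  stopifnot(length(ds$sections) >= 1)
  per_sec <- vapply(ds$sections, function(s) {
    occ <- s$occurrences
    lev_taxa <- tapply(occ$taxon, occ$level_index,
                       function(x) length(unique(x)))
    sp <- split(occ$level_index, occ$taxon)
    n <- 0L
    for (lv in sp) {
      if (lev_taxa[as.character(min(lv))] == 1L) n <- n + 1L
      if (lev_taxa[as.character(max(lv))] == 1L) n <- n + 1L
    }
    as.numeric(n)
  }, numeric(1))
  mean(per_sec)
}

#' Summarise a dataset as a list suitable for JSON output
#'
#' @param ds a [strat_dataset()].
#' @return list of counts, connectivity and section ranking.
#' @export
dataset_summary <- function(ds) {
  conn <- section_connectivity(ds)
  list(n_taxa = sum(!ds$taxa$pseudo),
       n_pseudo_taxa = sum(ds$taxa$pseudo),
       n_events = 2L * nrow(ds$taxa),
       n_sections = length(ds$sections),
       n_occurrences = sum(vapply(ds$sections,
                                  function(s) nrow(s$occurrences), numeric(1))),
       n_components = conn$n_components,
       correlatable = conn$correlatable,
       independent_events_per_section = independent_event_resolution(ds),
       ranking = rank_sections(ds))
}

#' @export
print.strat_dataset <- function(x, ...) {
  cat("<strat_dataset> ", sum(!x$taxa$pseudo), " taxa (",
      2L * nrow(x$taxa), " events), ", length(x$sections), " sections\n",
      sep = "")
  invisible(x)
}

#' @export
summary.strat_dataset <- function(object, ...) {
  s <- dataset_summary(object)
  cat("Stratigraphic dataset\n")
  cat("  taxa:        ", s$n_taxa,
      if (s$n_pseudo_taxa) paste0(" (+", s$n_pseudo_taxa, " marker pseudo-taxa)"),
      "\n", sep = "")
  cat("  sections:    ", s$n_sections, "\n", sep = "")
  cat("  occurrences: ", s$n_occurrences, "\n", sep = "")
  cat("  components:  ", s$n_components,
      if (s$correlatable) " (correlatable)" else " (NOT correlatable)",
      "\n", sep = "")
  cat("  independent events/section: ",
      round(s$independent_events_per_section, 2), "\n", sep = "")
  invisible(s)
}
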