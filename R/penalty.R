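# Event bookkeeping shared by the penalty and search code.
#
# Events are numbered 1..2T: taxon t owns FAD 2t-1 and LAD 2t.  `precede` is
# the hard-constraint matrix: precede[i, j] means event i must come before
# event j in any feasible composite.  Two families of constraints exist:
# each taxon's FAD before its own LAD, and for every section, FAD_A before
# LAD_B whenever taxon A's local first appearance lies at or below taxon B's
# local last appearance (observed coexistence / superposition).  All edges
# run from the FAD side to the LAD side, so the constraint graph is bipartite
# and acyclic: a feasible order always exists.
event_system <- function(ds) {
  taxa <- ds$taxa$taxon
  tt <- length(taxa)
  n <- 2L * tt
  ev_taxon <- rep(seq_len(tt), each = 2L)
  ev_kind <- rep(c("FAD", "LAD"), times = tt)
  fad_of <- seq(1L, n, by = 2L)
  lad_of <- seq(2L, n, by = 2L)
  precede <- matrix(FALSE, n, n)
  precede[cbind(fad_of, lad_of)] <- TRUE

  lr <- local_ranges(ds)
  lr$tx <- match(lr$taxon, taxa)
  sec_ids <- names(ds$sections)
  sections <- vector("list", length(sec_ids))
  for (si in seq_along(sec_ids)) {
    s <- ds$sections[[si]]
    r <- lr[lr$section_id == s$section_id, , drop = FALSE]
    # coexistence/superposition pairs: FAD_A must precede LAD_B when
    # A's local FAD level <= B's local LAD level (A != B)
    if (nrow(r) > 1) {
      m <- outer(r$fad_level, r$lad_level, "<=")
      diag(m) <- FALSE
      idx <- which(m, arr.ind = TRUE)
      if (nrow(idx))
        precede[cbind(fad_of[r$tx[idx[, 1]]], lad_of[r$tx[idx[, 2]]])] <- TRUE
    }
    ev <- c(fad_of[r$tx], lad_of[r$tx])
    obs <- c(r$fad_height, r$lad_height)
    isfad <- rep(c(TRUE, FALSE), each = nrow(r))
    sections[[si]] <- list(section_id = s$section_id, events = ev, obs = obs,
                           isfad = isfad, grid = sort(s$levels$height),
                           weight = s$weight, taxa = r$tx)
  }
  taxon_sections <- lapply(seq_len(tt), function(t)
    which(vapply(sections, function(sc) t %in% sc$taxa, logical(1))))
  list(taxa = taxa, n = n, ev_taxon = ev_taxon, ev_kind = ev_kind,
       fad_of = fad_of, lad_of = lad_of, precede = precede,
       sections = sections, taxon_sections = taxon_sections)
}

event_label <- function(es, ev) paste0(es$ev_kind[ev], " ", es$taxa[es$ev_taxon[ev]])

#' Composite event sequences
#'
#' A composite sequence is a total order over all taxa's FAD and LAD events
#' (position 1 = oldest).  Constructed either from an explicit event table or
#' internally by the optimiser.
#'
#' @param events data frame with columns `taxon` and `kind` (`"FAD"`/`"LAD"`),
#'   ordered oldest first, containing each taxon's FAD and LAD exactly once.
#' @param ds the [strat_dataset()] the sequence refers to.
#' @return An object of class `composite_seq` with elements `order` (internal
#'   event ids), `events` (the ordered event table) and `penalty` (cached
#'   total penalty or `NA`).
#' @export
composite_sequence <- function(events, ds) {
  es <- event_system(ds)
  tx <- match(events$taxon, es$taxa)
  if (anyNA(tx))
    stop("unknown taxa in event table: ",
         paste(unique(events$taxon[is.na(tx)]), collapse = ", "))
  ev <- ifelse(events$kind == "FAD", es$fad_of[tx], es$lad_of[tx])
  if (length(ev) != es$n || anyDuplicated(ev))
    stop("event table must list each taxon's FAD and LAD exactly once")
  new_composite(as.integer(ev), es)
}

new_composite <- function(order, es, penalty = NA_real_) {
  structure(list(order = order,
                 events = data.frame(
                   rank = seq_along(order),
                   taxon = es$taxa[es$ev_taxon[order]],
                   kind = es$ev_kind[order],
                   stringsAsFactors = FALSE),
                 penalty = penalty),
            class = "composite_seq")
}

#' @export
print.composite_seq <- function(x, ...) {
  cat("<composite_seq> ", length(x$order), " events",
      if (!is.na(x$penalty)) paste0(", penalty ", format(x$penalty)), "\n",
      sep = "")
  invisible(x)
}

#' Read / write a composite sequence CSV
#'
#' The dialect is `rank,taxon,event_kind` plus any extra columns added by
#' calibration (`level`, `age_ma`, ...), which round-trip unchanged.
#'
#' @param path CSV path.
#' @param ds the [strat_dataset()] the sequence refers to.
#' @return [read_composite()]: a `composite_seq`; [write_composite()]: the
#'   path, invisibly.
#' @export
read_composite <- function(path, ds) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("rank", "taxon", "event_kind") %in% names(df)))
  df <- df[order(df$rank), , drop = FALSE]
  composite_sequence(data.frame(taxon = df$taxon, kind = df$event_kind,
                                stringsAsFactors = FALSE), ds)
}

#' @rdname read_composite
#' @param seq a `composite_seq`.
#' @param extra optional data frame of extra per-event columns (same order).
#' @export
write_composite <- function(seq, path, extra = NULL) {
  df <- data.frame(rank = seq$events$rank, taxon = seq$events$taxon,
                   event_kind = seq$events$kind, stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_events_match <- function(seq, es) {
  if (length(seq$order) != es$n || anyDuplicated(seq$order) ||
      !all(seq$order %in% seq_len(es$n)))
    stop("sequence events do not match the dataset's event set")
}

# fast internal check on a raw order vector
order_feasible <- function(order, es) {
  pos <- integer(es$n)
  pos[order] <- seq_along(order)
  viol <- es$precede & outer(pos, pos, ">")
  if (!any(viol)) return(TRUE)
  ij <- which(viol, arr.ind = TRUE)[1, ]
  structure(FALSE, violation = paste0(event_label(es, ij[1]),
                                      " must precede ",
                                      event_label(es, ij[2])))
}

#' Feasibility of a composite sequence
#'
#' A sequence is feasible when (i) every taxon's FAD precedes its own LAD and
#' (ii) for every section and every ordered taxon pair (A, B) observed there
#' with A's local FAD level at or below B's local LAD level, FAD_A precedes
#' LAD_B.  Rule (ii) preserves all observed coexistences and superpositional
#' relations and guarantees that an extension-only placement exists in every
#' section.
#'
#' @param seq a [composite_sequence()].
#' @param ds the [strat_dataset()].
#' @return `TRUE`, or `FALSE` with attribute `"violation"` describing the
#'   first violated constraint.
#' @export
is_feasible <- function(seq, ds) {
  es <- event_system(ds)
  check_events_match(seq, es)
  order_feasible(seq$order, es)
}

# penalty of one preprocessed section against an order (internal)
sec_penalty_raw <- function(sc, pos) {
  o <- order(pos[sc$events])
  p <- cpp_section_penalty(sc$obs[o], sc$isfad[o], sc$grid)
  if (p < 0) return(NA_real_)
  p * sc$weight
}

#' Section penalty and placement witness
#'
#' Fits the composite order to one section by placing each observed event on
#' the section's level grid: placements must be non-decreasing in composite
#' order, a FAD may only move down (at or below its observed height) and a
#' LAD only up.  The penalty is the minimal summed |placed - observed|
#' height, times the section weight.  Feasibility rule (ii) guarantees a
#' placement exists.
#'
#' @param seq a feasible [composite_sequence()].
#' @param ds the [strat_dataset()].
#' @param section_id id of the section to fit.
#' @return list of class `placement`: `section_id`, `events` (data frame with
#'   observed and placed heights and per-event extension) and
#'   `section_penalty`.
#' @export
section_penalty <- function(seq, ds, section_id) {
  es <- event_system(ds)
  check_events_match(seq, es)
  feas <- order_feasible(seq$order, es)
  if (!isTRUE(feas))
    stop("infeasible sequence: ", attr(feas, "violation"))
  si <- which(vapply(es$sections, function(s) s$section_id == section_id,
                     logical(1)))
  if (!length(si)) stop("unknown section: ", section_id)
  sc <- es$sections[[si]]
  pos <- integer(es$n)
  pos[seq$order] <- seq_along(seq$order)
  o <- order(pos[sc$events])
  placed <- cpp_section_placement(sc$obs[o], sc$isfad[o], sc$grid)
  if (anyNA(placed))
    stop("no extension-only placement exists for section ", section_id,
         " (feasibility contract violated)")
  ext <- abs(placed - sc$obs[o])
  structure(list(
    section_id = section_id,
    events = data.frame(taxon = es$taxa[es$ev_taxon[sc$events[o]]],
                        kind = ifelse(sc$isfad[o], "FAD", "LAD"),
                        observed_height = sc$obs[o],
                        placed_height = placed,
                        extension = ext, stringsAsFactors = FALSE),
    section_penalty = sum(ext) * sc$weight),
    class = "placement")
}

#' Total range-extension penalty of a composite sequence
#'
#' Sum of [section_penalty()] over all sections; the economy-of-fit measure
#' minimised by the search.
#'
#' @inheritParams section_penalty
#' @return The penalty (nonnegative); also cached on the returned sequence by
#'   the optimiser.
#' @export
total_penalty <- function(seq, ds) {
  es <- event_system(ds)
  check_events_match(seq, es)
  feas <- order_feasible(seq$order, es)
  if (!isTRUE(feas))
    stop("infeasible sequence: ", attr(feas, "violation"))
  pos <- integer(es$n)
  pos[seq$order] <- seq_along(seq$order)
  sum(vapply(es$sections, sec_penalty_raw, numeric(1), pos = pos))
}

#' Incremental penalty change of an edit
#'
#' Computes `total_penalty(offspring) - total_penalty(parent)` by
#' re-evaluating only the sections that contain a taxon whose events were
#' touched by the edit; agreement with full recomputation is exact.  This is
#' the fast per-trial evaluation used by the search.
#'
#' @param seq the parent [composite_sequence()] (feasible).
#' @param offspring the edited sequence, as returned by [mutate_small()],
#'   [mutate_large()] or [recombine()]; positions that differ from the parent
#'   define the affected events.
#' @param ds the [strat_dataset()].
#' @return Signed penalty change, or `NA` (a rejection signal, not an error)
#'   when `offspring` is infeasible.
#' @export
delta_penalty <- function(seq, offspring, ds) {
  es <- event_system(ds)
  check_events_match(seq, es)
  check_events_match(offspring, es)
  if (!isTRUE(order_feasible(offspring$order, es))) return(NA_real_)
  moved <- seq$order != offspring$order
  if (!any(moved)) return(0)
  affected_tx <- unique(es$ev_taxon[unique(c(seq$order[moved],
                                             offspring$order[moved]))])
  secs <- unique(unlist(es$taxon_sections[affected_tx]))
  if (!length(secs)) return(0)
  pos_par <- integer(es$n); pos_par[seq$order] <- seq_along(seq$order)
  pos_off <- integer(es$n); pos_off[offspring$order] <- seq_along(offspring$order)
  sum(vapply(es$sections[secs], sec_penalty_raw, numeric(1), pos = pos_off)) -
    sum(vapply(es$sections[secs], sec_penalty_raw, numeric(1), pos = pos_par))
}

#' Per-taxon composite range positions
#'
#' @param seq a [composite_sequence()].
#' @return data frame `taxon, fad_rank, lad_rank` of 1-based positions in the
#'   composite order; every taxon's FAD rank is below its LAD rank.
#' @export
composite_ranges <- function(seq) {
  ev <- seq$events
  fad <- ev[ev$kind == "FAD", c("taxon", "rank")]
  lad <- ev[ev$kind == "LAD", c("taxon", "rank")]
  out <- data.frame(taxon = fad$taxon, fad_rank = fad$rank,
                    lad_rank = lad$rank[match(fad$taxon, lad$taxon)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$fad_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
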