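#' Search configuration
#'
#' Tuning parameters of the evolutionary search.  The defaults for
#' `population_size`, `start_temperature`, `steps` and `trials` follow the
#' reference settings for desk-scale comparative runs; rates without a
#' published value carry documented package defaults.
#'
#' @param population_size number of composite sequences kept (>= 2).
#' @param start_temperature initial annealing temperature; worsening moves
#'   are Metropolis-accepted with probability `exp(-delta/T)` while `T > 0`.
#' @param steps number of equal annealing stages; temperature decays
#'   linearly from `start_temperature` to exactly 0 at the last stage.
#' @param trials total number of proposals across all stages.
#' @param recombination_rate probability a trial proposes order-based
#'   crossover between two parents instead of a mutation.
#' @param memory_replay_rate probability a trial replays a stored improving
#'   move (type and event pair) instead of drawing a fresh one.
#' @param large_move_rate among mutations, probability of a block move
#'   (datum relocated past intervening datums) versus an adjacent swap.
#' @param seed integer seed; identical seed and config give bit-identical
#'   runs.
#' @param convergence_patience stop when the best-ever penalty has not
#'   improved for this many stages.
#' @param memory_size capacity of the FIFO improving-move memory.
#' @return An object of class `ea_config`.
#' @export
ea_config <- function(population_size = 24, start_temperature = 500,
                      steps = 700, trials = 40000,
                      recombination_rate = 0.2, memory_replay_rate = 0.1,
                      large_move_rate = 0.5, seed = 1,
                      convergence_patience = 100, memory_size = 1024) {
  cfg <- list(population_size = as.integer(population_size),
              start_temperature = start_temperature,
              steps = as.integer(steps), trials = as.integer(trials),
              recombination_rate = recombination_rate,
              memory_replay_rate = memory_replay_rate,
              large_move_rate = large_move_rate,
              seed = as.integer(seed),
              convergence_patience = as.integer(convergence_patience),
              memory_size = as.integer(memory_size))
  stopifnot(cfg$population_size >= 2, cfg$start_temperature >= 0,
            cfg$steps >= 1, cfg$trials >= cfg$steps,
            cfg$recombination_rate >= 0, cfg$recombination_rate <= 1,
            cfg$memory_replay_rate >= 0, cfg$memory_replay_rate <= 1,
            cfg$large_move_rate >= 0, cfg$large_move_rate <= 1,
            cfg$convergence_patience >= 1)
  structure(cfg, class = "ea_config")
}

# ---- internal section-penalty helpers on raw orders ----

# penalty of a (possibly partial) position vector against one section;
# pos[e] == 0 marks an event not yet placed
sec_penalty_partial <- function(sc, pos) {
  pres <- which(pos[sc$events] > 0L)
  if (!length(pres)) return(0)
  o <- pres[order(pos[sc$events[pres]])]
  p <- cpp_section_penalty(sc$obs[o], sc$isfad[o], sc$grid)
  if (p < 0) return(NA_real_)
  p * sc$weight
}

all_secpen <- function(es, pos)
  vapply(es$sections, sec_penalty_raw, numeric(1), pos = pos)

# ---- greedy constructive initialisation ----

# feasible insertion window for event e into a partial order of length k.
# Constraint edges always run FAD -> LAD, so the window is never empty.
insert_window <- function(e, pos, k, es) {
  lo <- 1L; hi <- k + 1L
  preds <- which(es$precede[, e]); preds <- preds[pos[preds] > 0L]
  if (length(preds)) lo <- max(pos[preds]) + 1L
  succs <- which(es$precede[e, ]); succs <- succs[pos[succs] > 0L]
  if (length(succs)) hi <- min(pos[succs])
  c(lo, hi)
}

insert_event_greedy <- function(ord, e, es, sample_ties = FALSE) {
  k <- length(ord)
  pos <- integer(es$n); pos[ord] <- seq_len(k)
  w <- insert_window(e, pos, k, es)
  secs <- es$taxon_sections[[es$ev_taxon[e]]]
  cand <- seq(w[1], w[2])
  pens <- vapply(cand, function(p) {
    ord2 <- append(ord, e, after = p - 1L)
    pos2 <- integer(es$n); pos2[ord2] <- seq_along(ord2)
    sum(vapply(es$sections[secs], sec_penalty_partial, numeric(1),
               pos = pos2))
  }, numeric(1))
  ties <- cand[pens <= min(pens) + 1e-12]
  best_p <- if (sample_ties && length(ties) > 1L)
    ties[sample.int(length(ties), 1L)] else ties[1L]
  append(ord, e, after = best_p - 1L)
}

# one member: anchor taxa of the top-ranked section in their local order,
# then insert the remaining taxa one by one at the cheapest feasible spot;
# sampled tie-breaking diversifies members beyond the insertion order alone
build_member <- function(es, anchor_taxa, other_taxa, sample_ties = FALSE) {
  ord <- integer(0)
  for (t in c(anchor_taxa, other_taxa)) {
    ord <- insert_event_greedy(ord, es$fad_of[t], es, sample_ties)
    ord <- insert_event_greedy(ord, es$lad_of[t], es, sample_ties)
  }
  ord
}

init_members_sections <- function(ds, es, cfg) {
  conn <- section_connectivity(ds)
  if (!conn$correlatable)
    stop("sections are not all connected through co-occurring taxa (",
         conn$n_components, " components): ",
         paste(vapply(conn$components, paste, character(1), collapse = "+"),
               collapse = " | "))
  ranking <- rank_sections(ds)
  top <- ds$sections[[ranking$section_id[1]]]
  lr <- local_ranges(ds)
  lr_top <- lr[lr$section_id == top$section_id, , drop = FALSE]
  anchor <- match(lr_top$taxon[order(lr_top$fad_level, lr_top$lad_level)],
                  es$taxa)
  others <- setdiff(seq_along(es$taxa), anchor)
  # deterministic occurrence-rich-first baseline for the remaining taxa
  occ_tot <- table(factor(unlist(lapply(ds$sections,
                                        function(s) s$occurrences$taxon)),
                          levels = es$taxa))
  others <- others[order(-as.numeric(occ_tot[others]), others)]
  members <- vector("list", cfg$population_size)
  for (m in seq_len(cfg$population_size)) {
    ot <- if (m == 1L) others else others[sample.int(length(others))]
    members[[m]] <- build_member(es, anchor, ot, sample_ties = m > 1L)
  }
  members
}

#' Initialise a population from the sections themselves
#'
#' Each member anchors the taxa of the top-ranked section in their locally
#' observed order, then inserts every remaining taxon's FAD and LAD at the
#' feasible position that greedily minimises the penalty of the sections
#' hosting that taxon.  Members differ through seeded perturbation of the
#' insertion order.
#'
#' @param ds a [strat_dataset()] whose sections form a single connected
#'   component.
#' @param config an [ea_config()].
#' @return list with `members` (list of [composite_sequence()] objects, each
#'   with cached penalty) and `penalties`.
#' @export
init_from_sections <- function(ds, config = ea_config()) {
  es <- event_system(ds)
  set.seed(config$seed)
  members <- init_members_sections(ds, es, config)
  wrap_population(members, es)
}

#' Initialise a population from prior composite sequences
#'
#' Seeds the population from previously computed composites (e.g. the best
#' sequences of earlier runs or of independent restarts), recycling and
#' perturbing them with random feasible mutations to fill
#' `config$population_size`.
#'
#' @param seqs list of [composite_sequence()] objects, all feasible for `ds`.
#' @param ds the [strat_dataset()].
#' @param config an [ea_config()].
#' @return As [init_from_sections()].
#' @export
init_from_sequences <- function(seqs, ds, config = ea_config()) {
  es <- event_system(ds)
  set.seed(config$seed)
  members <- init_members_sequences(seqs, es, config)
  wrap_population(members, es)
}

init_members_sequences <- function(seqs, es, cfg) {
  orders <- lapply(seqs, function(s) {
    check_events_match(s, es)
    feas <- order_feasible(s$order, es)
    if (!isTRUE(feas))
      stop("infeasible input sequence: ", attr(feas, "violation"))
    s$order
  })
  members <- vector("list", cfg$population_size)
  for (m in seq_len(cfg$population_size)) {
    base <- orders[[((m - 1L) %% length(orders)) + 1L]]
    if (m > length(orders)) base <- perturb_order(base, es, n_moves = es$n)
    members[[m]] <- base
  }
  members
}

# random walk of feasible small/large moves (used to diversify clones)
perturb_order <- function(ord, es, n_moves) {
  pos <- integer(es$n); pos[ord] <- seq_along(ord)
  for (k in seq_len(n_moves)) {
    mv <- if (stats::runif(1) < 0.5) propose_small(ord, es)
          else propose_large(ord, es)
    if (!is.null(mv)) { ord <- mv$ord; pos[ord] <- seq_along(ord) }
  }
  ord
}

wrap_population <- function(members, es) {
  pens <- vapply(members, function(o) {
    pos <- integer(es$n); pos[o] <- seq_along(o)
    sum(all_secpen(es, pos))
  }, numeric(1))
  list(members = lapply(seq_along(members), function(i)
         new_composite(members[[i]], es, penalty = pens[i])),
       penalties = pens)
}

# ---- move proposals on raw orders ----

propose_small <- function(ord, es, i = NULL) {
  n <- length(ord)
  if (is.null(i)) i <- sample.int(n - 1L, 1L)
  e1 <- ord[i]; e2 <- ord[i + 1L]
  if (es$precede[e1, e2]) return(NULL)
  ord[c(i, i + 1L)] <- c(e2, e1)
  list(ord = ord, changed = c(i, i + 1L), type = 1L, e1 = e1, e2 = e2)
}

propose_large <- function(ord, es, i = NULL, j = NULL) {
  n <- length(ord)
  if (is.null(i)) { ij <- sample.int(n, 2L); i <- ij[1]; j <- ij[2] }
  if (i == j) return(NULL)
  e <- ord[i]
  if (j > i) {
    block <- ord[(i + 1L):j]
    if (any(es$precede[e, block])) return(NULL)
    ord[i:(j - 1L)] <- block
    ord[j] <- e
    changed <- i:j
  } else {
    block <- ord[j:(i - 1L)]
    if (any(es$precede[block, e])) return(NULL)
    ord[(j + 1L):i] <- block
    ord[j] <- e
    changed <- j:i
  }
  list(ord = ord, changed = changed, type = 2L, e1 = e, e2 = ord[changed[1L]])
}

# order-based crossover: events of a window in parent 1 are reordered to
# their relative order in parent 2.  Because the window's event set is
# preserved and both parents are feasible, the offspring is always feasible.
propose_recomb <- function(ord, pos2, window = NULL) {
  n <- length(ord)
  if (is.null(window)) {
    a <- sample.int(n - 1L, 1L)
    b <- a + sample.int(n - a, 1L)
    window <- c(a, b)
  }
  a <- window[1]; b <- window[2]
  w <- ord[a:b]
  neww <- w[order(pos2[w])]
  changed <- (a:b)[neww != w]
  ord[a:b] <- neww
  list(ord = ord, changed = changed, type = 3L, e1 = NA_integer_,
       e2 = NA_integer_)
}

#' Constrained mutation and recombination operators
#'
#' `mutate_small()` swaps one uniformly chosen pair of neighbouring datums;
#' `mutate_large()` relocates one datum to another position, shifting the
#' intervening block by one place; `recombine()` applies order-based
#' crossover, reordering a contiguous window of `p1` to match the relative
#' order of those events in `p2`.  Offspring violating a stratigraphic
#' constraint are rejected (returned as `NULL`), never repaired.
#'
#' @param seq,p1,p2 feasible [composite_sequence()] objects.
#' @param ds the [strat_dataset()].
#' @param i,j optional explicit positions (1-based); drawn uniformly when
#'   omitted.
#' @param window optional `c(from, to)` window for `recombine`.
#' @return The offspring `composite_seq`, or `NULL` on rejection.
#' @export
mutate_small <- function(seq, ds, i = NULL) {
  es <- event_system(ds)
  mv <- propose_small(seq$order, es, i = i)
  if (is.null(mv)) return(NULL)
  new_composite(mv$ord, es)
}

#' @rdname mutate_small
#' @export
mutate_large <- function(seq, ds, i = NULL, j = NULL) {
  es <- event_system(ds)
  mv <- propose_large(seq$order, es, i = i, j = j)
  if (is.null(mv)) return(NULL)
  new_composite(mv$ord, es)
}

#' @rdname mutate_small
#' @export
recombine <- function(p1, p2, ds, window = NULL) {
  es <- event_system(ds)
  check_events_match(p1, es); check_events_match(p2, es)
  pos2 <- integer(es$n); pos2[p2$order] <- seq_along(p2$order)
  mv <- propose_recomb(p1$order, pos2, window = window)
  new_composite(mv$ord, es)
}

# ---- the steady-state evolutionary loop ----

ea_core <- function(es, cfg, members) {
  m <- cfg$population_size
  ns <- length(es$sections)
  state <- lapply(members, function(o) {
    pos <- integer(es$n); pos[o] <- seq_along(o)
    sp <- all_secpen(es, pos)
    list(ord = o, pos = pos, secpen = sp, pen = sum(sp))
  })
  pens <- vapply(state, `[[`, numeric(1), "pen")
  bi <- which.min(pens)
  best_ord <- state[[bi]]$ord
  best_pen <- pens[bi]

  mem <- matrix(NA_integer_, nrow = cfg$memory_size, ncol = 3)
  mem_n <- 0L; mem_head <- 0L

  per_stage <- rep(cfg$trials %/% cfg$steps, cfg$steps)
  rem <- cfg$trials %% cfg$steps
  if (rem > 0) per_stage[seq_len(rem)] <- per_stage[seq_len(rem)] + 1L

  hist_gen <- integer(0); hist_T <- hist_best <- hist_mean <- hist_acc <- numeric(0)
  stale <- 0L
  trials_done <- 0L

  for (k in seq_len(cfg$steps)) {
    Tk <- if (cfg$steps == 1L) 0 else
      cfg$start_temperature * (cfg$steps - k) / (cfg$steps - 1)
    acc <- 0L
    stage_best_before <- best_pen
    for (tr in seq_len(per_stage[k])) {
      trials_done <- trials_done + 1L
      # linear rank bias: best rank has twice the weight of the worst
      r <- rank(pens, ties.method = "first")
      wts <- 2 - (r - 1) / max(1L, m - 1L)
      j <- sample.int(m, 1L, prob = wts)
      st <- state[[j]]

      mv <- NULL
      u <- stats::runif(1)
      if (u < cfg$memory_replay_rate && mem_n > 0L) {
        entry <- mem[sample.int(mem_n, 1L), ]
        mv <- replay_move(entry, st$ord, st$pos, es)
      } else if (u < cfg$memory_replay_rate + cfg$recombination_rate && m > 1L) {
        j2 <- sample.int(m, 1L, prob = wts)
        if (j2 != j) mv <- propose_recomb(st$ord, state[[j2]]$pos)
      } else {
        mv <- if (stats::runif(1) < cfg$large_move_rate)
          propose_large(st$ord, es) else propose_small(st$ord, es)
      }
      if (is.null(mv) || length(mv$changed) == 0L) next

      touched <- unique(c(st$ord[mv$changed], mv$ord[mv$changed]))
      secs <- unique(unlist(es$taxon_sections[unique(es$ev_taxon[touched])]))
      pos2 <- st$pos
      pos2[mv$ord[mv$changed]] <- mv$changed
      newsp <- st$secpen
      for (s in secs) newsp[s] <- sec_penalty_raw(es$sections[[s]], pos2)
      delta <- sum(newsp[secs]) - sum(st$secpen[secs])

      accept <- delta < 0 ||
        (Tk > 0 && stats::runif(1) < exp(-delta / Tk))
      if (!accept) next
      acc <- acc + 1L

      off <- list(ord = mv$ord, pos = pos2, secpen = newsp, pen = sum(newsp))
      if (delta < 0 && mv$type != 3L && !is.na(mv$e1)) {
        if (mem_n < cfg$memory_size) mem_n <- mem_n + 1L
        mem_head <- (mem_head %% cfg$memory_size) + 1L
        mem[mem_head, ] <- c(mv$type, mv$e1, mv$e2)
      }
      worst <- which.max(pens)
      if (off$pen < pens[worst]) {
        state[[worst]] <- off; pens[worst] <- off$pen
      } else {
        state[[j]] <- off; pens[j] <- off$pen
      }
      if (off$pen < best_pen) { best_pen <- off$pen; best_ord <- off$ord }
    }
    hist_gen <- c(hist_gen, k); hist_T <- c(hist_T, Tk)
    hist_best <- c(hist_best, best_pen); hist_mean <- c(hist_mean, mean(pens))
    hist_acc <- c(hist_acc, acc / max(1L, per_stage[k]))
    stale <- if (best_pen < stage_best_before) 0L else stale + 1L
    if (stale >= cfg$convergence_patience) break
    if (best_pen == 0 && all(pens == 0)) break
  }

  list(best_ord = best_ord, best_pen = best_pen, state = state, pens = pens,
       trials_done = trials_done,
       history = data.frame(generation = hist_gen, temperature = hist_T,
                            best_penalty = hist_best, mean_penalty = hist_mean,
                            acceptance_rate = hist_acc))
}

replay_move <- function(entry, ord, pos, es) {
  type <- entry[1]; e1 <- entry[2]; e2 <- entry[3]
  if (type == 1L) {
    i <- pos[e1]; j <- pos[e2]
    if (abs(i - j) != 1L) return(NULL)
    propose_small(ord, es, i = min(i, j))
  } else {
    propose_large(ord, es, i = pos[e1], j = pos[e2])
  }
}

#' Fit a composite sequence by evolutionary search
#'
#' The model-fitting entry point: evolves a population of feasible composite
#' sequences under the range-extension penalty, using constrained adjacent
#' swaps and block moves, order-based recombination, replay of remembered
#' improving moves, linear rank-biased parent selection, Metropolis
#' acceptance under a linearly annealed temperature, and steady-state
#' replacement of the worst member.  At temperature 0 only strictly
#' improving moves are accepted.
#'
#' @param ds a [strat_dataset()]; its sections must form one connected
#'   component (see [section_connectivity()]).
#' @param config an [ea_config()].
#' @param init optional list of [composite_sequence()] objects to seed the
#'   population from (see [init_from_sequences()]); by default the
#'   population is constructed from the sections themselves.
#' @return An object of class `conop_fit`: the best `sequence` (with cached
#'   penalty), `penalty`, per-stage `history`, the final `population`, the
#'   `config` and the dataset.
#' @examples
#' w <- simulate_world(n_taxa = 8, n_sections = 4, seed = 42)
#' fit <- conop(w$dataset, ea_config(steps = 20, trials = 2000, seed = 1,
#'                                   population_size = 8))
#' fit
#' @export
conop <- function(ds, config = ea_config(), init = NULL) {
  es <- event_system(ds)
  set.seed(config$seed)
  members <- if (is.null(init)) init_members_sections(ds, es, config)
             else init_members_sequences(init, es, config)
  res <- ea_core(es, config, members)
  structure(list(
    sequence = new_composite(res$best_ord, es, penalty = res$best_pen),
    penalty = res$best_pen,
    history = res$history,
    trials_done = res$trials_done,
    population = lapply(seq_along(res$state), function(i)
      new_composite(res$state[[i]]$ord, es, penalty = res$pens[i])),
    config = config,
    dataset = ds), class = "conop_fit")
}

#' @export
print.conop_fit <- function(x, ...) {
  cat("Composite sequence fit (evolutionary search)\n")
  cat("  events:   ", length(x$sequence$order), "\n", sep = "")
  cat("  sections: ", length(x$dataset$sections), "\n", sep = "")
  cat("  penalty:  ", format(x$penalty), "\n", sep = "")
  cat("  trials:   ", x$trials_done, " (", nrow(x$history),
      " generations)\n", sep = "")
  invisible(x)
}

#' @export
summary.conop_fit <- function(object, ...) {
  h <- object$history
  cat("Composite sequence fit\n")
  print(object)
  cat("  final population penalties: ",
      paste(format(sort(vapply(object$population, `[[`, numeric(1),
                               "penalty"))), collapse = " "), "\n", sep = "")
  cat("  best-penalty trace: ", format(h$best_penalty[1]), " -> ",
      format(h$best_penalty[nrow(h)]), "\n", sep = "")
  invisible(object)
}

#' @export
plot.conop_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$generation, h$best_penalty, type = "s",
                 xlab = "generation", ylab = "penalty",
                 ylim = range(c(h$best_penalty, h$mean_penalty)), ...)
  graphics::lines(h$generation, h$mean_penalty, lty = 2, col = "grey40")
  graphics::legend("topright", c("best", "population mean"),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(x)
}

#' @export
as.data.frame.conop_fit <- function(x, ...) x$sequence$events

#' Compare the full search against a pure-annealing baseline
#'
#' Runs the full evolutionary search and a degenerate configuration
#' (no recombination, no move memory, population of 2 -- i.e. simulated
#' annealing) at equal trial budgets over several seeds and tabulates the
#' final penalties.
#'
#' @param ds a [strat_dataset()].
#' @param config an [ea_config()] for the full search.
#' @param n_seeds number of replicate seeds (consecutive from
#'   `config$seed`).
#' @return data frame of class `conop_comparison` with one row per seed and
#'   columns `seed, ea_penalty, baseline_penalty`.
#' @export
compare_runs <- function(ds, config = ea_config(), n_seeds = 10) {
  base_cfg <- config
  base_cfg$recombination_rate <- 0
  base_cfg$memory_replay_rate <- 0
  base_cfg$population_size <- 2L
  out <- data.frame(seed = config$seed + seq_len(n_seeds) - 1L,
                    ea_penalty = NA_real_, baseline_penalty = NA_real_)
  for (i in seq_len(n_seeds)) {
    cfg1 <- config; cfg1$seed <- out$seed[i]
    cfg0 <- base_cfg; cfg0$seed <- out$seed[i]
    out$ea_penalty[i] <- conop(ds, cfg1)$penalty
    out$baseline_penalty[i] <- conop(ds, cfg0)$penalty
  }
  class(out) <- c("conop_comparison", "data.frame")
  out
}

#' @export
print.conop_comparison <- function(x, ...) {
  print.data.frame(x, ...)
  cat("mean penalties: EA ", format(mean(x$ea_penalty)), ", baseline ",
      format(mean(x$baseline_penalty)), " (difference ",
      format(mean(x$baseline_penalty) - mean(x$ea_penalty)), ")\n", sep = "")
  invisible(x)
}
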