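#' Genetic algorithm configuration for threshold learning
#'
#' Population size and generation count default to 100 each; the search
#' range for higher-order pattern thresholds defaults to the integers 0..6.
#' Selection, crossover and mutation are standard (tournament of size 2,
#' uniform crossover, per-gene uniform mutation) with elitism of one.
#'
#' @param population_size,generations positive integers.
#' @param range integer vector of candidate threshold values.
#' @param tournament_k tournament size for selection.
#' @param crossover_rate,mutation_rate probabilities.
#' @param elitism number of best genomes carried over unchanged.
#' @param seed RNG seed; runs are bit-reproducible given the seed.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 100L,
                      range = 0:6, tournament_k = 2L, crossover_rate = 0.9,
                      mutation_rate = 0.1, elitism = 1L, seed = 1L) {
  stopifnot(population_size >= 1, generations >= 1, length(range) >= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 range = sort(unique(as.integer(range))),
                 tournament_k = as.integer(tournament_k),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Empirical-risk-minimization configuration
#'
#' @param lambda_reg non-negative regularization weight on total pattern
#'   redundancy; on the unit-weight scale meaningful values are small
#'   integers such as 3 or 6.
#' @return object of class `erm_config`.
#' @export
erm_config <- function(lambda_reg = 3) {
  if (lambda_reg < 0) abort("lambda_reg must be non-negative")
  structure(list(lambda_reg = lambda_reg), class = "erm_config")
}

#' Redundancy of a pattern
#'
#' The fraction of pattern nodes that are non-essential (not bound to the
#' trigger, a sub-event trigger or an argument): `|V_r \ V_r'| / |V_r|`.
#'
#' @param p an [event_pattern()].
#' @return number in `[0, 1)`.
#' @export
pattern_redundancy <- function(p) {
  (nrow(p$nodes) - length(p$essential)) / nrow(p$nodes)
}

# ---- fast shared evaluator over cached candidates -------------------------

# Precompute index structures so that re-scoring a threshold assignment (the
# GA fitness, the ERM objective, pattern statistics) is a cheap vector pass
# instead of a fresh extraction.
prep_candidate_eval <- function(cands, gold) {
  gold_sigs <- if (is.character(gold)) gold else unlist(lapply(gold, gold_signatures))
  gold_sigs <- unique(gold_sigs)
  cl <- cands$candidates
  sigs <- names(cl)
  n <- length(cl)
  child_idx <- lapply(cl, function(cd) {
    match(cd$args$target[cd$args$kind == "event"], sigs)
  })
  # topological order, children before parents
  depth <- rep(NA_integer_, n)
  depth_of <- function(i) {
    if (!is.na(depth[i])) return(depth[i])
    d <- if (length(child_idx[[i]])) {
      1L + max(vapply(child_idx[[i]], depth_of, integer(1)))
    } else 0L
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) depth_of(i)
  group <- vapply(cl, candidate_group_key, character(1))
  # subsumption is threshold-independent: precompute, per candidate, the
  # indices of its strict subsumers within its group
  memo <- new.env(parent = emptyenv())
  subsumers <- lapply(seq_len(n), function(i) {
    js <- setdiff(which(group == group[i]), i)
    js[vapply(js, function(j) {
      candidate_subsumes(cl, sigs[i], sigs[j], memo)
    }, logical(1))]
  })
  # producers as integer pattern indices so re-scoring avoids name lookups
  pid_levels <- sort(unique(unlist(lapply(cl, function(cd) {
    cd$producers$pattern_id
  }))))
  list(
    n = n, sigs = sigs, pid_levels = pid_levels,
    prod_idx = lapply(cl, function(cd) {
      match(cd$producers$pattern_id, pid_levels)
    }),
    prod_d = lapply(cl, function(cd) cd$producers$distance),
    child_idx = child_idx,
    group = group,
    n_args = vapply(cl, function(cd) nrow(cd$args), integer(1)),
    subsumers = subsumers,
    in_gold = sigs %in% gold_sigs,
    n_gold = length(gold_sigs),
    topo = order(depth)
  )
}

# named threshold vector -> numeric vector over prep$pid_levels (NA = removed)
index_thresholds <- function(prep, thresholds) {
  thr <- rep(NA_real_, length(prep$pid_levels))
  m <- match(names(thresholds), prep$pid_levels)
  ok <- !is.na(m)
  thr[m[ok]] <- as.numeric(thresholds[ok])
  thr
}

# validity + finalization + strict scores for one threshold assignment.
# Patterns absent from `thresholds` are treated as removed.
eval_thresholds <- function(prep, thresholds, .indexed = FALSE) {
  thr_vec <- if (.indexed) thresholds else index_thresholds(prep, thresholds)
  valid <- logical(prep$n)
  for (i in prep$topo) {
    thr <- thr_vec[prep$prod_idx[[i]]]
    ok <- any(!is.na(thr) & prep$prod_d[[i]] <= thr + 1e-9)
    if (ok && length(prep$child_idx[[i]])) {
      ok <- all(valid[prep$child_idx[[i]]])
    }
    valid[i] <- ok
  }
  vi <- which(valid)
  # drop candidates with a valid strict subsumer; representative = the kept
  # subsumer with the most arguments (tie: lexicographic signature)
  kept <- vapply(vi, function(i) !any(valid[prep$subsumers[[i]]]),
                 logical(1))
  rep_of <- setNames(vi, prep$sigs[vi])
  for (k in which(!kept)) {
    i <- vi[k]
    sup <- prep$subsumers[[i]]
    sup <- sup[valid[sup] & vapply(sup, function(j)
      !any(valid[prep$subsumers[[j]]]), logical(1))]
    if (length(sup)) {
      rep_of[prep$sigs[i]] <-
        sup[order(-prep$n_args[sup], prep$sigs[sup])][1]
    }
  }
  fi <- vi[kept]
  tp <- sum(prep$in_gold[fi])
  fp <- length(fi) - tp
  fn <- prep$n_gold - tp
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  list(valid = vi, final = fi, rep_of = rep_of, tp = tp, fp = fp, fn = fn,
       recall = recall, precision = precision, f_score = f)
}

# per-pattern prediction statistics under a threshold assignment; a pattern
# is credited with the finalization representative of each of its valid
# candidates, so individual-path patterns share credit with the union
# pattern that subsumes their partial events.
pattern_stats_from_eval <- function(prep, thresholds, ev) {
  thr_vec <- index_thresholds(prep, thresholds)
  stats <- list()
  for (i in ev$valid) {
    thr <- thr_vec[prep$prod_idx[[i]]]
    firing <- prep$pid_levels[
      prep$prod_idx[[i]][!is.na(thr) & prep$prod_d[[i]] <= thr + 1e-9]]
    rep_i <- ev$rep_of[[prep$sigs[i]]]
    for (pid in unique(firing)) {
      stats[[pid]] <- union(stats[[pid]], rep_i)
    }
  }
  tibble(
    pattern_id = as.character(names(stats) %||% character(0)),
    n_total = unname(vapply(stats, length, integer(1))),
    n_correct = unname(vapply(stats, function(s) {
      sum(prep$in_gold[s])
    }, integer(1)))
  ) |> mutate(precision = ifelse(.data$n_total > 0,
                                 .data$n_correct / .data$n_total, 0))
}

threshold_vector <- function(patterns, cfg = NULL, default = 0) {
  vapply(patterns, function(p) pattern_threshold(p, cfg, NULL), numeric(1)) |>
    setNames(vapply(patterns, `[[`, "", "pattern_id"))
}

#' Prediction precision of each pattern
#'
#' Runs extraction over the documents with the full pattern set and credits
#' each pattern with the events its matches produced; precision is
#' `n_correct / n_total` against the gold annotation (0 for a pattern with
#' no predictions).
#'
#' @param patterns list of [event_pattern()].
#' @param docs anonymized annotated documents.
#' @param gold gold events (documents or signature vector); defaults to
#'   `docs`.
#' @param cfg optional [task_config()].
#' @return tibble with pattern_id, n_total, n_correct, precision (patterns
#'   with no predictions included with zeros).
#' @export
pattern_precision <- function(patterns, docs, gold = docs, cfg = NULL) {
  thr <- threshold_vector(patterns, cfg)
  cands <- extract_corpus(docs, patterns, cfg, thresholds = max(c(thr, 0)))
  prep <- prep_candidate_eval(cands, gold)
  ev <- eval_thresholds(prep, thr)
  st <- pattern_stats_from_eval(prep, thr, ev)
  missing <- setdiff(names(thr), st$pattern_id)
  bind_rows(st, tibble(pattern_id = missing, n_total = 0L, n_correct = 0L,
                       precision = 0)) |>
    arrange(match(.data$pattern_id, names(thr)))
}

#' Iterative precision-based pattern filtering
#'
#' Repeats end-to-end extraction, per-pattern precision ranking and removal
#' of patterns below `min_precision` until a fixed point: removing a pattern
#' can strand higher-order patterns whose sub-events it produced, so the
#' process iterates until no further pattern falls below the cutoff.
#'
#' @inheritParams pattern_precision
#' @param min_precision removal cutoff in `[0, 1]` (default 0.25, the
#'   preserve-above-a-quarter criterion).
#' @return the retained pattern list.
#' @export
precision_filter <- function(patterns, docs, gold = docs,
                             min_precision = 0.25, cfg = NULL) {
  stopifnot(min_precision >= 0, min_precision <= 1)
  repeat {
    if (!length(patterns)) return(patterns)
    st <- pattern_precision(patterns, docs, gold, cfg)
    bad <- st$pattern_id[st$precision < min_precision]
    if (!length(bad)) return(patterns)
    patterns <- discard(patterns, function(p) p$pattern_id %in% bad)
  }
}

#' Learn individual thresholds for lower-order patterns
#'
#' For each pattern whose arguments are all entities, candidate threshold
#' values are scanned in ascending order; a value is accepted only if it
#' yields strictly more correct predictions on the training data at an equal
#' or better precision, and does not decrease correct predictions or
#' precision on the held-out data (overfitting guard). Matching is performed
#' once at the maximum of the range and re-filtered per value. When several
#' values tie, the smallest is kept.
#'
#' @param lower list of lower-order [event_pattern()].
#' @param train,heldout anonymized annotated document lists.
#' @param range integer vector of candidate values (default 0:12).
#' @param cfg optional [task_config()].
#' @return named numeric vector of learned thresholds by pattern id.
#' @export
learn_lower_thresholds <- function(lower, train, heldout, range = 0:12,
                                   cfg = NULL) {
  range <- sort(unique(range))
  if (any(vapply(lower, is_higher_order, logical(1)))) {
    abort("learn_lower_thresholds expects lower-order patterns only")
  }
  ids <- vapply(lower, `[[`, "", "pattern_id")
  tmax <- max(range)
  cands_tr <- extract_corpus(train, lower, cfg, thresholds = tmax)
  cands_ho <- extract_corpus(heldout, lower, cfg, thresholds = tmax)
  gold_tr <- unique(unlist(lapply(train, gold_signatures)))
  gold_ho <- unique(unlist(lapply(heldout, gold_signatures)))
  # individual assessment: only the pattern's own candidates
  per_pattern <- function(cands, gold_sigs, pid, v) {
    tot <- 0L; corr <- 0L
    for (cd in cands$candidates) {
      d <- cd$producers$distance[cd$producers$pattern_id == pid]
      if (length(d) && min(d) <= v + 1e-9) {
        tot <- tot + 1L
        if (cd$sig %in% gold_sigs) corr <- corr + 1L
      }
    }
    c(total = tot, correct = corr,
      precision = if (tot > 0) corr / tot else 0)
  }
  out <- setNames(numeric(length(ids)), ids)
  for (pid in ids) {
    cur <- range[1]
    cur_tr <- per_pattern(cands_tr, gold_tr, pid, cur)
    cur_ho <- per_pattern(cands_ho, gold_ho, pid, cur)
    for (v in range[-1]) {
      tr <- per_pattern(cands_tr, gold_tr, pid, v)
      ho <- per_pattern(cands_ho, gold_ho, pid, v)
      if (tr[["correct"]] > cur_tr[["correct"]] &&
          tr[["precision"]] >= cur_tr[["precision"]] - 1e-12 &&
          ho[["correct"]] >= cur_ho[["correct"]] &&
          ho[["precision"]] >= cur_ho[["precision"]] - 1e-12) {
        cur <- v; cur_tr <- tr; cur_ho <- ho
      }
    }
    out[pid] <- cur
  }
  out
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Optimize higher-order pattern thresholds with a genetic algorithm
#'
#' The genome assigns one integer threshold (within `ga$range`) to every
#' higher-order pattern; lower-order thresholds stay fixed at their learned
#' values and feed sub-events to the higher-order patterns. Fitness is the
#' F-score of the whole pattern set on the training data, computed by
#' re-filtering candidates extracted once at the maximal threshold. The best
#' genome ever seen is returned (elitist, so the result is at least as fit
#' as every initial-population member); runs are reproducible given
#' `ga$seed`.
#'
#' @param patterns full pattern list (lower- and higher-order).
#' @param lower_thresholds named numeric vector for the lower-order patterns.
#' @param train anonymized annotated documents.
#' @param gold gold events; defaults to `train`.
#' @param ga a [ga_config()].
#' @param cfg optional [task_config()].
#' @return named numeric vector of thresholds for the higher-order patterns
#'   (empty when there are none), with attribute `fitness`.
#' @export
ga_optimize_thresholds <- function(patterns, lower_thresholds, train,
                                   gold = train, ga = ga_config(),
                                   cfg = NULL) {
  higher <- keep(patterns, is_higher_order)
  if (!length(higher)) {
    return(structure(setNames(numeric(0), character(0)), fitness = NA_real_))
  }
  hids <- vapply(higher, `[[`, "", "pattern_id")
  tmax <- max(c(ga$range, lower_thresholds, 0))
  cands <- extract_corpus(train, patterns, cfg, thresholds = tmax)
  prep <- prep_candidate_eval(cands, gold)
  thr_base <- index_thresholds(prep, lower_thresholds)
  hidx <- match(hids, prep$pid_levels)
  fitness <- function(genome) {
    thr <- thr_base
    thr[hidx[!is.na(hidx)]] <- genome[!is.na(hidx)]
    eval_thresholds(prep, thr, .indexed = TRUE)$f_score
  }
  ng <- length(hids)
  rng <- ga$range
  draw <- function(n) rng[sample.int(length(rng), n, replace = TRUE)]
  with_seed(ga$seed, {
    pop <- lapply(seq_len(ga$population_size), function(i) draw(ng))
    fit <- vapply(pop, fitness, numeric(1))
    best <- pop[[which.max(fit)]]; best_fit <- max(fit)
    for (gen in seq_len(ga$generations)) {
      sel <- function() {
        k <- sample.int(length(pop), ga$tournament_k, replace = TRUE)
        pop[[k[which.max(fit[k])]]]
      }
      newpop <- list()
      ord <- order(-fit)
      for (e in seq_len(min(ga$elitism, length(pop)))) {
        newpop[[length(newpop) + 1L]] <- pop[[ord[e]]]
      }
      while (length(newpop) < ga$population_size) {
        p1 <- sel(); p2 <- sel()
        child <- if (stats::runif(1) < ga$crossover_rate) {
          mask <- stats::runif(ng) < 0.5
          ifelse(mask, p1, p2)
        } else p1
        mut <- stats::runif(ng) < ga$mutation_rate
        if (any(mut)) child[mut] <- draw(sum(mut))
        newpop[[length(newpop) + 1L]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, fitness, numeric(1))
      if (max(fit) > best_fit) {
        best <- pop[[which.max(fit)]]; best_fit <- max(fit)
      }
    }
    structure(setNames(as.numeric(best), hids), fitness = best_fit)
  })
}

#' Exhaustive threshold search (oracle counterpart of the GA)
#'
#' Enumerates every assignment in `range^k` over the higher-order patterns
#' and returns the global optimum of the same fitness the GA maximizes.
#' Intended for small fixtures.
#'
#' @inheritParams ga_optimize_thresholds
#' @param range integer vector of candidate values.
#' @return named numeric vector with attribute `fitness`.
#' @export
exhaustive_thresholds <- function(patterns, lower_thresholds, train,
                                  gold = train, range = 0:5, cfg = NULL) {
  higher <- keep(patterns, is_higher_order)
  hids <- vapply(higher, `[[`, "", "pattern_id")
  if (length(range)^length(hids) > 1e5) abort("search space too large")
  tmax <- max(c(range, lower_thresholds, 0))
  cands <- extract_corpus(train, patterns, cfg, thresholds = tmax)
  prep <- prep_candidate_eval(cands, gold)
  thr_base <- index_thresholds(prep, lower_thresholds)
  hidx <- match(hids, prep$pid_levels)
  grid <- as.matrix(expand.grid(rep(list(range), length(hids)),
                                KEEP.OUT.ATTRS = FALSE))
  best <- NULL; best_fit <- -Inf
  for (r in seq_len(nrow(grid))) {
    genome <- as.numeric(grid[r, ])
    thr <- thr_base
    thr[hidx[!is.na(hidx)]] <- genome[!is.na(hidx)]
    f <- eval_thresholds(prep, thr, .indexed = TRUE)$f_score
    if (f > best_fit) { best_fit <- f; best <- genome }
  }
  structure(setNames(best, hids), fitness = best_fit)
}

#' Regularized empirical-risk objective of a pattern set
#'
#' `f(P) = E(P, G) + lambda * C_P` where `E` counts wrongly predicted plus
#' missed events under strict evaluation of extraction with pattern set `P`
#' (thresholds fixed per pattern) and `C_P` is the summed redundancy
#' (fraction of non-essential nodes) of the patterns in `P`.
#'
#' @param patterns pattern list `P` (with fixed thresholds, see
#'   [pattern_threshold()] resolution).
#' @param docs anonymized annotated documents.
#' @param gold gold events; defaults to `docs`.
#' @param cfg_erm an [erm_config()].
#' @param cfg optional [task_config()].
#' @return the objective value (non-negative).
#' @export
erm_objective <- function(patterns, docs, gold = docs,
                          cfg_erm = erm_config(), cfg = NULL) {
  thr <- threshold_vector(patterns, cfg)
  cands <- extract_corpus(docs, patterns, cfg, thresholds = max(c(thr, 0)))
  prep <- prep_candidate_eval(cands, gold)
  ev <- eval_thresholds(prep, thr)
  c_p <- sum(vapply(patterns, pattern_redundancy, numeric(1)))
  (ev$fp + ev$fn) + cfg_erm$lambda_reg * c_p
}

#' ERM-based pattern set optimization by greedy backward elimination
#'
#' Starting from the full pattern set, repeatedly removes the pattern whose
#' removal yields the largest strict reduction in the regularized objective
#' `f(P)`; stops when no removal reduces `f` (ties broken by smallest
#' pattern id). Candidates are extracted once at the patterns' fixed
#' thresholds and re-filtered per subset, which equals full re-evaluation.
#'
#' @inheritParams erm_objective
#' @return the optimized pattern list, with attribute `objective_trace`
#'   holding the strictly decreasing sequence of objective values.
#' @export
erm_optimize <- function(patterns, docs, gold = docs,
                         cfg_erm = erm_config(), cfg = NULL) {
  thr_all <- threshold_vector(patterns, cfg)
  cands <- extract_corpus(docs, patterns, cfg, thresholds = max(c(thr_all, 0)))
  prep <- prep_candidate_eval(cands, gold)
  red <- setNames(vapply(patterns, pattern_redundancy, numeric(1)),
                  names(thr_all))
  objective <- function(ids) {
    ev <- eval_thresholds(prep, thr_all[ids])
    (ev$fp + ev$fn) + cfg_erm$lambda_reg * sum(red[ids])
  }
  current <- names(thr_all)
  f_cur <- objective(current)
  trace <- f_cur
  while (length(current)) {
    gains <- vapply(current, function(pid) {
      f_cur - objective(setdiff(current, pid))
    }, numeric(1))
    ord <- order(-gains, names(gains))
    if (gains[ord[1]] <= 1e-9) break
    drop_id <- names(gains)[ord[1]]
    current <- setdiff(current, drop_id)
    f_cur <- unname(f_cur - gains[ord[1]])
    trace <- c(trace, f_cur)
  }
  out <- keep(patterns, function(p) p$pattern_id %in% current)
  attr(out, "objective_trace") <- trace
  out
}
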