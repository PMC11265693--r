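#' Settings for one enhanced scatter-search worker
#'
#' @param refset_size Even integer (at least 4) size of the reference set;
#'   default `2 * ceiling(sqrt(dim))` rounded up to even, chosen at
#'   initialization when `NULL`.
#' @param diversification_size Latin-hypercube sample size used to seed the
#'   reference set; default `10 * dim`.
#' @param local_search_max_evals Evaluation budget of each dynamic
#'   hill-climbing call.
#' @param local_search_trigger Scatter-search iterations between local
#'   search calls.
#' @param balance Intensification/diversification weight in `[0, 1]`: larger
#'   values shrink the combination rectangle on the side of the worse parent.
#' @param restart_after_evals Worker evaluations without improving its own
#'   reference-set best before the whole reference set is rebuilt from a
#'   fresh diversification sample (the incumbent stays in the archive).
#' @param seed Integer seed of the worker's private random stream.
#'
#' @return A `worker_config` list.
#' @export
worker_config <- function(refset_size = NULL, diversification_size = NULL,
                          local_search_max_evals = 2000L,
                          local_search_trigger = 5L, balance = 0.5,
                          restart_after_evals = 40000L, seed = 1L) {
  if (!is.null(refset_size)) {
    stopifnot(refset_size >= 4, refset_size %% 2 == 0)
  }
  stopifnot(
    local_search_max_evals >= 1, local_search_trigger >= 1,
    balance >= 0, balance <= 1
  )
  structure(
    list(
      refset_size = refset_size,
      diversification_size = diversification_size,
      local_search_max_evals = as.integer(local_search_max_evals),
      local_search_trigger = as.integer(local_search_trigger),
      balance = balance,
      restart_after_evals = as.integer(restart_after_evals),
      seed = as.integer(seed)
    ),
    class = "worker_config"
  )
}

#' Settings for the cooperative master
#'
#' @param n_workers Number of scatter-search workers stepped round-robin.
#' @param improvement_threshold Relative cost improvement over the last
#'   broadcast solution required before the master propagates a candidate;
#'   halved whenever more than 20 improving candidates are rejected.
#' @param reconfigure_after_evals Per-worker evaluation budget without an
#'   accepted improvement before the master replaces the worker's settings
#'   with a jittered copy of the current best scorer's settings.
#' @param scoreboard_window Evaluation window over which per-worker accepted
#'   improvements are counted.
#' @param max_evals_total Total evaluation budget across workers.
#' @param cost_tol Stop early once the global best cost reaches this value.
#'
#' @return A `cooperation_config` list.
#' @export
cooperation_config <- function(n_workers = 2L, improvement_threshold = 0.1,
                               reconfigure_after_evals = 30000L,
                               scoreboard_window = 10000L,
                               max_evals_total = 50000L, cost_tol = -Inf) {
  stopifnot(
    n_workers >= 1,
    improvement_threshold > 0, improvement_threshold < 1,
    reconfigure_after_evals >= 1, scoreboard_window >= 1,
    max_evals_total >= 1
  )
  structure(
    list(
      n_workers = as.integer(n_workers),
      improvement_threshold = improvement_threshold,
      reconfigure_after_evals = as.integer(reconfigure_after_evals),
      scoreboard_window = as.integer(scoreboard_window),
      max_evals_total = as.integer(max_evals_total),
      cost_tol = cost_tol
    ),
    class = "cooperation_config"
  )
}

as_bounds <- function(bounds) {
  if (is.list(bounds) && !is.null(bounds$lower)) {
    lower <- as.numeric(bounds$lower)
    upper <- as.numeric(bounds$upper)
  } else {
    b <- as.matrix(bounds)
    lower <- b[, 1]
    upper <- b[, 2]
  }
  stopifnot(length(lower) == length(upper), all(upper > lower))
  list(lower = lower, upper = upper)
}

clip_bounds <- function(theta, lower, upper) pmin(pmax(theta, lower), upper)

# Shared evaluation bookkeeping: counter, archive, best, trace. The archive
# accumulates in small fixed-size buffer chunks: repeatedly writing rows into
# one ever-growing matrix bound in an environment triggers a full copy per
# evaluation (quadratic time for long runs).
ARCH_CHUNK <- 2048L

new_eval_env <- function(dim, max_evals, cost_tol) {
  e <- new.env(parent = emptyenv())
  e$dim <- dim
  e$n <- 0L
  e$buf <- matrix(NA_real_, ARCH_CHUNK, dim + 3L) # theta, cost, worker, seed
  e$buf_n <- 0L
  e$chunks <- vector("list", 64L)
  e$n_chunks <- 0L
  e$best_cost <- Inf
  e$best_theta <- rep(NA_real_, dim)
  e$trace <- vector("list", 256L)
  e$n_trace <- 0L
  e$max_evals <- max_evals
  e$cost_tol <- cost_tol
  e
}

flush_archive_buffer <- function(ev) {
  if (ev$buf_n > 0L) {
    if (ev$n_chunks >= length(ev$chunks)) {
      length(ev$chunks) <- 2L * length(ev$chunks)
    }
    ev$n_chunks <- ev$n_chunks + 1L
    ev$chunks[[ev$n_chunks]] <- ev$buf[seq_len(ev$buf_n), , drop = FALSE]
    ev$buf_n <- 0L
  }
  invisible(ev)
}

eval_cost <- function(ev, cost_fn, theta, worker, stochastic) {
  seed <- NA_real_
  cost <- if (stochastic) {
    seed <- sample.int(2147483646L, 1)
    cost_fn(theta, eval_seed = seed)
  } else {
    cost_fn(theta)
  }
  if (is.na(cost)) cost <- Inf
  ev$n <- ev$n + 1L
  if (ev$buf_n >= ARCH_CHUNK) flush_archive_buffer(ev)
  ev$buf_n <- ev$buf_n + 1L
  ev$buf[ev$buf_n, ] <- c(theta, cost, worker, seed)
  if (cost < ev$best_cost) {
    ev$best_cost <- cost
    ev$best_theta <- theta
    if (ev$n_trace >= length(ev$trace)) length(ev$trace) <- 2L * length(ev$trace)
    ev$n_trace <- ev$n_trace + 1L
    ev$trace[[ev$n_trace]] <- c(ev$n, cost)
  }
  cost
}

stop_reached <- function(ev) {
  ev$n >= ev$max_evals || ev$best_cost <= ev$cost_tol
}

#' Initialize a scatter-search reference set
#'
#' Evaluates a Latin-hypercube diversification sample and keeps the best
#' half by cost plus the most diverse half by greedy max-min normalized
#' distance.
#'
#' @param cost_fn Cost function `f(theta)`.
#' @param bounds List with `lower`/`upper` vectors (or a 2-column matrix).
#' @param config A [worker_config()]; the current RNG state drives sampling.
#'
#' @return A list with `theta` (members-by-dim matrix) and `cost`.
#' @export
initialize_refset <- function(cost_fn, bounds, config = worker_config()) {
  b <- as_bounds(bounds)
  dim <- length(b$lower)
  m <- refset_size_for(config, dim)
  nd <- config$diversification_size %||% max(10L * dim, 2L * m)
  cand <- sweep(
    sweep(lhs::randomLHS(nd, dim), 2, b$upper - b$lower, "*"),
    2, b$lower, "+"
  )
  cost <- apply(cand, 1, cost_fn)
  cost[is.na(cost)] <- Inf
  if (all(!is.finite(cost))) {
    abort("all diversification candidates evaluated to non-finite cost",
          class = "vepfit_init_failed")
  }
  sel <- select_refset(cand, cost, m, b)
  list(theta = cand[sel, , drop = FALSE], cost = cost[sel])
}

refset_size_for <- function(config, dim) {
  m <- config$refset_size %||% {
    k <- 2L * ceiling(sqrt(dim))
    as.integer(if (k %% 2 == 1) k + 1 else k)
  }
  max(4L, m)
}

select_refset <- function(cand, cost, m, b) {
  h <- m %/% 2
  ord <- order(cost)
  sel <- ord[seq_len(min(h, length(ord)))]
  pool <- setdiff(seq_len(nrow(cand)), sel)
  scale <- b$upper - b$lower
  norm <- sweep(cand, 2, scale, "/")
  while (length(sel) < m && length(pool) > 0) {
    dmin <- vapply(pool, function(i) {
      min(sqrt(rowSums((norm[sel, , drop = FALSE] -
                          matrix(norm[i, ], length(sel), ncol(norm),
                                 byrow = TRUE))^2)))
    }, numeric(1))
    pick <- pool[which.max(dmin)]
    sel <- c(sel, pick)
    pool <- setdiff(pool, pick)
  }
  sel
}

#' Combine two solutions into a trial point
#'
#' Draws uniformly from the hyper-rectangle spanned by `a` and `b`, expanded
#' beyond each endpoint by a multiple of the pair's displacement, and clips
#' to bounds.
#'
#' @param a,b Distinct parameter vectors.
#' @param bounds Bounds as in [initialize_refset()].
#' @param expand_a,expand_b Expansion factors beyond `a` and beyond `b`
#'   (0 = no expansion on that side).
#'
#' @return A parameter vector within bounds.
#' @export
combine_solutions <- function(a, b, bounds, expand_a = 1, expand_b = 1) {
  if (all(a == b)) abort("`a` and `b` must differ.")
  bb <- as_bounds(bounds)
  d <- abs(b - a)
  lo <- ifelse(a <= b, a - expand_a * d, b - expand_b * d)
  hi <- ifelse(a <= b, b + expand_b * d, a + expand_a * d)
  clip_bounds(runif(length(a), lo, hi), bb$lower, bb$upper)
}

#' Go-beyond intensification step
#'
#' When a child improves on its parent, keeps stepping further along the
#' child-minus-parent direction while improvement continues, halving the
#' advance factor after every pair of consecutive successes, and returns the
#' best point found (clipped to bounds).
#'
#' @param parent,child Lists with elements `theta` and `cost`;
#'   `child$cost < parent$cost`.
#' @param cost_fn Cost function.
#' @param bounds Bounds as in [initialize_refset()].
#'
#' @return A list with `theta`, `cost`, and `evals` used.
#' @export
go_beyond <- function(parent, child, cost_fn, bounds) {
  stopifnot(child$cost < parent$cost)
  b <- as_bounds(bounds)
  denom <- 1
  successes <- 0L
  evals <- 0L
  repeat {
    step <- (child$theta - parent$theta) / denom
    cand <- clip_bounds(child$theta + step, b$lower, b$upper)
    if (all(cand == child$theta) || evals >= 20L) break
    cc <- cost_fn(cand)
    evals <- evals + 1L
    if (is.na(cc) || cc >= child$cost) break
    parent <- child
    child <- list(theta = cand, cost = cc)
    successes <- successes + 1L
    if (successes %% 2L == 0L) denom <- denom * 2
  }
  list(theta = child$theta, cost = child$cost, evals = evals)
}

#' Dynamic hill-climbing local search
#'
#' Derivative-free coordinate search with per-coordinate step sizes that
#' double on success and halve on failure, terminating when every step falls
#' below 1e-9 or the evaluation budget is spent. Never returns a point worse
#' than the start.
#'
#' @param start Starting parameter vector.
#' @param cost_fn Cost function.
#' @param bounds Bounds as in [initialize_refset()].
#' @param max_evals Evaluation budget (at least `2 * dim` to probe every
#'   coordinate in both directions).
#' @param start_cost Optional known cost at `start` (saves one evaluation).
#'
#' @return A list with `theta`, `cost`, and `evals` used.
#' @export
dhc_local_search <- function(start, cost_fn, bounds, max_evals = 2000L,
                             start_cost = NULL) {
  b <- as_bounds(bounds)
  dim <- length(start)
  theta <- clip_bounds(start, b$lower, b$upper)
  evals <- 0L
  if (is.null(start_cost)) {
    start_cost <- cost_fn(theta)
    evals <- evals + 1L
  }
  cost <- start_cost
  v <- (b$upper - b$lower) / 20
  repeat {
    if (all(abs(v) < 1e-9) || evals >= max_evals) break
    for (i in seq_len(dim)) {
      if (evals >= max_evals) break
      if (abs(v[i]) < 1e-9) next
      cand <- theta
      cand[i] <- min(max(theta[i] + v[i], b$lower[i]), b$upper[i])
      cc <- if (cand[i] != theta[i]) cost_fn(cand) else Inf
      if (cand[i] != theta[i]) evals <- evals + 1L
      if (!is.na(cc) && cc < cost) {
        theta <- cand
        cost <- cc
        v[i] <- sign(v[i]) * min(abs(v[i]) * 2, b$upper[i] - b$lower[i])
        next
      }
      if (evals >= max_evals) break
      cand2 <- theta
      cand2[i] <- min(max(theta[i] - v[i], b$lower[i]), b$upper[i])
      cc2 <- if (cand2[i] != theta[i]) cost_fn(cand2) else Inf
      if (cand2[i] != theta[i]) evals <- evals + 1L
      if (!is.na(cc2) && cc2 < cost) {
        theta <- cand2
        cost <- cc2
        v[i] <- -sign(v[i]) * min(abs(v[i]) * 2, b$upper[i] - b$lower[i])
      } else {
        v[i] <- v[i] / 2
      }
    }
  }
  list(theta = theta, cost = cost, evals = evals)
}

# ---- eSS worker state machine ----------------------------------------------

ess_init <- function(cost_fn, bounds, config, ev, worker_id = 1L,
                     init_solutions = NULL) {
  b <- as_bounds(bounds)
  dim <- length(b$lower)
  stochastic <- isTRUE(attr(cost_fn, "stochastic"))
  st <- new.env(parent = emptyenv())
  st$cost_fn <- cost_fn
  st$lower <- b$lower
  st$upper <- b$upper
  st$dim <- dim
  st$config <- config
  st$ev <- ev
  st$id <- worker_id
  st$stochastic <- stochastic
  st$iter <- 0L
  st$stag <- 0L
  st$alive <- TRUE

  m <- refset_size_for(config, dim)
  nd <- config$diversification_size %||% max(10L * dim, 2L * m)
  cand <- sweep(
    sweep(lhs::randomLHS(nd, dim), 2, b$upper - b$lower, "*"),
    2, b$lower, "+"
  )
  if (!is.null(init_solutions)) {
    clipped <- t(apply(as.matrix(init_solutions), 1, function(r) {
      pmin(pmax(r, b$lower), b$upper)
    }))
    cand <- rbind(clipped, cand)
  }
  cost <- vapply(seq_len(nrow(cand)), function(i) {
    eval_cost(ev, cost_fn, cand[i, ], worker_id, stochastic)
  }, numeric(1))
  if (all(!is.finite(cost))) {
    abort("all diversification candidates evaluated to non-finite cost",
          class = "vepfit_init_failed")
  }
  sel <- select_refset(cand, cost, m, b)
  st$refset <- cand[sel, , drop = FALSE]
  st$refcost <- cost[sel]
  st$refined <- rep(FALSE, length(sel))
  st$last_gain_evals <- ev$n
  st
}

worker_eval <- function(st, theta) {
  eval_cost(st$ev, st$cost_fn, theta, st$id, st$stochastic)
}

min_norm_dist <- function(theta, refset, lower, upper, exclude = integer(0)) {
  keep <- setdiff(seq_len(nrow(refset)), exclude)
  if (length(keep) == 0) return(Inf)
  scale <- upper - lower
  d <- sweep(refset[keep, , drop = FALSE], 2, theta, "-")
  d <- sweep(d, 2, scale, "/")
  min(sqrt(rowSums(d^2)))
}

ess_step <- function(st) {
  st$iter <- st$iter + 1L
  m <- nrow(st$refset)
  improved <- FALSE
  cfg <- st$config
  gb_bounds <- list(lower = st$lower, upper = st$upper)

  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      if (stop_reached(st$ev)) return(invisible(st))
      better <- if (st$refcost[i] <= st$refcost[j]) i else j
      worse <- if (better == i) j else i
      if (all(st$refset[i, ] == st$refset[j, ])) next
      child <- combine_solutions(
        st$refset[better, ], st$refset[worse, ], gb_bounds,
        expand_a = 1, expand_b = 1 - cfg$balance
      )
      cc <- worker_eval(st, child)
      if (cc < st$refcost[worse]) {
        if (cc < st$refcost[better] && !stop_reached(st$ev)) {
          gb <- go_beyond(
            parent = list(theta = st$refset[better, ],
                          cost = st$refcost[better]),
            child = list(theta = child, cost = cc),
            cost_fn = function(t) worker_eval(st, t),
            bounds = gb_bounds
          )
          child <- gb$theta
          cc <- gb$cost
        }
        if (min_norm_dist(child, st$refset, st$lower, st$upper,
                          exclude = worse) > 1e-8) {
          st$refset[worse, ] <- child
          st$refcost[worse] <- cc
          st$refined[worse] <- FALSE
          improved <- TRUE
        }
      }
    }
  }

  # periodic local search from the best not-yet-refined member
  if (st$iter %% cfg$local_search_trigger == 0L && !stop_reached(st$ev)) {
    open <- which(!st$refined)
    if (length(open) > 0) {
      k <- open[which.min(st$refcost[open])]
      budget <- min(cfg$local_search_max_evals,
                    max(st$ev$max_evals - st$ev$n, 2L * st$dim))
      ls <- dhc_local_search(
        st$refset[k, ], function(t) worker_eval(st, t), gb_bounds,
        max_evals = budget, start_cost = st$refcost[k]
      )
      st$refined[k] <- TRUE
      if (ls$cost < st$refcost[k]) {
        st$refset[k, ] <- ls$theta
        st$refcost[k] <- ls$cost
        improved <- TRUE
      }
    }
  }

  # stagnation-triggered partial regeneration of the worst half
  st$stag <- if (improved) 0L else st$stag + 1L
  if (improved) st$last_gain_evals <- st$ev$n
  if (st$stag >= 20L && !stop_reached(st$ev)) {
    worst <- order(st$refcost, decreasing = TRUE)[seq_len(m %/% 2)]
    for (k in worst) {
      fresh <- runif(st$dim, st$lower, st$upper)
      st$refset[k, ] <- fresh
      st$refcost[k] <- worker_eval(st, fresh)
      st$refined[k] <- FALSE
      if (stop_reached(st$ev)) break
    }
    st$stag <- 0L
  }

  # deep stagnation: rebuild the whole reference set from a fresh
  # diversification sample (the incumbent lives on in the archive)
  if (st$ev$n - st$last_gain_evals > cfg$restart_after_evals &&
      !stop_reached(st$ev)) {
    nd <- max(5L * st$dim, 2L * m)
    cand <- sweep(
      sweep(lhs::randomLHS(nd, st$dim), 2, st$upper - st$lower, "*"),
      2, st$lower, "+"
    )
    cost <- vapply(seq_len(nd), function(i) worker_eval(st, cand[i, ]),
                   numeric(1))
    if (any(is.finite(cost))) {
      sel <- select_refset(cand, cost, m,
                           list(lower = st$lower, upper = st$upper))
      st$refset <- cand[sel, , drop = FALSE]
      st$refcost <- cost[sel]
      st$refined <- rep(FALSE, length(sel))
    }
    st$stag <- 0L
    st$last_gain_evals <- st$ev$n
  }
  invisible(st)
}

inject_solution <- function(st, theta, cost) {
  if (min_norm_dist(theta, st$refset, st$lower, st$upper) <= 1e-8) {
    return(invisible(st))
  }
  worst <- which.max(st$refcost)
  if (cost < st$refcost[worst]) {
    st$refset[worst, ] <- theta
    st$refcost[worst] <- cost
    st$refined[worst] <- FALSE
  }
  invisible(st)
}

# RNG stream juggling: each worker owns a .Random.seed snapshot
grab_rng <- function() get(".Random.seed", envir = globalenv())
put_rng <- function(s) assign(".Random.seed", s, envir = globalenv())

finish_fit <- function(ev, states, coop, broadcasts, scoreboard) {
  flush_archive_buffer(ev)
  n <- ev$n
  dim <- ev$dim
  all_rows <- do.call(rbind, ev$chunks[seq_len(ev$n_chunks)])
  arch <- tibble::as_tibble(
    all_rows[, seq_len(dim), drop = FALSE], .name_repair = "minimal"
  )
  names(arch) <- paste0("theta_", seq_len(dim))
  arch$cost <- all_rows[, dim + 1L]
  arch$worker <- as.integer(all_rows[, dim + 2L])
  arch$eval <- seq_len(n)
  arch$eval_seed <- as.integer(all_rows[, dim + 3L])
  tr <- do.call(rbind, ev$trace[seq_len(ev$n_trace)])

  stats <- tibble::tibble(
    worker = vapply(states, function(s) s$id, integer(1)),
    evals = vapply(states, function(s) sum(arch$worker == s$id), integer(1)),
    accepted = vapply(states, function(s) {
      sum(scoreboard$worker == s$id)
    }, integer(1)),
    best_cost = vapply(states, function(s) {
      w <- arch$worker == s$id
      if (any(w)) min(arch$cost[w]) else Inf
    }, numeric(1)),
    alive = vapply(states, function(s) s$alive, logical(1))
  )

  structure(
    list(
      best_theta = ev$best_theta,
      best_cost = ev$best_cost,
      trace = tibble::tibble(evals = as.integer(tr[, 1]), cost = tr[, 2]),
      archive = arch,
      n_evals = n,
      n_workers = length(states),
      worker_stats = stats,
      broadcasts = broadcasts,
      bounds = list(lower = states[[1]]$lower, upper = states[[1]]$upper)
    ),
    class = "vep_fit"
  )
}

#' Run a single enhanced scatter-search worker
#'
#' Hybrid global/local search: a small reference set of high-quality,
#' diverse solutions is combined pairwise, improvements are intensified by
#' the go-beyond rule, and dynamic hill climbing periodically polishes the
#' best unrefined member. Duplicate members (normalized distance below
#' 1e-8) are rejected and prolonged stagnation regenerates the worst half
#' of the reference set.
#'
#' @param cost_fn Cost function `f(theta)` (attribute `stochastic = TRUE`
#'   makes the optimizer draw and record an `eval_seed` per evaluation).
#' @param bounds List with `lower`/`upper` vectors (or a 2-column matrix).
#' @param config A [worker_config()]; `config$seed` seeds the run.
#' @param max_evals Total evaluation budget.
#' @param cost_tol Stop early at this cost.
#'
#' @return A `vep_fit` with the best solution, a non-increasing
#'   best-so-far `trace`, and the full evaluation `archive`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- run_ess(sphere, list(lower = rep(-1, 3), upper = rep(1, 3)),
#'                worker_config(seed = 1), max_evals = 3000)
#' fit$best_cost
run_ess <- function(cost_fn, bounds, config = worker_config(),
                    max_evals = 50000L, cost_tol = -Inf) {
  b <- as_bounds(bounds)
  ev <- new_eval_env(length(b$lower), max_evals, cost_tol)
  set.seed(config$seed)
  st <- ess_init(cost_fn, bounds, config, ev, worker_id = 1L)
  while (!stop_reached(ev)) ess_step(st)
  finish_fit(ev, list(st), NULL,
             broadcasts = empty_broadcasts(),
             scoreboard = data.frame(worker = integer(0), eval = integer(0)))
}

empty_broadcasts <- function() {
  tibble::tibble(eval = integer(0), worker = integer(0), cost = numeric(0),
                 prev_cost = numeric(0), threshold = numeric(0))
}

#' Heterogeneous default worker settings
#'
#' Builds one [worker_config()] per worker with varied reference-set sizes,
#' local-search budgets, triggers, and balance weights (aggressive and
#' conservative mixes), seeded consecutively from `seed`.
#'
#' @param n_workers Number of workers.
#' @param dim Problem dimension (sets the default reference-set size).
#' @param seed Base seed; worker `k` gets `seed + k - 1`.
#' @return A list of `worker_config`s.
#' @export
default_worker_configs <- function(n_workers, dim, seed) {
  base <- 2L * ceiling(sqrt(dim))
  if (base %% 2L == 1L) base <- base + 1L
  lapply(seq_len(n_workers), function(k) {
    worker_config(
      refset_size = max(4L, base + 2L * ((k - 1L) %% 2L)),
      local_search_max_evals = c(2000L, 4000L, 1000L)[(k - 1L) %% 3L + 1L],
      local_search_trigger = c(5L, 3L, 8L)[(k - 1L) %% 3L + 1L],
      balance = c(0.5, 0.3, 0.7)[(k - 1L) %% 3L + 1L],
      seed = seed + (k - 1L)
    )
  })
}

jitter_config <- function(cfg, seed) {
  j <- function(x) max(1L, as.integer(round(x * runif(1, 0.8, 1.2))))
  worker_config(
    refset_size = {
      r <- j(cfg$refset_size %||% 10L)
      r <- max(4L, r)
      if (r %% 2L == 1L) r + 1L else r
    },
    diversification_size = cfg$diversification_size,
    local_search_max_evals = j(cfg$local_search_max_evals),
    local_search_trigger = j(cfg$local_search_trigger),
    balance = min(1, max(0, cfg$balance * runif(1, 0.8, 1.2))),
    restart_after_evals = cfg$restart_after_evals,
    seed = seed
  )
}

#' Run cooperating scatter-search workers
#'
#' Steps several heterogeneous eSS workers round-robin, each on its own
#' random stream. After each step a worker reports its best solution; the
#' master broadcasts it to the other workers (who inject it into their
#' reference sets) only when it beats the last broadcast by more than
#' `improvement_threshold` relatively, and the acceptance is registered on
#' a scoreboard. Workers that go `reconfigure_after_evals` evaluations
#' without an accepted improvement have their settings replaced by a
#' perturbed copy of the current best scorer's settings. With one worker
#' the master never intervenes and the run is identical to [run_ess()].
#'
#' @inheritParams run_ess
#' @param worker_configs Optional list of [worker_config()]s (one per
#'   worker); defaults to a heterogeneous mix seeded from `seed`.
#' @param coop A [cooperation_config()] carrying worker count, thresholds,
#'   and stopping criteria.
#' @param seed Base seed used when `worker_configs` is `NULL` and for the
#'   master's jitter stream.
#'
#' @return A `vep_fit`; `worker_stats` and `broadcasts` record the
#'   cooperation history.
#' @export
run_cooperative <- function(cost_fn, bounds, worker_configs = NULL,
                            coop = cooperation_config(), seed = 1L,
                            init_solutions = NULL, init_workers = NULL) {
  b <- as_bounds(bounds)
  dim <- length(b$lower)
  n_w <- coop$n_workers
  worker_configs <- worker_configs %||% default_worker_configs(n_w, dim, seed)
  stopifnot(length(worker_configs) == n_w)
  ev <- new_eval_env(dim, coop$max_evals_total, coop$cost_tol)

  states <- vector("list", n_w)
  rngs <- vector("list", n_w)
  for (k in seq_len(n_w)) {
    set.seed(worker_configs[[k]]$seed)
    init_k <- if (is.null(init_workers) || k %in% init_workers) {
      init_solutions
    } else {
      NULL
    }
    states[[k]] <- ess_init(cost_fn, bounds, worker_configs[[k]], ev,
                            worker_id = k, init_solutions = init_k)
    rngs[[k]] <- grab_rng()
    if (stop_reached(ev)) break
  }
  states <- states[!vapply(states, is.null, logical(1))]

  set.seed(seed + 999983L)
  master_rng <- grab_rng()

  thr <- coop$improvement_threshold
  last_broadcast <- Inf
  rejections <- 0L
  scoreboard <- data.frame(worker = integer(0), eval = integer(0))
  broadcasts <- empty_broadcasts()
  last_accept_eval <- rep(0L, length(states))
  reported_best <- vapply(states, function(s) min(s$refcost), numeric(1))

  while (!stop_reached(ev) && any(vapply(states, function(s) s$alive,
                                         logical(1)))) {
    for (k in seq_along(states)) {
      st <- states[[k]]
      if (!st$alive) next
      if (stop_reached(ev)) break
      put_rng(rngs[[k]])
      ok <- tryCatch({
        ess_step(st)
        TRUE
      }, error = function(e) {
        if (inherits(e, "vepfit_contract")) stop(e)
        message(sprintf("worker %d failed: %s", st$id, conditionMessage(e)))
        FALSE
      })
      rngs[[k]] <- grab_rng()
      if (!ok) {
        st$alive <- FALSE
        next
      }
      cand_cost <- min(st$refcost)
      if (n_w > 1L && cand_cost < reported_best[k]) {
        reported_best[k] <- cand_cost
        rel_gain <- (last_broadcast - cand_cost) /
          max(abs(last_broadcast), .Machine$double.eps)
        if (!is.finite(last_broadcast) || rel_gain > thr) {
          idx <- which.min(st$refcost)
          theta <- st$refset[idx, ]
          broadcasts <- dplyr::bind_rows(broadcasts, tibble::tibble(
            eval = ev$n, worker = st$id, cost = cand_cost,
            prev_cost = last_broadcast, threshold = thr
          ))
          last_broadcast <- cand_cost
          scoreboard <- rbind(scoreboard,
                              data.frame(worker = st$id, eval = ev$n))
          last_accept_eval[k] <- ev$n
          for (other in seq_along(states)) {
            if (other != k && states[[other]]$alive) {
              inject_solution(states[[other]], theta, cand_cost)
            }
          }
        } else {
          rejections <- rejections + 1L
          if (rejections > 20L) {
            thr <- thr / 2
            rejections <- 0L
          }
        }
      }
      # scoreboard-driven reconfiguration of inactive workers
      if (n_w > 1L &&
          ev$n - last_accept_eval[k] > coop$reconfigure_after_evals) {
        recent <- scoreboard[scoreboard$eval > ev$n - coop$scoreboard_window, ]
        winner <- if (nrow(recent) > 0) {
          as.integer(names(which.max(table(recent$worker))))
        } else {
          which.min(vapply(states, function(s) min(s$refcost), numeric(1)))
        }
        put_rng(master_rng)
        st$config <- jitter_config(states[[winner]]$config,
                                   seed = st$config$seed)
        master_rng <- grab_rng()
        st$stag <- 20L # force partial refset regeneration next step
        last_accept_eval[k] <- ev$n
      }
    }
    if (all(!vapply(states, function(s) s$alive, logical(1)))) {
      abort("all cooperative workers failed")
    }
  }
  finish_fit(ev, states, coop, broadcasts, scoreboard)
}

#' @export
print.vep_fit <- function(x, ...) {
  cat(sprintf(
    "<vep_fit> best cost %.6g after %d evaluations (%d worker%s)\n",
    x$best_cost, x$n_evals, x$n_workers, if (x$n_workers > 1) "s" else ""
  ))
  invisible(x)
}

#' @describeIn run_ess Tidy the fitted parameters: one row per parameter
#'   with its normalized position in the bounds.
#' @param x A `vep_fit`.
#' @param ... Unused.
#' @export
tidy.vep_fit <- function(x, ...) {
  dim <- length(x$best_theta)
  tibble::tibble(
    term = paste0("theta_", seq_len(dim)),
    estimate = x$best_theta,
    normalized = (x$best_theta - x$bounds$lower) /
      (x$bounds$upper - x$bounds$lower)
  )
}

#' @describeIn run_ess One-row summary of the optimization run.
#' @export
glance.vep_fit <- function(x, ...) {
  tibble::tibble(
    best_cost = x$best_cost,
    n_evals = x$n_evals,
    n_workers = x$n_workers,
    n_broadcasts = nrow(x$broadcasts),
    n_archive = nrow(x$archive)
  )
}
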