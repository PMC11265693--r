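# Zone-pair relabeling refinement. Two degeneracies of the rank-deficient
# sensor problems defeat plain coordinate search: (i) weakly observed
# quiescent regions trade excitability levels pairwise at almost no cost,
# parking one of them a zone too high; (ii) an oscillator identity swap,
# where a healthy region seizes in place of the true epileptogenic one and
# the mixture looks similar through the gain. Both are pairwise
# relabelings. Candidate relabelings (single regions and region pairs
# clamped to representative excitability levels) are therefore evaluated,
# and the most promising are re-relaxed with hill climbing: cheap probes
# whose cost is already low get a full descent, and the best probe of each
# pair additionally gets a short screening descent — a swap probe often
# starts worse than the incumbent but descends far below it.
pair_refine <- function(best, best_cost, cost_fn, bounds, n_regions,
                        reps = c(-1.6, -2.25, -2.6, -3.0, -3.5),
                        relax_evals = 3000L, screen_evals = 400L,
                        max_evals = 50000L) {
  evals <- 0L
  improved_any <- TRUE
  while (improved_any && evals < max_evals) {
    improved_any <- FALSE
    probes <- list()
    pcost <- numeric(0)
    psig <- character(0)
    ppair <- character(0)
    add_probe <- function(th, sig, pair_id) {
      probes[[length(probes) + 1L]] <<- th
      pcost[length(pcost) + 1L] <<- cost_fn(th)
      psig[length(psig) + 1L] <<- sig
      ppair[length(ppair) + 1L] <<- pair_id
      evals <<- evals + 1L
    }
    for (r in seq_len(n_regions)) {
      for (v in reps) {
        if (abs(best[r] - v) < 0.3) next
        add_probe(`[<-`(best, r, v), sprintf("%d>%.1f", r, v), sprintf("s%d", r))
      }
    }
    for (r in seq_len(n_regions - 1)) {
      for (s2 in seq(r + 1, n_regions)) {
        for (vr in reps) {
          for (vs in reps) {
            if (abs(best[r] - vr) < 0.3 || abs(best[s2] - vs) < 0.3) next
            th <- best
            th[r] <- vr
            th[s2] <- vs
            add_probe(th, sprintf("%d>%.1f,%d>%.1f", r, vr, s2, vs),
                      sprintf("p%d.%d", r, s2))
          }
        }
      }
    }

    try_descend <- function(k, budget) {
      ls <- dhc_local_search(probes[[k]], cost_fn, bounds,
                             max_evals = budget, start_cost = pcost[k])
      evals <<- evals + ls$evals
      ls
    }

    # full descents on the cheapest distinct relabelings
    seen <- character(0)
    n_full <- 0L
    for (k in order(pcost)) {
      if (n_full >= 3L || evals + relax_evals > max_evals) break
      if (psig[k] %in% seen) next
      seen <- c(seen, psig[k])
      n_full <- n_full + 1L
      ls <- try_descend(k, relax_evals)
      if (ls$cost < best_cost) {
        best <- ls$theta
        best_cost <- ls$cost
        improved_any <- TRUE
        break
      }
    }
    if (improved_any) next

    # screening descents on the best probe of each pair, cheapest pairs first
    pair_best <- vapply(split(seq_along(pcost), ppair),
                        function(ix) ix[which.min(pcost[ix])], integer(1))
    pair_best <- pair_best[order(pcost[pair_best])]
    screened <- integer(0)
    scost <- numeric(0)
    for (k in pair_best) {
      if (evals + screen_evals > max_evals) break
      ls <- try_descend(k, screen_evals)
      screened <- c(screened, k)
      scost <- c(scost, ls$cost)
      if (ls$cost < best_cost) { # screening alone already improved
        best <- ls$theta
        best_cost <- ls$cost
        improved_any <- TRUE
        break
      }
    }
    if (improved_any) next
    for (k in screened[utils::head(order(scost), 2L)]) {
      if (evals + relax_evals > max_evals) break
      ls <- try_descend(k, relax_evals)
      if (ls$cost < best_cost) {
        best <- ls$theta
        best_cost <- ls$cost
        improved_any <- TRUE
        break
      }
    }
  }
  list(theta = best, cost = best_cost, evals = evals)
}

truncate_observed <- function(problem, observed, horizon) {
  keep <- observed$time <= horizon + 1e-9
  obs_h <- observed[keep, , drop = FALSE]
  class(obs_h) <- class(observed)
  p_h <- problem
  p_h$duration <- horizon
  list(problem = p_h, observed = obs_h)
}

#' Calibrate a benchmark problem with the cooperative optimizer
#'
#' High-level driver used by the shipped benchmarks: builds the RMSE cost,
#' runs cooperating scatter-search workers, and (by default) wraps the run
#' in a horizon continuation — the workers first calibrate against the
#' opening fraction of the observation window, where every region still
#' relaxes from the shared initial condition and the cost surface is
#' smooth in all excitabilities, and the best diverse solutions of that
#' stage seed the full-window optimization. A final hill-climbing polish
#' refines the incumbent. All stages share one evaluation budget.
#'
#' @param problem,observed A benchmark pair from [make_problem()].
#' @param n_workers Number of cooperative workers.
#' @param max_evals Total cost-evaluation budget across all stages.
#' @param seed Integer seed for all optimizer randomness.
#' @param cost_tol Early-stop cost on the full-window objective.
#' @param continuation Use the horizon-continuation stage.
#' @param horizon_frac Fraction of the window fitted in the first stage.
#' @param stage1_frac Fraction of the budget spent on the first stage.
#'   Continuation solutions seed only the first worker's reference set, so
#'   the other workers keep an independent inductive bias.
#' @param polish_evals Evaluation cap of the final polish.
#' @param refine Run the zone-pair profile refinement between the global
#'   stage and the final polish (escapes pairwise level trades between
#'   weakly observed quiescent regions).
#'
#' @return A `vep_fit` for the full-window cost (its `archive` contains
#'   only full-window evaluations; continuation evaluations are counted in
#'   `n_evals` and reported in attribute `n_evals_stage1`).
#' @export
fit_problem <- function(problem, observed, n_workers = 2L, max_evals = 2e5,
                        seed = 1L, cost_tol = 1e-8, continuation = TRUE,
                        horizon_frac = 0.3, stage1_frac = 0.15,
                        polish_evals = 10000L, refine = TRUE) {
  fn_full <- make_cost_fn(problem, observed)
  bounds <- problem$bounds
  used1 <- 0L
  init <- NULL

  if (continuation) {
    h <- truncate_observed(problem, observed,
                           horizon = horizon_frac * problem$duration)
    fn_h <- make_cost_fn(h$problem, h$observed)
    stage1 <- run_cooperative(
      fn_h, bounds,
      coop = cooperation_config(
        n_workers = n_workers,
        max_evals_total = as.integer(stage1_frac * max_evals),
        cost_tol = cost_tol
      ),
      seed = seed
    )
    used1 <- stage1$n_evals
    kept <- filter_archive(stage1$archive, rel_threshold = 100,
                           stochastic = problem$stochastic)
    init <- theta_matrix(
      subsample_representative(kept, target_n = 16L, bounds = bounds)
    )
  }

  refine_budget <- if (refine) 60000L else 0L
  budget2 <- max(1000L,
                 as.integer(max_evals - used1 - polish_evals - refine_budget))
  fit <- run_cooperative(
    fn_full, bounds,
    coop = cooperation_config(
      n_workers = n_workers,
      max_evals_total = budget2,
      cost_tol = cost_tol
    ),
    seed = seed + 1000L,
    init_solutions = init,
    init_workers = 1L
  )

  accept_improvement <- function(fit, theta, cost, evals_used) {
    fit$n_evals <- fit$n_evals + evals_used
    if (cost < fit$best_cost) {
      fit$best_theta <- theta
      fit$best_cost <- cost
      extra <- fit$archive[1, ]
      extra[1, seq_along(theta)] <- as.list(theta)
      extra$cost <- cost
      extra$worker <- 0L
      extra$eval <- fit$n_evals
      extra$eval_seed <- NA_integer_
      fit$archive <- dplyr::bind_rows(fit$archive, extra)
      fit$trace <- dplyr::bind_rows(
        fit$trace, tibble::tibble(evals = fit$n_evals, cost = cost)
      )
    }
    fit
  }

  remaining <- max(0L, as.integer(max_evals - used1 - fit$n_evals))
  if (refine && remaining > 20000L && fit$best_cost > cost_tol) {
    rf <- pair_refine(fit$best_theta, fit$best_cost,
                      function(t) fn_full(t), bounds,
                      n_regions = length(fit$best_theta) - 1L,
                      max_evals = min(remaining - polish_evals, 70000L))
    fit <- accept_improvement(fit, rf$theta, rf$cost, rf$evals)
  }

  remaining <- max(0L, as.integer(max_evals - used1 - fit$n_evals))
  if (remaining >= 2L * length(fit$best_theta) && fit$best_cost > cost_tol) {
    pol <- dhc_local_search(
      fit$best_theta, function(t) fn_full(t), bounds,
      max_evals = min(remaining, polish_evals),
      start_cost = fit$best_cost
    )
    fit <- accept_improvement(fit, pol$theta, pol$cost, pol$evals)
  }
  fit$n_evals <- fit$n_evals + used1
  attr(fit, "n_evals_stage1") <- used1
  fit
}
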