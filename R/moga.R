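#' Default protocol search box
#'
#' The experimental envelope of the study: NaOCl 0-1.26 \% w/v,
#' H2O2 0-12.25 \%, HgCl2 0-0.2 \%, immersion time 5-30 min.
#'
#' @return 4 x 2 matrix of `lower` / `upper` bounds, rows named by variable.
#' @export
default_bounds <- function() {
  matrix(c(0, 1.26, 0, 12.25, 0, 0.2, 5, 30), nrow = 4, byrow = TRUE,
         dimnames = list(.var_ids, c("lower", "upper")))
}

#' Multi-objective GA configuration
#'
#' Defaults follow the optimization settings of the study: population 50,
#' crossover fraction 0.8, migration fraction 0.2, at most 400 generations
#' with a 100-generation stall window. Both objectives are minimized
#' (negated disinfection efficiency and negative disinfection effect).
#'
#' @param pop_size individuals per population (>= 4).
#' @param crossover_fraction fraction of offspring created by intermediate
#'   crossover; the remainder are adaptive-feasible mutants.
#' @param migration_fraction fraction exchanged between subpopulations every
#'   `migration_interval` generations; inert when `n_subpops = 1`.
#' @param max_generations hard generation limit.
#' @param stall_generations stop after this many consecutive generations in
#'   which the front's mean crowding spread changes by less than
#'   `stall_tolerance`.
#' @param stall_tolerance spread-change threshold.
#' @param bounds per-variable `[lower, upper]` matrix (raw units).
#' @param seed integer seed; required.
#' @param tournament_k tournament size for parent selection.
#' @param crossover_ratio intermediate-crossover ratio.
#' @param pareto_fraction controlled elitism: at most this fraction of each
#'   population may come from the first non-domination rank during
#'   environmental selection, the remainder being filled from higher ranks.
#'   Keeping dominated individuals alive preserves the diversity needed to
#'   cover fronts that are disconnected in gene space.
#' @param n_subpops number of subpopulations (1 = single population).
#' @param migration_interval generations between ring migrations.
#' @param hybrid_refine run a local goal-attainment polish (Nelder-Mead)
#'   from points spread along the front after the generational loop, the
#'   hybrid-function stage customary in this solver family; all its
#'   evaluations update the front. Skipped when `max_generations` is 0.
#' @param n_refine number of front points used as refinement starts.
#' @param n_explore size of the uniform exploration sample archived at the
#'   start of the hybrid stage; guards against basins of the front whose
#'   gene-space volume is too small for the population to find reliably.
#' @param max_archive archive capacity: on problems with a continuous front
#'   the non-dominated set is unbounded, so the archive is thinned back to
#'   this many members by crowding distance whenever it overflows.
#' @return a `ga_config` list.
#' @export
ga_config <- function(pop_size = 50, crossover_fraction = 0.8,
                      migration_fraction = 0.2, max_generations = 400,
                      stall_generations = 100, stall_tolerance = 1e-4,
                      bounds = default_bounds(), seed, tournament_k = 2,
                      crossover_ratio = 1.0, pareto_fraction = 0.35,
                      n_subpops = 1, migration_interval = 20,
                      hybrid_refine = TRUE, n_refine = 60,
                      n_explore = 20000, max_archive = 4000) {
  if (missing(seed)) stop("an explicit seed is required")
  bounds <- as.matrix(bounds)
  if (is.null(rownames(bounds))) {
    rownames(bounds) <- paste0("g", seq_len(nrow(bounds)))
  }
  stopifnot(pop_size >= 4, crossover_fraction >= 0, crossover_fraction <= 1,
            migration_fraction >= 0, migration_fraction <= 1,
            max_generations >= 0, stall_generations >= 1,
            ncol(bounds) == 2, all(bounds[, 2] > bounds[, 1]))
  structure(list(pop_size = as.integer(pop_size),
                 crossover_fraction = crossover_fraction,
                 migration_fraction = migration_fraction,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 stall_tolerance = stall_tolerance, bounds = bounds,
                 seed = as.integer(seed), tournament_k = as.integer(tournament_k),
                 crossover_ratio = crossover_ratio,
                 pareto_fraction = pareto_fraction,
                 n_subpops = as.integer(n_subpops),
                 migration_interval = as.integer(migration_interval),
                 hybrid_refine = isTRUE(hybrid_refine),
                 n_refine = as.integer(n_refine),
                 n_explore = as.integer(n_explore),
                 max_archive = as.integer(max_archive)),
            class = "ga_config")
}

#' Pareto dominance (minimization)
#'
#' `a` dominates `b` when `a` is no worse in every objective and strictly
#' better in at least one.
#'
#' @param a,b numeric objective vectors of equal length.
#' @return logical scalar.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("objective vectors differ in length")
  all(a <= b) && any(a < b)
}

#' Non-dominated sorting with crowding distances
#'
#' Assigns each point its non-domination rank (rank 1 = the Pareto front of
#' the set; rank k = the front after removing ranks below k) and, within each
#' rank, the crowding distance (boundary points infinite).
#'
#' @param obj n x m matrix of objective values (minimization).
#' @return list with integer `rank` and numeric `crowding`, both length n.
#' @export
non_dominated_sort <- function(obj) {
  obj <- as.matrix(obj)
  if (any(!is.finite(obj))) stop("all individuals must have finite, evaluated objectives")
  n <- nrow(obj)
  dom <- domination_matrix(obj)
  rank <- integer(n)
  remaining <- rep(TRUE, n)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    n_dominators <- colSums(dom[remaining, , drop = FALSE])
    nd <- remaining & n_dominators == 0
    rank[nd] <- r
    remaining <- remaining & !nd
  }
  crowding <- numeric(n)
  for (rr in seq_len(r)) {
    idx <- which(rank == rr)
    crowding[idx] <- crowding_distance(obj[idx, , drop = FALSE])
  }
  list(rank = rank, crowding = crowding)
}

# dom[i, j] is TRUE when point i dominates point j (minimization)
domination_matrix <- function(obj) {
  n <- nrow(obj)
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (m in seq_len(ncol(obj))) {
    le <- le & outer(obj[, m], obj[, m], "<=")
    lt <- lt | outer(obj[, m], obj[, m], "<")
  }
  le & lt
}

crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    d[o[1]] <- d[o[n]] <- Inf
    span <- obj[o[n], m] - obj[o[1], m]
    if (span > 0) {
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (obj[o[3:n], m] - obj[o[1:(n - 2)], m]) / span
    }
  }
  d
}

#' Binary (k-ary) tournament selection
#'
#' Draws `k` individuals uniformly and returns the index of the best by
#' rank, ties broken by larger crowding distance.
#'
#' @param rank,crowding vectors from [non_dominated_sort()].
#' @param k tournament size.
#' @return selected index.
#' @export
tournament_select <- function(rank, crowding, k = 2) {
  n <- length(rank)
  cand <- sample.int(n, min(k, n))
  cand[order(rank[cand], -crowding[cand])][1]
}

#' Intermediate crossover
#'
#' `child = pa + r * ratio * (pb - pa)` with an independent uniform `r` per
#' gene, clamped to the bounds.
#'
#' @param pa,pb parent gene vectors.
#' @param ratio crossover ratio (default 1: child anywhere in the parental
#'   hyper-rectangle).
#' @param bounds per-variable bounds matrix.
#' @return child gene vector.
#' @export
intermediate_crossover <- function(pa, pb, ratio = 1.0, bounds) {
  child <- pa + stats::runif(length(pa)) * ratio * (pb - pa)
  pmin(pmax(child, bounds[, 1]), bounds[, 2])
}

#' Adaptive feasible mutation
#'
#' Perturbs the genes along a random direction with a step proportional to
#' the box size, halving the step until the mutant is feasible; feasibility
#' is guaranteed by construction (the step collapses onto the parent in the
#' worst case). The caller adapts `step` across generations: it shrinks when
#' the search stalls and grows after successful generations.
#'
#' @param x gene vector within bounds.
#' @param bounds per-variable bounds matrix.
#' @param step relative step size (fraction of each variable's range).
#' @return mutant gene vector, always within bounds.
#' @export
adaptive_feasible_mutation <- function(x, bounds, step = 0.1) {
  if (step <= 0) return(x)
  dir <- stats::rnorm(length(x))
  dir <- dir / sqrt(sum(dir^2))
  scale <- step * (bounds[, 2] - bounds[, 1])
  for (i in 1:30) {
    cand <- x + scale * dir
    if (all(cand >= bounds[, 1] & cand <= bounds[, 2])) return(cand)
    scale <- scale / 2
  }
  x
}

# hypervolume (area) dominated by a 2-objective front up to a reference point
hypervolume2 <- function(front, ref) {
  front <- front[front[, 1] <= ref[1] & front[, 2] <= ref[2], , drop = FALSE]
  if (nrow(front) == 0) return(0)
  o <- order(front[, 1], front[, 2])
  front <- front[o, , drop = FALSE]
  hv <- 0
  prev_f2 <- ref[2]
  for (i in seq_len(nrow(front))) {
    if (front[i, 2] < prev_f2) {
      hv <- hv + (ref[1] - front[i, 1]) * (prev_f2 - front[i, 2])
      prev_f2 <- front[i, 2]
    }
  }
  hv
}

# non-dominated, de-duplicated subset of a 2-objective matrix via an
# O(n log n) sweep: sort by (f1, f2), keep strict minima of f2
pareto_filter <- function(obj) {
  n <- nrow(obj)
  keep <- logical(n)
  o <- order(obj[, 1], obj[, 2])
  best_f2 <- Inf
  for (i in o) {
    if (obj[i, 2] < best_f2) {
      keep[i] <- TRUE
      best_f2 <- obj[i, 2]
    }
  }
  keep
}

# bounded-archive thinning: when a continuous front makes the non-dominated
# set arbitrarily large, keep the max_size members with the largest crowding
# distance (extremes always survive, spread is preserved)
thin_front <- function(archive, d, max_size) {
  n <- nrow(archive)
  if (n <= max_size) return(archive)
  cd <- crowding_distance(archive[, d + 1:2, drop = FALSE])
  archive[order(-cd)[seq_len(max_size)], , drop = FALSE]
}

# environmental selection with controlled elitism: rank-1 individuals are
# capped at ceil(pareto_fraction * n); remaining slots go to higher ranks in
# order, partial ranks resolved by crowding distance
controlled_elitist_select <- function(obj, n, pareto_fraction) {
  sc <- non_dominated_sort(obj)
  cap1 <- max(1L, ceiling(pareto_fraction * n))
  keep <- integer(0)
  for (r in sort(unique(sc$rank))) {
    idx <- which(sc$rank == r)
    quota <- if (r == 1L) min(length(idx), cap1, n) else
      min(length(idx), n - length(keep))
    if (quota <= 0) break
    keep <- c(keep, idx[order(-sc$crowding[idx])][seq_len(quota)])
    if (length(keep) >= n) break
  }
  # if capping rank 1 left unfilled slots (few dominated points exist),
  # top up with the best remaining individuals
  if (length(keep) < n) {
    rest <- setdiff(order(sc$rank, -sc$crowding), keep)
    keep <- c(keep, rest[seq_len(n - length(keep))])
  }
  keep[seq_len(n)]
}

#' Run the multi-objective genetic algorithm
#'
#' A controlled-elitist non-dominated-sorting GA over a box-bounded
#' real-coded search space: tournament selection on (rank, crowding),
#' intermediate crossover, adaptive feasible mutation, and elitist
#' environmental selection of the combined parent + offspring population by
#' rank then crowding. An archive of every non-dominated point evaluated so
#' far is maintained; the returned front is the archive's non-dominated set,
#' so front quality never degrades across generations. The run stops at
#' `max_generations` or once the front's mean crowding spread has changed by
#' less than `stall_tolerance` for `stall_generations` consecutive
#' generations.
#'
#' With `n_subpops > 1` the population is split into independent
#' subpopulations with ring migration of the best `migration_fraction`
#' every `migration_interval` generations.
#'
#' @param objective_fn function mapping an n x d gene matrix to an n x 2
#'   matrix of objectives, both minimized.
#' @param config a `ga_config`.
#' @return a `pareto_front`: `solutions` (genes + objectives `f1`, `f2` of
#'   the front), `generations_run`, `stop_reason`
#'   (`"max_generations"` or `"stall"`), and a per-generation `history` of
#'   front size, spread and hypervolume.
#' @export
run_moga <- function(objective_fn, config) {
  stopifnot(inherits(config, "ga_config"))
  with_seed(config$seed, run_moga_impl(objective_fn, config))
}

run_moga_impl <- function(objective_fn, cfg) {
  bounds <- cfg$bounds
  d <- nrow(bounds)
  n_sub <- max(1L, cfg$n_subpops)
  sub_size <- ceiling(cfg$pop_size / n_sub)

  rand_pop <- function(n) {
    sapply(seq_len(d), function(j) stats::runif(n, bounds[j, 1], bounds[j, 2]))
  }
  pops <- lapply(seq_len(n_sub), function(i) {
    g <- rand_pop(sub_size)
    list(genes = g, obj = objective_fn(g))
  })
  archive <- do.call(rbind, lapply(pops, function(p) cbind(p$genes, p$obj)))
  prune_archive <- function(arch) {
    obj <- arch[, d + 1:2, drop = FALSE]
    thin_front(arch[pareto_filter(obj), , drop = FALSE], d, cfg$max_archive)
  }
  archive <- prune_archive(archive)

  ref <- c(max(archive[, d + 1]) + 1, max(archive[, d + 2]) + 1)
  spread_of <- function(arch) {
    cd <- crowding_distance(arch[, d + 1:2, drop = FALSE])
    if (all(!is.finite(cd))) 0 else mean(cd[is.finite(cd)])
  }
  step <- 0.1
  stall <- 0L
  prev_spread <- spread_of(archive)
  history <- data.frame(generation = 0L, front_size = nrow(archive),
                        spread = prev_spread,
                        hypervolume = hypervolume2(archive[, d + 1:2,
                                                           drop = FALSE], ref))
  stop_reason <- "max_generations"
  gen <- 0L
  while (gen < cfg$max_generations) {
    gen <- gen + 1L
    for (s in seq_len(n_sub)) {
      pop <- pops[[s]]
      sc <- non_dominated_sort(pop$obj)
      n <- nrow(pop$genes)
      n_x <- round(cfg$crossover_fraction * n)
      children <- matrix(0, n, d)
      for (i in seq_len(n)) {
        if (i <= n_x) {
          pa <- pop$genes[tournament_select(sc$rank, sc$crowding,
                                            cfg$tournament_k), ]
          pb <- pop$genes[tournament_select(sc$rank, sc$crowding,
                                            cfg$tournament_k), ]
          children[i, ] <- intermediate_crossover(pa, pb, cfg$crossover_ratio,
                                                  bounds)
        } else {
          pa <- pop$genes[tournament_select(sc$rank, sc$crowding,
                                            cfg$tournament_k), ]
          children[i, ] <- adaptive_feasible_mutation(pa, bounds, step)
        }
      }
      child_obj <- objective_fn(children)
      comb_genes <- rbind(pop$genes, children)
      comb_obj <- rbind(pop$obj, child_obj)
      keep <- controlled_elitist_select(comb_obj, n, cfg$pareto_fraction)
      pops[[s]] <- list(genes = comb_genes[keep, , drop = FALSE],
                        obj = comb_obj[keep, , drop = FALSE])
      archive <- prune_archive(rbind(archive, cbind(children, child_obj)))
    }
    if (n_sub > 1 && gen %% cfg$migration_interval == 0) {
      n_mig <- max(1L, round(cfg$migration_fraction * sub_size))
      moved <- lapply(pops, function(p) {
        sc <- non_dominated_sort(p$obj)
        ord <- order(sc$rank, -sc$crowding)
        list(genes = p$genes[ord[seq_len(n_mig)], , drop = FALSE],
             obj = p$obj[ord[seq_len(n_mig)], , drop = FALSE])
      })
      for (s in seq_len(n_sub)) {
        from <- moved[[if (s == 1) n_sub else s - 1]]  # ring: s receives from s-1
        sc <- non_dominated_sort(pops[[s]]$obj)
        worst <- order(sc$rank, -sc$crowding, decreasing = TRUE)[seq_len(n_mig)]
        pops[[s]]$genes[worst, ] <- from$genes
        pops[[s]]$obj[worst, ] <- from$obj
      }
    }
    spread <- spread_of(archive)
    history <- rbind(history,
                     data.frame(generation = gen, front_size = nrow(archive),
                                spread = spread,
                                hypervolume = hypervolume2(
                                  archive[, d + 1:2, drop = FALSE], ref)))
    if (abs(spread - prev_spread) < cfg$stall_tolerance) {
      stall <- stall + 1L
      step <- max(step * 0.95, 1e-4)   # adapt mutation step down when stalled
    } else {
      stall <- 0L
      step <- min(step * 1.05, 0.5)
    }
    prev_spread <- spread
    if (stall >= cfg$stall_generations) {
      stop_reason <- "stall"
      break
    }
  }
  if (cfg$hybrid_refine && gen > 0) {
    archive <- prune_archive(hybrid_refine_front(archive, objective_fn, cfg))
  }
  sol <- as.data.frame(archive)
  names(sol) <- c(rownames(bounds), "f1", "f2")
  structure(list(solutions = sol, generations_run = gen,
                 stop_reason = stop_reason, history = history,
                 config = cfg),
            class = "pareto_front")
}

# local polish of the front: from starts spread along the front, minimize the
# goal-attainment scalarization max_k (f_k(x) - z_k) / w_k (z = the start's
# own objective vector, w = the front's objective spans) with Nelder-Mead,
# genes clamped to the box; every evaluation is returned for archive update
hybrid_refine_front <- function(archive, objective_fn, cfg) {
  bounds <- cfg$bounds
  d <- nrow(bounds)
  range_g <- bounds[, 2] - bounds[, 1]
  prune <- function(a) {
    thin_front(a[pareto_filter(a[, d + 1:2, drop = FALSE]), , drop = FALSE],
               d, cfg$max_archive)
  }
  clamp <- function(x) {
    pmin(pmax(x, matrix(bounds[, 1], nrow(x), d, byrow = TRUE)),
         matrix(bounds[, 2], nrow(x), d, byrow = TRUE))
  }
  # exploration stage: a uniform sample of the box, to seed basins that are
  # optimal only over a small volume and easily missed by the population
  if (cfg$n_explore > 0) {
    ex <- sapply(seq_len(d), function(j)
      stats::runif(cfg$n_explore, bounds[j, 1], bounds[j, 2]))
    archive <- prune(rbind(archive, cbind(ex, objective_fn(ex))))
  }
  for (round in 1:4) {
    # whole-front stochastic polish: jitter every front point with shrinking
    # Gaussian steps, keeping whatever the dominance filter retains
    for (sigma in rep(c(0.05, 0.02, 0.01, 0.004), each = 2)) {
      x <- archive[, seq_len(d), drop = FALSE]
      prop <- clamp(x + matrix(stats::rnorm(length(x)), nrow(x), d) *
                      matrix(sigma * range_g, nrow(x), d, byrow = TRUE))
      archive <- prune(rbind(archive, cbind(prop, objective_fn(prop))))
    }
    # directional goal-attainment descent from starts spread evenly over the
    # front's second-objective range
    n <- nrow(archive)
    ord <- order(archive[, d + 2])
    f2_sorted <- archive[ord, d + 2]
    targets <- seq(f2_sorted[1], f2_sorted[n],
                   length.out = min(cfg$n_refine, n))
    starts <- unique(vapply(targets, function(t)
      which.min(abs(f2_sorted - t)), integer(1)))
    w <- pmax(apply(archive[, d + 1:2, drop = FALSE], 2, function(o)
      diff(range(o))), 1e-8)
    seen <- new.env(parent = emptyenv())
    seen$rows <- vector("list", 0)
    best_gain <- 0
    for (i in starts) {
      z <- archive[ord[i], d + 1:2]
      fn <- function(x) {
        xc <- pmin(pmax(x, bounds[, 1]), bounds[, 2])
        f <- objective_fn(matrix(xc, nrow = 1))
        seen$rows[[length(seen$rows) + 1L]] <- c(xc, f)
        max((f - z) / w) + 1000 * sum(((x - xc) / range_g)^2)
      }
      # descend from the anchor itself and from front neighbours on either
      # side: when the front is disconnected in gene space, the improving
      # basin for an anchor is often reachable only from a neighbour's genes
      for (j in unique(pmin(pmax(c(i, i - 8, i + 8), 1), n))) {
        fit <- try(stats::optim(archive[ord[j], seq_len(d)], fn,
                                method = "Nelder-Mead",
                                control = list(maxit = 80,
                                               parscale = range_g,
                                               warn.1d.NelderMead = FALSE)),
                   silent = TRUE)
        if (!inherits(fit, "try-error")) {
          best_gain <- max(best_gain, -fit$value)
        }
      }
    }
    archive <- prune(rbind(archive, do.call(rbind, seen$rows)))
    # converged: no start could improve both objectives by 1% of their spans
    if (best_gain < 0.01) break
  }
  archive
}

#' Objectives of a candidate protocol under a fitted model
#'
#' Both objectives are minimized: the first is the negated predicted
#' disinfection efficiency, the second the predicted negative disinfection
#' effect.
#'
#' @param genes length-4 vector or n x 4 matrix of protocol variables
#'   (NaOCl, H2O2, HgCl2, time).
#' @param params an `mlp_params`.
#' @param scaler a `minmax_scaler`.
#' @return n x 2 matrix `(-de_pred, nde_pred)`.
#' @export
evaluate_objectives <- function(genes, params, scaler) {
  pred <- predict_treatments(genes, params, scaler)
  cbind(-pred$de_pred, pred$nde_pred)
}

#' Search for Pareto-optimal disinfection protocols
#'
#' Runs [run_moga()] with the network's predictions as the two fitness
#' functions and attaches raw-unit predicted DE / NDE columns plus a
#' single recommended protocol chosen by [select_recommendation()].
#'
#' @param params an `mlp_params`.
#' @param scaler a `minmax_scaler`.
#' @param config a `ga_config`.
#' @return a `pareto_front` whose `solutions` gain `de_pred` / `nde_pred`
#'   columns, plus a `recommendation` element (one solution row).
#' @export
optimize_protocol <- function(params, scaler, config) {
  front <- run_moga(function(g) evaluate_objectives(g, params, scaler), config)
  front$solutions$de_pred <- -front$solutions$f1
  front$solutions$nde_pred <- front$solutions$f2
  front$recommendation <- select_recommendation(front)
  front
}

#' Pick one protocol from a Pareto front
#'
#' Default rule `"ideal_distance"`: min-max scale each objective over the
#' front and return the solution closest (Euclidean) to the ideal point
#' (best value of each objective on the front); ties break toward the lower
#' second objective (lower phytotoxicity).
#'
#' Rule `"target_de"` mirrors the study's stated aim — full disinfection at
#' the least possible damage: among front members within 5\% of the front's
#' best first objective (highest predicted DE), take the one with the lowest
#' second objective.
#'
#' The rule is also pluggable: pass any function taking the objective matrix
#' and returning a row index.
#'
#' @param front a `pareto_front`.
#' @param rule `"ideal_distance"`, `"target_de"`, or a function
#'   `(obj_matrix) -> index`.
#' @return the selected row of `front$solutions`.
#' @export
select_recommendation <- function(front, rule = "ideal_distance") {
  stopifnot(inherits(front, "pareto_front"))
  sol <- front$solutions
  if (nrow(sol) == 0) stop("empty Pareto front")
  if (nrow(sol) == 1) return(sol)
  obj <- as.matrix(sol[, c("f1", "f2")])
  idx <- if (is.function(rule)) {
    rule(obj)
  } else if (identical(rule, "ideal_distance")) {
    scl <- apply(obj, 2, function(o) {
      if (max(o) > min(o)) (o - min(o)) / (max(o) - min(o)) else o * 0
    })
    dist2 <- rowSums(scl^2)  # ideal point is (0, 0) after scaling
    cand <- which(dist2 <= min(dist2) + 1e-12)
    cand[which.min(obj[cand, 2])]
  } else if (identical(rule, "target_de")) {
    span <- max(obj[, 1]) - min(obj[, 1])
    cand <- which(obj[, 1] <= min(obj[, 1]) + 0.05 * span)
    cand[which.min(obj[cand, 2])]
  } else {
    stop("unknown selection rule: ", rule)
  }
  sol[idx, , drop = FALSE]
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("Pareto front: %d solutions after %d generations (%s)\n",
              nrow(x$solutions), x$generations_run, x$stop_reason))
  if (!is.null(x$recommendation)) {
    r <- x$recommendation
    cat(sprintf("  recommended: NaOCl %.3f%%, H2O2 %.3f%%, HgCl2 %.3f%%, %.3f min -> DE %.1f%%, NDE %.1f%%\n",
                r$naocl, r$h2o2, r$hgcl2, r$time, r$de_pred, r$nde_pred))
  }
  invisible(x)
}
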