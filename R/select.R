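
#' Define a budgeted phylogenetic-diversity selection problem
#'
#' The Noah's Ark formulation of cell prioritization: choose at most `cap`
#' candidate leaves, with total cost at most `budget`, maximizing the sum of
#' active branch lengths (Faith's rooted PD). When `anchored = TRUE`
#' (default) the non-candidate leaves of the tree — e.g. reference genomes a
#' placement tool grafted the candidates among — count as already selected,
#' so candidates are scored by the marginal diversity they add to the
#' existing tree.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param costs Named numeric vector: selection cost per candidate leaf
#'   (minutes); `Inf` marks cells excluded from selection (e.g. failed
#'   amplification). Names define the candidate set and must be tip labels.
#' @param budget Total cost budget (same units as `costs`); default `Inf`
#'   (only the cardinality cap binds).
#' @param cap Maximum number of selected leaves.
#' @param anchored Treat non-candidate leaves as pre-selected (default
#'   `TRUE`).
#' @return An object of class `sag_selection_problem`.
#' @export
selection_problem <- function(tree, costs, budget = Inf, cap = length(costs),
                              anchored = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(costs)) || anyNA(names(costs))) {
    stop_invalid("`costs` must be a named vector (names = candidate tip labels)")
  }
  unknown <- setdiff(names(costs), tree$tip.label)
  if (length(unknown) > 0L) {
    stop_invalid(paste0("candidates not in tree: ", paste(unknown, collapse = ", ")))
  }
  if (any(is.na(costs)) || any(costs < 0)) stop_invalid("costs must be >= 0")
  if (budget < 0) stop_invalid("`budget` must be >= 0")
  cap <- check_count(cap, "cap", min = 0L)
  ord <- order(names(costs)) # deterministic lexicographic candidate order
  structure(
    list(tree = tree, costs = costs[ord], budget = budget, cap = cap,
         anchored = anchored),
    class = "sag_selection_problem"
  )
}

# internal: compiled incidence view of a selection problem
compile_problem <- function(problem) {
  stopifnot(inherits(problem, "sag_selection_problem"))
  idx <- pd_index(problem$tree)
  cand <- names(problem$costs)
  anchors <- if (problem$anchored) setdiff(problem$tree$tip.label, cand) else character()
  base_active <- rep(FALSE, length(idx$edge_len))
  for (l in anchors) base_active[idx$tip_edges[[l]]] <- TRUE
  list(
    idx = idx,
    cand = cand,
    costs = unname(problem$costs),
    feasible = is.finite(problem$costs) & problem$costs <= problem$budget,
    cand_edges = idx$tip_edges[cand],
    base_active = base_active,
    base_len = sum(idx$edge_len[base_active]),
    budget = problem$budget,
    cap = problem$cap
  )
}

# internal: assemble a SelectionResult and re-validate its invariants
make_result <- function(problem, cp, chosen_idx, solver, optimal) {
  chosen <- cp$cand[sort(chosen_idx)]
  total_cost <- sum(cp$costs[chosen_idx])
  active <- cp$base_active
  for (i in chosen_idx) active[cp$cand_edges[[i]]] <- TRUE
  res <- structure(
    list(
      chosen = chosen,
      pd = pd_of(problem$tree, chosen),
      objective = sum(cp$idx$edge_len[active]),
      total_cost = total_cost,
      solver = solver,
      optimal = optimal,
      budget = problem$budget,
      cap = problem$cap
    ),
    class = "sag_selection"
  )
  stopifnot(length(res$chosen) <= problem$cap,
            res$total_cost <= problem$budget + 1e-9)
  res
}

#' @export
print.sag_selection <- function(x, ...) {
  cat(sprintf("<sag_selection> %s: %d leaves, pd = %.6g, objective = %.6g, cost = %.6g%s\n",
              x$solver, length(x$chosen), x$pd, x$objective, x$total_cost,
              if (x$optimal) " (optimal)" else ""))
  invisible(x)
}

#' @export
tidy.sag_selection <- function(x, ...) {
  tibble(leaf = x$chosen, rank = seq_along(x$chosen))
}

#' @export
glance.sag_selection <- function(x, ...) {
  tibble(n_chosen = length(x$chosen), pd = x$pd, objective = x$objective,
         total_cost = x$total_cost, solver = x$solver, optimal = x$optimal,
         budget = x$budget, cap = x$cap)
}

#' Exhaustive (oracle) solver for small selection problems
#'
#' Enumerates every feasible candidate subset. Intended as the correctness
#' oracle for [solve_exact()]; refuses more than 20 candidates.
#'
#' @param problem A [selection_problem()].
#' @return A `sag_selection` with `solver = "bruteforce"`, `optimal = TRUE`.
#'   Ties in the objective are broken toward the lexicographically smallest
#'   chosen set.
#' @export
solve_bruteforce <- function(problem) {
  cp <- compile_problem(problem)
  n <- length(cp$cand)
  if (n > 20L) stop_invalid("brute force refuses > 20 candidates; use solve_exact()")
  # enumerate all 2^n subsets at once via the edge/leaf incidence matrix;
  # columns in descending-mask order == include-earliest-first, so the first
  # maximum (which.max) is the lexicographically smallest optimal set
  n_edges <- length(cp$idx$edge_len)
  M <- matrix(0, n_edges, n)
  for (i in seq_len(n)) M[cp$cand_edges[[i]], i] <- 1
  masks <- (2^n - 1):0
  X <- vapply(masks, function(m) {
    as.numeric(bitwAnd(as.integer(m), bitwShiftL(1L, (n - 1L):0L)) != 0L)
  }, numeric(n))
  X <- matrix(X, nrow = n)
  active <- (M %*% X) > 0 | cp$base_active
  obj <- as.numeric(crossprod(cp$idx$edge_len, active))
  sizes <- colSums(X)
  fin_costs <- ifelse(cp$feasible, cp$costs, 0) # infeasible columns die below
  cost <- as.numeric(crossprod(fin_costs, X))
  bad <- sizes > cp$cap |
    colSums(X[!cp$feasible, , drop = FALSE]) > 0 |
    cost > cp$budget
  obj[bad] <- -Inf
  best_col <- which.max(obj)
  best <- which(X[, best_col] > 0)
  make_result(problem, cp, best, "bruteforce", TRUE)
}

# internal greedy sweep; mode "gain" or "density"
greedy_sweep <- function(cp, mode) {
  active <- cp$base_active
  chosen <- integer()
  cost_used <- 0
  avail <- which(cp$feasible)
  while (length(chosen) < cp$cap && length(avail) > 0L) {
    gains <- vapply(avail, function(i) {
      e <- cp$cand_edges[[i]]
      sum(cp$idx$edge_len[e[!active[e]]])
    }, numeric(1))
    ok <- cp$costs[avail] <= cp$budget - cost_used + 1e-12
    if (!any(ok)) break
    score <- if (mode == "density") {
      ifelse(cp$costs[avail] > 0, gains / cp$costs[avail], Inf)
    } else {
      gains
    }
    score[!ok] <- -Inf
    pick <- avail[which.max(score)] # which.max: first (lex-smallest) on ties
    chosen <- c(chosen, pick)
    cost_used <- cost_used + cp$costs[pick]
    active[cp$cand_edges[[pick]]] <- TRUE
    avail <- setdiff(avail, pick)
  }
  chosen
}

#' Greedy heuristic for the selection problem
#'
#' Two sweeps — marginal PD gain per unit cost, then plain marginal PD gain —
#' each adding the best feasible candidate until the budget or cap is
#' exhausted; the better of the two selections is returned. PD is monotone
#' submodular, so with uniform costs the greedy selection is guaranteed at
#' least a (1 - 1/e) fraction of the optimum.
#'
#' @param problem A [selection_problem()].
#' @return A `sag_selection` with `solver = "greedy"`, `optimal = FALSE`.
#' @export
solve_greedy <- function(problem) {
  cp <- compile_problem(problem)
  pick_obj <- function(chosen) {
    active <- cp$base_active
    for (i in chosen) active[cp$cand_edges[[i]]] <- TRUE
    sum(cp$idx$edge_len[active])
  }
  s1 <- greedy_sweep(cp, "density")
  s2 <- greedy_sweep(cp, "gain")
  best <- if (pick_obj(s2) > pick_obj(s1)) s2 else s1
  make_result(problem, cp, best, "greedy", FALSE)
}

#' Exact solver: branch-and-bound over the selection integer program
#'
#' Maximizes the sum of active branch lengths subject to the cost budget and
#' cardinality cap. With an infinite budget the problem reduces to PD
#' maximization under a pure cardinality constraint, which the greedy
#' algorithm solves to optimality on trees; otherwise a best-bound
#' depth-first branch-and-bound over candidate leaves is used, pruning with
#' the tighter of a submodular top-k bound and a fractional-knapsack bound.
#' Ties are broken toward the lexicographically smallest chosen leaf set.
#'
#' @param problem A [selection_problem()] (intended for up to ~200
#'   candidates).
#' @return A `sag_selection` with `solver = "exact"`, `optimal = TRUE`.
#' @export
solve_exact <- function(problem) {
  cp <- compile_problem(problem)
  n <- length(cp$cand)

  if (!is.finite(cp$budget)) {
    # cardinality-only PD maximization: greedy is exactly optimal on trees
    chosen <- greedy_sweep(cp, "gain")
    return(make_result(problem, cp, chosen, "exact", TRUE))
  }

  best_obj <- -Inf
  best <- integer()
  elen <- cp$idx$edge_len

  bound_from <- function(i, active, obj, cost_used, n_used) {
    rem <- i:n
    rem <- rem[cp$feasible[rem] & cp$costs[rem] <= cp$budget - cost_used + 1e-12]
    if (length(rem) == 0L) return(obj)
    gains <- vapply(rem, function(j) {
      e <- cp$cand_edges[[j]]
      sum(elen[e[!active[e]]])
    }, numeric(1))
    r_cap <- cp$cap - n_used
    # submodular bound: top r_cap individual marginal gains
    b1 <- sum(head(sort(gains, decreasing = TRUE), r_cap))
    # fractional knapsack bound on the remaining budget
    costs <- cp$costs[rem]
    dens <- ifelse(costs > 0, gains / costs, Inf)
    ord <- order(-dens)
    budget_left <- cp$budget - cost_used
    b2 <- 0
    for (j in ord) {
      if (budget_left <= 0) break
      take <- min(1, budget_left / max(costs[j], 1e-300))
      b2 <- b2 + take * gains[j]
      budget_left <- budget_left - take * costs[j]
    }
    obj + min(b1, b2)
  }

  rec <- function(i, chosen, active, obj, cost_used) {
    if (obj > best_obj) {
      best_obj <<- obj
      best <<- chosen
    }
    if (i > n || length(chosen) >= cp$cap) return()
    if (bound_from(i, active, obj, cost_used, length(chosen)) <= best_obj) return()
    # include branch first: DFS then finds lexicographically smaller sets first
    if (cp$feasible[i] && cost_used + cp$costs[i] <= cp$budget + 1e-12) {
      e <- cp$cand_edges[[i]]
      new_e <- e[!active[e]]
      active2 <- active
      active2[new_e] <- TRUE
      rec(i + 1L, c(chosen, i), active2, obj + sum(elen[new_e]),
          cost_used + cp$costs[i])
    }
    rec(i + 1L, chosen, active, obj, cost_used)
  }
  rec(1L, integer(), cp$base_active, cp$base_len, 0)
  make_result(problem, cp, best, "exact", TRUE)
}

#' Re-validate a selection result against its problem
#'
#' Recomputes PD, objective, total cost and cardinality from scratch and
#' checks them against the stored values.
#'
#' @param problem The [selection_problem()] the result came from.
#' @param result A `sag_selection`.
#' @return `TRUE` invisibly; errors if any invariant fails.
#' @export
validate_selection <- function(problem, result) {
  cp <- compile_problem(problem)
  idx <- match(result$chosen, cp$cand)
  stopifnot(!anyNA(idx))
  redo <- make_result(problem, cp, idx, result$solver, result$optimal)
  stopifnot(
    abs(redo$pd - result$pd) < 1e-9,
    abs(redo$objective - result$objective) < 1e-9,
    abs(redo$total_cost - result$total_cost) < 1e-9,
    length(result$chosen) <= problem$cap,
    result$total_cost <= problem$budget + 1e-9,
    all(is.finite(problem$costs[result$chosen]))
  )
  invisible(TRUE)
}
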