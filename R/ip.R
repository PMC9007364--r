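
#' Build the selection integer program
#'
#' Constructs the bipartite leaf/branch formulation of the budgeted
#' phylogenetic-diversity problem as a solver-agnostic object: one binary
#' variable \eqn{x_l} per candidate leaf, one binary variable \eqn{y_e} per
#' tree edge not already active through anchored leaves, objective
#' \eqn{\max \sum_e len(e) y_e}, and constraints
#' \itemize{
#'   \item \eqn{y_e \le \sum_{l \; under \; e} x_l} for every edge (an edge
#'     is active only if some selected leaf lies below it),
#'   \item \eqn{\sum_l cost_l x_l \le B} (budget, omitted when infinite),
#'   \item \eqn{\sum_l x_l \le k} (cardinality cap).
#' }
#' Edges active through anchored leaves enter the objective as the constant
#' `objective_constant`.
#'
#' @param problem A [selection_problem()] with a nonempty finite-cost
#'   candidate set.
#' @return An object of class `sag_ip`: list with `var_names`, `n_x`, `n_y`,
#'   `objective` (coefficient vector), `objective_constant`, `constraints`
#'   (list of `list(coef, dir, rhs)` with dense coefficient vectors), and the
#'   candidate bookkeeping needed to map a solution back to leaves.
#' @export
build_ip <- function(problem) {
  cp <- compile_problem(problem)
  keep <- cp$feasible
  if (!any(keep)) stop_invalid("no finite-cost candidate within budget")
  cand <- cp$cand[keep]
  costs <- cp$costs[keep]
  cand_edges <- cp$cand_edges[keep]
  free_edges <- which(!cp$base_active) # edges not already active
  n_x <- length(cand)
  n_y <- length(free_edges)
  ypos <- setNames(seq_len(n_y) + n_x, free_edges)

  obj <- c(rep(0, n_x), cp$idx$edge_len[free_edges])
  cons <- vector("list", n_y + 2L)
  ci <- 0L
  # leaves-under-edge incidence, restricted to free edges
  for (j in seq_len(n_y)) {
    e <- free_edges[j]
    under <- which(vapply(cand_edges, function(p) e %in% p, logical(1)))
    coef <- rep(0, n_x + n_y)
    coef[n_x + j] <- 1
    coef[under] <- -1
    ci <- ci + 1L
    cons[[ci]] <- list(coef = coef, dir = "<=", rhs = 0)
  }
  if (is.finite(problem$budget)) {
    ci <- ci + 1L
    cons[[ci]] <- list(coef = c(costs, rep(0, n_y)), dir = "<=",
                       rhs = problem$budget)
  }
  ci <- ci + 1L
  cons[[ci]] <- list(coef = c(rep(1, n_x), rep(0, n_y)), dir = "<=",
                     rhs = problem$cap)
  structure(
    list(
      var_names = c(paste0("x_", cand), paste0("y_", free_edges)),
      n_x = n_x, n_y = n_y,
      candidates = cand, costs = setNames(costs, cand),
      objective = obj,
      objective_constant = cp$base_len,
      constraints = cons[seq_len(ci)]
    ),
    class = "sag_ip"
  )
}

#' @export
print.sag_ip <- function(x, ...) {
  cat(sprintf("<sag_ip> %d leaf vars + %d edge vars, %d constraints, max <len, y> + %.6g\n",
              x$n_x, x$n_y, length(x$constraints), x$objective_constant))
  invisible(x)
}

#' Linear-programming relaxation bound of a selection IP
#'
#' Solves the LP relaxation (all variables in `[0, 1]`) with the simplex
#' method and returns the optimal value including the anchored-edge constant.
#' This value is an upper bound on the integer optimum.
#'
#' @param ip A `sag_ip` from [build_ip()].
#' @return The LP optimum (numeric scalar).
#' @export
ip_lp_bound <- function(ip) {
  stopifnot(inherits(ip, "sag_ip"))
  nv <- ip$n_x + ip$n_y
  A1 <- do.call(rbind, purrr::map(ip$constraints, "coef"))
  b1 <- vapply(ip$constraints, function(c) c$rhs, numeric(1))
  # box constraints: variables <= 1 (>= 0 is implicit in the simplex form)
  A1 <- rbind(A1, diag(nv))
  b1 <- c(b1, rep(1, nv))
  sol <- boot::simplex(a = ip$objective, A1 = A1, b1 = b1, maxi = TRUE)
  sol$value + ip$objective_constant
}
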