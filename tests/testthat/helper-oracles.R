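# Independent brute-force oracles for the LP and QP solvers.
#
# Both enumerate sign patterns: every variable is either free, pinned at
# its lower bound, or pinned at its upper bound (3^n patterns).  The
# optimum of a bounded LP sits at a vertex, and the strictly convex QP
# optimum equals the equality-constrained minimizer over the affine hull
# of its active face, so the best primal-feasible candidate over all
# patterns is the exact optimum.  Deliberately naive and entirely
# independent of the package's simplex and of quadprog.

.oracle_patterns <- function(n) {
  grid <- do.call(expand.grid, rep(list(c("free", "lb", "ub")), n))
  lapply(seq_len(nrow(grid)), function(i) as.character(unlist(grid[i, ])))
}

# max c'v  s.t.  S v = 0, lb <= v <= ub   (finite bounds)
lp_vertex_oracle <- function(cvec, S, lb, ub, tol = 1e-7) {
  n <- length(cvec)
  best <- -Inf
  feasible <- FALSE
  for (pat in .oracle_patterns(n)) {
    fixed <- pat != "free"
    v <- numeric(n)
    v[pat == "lb"] <- lb[pat == "lb"]
    v[pat == "ub"] <- ub[pat == "ub"]
    if (any(!fixed)) {
      Sf <- S[, !fixed, drop = FALSE]
      if (qr(Sf)$rank < sum(!fixed)) next   # not a vertex pattern
      rhs <- -S[, fixed, drop = FALSE] %*% v[fixed]
      sol <- qr.coef(qr(Sf), rhs)
      if (anyNA(sol)) next
      v[!fixed] <- sol
    }
    if (max(abs(S %*% v)) > tol) next
    if (any(v < lb - tol) || any(v > ub + tol)) next
    feasible <- TRUE
    best <- max(best, sum(cvec * v))
  }
  if (!feasible) list(status = "infeasible", objective = NA_real_)
  else list(status = "optimal", objective = best)
}

# min sum((v - vref)^2)  s.t.  S v = 0, extra equalities, lb <= v <= ub
qp_kkt_oracle <- function(vref, S, lb, ub, fix_idx = integer(),
                          fix_val = numeric(), tol = 1e-7) {
  n <- length(vref)
  Aex <- matrix(0, length(fix_idx), n)
  if (length(fix_idx)) Aex[cbind(seq_along(fix_idx), fix_idx)] <- 1
  A_all <- rbind(S, Aex)
  b_all <- c(rep(0, nrow(S)), fix_val)
  best <- Inf
  feasible <- FALSE
  for (pat in .oracle_patterns(n)) {
    fixed <- pat != "free"
    v <- numeric(n)
    v[pat == "lb"] <- lb[pat == "lb"]
    v[pat == "ub"] <- ub[pat == "ub"]
    if (any(!fixed)) {
      A <- A_all[, !fixed, drop = FALSE]
      cc <- b_all - (if (any(fixed))
        A_all[, fixed, drop = FALSE] %*% v[fixed] else 0)
      # min ||v_F - vref_F||^2 s.t. A v_F = cc  (minimum-norm correction)
      Ap <- MASS::ginv(A)
      vf <- vref[!fixed] - Ap %*% (A %*% vref[!fixed] - cc)
      if (max(abs(A %*% vf - cc)) > tol) next    # inconsistent system
      v[!fixed] <- vf
    } else {
      if (max(abs(A_all %*% v - b_all)) > tol) next
    }
    if (any(v < lb - tol) || any(v > ub + tol)) next
    feasible <- TRUE
    best <- min(best, sum((v - vref)^2))
  }
  if (!feasible) list(status = "infeasible", distance_sq = NA_real_)
  else list(status = "optimal", distance_sq = best)
}

# random bounded LP instance drawn through the package generator
random_lp_instance <- function(seed, n_reactions = NULL) {
  if (is.null(n_reactions)) n_reactions <- 3 + (seed %% 4)  # 3..6
  m <- random_toy_model(n_reactions = n_reactions, seed = seed)
  list(model = m,
       S = stoich_matrix(m),
       lb = flux_bounds(m)[, "lower"],
       ub = flux_bounds(m)[, "upper"],
       cvec = as.numeric(reaction_ids(m) == m$objective_id))
}
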