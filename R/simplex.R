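# Dense bounded-variable primal simplex with Bland's rule.
#
# Solves    max/min  c'x   s.t.  A x = b,  lb <= x <= ub
# via a two-phase method: phase I minimizes the sum of artificial
# variables, phase II optimizes c over the feasible basis.  Bland's
# smallest-index rule guarantees finite termination; all pivots use a
# fresh dense factorization of the basis, which is appropriate for the
# desk-scale networks this package targets (tens of reactions).
#
# Nonbasic variables sit at a finite bound, or at zero when free in both
# directions.  Infinite bounds are honoured, so genuinely unbounded
# programs are reported as such rather than truncated.

.lp_tol <- 1e-9

# returns list(status = "optimal"|"infeasible"|"unbounded", x, objective)
.simplex_bounded <- function(cvec, A, b, lb, ub, maximize = TRUE,
                             max_iter = 20000L) {
  if (!maximize) {
    r <- .simplex_bounded(-cvec, A, b, lb, ub, TRUE, max_iter)
    if (r$status == "optimal") r$objective <- -r$objective
    return(r)
  }
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cvec) == n,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + .lp_tol))
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))

  # start nonbasic variables at the finite bound closest to zero
  start_val <- function(j) {
    if (is.finite(lb[j]) && is.finite(ub[j])) {
      if (abs(lb[j]) <= abs(ub[j])) lb[j] else ub[j]
    } else if (is.finite(lb[j])) lb[j]
    else if (is.finite(ub[j])) ub[j]
    else 0
  }
  nb_state <- function(j, v) {
    if (is.finite(lb[j]) && abs(v - lb[j]) < .lp_tol) "lb"
    else if (is.finite(ub[j]) && abs(v - ub[j]) < .lp_tol) "ub"
    else "free"
  }

  ntot <- n + m                     # real + artificial
  lb_t <- c(lb, rep(0, m))
  ub_t <- c(ub, rep(Inf, m))
  x <- numeric(ntot)
  for (j in seq_len(n)) x[j] <- start_val(j)
  resid <- b - A %*% x[seq_len(n)]
  art_sign <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(as.vector(art_sign), nrow = m, ncol = m))
  x[n + seq_len(m)] <- abs(resid)
  basis <- n + seq_len(m)
  state <- character(ntot)          # nonbasic state for non-basis vars
  for (j in seq_len(n)) state[j] <- nb_state(j, x[j])

  run_phase <- function(obj, x, basis, state, phase1) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        stop("simplex iteration limit reached (", max_iter, ")")
      B <- Afull[, basis, drop = FALSE]
      Binv_t <- tryCatch(solve(t(B)), error = function(e) NULL)
      if (is.null(Binv_t))
        stop("simplex: singular basis encountered")
      y <- Binv_t %*% obj[basis]                 # duals
      nonbasic <- setdiff(seq_len(ntot), basis)
      entering <- 0L; direction <- 0
      for (j in nonbasic) {                      # Bland: smallest index
        if (phase1 == FALSE && j > n) next       # artificials locked out
        if (ub_t[j] - lb_t[j] < .lp_tol) next    # fixed variable cannot move
        dj <- obj[j] - sum(y * Afull[, j])
        if (state[j] %in% c("lb", "free") && dj > .lp_tol) {
          entering <- j; direction <- 1; break
        }
        if (state[j] %in% c("ub", "free") && dj < -.lp_tol) {
          entering <- j; direction <- -1; break
        }
      }
      if (entering == 0L) {
        return(list(x = x, basis = basis, state = state,
                    objective = sum(obj * x), status = "optimal"))
      }
      d_B <- -solve(B, Afull[, entering]) * direction
      # ratio test: how far can x[entering] move in 'direction'?
      t_max <- Inf; leaving <- 0L; leave_to <- ""
      # entering variable's own opposite bound
      own_cap <- if (direction > 0) ub_t[entering] - x[entering]
                 else x[entering] - lb_t[entering]
      if (is.finite(own_cap) && own_cap < t_max - .lp_tol * 0) {
        t_max <- own_cap; leaving <- -1L
      }
      better <- function(cap, i) {
        # strict improvement, or tie broken by smaller variable index (Bland)
        cap < t_max - 1e-12 ||
          (cap < t_max + 1e-12 && leaving > 0L && basis[i] < basis[leaving])
      }
      for (i in seq_along(basis)) {
        bi <- basis[i]
        if (d_B[i] > .lp_tol && is.finite(ub_t[bi])) {
          cap <- (ub_t[bi] - x[bi]) / d_B[i]
          if (better(cap, i)) { t_max <- cap; leaving <- i; leave_to <- "ub" }
        } else if (d_B[i] < -.lp_tol && is.finite(lb_t[bi])) {
          cap <- (lb_t[bi] - x[bi]) / d_B[i]
          if (better(cap, i)) { t_max <- cap; leaving <- i; leave_to <- "lb" }
        }
      }
      if (!is.finite(t_max))
        return(list(x = x, basis = basis, state = state,
                    objective = Inf, status = "unbounded"))
      t_max <- max(t_max, 0)
      x[entering] <- x[entering] + direction * t_max
      x[basis] <- x[basis] + d_B * t_max
      if (leaving == -1L) {
        # bound flip: entering stays nonbasic at its other bound
        state[entering] <- if (direction > 0) "ub" else "lb"
      } else {
        out <- basis[leaving]
        state[out] <- leave_to
        x[out] <- if (leave_to == "ub") ub_t[out] else lb_t[out]
        basis[leaving] <- entering
        state[entering] <- ""
      }
    }
  }

  # phase I: minimize sum of artificials (maximize the negative)
  obj1 <- c(rep(0, n), rep(-1, m))
  r1 <- run_phase(obj1, x, basis, state, phase1 = TRUE)
  if (r1$status != "optimal" || -r1$objective > 1e-7)
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_))
  # lock artificials at zero and run phase II on the real objective
  ub_t[n + seq_len(m)] <- 0
  lb_t[n + seq_len(m)] <- 0
  x <- r1$x; x[n + seq_len(m)] <- pmin(pmax(x[n + seq_len(m)], 0), 0)
  state <- r1$state
  for (j in (n + seq_len(m))) if (!(j %in% r1$basis)) state[j] <- "lb"
  obj2 <- c(cvec, rep(0, m))
  r2 <- run_phase(obj2, x, r1$basis, state, phase1 = FALSE)
  if (r2$status == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objective = Inf))
  xx <- r2$x[seq_len(n)]
  # snap tiny bound violations from floating-point pivots
  xx <- pmin(pmax(xx, lb - 1e-9), ub + 1e-9)
  list(status = "optimal", x = xx, objective = sum(cvec * xx))
}
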