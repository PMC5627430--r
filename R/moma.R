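# Minimization of metabolic adjustment: quadratic program minimizing the
# squared Euclidean distance to a reference flux distribution subject to
# steady state, bounds and perturbation constraints.

# Solve  min 1/2 sum(Dvec_i x_i^2) - dvec'x  s.t. Aeq x = beq, lb <= x <= ub.
#
# The equalities are eliminated first: an SVD of Aeq yields a particular
# solution x0 (anchored at the unconstrained minimizer, so the reduced
# problem is well scaled) and an orthonormal null-space basis N; the
# box-constrained QP in the reduced coordinates x = x0 + N z is then
# handed to quadprog (Goldfarb-Idnani dual active set).  Working in the
# null space keeps every iterate exactly on the steady-state subspace,
# which both polishes the solution and avoids the spurious
# "constraints are inconsistent" failures quadprog exhibits when
# degenerate equalities are passed through meq.
# Dvec may be a vector (diagonal Hessian) or a full positive-definite
# matrix.
.solve_qp_box <- function(Dvec, dvec, Aeq, beq, lb, ub, tol = 1e-8) {
  diagD <- !is.matrix(Dvec)
  n <- if (diagD) length(Dvec) else nrow(Dvec)
  # variables pinned by lb == ub become equality rows: the opposed
  # inequality pair would be degenerate for the dual active-set method
  pinned <- which(is.finite(lb) & is.finite(ub) & ub - lb < 1e-12)
  if (length(pinned)) {
    E <- matrix(0, length(pinned), n)
    E[cbind(seq_along(pinned), pinned)] <- 1
    Aeq <- rbind(Aeq, E)
    beq <- c(beq, (lb[pinned] + ub[pinned]) / 2)
    lb[pinned] <- -Inf
    ub[pinned] <- Inf
  }
  xc <- if (diagD) dvec / Dvec else solve(Dvec, dvec)  # unconstrained minimizer
  if (is.null(Aeq) || nrow(Aeq) == 0) {
    if (!diagD) stop("unconstrained dense-Hessian case not used")
    x <- pmin(pmax(xc, lb), ub)           # separable box projection
    return(list(status = "optimal", x = x))
  }
  sv <- svd(Aeq, nu = nrow(Aeq), nv = n)
  pos <- sv$d > max(sv$d[1], 1) * 1e-12
  r <- sum(pos)
  # particular solution closest to the unconstrained minimizer
  res0 <- as.numeric(Aeq %*% xc - beq)
  corr <- sv$v[, seq_len(r), drop = FALSE] %*%
    ((crossprod(sv$u[, seq_len(r), drop = FALSE], res0)) / sv$d[seq_len(r)])
  x0 <- xc - as.numeric(corr)
  if (max(abs(Aeq %*% x0 - beq)) > tol * (1 + max(abs(beq))))
    return(list(status = "infeasible", x = rep(NA_real_, n)))
  if (r == n) {                           # unique point; check the box
    if (any(x0 < lb - tol) || any(x0 > ub + tol))
      return(list(status = "infeasible", x = rep(NA_real_, n)))
    return(list(status = "optimal", x = x0))
  }
  N <- sv$v[, (r + 1):n, drop = FALSE]
  Dz <- if (diagD) crossprod(N, N * Dvec) else crossprod(N, Dvec %*% N)
  Dz <- (Dz + t(Dz)) / 2                  # positive definite by construction
  Dx0 <- if (diagD) Dvec * x0 else as.numeric(Dvec %*% x0)
  dz <- as.numeric(crossprod(N, dvec - Dx0))
  rows <- list(); rhs <- numeric(0)
  push <- function(a, b) {
    # a'z >= b; variables outside the null space give a ~ 0: such a row
    # is either trivially satisfied or proves infeasibility outright
    nrm <- sqrt(sum(a^2))
    if (nrm < 1e-10) {
      if (b > tol) rows[[1L]] <<- NA      # sentinel: infeasible
      return(invisible())
    }
    rows[[length(rows) + 1L]] <<- a / nrm
    rhs <<- c(rhs, b / nrm)
  }
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) push(N[j, ], lb[j] - x0[j])
    if (is.finite(ub[j])) push(-N[j, ], x0[j] - ub[j])
  }
  if (length(rows) && identical(rows[[1L]], NA))
    return(list(status = "infeasible", x = rep(NA_real_, n)))
  if (!length(rows)) {
    z <- solve(Dz, dz)
    return(list(status = "optimal", x = x0 + as.numeric(N %*% z)))
  }
  Amat <- t(do.call(rbind, rows))
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = Dz, dvec = dz, Amat = Amat, bvec = rhs),
    error = function(e) e)
  if (inherits(sol, "error")) {
    if (grepl("inconsistent|no solution", conditionMessage(sol)))
      return(list(status = "infeasible", x = rep(NA_real_, n)))
    stop("QP solver failure: ", conditionMessage(sol))
  }
  list(status = "optimal", x = x0 + as.numeric(N %*% sol$solution))
}

#' Minimization of metabolic adjustment (MOMA)
#'
#' Given a perturbed network, finds the feasible flux vector closest (in
#' squared Euclidean distance, optionally weighted) to a wild-type
#' reference.  The perturbation is expressed as bound edits and/or
#' flux-fixing equality constraints; for an overexpression scan the
#' latter imposes `v_j = k * v_ref_j`.
#'
#' @param model A [metabolic_model()].
#' @param reference A `flux_distribution` (from [fba()] or
#'   [reference_flux()]) or a named numeric vector covering every model
#'   reaction.
#' @param perturbation Optional [bound_edits()] data frame.
#' @param fix Optional named numeric vector of equality flux constraints.
#' @param weights Optional positive weights per reaction (named, or in
#'   model order); the distance is `sum(w * (v - v_ref)^2)`.  Default 1.
#' @return A `moma_solution` (inherits `flux_distribution`) with fields
#'   `fluxes`, `distance_sq`, `objective_value` (flux through the model
#'   objective) and `status`.  An infeasible perturbation is signalled by
#'   `status = "infeasible"`, not by an error, so scans can skip it.
#' @export
#' @examples
#' m <- make_core_ascomycin_toy()
#' ref <- reference_flux(m)
#' sol <- moma(m, ref, fix = c(CCCR = 2 * ref$fluxes[["CCCR"]]))
#' sol$distance_sq
moma <- function(model, reference, perturbation = NULL, fix = NULL,
                 weights = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  vref <- if (inherits(reference, "flux_distribution")) reference$fluxes
          else reference
  ids <- reaction_ids(model)
  if (!all(ids %in% names(vref)))
    stop("reference does not cover all model reactions: missing ",
         paste(utils::head(setdiff(ids, names(vref)), 5), collapse = ", "))
  vref <- as.numeric(vref[ids])
  n <- length(ids)
  w <- if (is.null(weights)) rep(1, n)
       else if (!is.null(names(weights))) {
         stopifnot(all(ids %in% names(weights)))
         as.numeric(weights[ids])
       } else as.numeric(weights)
  stopifnot(length(w) == n, all(w > 0))
  S <- stoich_matrix(model)
  bb <- flux_bounds(model)
  ab <- .apply_bounds(model, bb[, "lower"], bb[, "upper"], perturbation, NULL)
  lb <- ab$lb; ub <- ab$ub
  Aeq <- S; beq <- rep(0, nrow(S))
  if (!is.null(fix) && length(fix)) {
    unknown <- setdiff(names(fix), ids)
    if (length(unknown))
      stop("perturbation fixes unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    for (j in names(fix)) {
      e <- numeric(n); e[match(j, ids)] <- 1
      Aeq <- rbind(Aeq, e)
      beq <- c(beq, fix[[j]])
    }
  }
  # objective: min sum w (v - vref)^2 = 1/2 v'(2w)v - (2 w vref)'v + const
  qp <- .solve_qp_box(Dvec = 2 * w, dvec = 2 * w * vref,
                      Aeq = Aeq, beq = beq, lb = lb, ub = ub)
  if (qp$status != "optimal") {
    out <- .new_flux_distribution(model, rep(NA_real_, n), NA_real_,
                                  "infeasible", method = "moma")
    out$distance_sq <- NA_real_
    class(out) <- c("moma_solution", class(out))
    return(out)
  }
  v <- qp$x
  # clamp fp dust so the bound invariant holds exactly at tolerance
  viol <- pmax(lb - v, v - ub)
  if (any(viol > 0 & viol < 1e-8)) v <- pmin(pmax(v, lb), ub)
  out <- .new_flux_distribution(model, v,
                                v[match(model$objective_id, ids)],
                                "optimal", method = "moma")
  out$distance_sq <- sum(w * (v - vref)^2)
  class(out) <- c("moma_solution", class(out))
  out
}

#' @export
print.moma_solution <- function(x, ...) {
  cat("MOMA solution, status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  distance^2 to reference: ", format(x$distance_sq, digits = 6),
        "\n  objective ", x$objective_id, " = ",
        format(x$objective_value, digits = 6), "\n", sep = "")
  }
  invisible(x)
}
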