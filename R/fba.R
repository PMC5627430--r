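# Flux balance analysis: maximize the objective flux subject to
# steady state (S v = 0) and flux bounds.

.new_flux_distribution <- function(model, v, objective_value, status,
                                   method = "fba") {
  fl <- stats::setNames(as.numeric(v), reaction_ids(model))
  structure(list(fluxes = fl, objective_value = objective_value,
                 status = status, objective_id = model$objective_id,
                 product_id = model$product_id, method = method),
            class = "flux_distribution")
}

#' Flux balance analysis
#'
#' Solves the linear program `max v_obj  s.t.  S v = 0, lb <= v <= ub`,
#' where the objective is the model's biomass reaction.  Additional bound
#' edits (typically fixed substrate-uptake rates) can be supplied without
#' modifying the model.
#'
#' @param model A [metabolic_model()].
#' @param extra_bounds Optional [bound_edits()] data frame applied on top
#'   of the model's bounds.
#' @param fix Optional named numeric vector; each entry clamps a
#'   reaction's flux to the given value (both bounds).
#' @return A `flux_distribution`: named `fluxes`, `objective_value`, and
#'   `status` (`"optimal"`, `"infeasible"` or `"unbounded"`).  For
#'   non-optimal statuses the fluxes are `NA`.
#' @seealso [reference_flux()] for a deterministic parsimonious variant.
#' @export
#' @examples
#' m <- make_toy_model(branch_yields = c(1, 2))
#' sol <- fba(m)
#' sol$objective_value   # uptake * best yield
fba <- function(model, extra_bounds = NULL, fix = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- stoich_matrix(model)
  bb <- flux_bounds(model)
  ab <- .apply_bounds(model, bb[, "lower"], bb[, "upper"], extra_bounds, fix)
  cvec <- as.numeric(reaction_ids(model) == model$objective_id)
  r <- .simplex_bounded(cvec, S, rep(0, nrow(S)), ab$lb, ab$ub,
                        maximize = TRUE)
  .new_flux_distribution(model, r$x, r$objective, r$status)
}

#' Deterministic wild-type reference flux distribution
#'
#' FBA optima are usually degenerate; MOMA and the target scan need one
#' reproducible reference.  This routine (i) solves FBA, (ii) fixes the
#' objective at its maximum and minimizes total absolute flux (the
#' parsimonious criterion), then (iii) resolves any remaining degeneracy
#' by taking the minimum-Euclidean-norm point of the parsimonious
#' optimal set, restricted to the sign pattern found in (ii).  Step (iii)
#' is a strictly convex quadratic program, so the result is unique and
#' identical across runs; two parallel identical pathways receive equal
#' shares of their combined flux.
#'
#' @inheritParams fba
#' @return A `flux_distribution` with `method = "pfba"`; `status` mirrors
#'   the FBA status when the program is infeasible or unbounded.
#' @export
reference_flux <- function(model, extra_bounds = NULL, fix = NULL) {
  f <- fba(model, extra_bounds, fix)
  if (f$status != "optimal") return(f)
  obj_star <- f$objective_value
  S <- stoich_matrix(model)
  bb <- flux_bounds(model)
  ab <- .apply_bounds(model, bb[, "lower"], bb[, "upper"], extra_bounds, fix)
  lb <- ab$lb; ub <- ab$ub
  n <- ncol(S); m <- nrow(S)
  cvec <- as.numeric(reaction_ids(model) == model$objective_id)

  # stage 2: min sum(p + q), v = p - q  (split-variable L1 program)
  lb_p <- pmax(lb, 0); ub_p <- pmax(ub, 0)
  lb_q <- pmax(-ub, 0); ub_q <- pmax(-lb, 0)
  A2 <- rbind(cbind(S, -S), c(cvec, -cvec))
  b2 <- c(rep(0, m), obj_star)
  r2 <- .simplex_bounded(rep(-1, 2 * n), A2, b2,
                         c(lb_p, lb_q), c(ub_p, ub_q), maximize = TRUE)
  if (r2$status != "optimal") {
    # numerically marginal; fall back to the raw FBA solution
    return(.new_flux_distribution(model, f$fluxes, obj_star, "optimal",
                                  method = "pfba"))
  }
  p <- r2$x[seq_len(n)]; q <- r2$x[n + seq_len(n)]
  v1 <- p - q
  l1 <- sum(p) + sum(q)

  # stage 3: among all flux vectors with the optimal objective AND the
  # minimal total absolute flux, take the unique minimum-Euclidean-norm
  # point.  Work in the split variables (p, q) with sum(p + q) = l1 so
  # the whole L1-optimal set is searched, not just the vertex the
  # simplex happened to return; a 1e-9 ridge keeps the Hessian positive
  # definite without biasing the solution measurably.
  ridge <- 1e-9
  In <- diag(1, n)
  D3 <- 2 * rbind(cbind((1 + ridge) * In, -In),
                  cbind(-In, (1 + ridge) * In))
  Aeq3 <- rbind(A2, rep(1, 2 * n))
  beq3 <- c(b2, l1)
  qp <- .solve_qp_box(Dvec = D3, dvec = rep(0, 2 * n),
                      Aeq = Aeq3, beq = beq3,
                      lb = c(lb_p, lb_q), ub = c(ub_p, ub_q))
  v <- if (qp$status == "optimal") qp$x[seq_len(n)] - qp$x[n + seq_len(n)]
       else v1
  .new_flux_distribution(model, v, obj_star, "optimal", method = "pfba")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("Flux distribution (", x$method, "), status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective ", x$objective_id, " = ",
        format(x$objective_value, digits = 6), "\n", sep = "")
    nz <- sum(abs(x$fluxes) > 1e-9)
    cat("  ", nz, " of ", length(x$fluxes), " reactions carry flux\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.flux_distribution <- function(x, ...) {
  data.frame(reaction = names(x$fluxes), flux = unname(x$fluxes),
             stringsAsFactors = FALSE)
}

#' @export
plot.flux_distribution <- function(x, n = 20, ...) {
  fl <- sort(x$fluxes[abs(x$fluxes) > 1e-9], decreasing = TRUE)
  fl <- utils::head(fl, n)
  op <- graphics::par(mar = c(4, 8, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(rev(fl), horiz = TRUE, las = 1,
                    xlab = "flux (mmol/gDCW/h)",
                    main = paste("Flux distribution:", x$method), ...)
  invisible(x)
}
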