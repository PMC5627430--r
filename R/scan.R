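# Overexpression-target identification: amplify each non-zero wild-type
# flux, re-solve by MOMA, score by f_PH and rank.

#' Compute the f_PH score from its four flux components
#'
#' `f_PH = f_biomass * f_ascomycin`, where `f_biomass` is the ratio of
#' the perturbed to the wild-type specific growth rate and `f_ascomycin`
#' the ratio of the perturbed to the wild-type product synthesis rate.
#' Candidates with `f_PH > 1` improve the growth-production trade-off.
#'
#' @param v_bio_wild,v_bio_over Wild-type and perturbed biomass fluxes
#'   (1/h); the wild-type value must be positive.
#' @param v_asc_wild,v_asc_over Wild-type and perturbed product fluxes
#'   (mmol/gDCW/h); the wild-type value must be positive.
#' @return A list with `f_biomass`, `f_ascomycin` and `f_ph`.
#' @export
#' @examples
#' compute_fph(0.05, 0.10, 2e-4, 6e-4)  # f_ph = 6
compute_fph <- function(v_bio_wild, v_bio_over, v_asc_wild, v_asc_over) {
  if (!is.finite(v_bio_wild) || v_bio_wild <= 0)
    stop("wild-type biomass flux must be positive to score a target (got ",
         v_bio_wild, ")")
  if (!is.finite(v_asc_wild) || v_asc_wild <= 0)
    stop("wild-type product flux must be positive to score a target (got ",
         v_asc_wild, ")")
  f_bio <- v_bio_over / v_bio_wild
  f_asc <- v_asc_over / v_asc_wild
  list(f_biomass = f_bio, f_ascomycin = f_asc, f_ph = f_bio * f_asc)
}

#' Scan all carried fluxes for overexpression targets
#'
#' For every reaction whose wild-type reference flux is non-zero (and not
#' excluded), the flux is amplified to `k` times its reference value
#' (sign-preserving), the perturbed network is re-solved by [moma()], and
#' the result is scored by [compute_fph()] against the reference biomass
#' and product fluxes.  By default the amplification is imposed as an
#' equality constraint (`mode = "fix"`); `mode = "min"` instead raises
#' the bound on the carried direction, the laxer reading of an
#' overexpression.
#'
#' The model's objective and product reactions are never scanned: they
#' are pseudo-reactions, not enzyme targets.
#'
#' @param model A [metabolic_model()] with a product reaction set.
#' @param reference Optional `flux_distribution`; computed by
#'   [reference_flux()] when omitted.  Must be optimal and carry positive
#'   biomass and product fluxes.
#' @param k Amplification factor (>= 1); default 2.
#' @param exclude_subsystems,exclude_reactions Character vectors removed
#'   from the scan before solving (e.g. exchange, inorganic ion
#'   transport, nucleotide salvage, ATP maintenance).
#' @param zero_tol Fluxes with `|v_ref|` at or below this are "not
#'   carried" and skipped (default `1e-9`).
#' @param mode `"fix"` (equality, default) or `"min"` (directional bound).
#' @return A `target_ranking`: a data frame of per-reaction scores
#'   (`reaction_id`, `subsystem`, `v_wild`, `v_amplified`, `f_biomass`,
#'   `f_ascomycin`, `f_ph`, `status`) sorted by `f_ph` descending then id
#'   ascending, with the scan parameters attached.
#' @seealso [count_targets()], [compute_fph()], [moma()]
#' @export
#' @examples
#' m <- make_core_ascomycin_toy()
#' rk <- scan_targets(m, k = 2)
#' head(as.data.frame(rk))
scan_targets <- function(model, reference = NULL, k = 2,
                         exclude_subsystems = character(),
                         exclude_reactions = character(),
                         zero_tol = 1e-9, mode = c("fix", "min")) {
  stopifnot(inherits(model, "metabolic_model"))
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("amplification factor k must be a single number >= 1")
  if (is.na(model$product_id))
    stop("model has no product reaction; set product_id to scan")
  if (is.null(reference)) reference <- reference_flux(model)
  if (!inherits(reference, "flux_distribution") ||
      reference$status != "optimal")
    stop("reference flux distribution must be optimal")
  vref <- reference$fluxes
  ids <- reaction_ids(model)
  if (!all(ids %in% names(vref)))
    stop("reference lacks flux values for some model reactions")
  v_bio_wild <- vref[[model$objective_id]]
  v_asc_wild <- vref[[model$product_id]]
  if (!is.finite(v_bio_wild) || v_bio_wild <= 0)
    stop("reference biomass flux is not positive; cannot score targets")
  if (!is.finite(v_asc_wild) || v_asc_wild <= 0)
    stop("reference product flux is not positive; give the product ",
         "reaction a positive lower bound (baseline synthesis rate)")
  subsys <- vapply(model$reactions, `[[`, character(1), "subsystem")
  carried <- ids[abs(vref[ids]) > zero_tol]
  carried <- setdiff(carried, c(model$objective_id, model$product_id))
  excluded <- carried[subsys[carried] %in% exclude_subsystems |
                        carried %in% exclude_reactions]
  scan_set <- setdiff(carried, excluded)
  rows <- vector("list", length(scan_set))
  for (i in seq_along(scan_set)) {
    j <- scan_set[i]
    target <- k * vref[[j]]
    if (mode == "fix") {
      sol <- moma(model, reference, fix = stats::setNames(target, j))
    } else {
      pe <- if (vref[[j]] >= 0) bound_edits(j, "lower", target)
            else bound_edits(j, "upper", target)
      sol <- moma(model, reference, perturbation = pe)
    }
    if (sol$status == "optimal") {
      sc <- compute_fph(v_bio_wild, sol$fluxes[[model$objective_id]],
                        v_asc_wild, sol$fluxes[[model$product_id]])
      rows[[i]] <- data.frame(
        reaction_id = j, subsystem = subsys[[j]],
        v_wild = vref[[j]], v_amplified = target,
        f_biomass = sc$f_biomass, f_ascomycin = sc$f_ascomycin,
        f_ph = sc$f_ph, status = "scored", stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        reaction_id = j, subsystem = subsys[[j]],
        v_wild = vref[[j]], v_amplified = target,
        f_biomass = NA_real_, f_ascomycin = NA_real_,
        f_ph = NA_real_, status = "infeasible", stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(reaction_id = character(), subsystem = character(),
                         v_wild = numeric(), v_amplified = numeric(),
                         f_biomass = numeric(), f_ascomycin = numeric(),
                         f_ph = numeric(), status = character(),
                         stringsAsFactors = FALSE)
  ord <- order(-ifelse(is.na(tab$f_ph), -Inf, tab$f_ph), tab$reaction_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(
    scores = tab,
    parameters = list(k = k, mode = mode,
                      exclude_subsystems = exclude_subsystems,
                      exclude_reactions = exclude_reactions,
                      zero_tol = zero_tol,
                      objective_id = model$objective_id,
                      product_id = model$product_id,
                      v_bio_wild = v_bio_wild, v_asc_wild = v_asc_wild),
    excluded = excluded),
    class = "target_ranking")
}

#' Count potential targets in a ranking
#'
#' Counts scored reactions with `f_ph` above a threshold and splits them
#' into primary and secondary metabolism by subsystem membership.
#'
#' @param ranking A `target_ranking` from [scan_targets()].
#' @param threshold Score cutoff; a "potential target" has
#'   `f_ph > threshold` (default 1, i.e. better than wild type).
#' @param secondary_subsystems Subsystem tokens counted as secondary
#'   metabolism.
#' @return List with `n_total`, `n_primary`, `n_secondary` and the
#'   qualifying score rows.
#' @export
count_targets <- function(ranking, threshold = 1,
                          secondary_subsystems = character()) {
  stopifnot(inherits(ranking, "target_ranking"))
  sc <- ranking$scores
  hit <- sc$status == "scored" & !is.na(sc$f_ph) & sc$f_ph > threshold
  rows <- sc[hit, , drop = FALSE]
  secondary <- rows$subsystem %in% secondary_subsystems
  list(n_total = nrow(rows),
       n_primary = sum(!secondary),
       n_secondary = sum(secondary),
       targets = rows)
}

#' @export
print.target_ranking <- function(x, n = 10, ...) {
  p <- x$parameters
  cat("Overexpression target ranking (k = ", p$k, ", mode = ", p$mode,
      ")\n", sep = "")
  cat("  scanned: ", nrow(x$scores), " reactions (",
      sum(x$scores$status == "scored"), " scored, ",
      sum(x$scores$status == "infeasible"), " infeasible, ",
      length(x$excluded), " excluded)\n", sep = "")
  print(utils::head(x$scores, n))
  if (nrow(x$scores) > n) cat("  ... ", nrow(x$scores) - n, " more rows\n")
  invisible(x)
}

#' @export
summary.target_ranking <- function(object, threshold = 1, ...) {
  ct <- count_targets(object, threshold)
  cat("Targets with f_PH >", threshold, ":", ct$n_total, "\n")
  invisible(ct)
}

#' @export
as.data.frame.target_ranking <- function(x, ...) x$scores

#' @export
plot.target_ranking <- function(x, n = 15, ...) {
  sc <- x$scores[x$scores$status == "scored", , drop = FALSE]
  sc <- utils::head(sc, n)
  op <- graphics::par(mar = c(4, 8, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(rev(sc$f_ph), names.arg = rev(sc$reaction_id),
                    horiz = TRUE, las = 1, xlab = "f_PH", ...)
  graphics::abline(v = 1, lty = 2)
  invisible(x)
}
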