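# Pipeline driver wiring the stages (build -> simulate -> scan) plus the
# thin command-line dispatcher used by inst/cli/ascoflux.R.

.pkg_version <- function() {
  as.character(utils::packageVersion("ascoflux"))
}

# hash of the semantically meaningful configuration fields
.config_hash <- function(config) {
  core <- config[setdiff(names(config), c("out_dir", "log_level"))]
  core <- core[order(names(core))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(core, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.provenance_header <- function(config_hash, stamp = TRUE) {
  c(paste0("# ascoflux ", .pkg_version(), "; config ", config_hash),
    if (stamp) paste0("# generated ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}

.write_tsv_with_header <- function(df, path, config_hash) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_header(config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.log_msg <- function(level, ...) {
  message("[", level, "] ", ...)
}

#' Run the target-prediction pipeline
#'
#' Executes, in order: `build` (apply an edit script to the input model),
#' `simulate` (deterministic wild-type reference by [reference_flux()])
#' and `scan` ([scan_targets()] plus [count_targets()]).  Every output
#' table carries a header comment with the tool version, a hash of the
#' semantically meaningful configuration fields, and a timestamp; re-runs
#' with an identical configuration reproduce identical content modulo the
#' timestamp line.
#'
#' @param config Named list (or path to a JSON file) with fields:
#'   `model` (path) and optional `format`; optional `edit_script` (an
#'   [edit_script()] or path to a JSON encoding with the same field
#'   names); optional `fix` (named list/vector of fixed fluxes, e.g.
#'   substrate uptake); `k` (amplification factor, default 2);
#'   `threshold` (f_PH cutoff for counting, default 1);
#'   `exclude_subsystems`, `exclude_reactions`,
#'   `secondary_subsystems` (character vectors); `out_dir` (default
#'   `"ascoflux_out"`).
#' @param dry_run Print the resolved stage plan and touch nothing.
#' @return Invisibly, a list with the built model, the reference flux
#'   distribution, the `target_ranking`, the target counts and the paths
#'   of the artifact files.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (is.null(config$model)) stop("config lacks a 'model' path")
  if (!file.exists(config$model))
    stop("model file not found: ", config$model)
  k <- config$k %||% 2
  threshold <- config$threshold %||% 1
  out_dir <- config$out_dir %||% "ascoflux_out"
  hash <- .config_hash(config)
  plan <- c(
    sprintf("build:    load %s%s", config$model,
            if (!is.null(config$edit_script)) " + apply edit script" else ""),
    sprintf("simulate: parsimonious reference flux%s",
            if (length(config$fix)) paste0(" (fixed: ",
              paste(names(config$fix), unlist(config$fix), sep = "=",
                    collapse = ", "), ")") else ""),
    sprintf("scan:     k = %g, threshold = %g -> %s", k, threshold, out_dir))
  if (dry_run) {
    cat("ascoflux pipeline plan (config ", hash, "):\n  ",
        paste(plan, collapse = "\n  "), "\n", sep = "")
    return(invisible(NULL))
  }
  # build
  model <- load_model(config$model,
                      format = config$format %||% "guess")
  if (!is.null(config$objective_id)) model$objective_id <- config$objective_id
  if (!is.null(config$product_id)) model$product_id <- config$product_id
  if (!is.null(config$edit_script)) {
    es <- config$edit_script
    if (is.character(es)) es <- .read_edit_script_json(es)
    model <- apply_edit_script(model, es)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .log_msg("info", "build: model with ", length(model$reactions),
           " reactions / ", length(model$metabolites), " metabolites")
  # simulate
  fix <- if (length(config$fix)) unlist(config$fix) else NULL
  ref <- reference_flux(model, fix = fix)
  if (ref$status != "optimal")
    stop("simulate stage failed: reference flux is ", ref$status)
  .log_msg("info", "simulate: growth ",
           format(ref$objective_value, digits = 6), " 1/h")
  flux_path <- file.path(out_dir, "reference_fluxes.tsv")
  .write_tsv_with_header(as.data.frame(ref), flux_path, hash)
  # scan
  ranking <- scan_targets(
    model, ref, k = k,
    exclude_subsystems = config$exclude_subsystems %||% character(),
    exclude_reactions = config$exclude_reactions %||% character())
  counts <- count_targets(ranking, threshold = threshold,
                          secondary_subsystems =
                            config$secondary_subsystems %||% character())
  sc <- ranking$scores
  sc <- cbind(rank = seq_len(nrow(sc)), sc)
  rank_path <- file.path(out_dir, "target_ranking.tsv")
  .write_tsv_with_header(sc, rank_path, hash)
  .log_msg("info", "scan: ", counts$n_total, " target(s) with f_PH > ",
           threshold, " (", counts$n_primary, " primary, ",
           counts$n_secondary, " secondary)")
  invisible(list(model = model, reference = ref, ranking = ranking,
                 counts = counts,
                 files = c(reference = flux_path, ranking = rank_path),
                 config_hash = hash))
}

.read_edit_script_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  adds <- lapply(x$add_reactions, function(r)
    reaction(r$id, unlist(r$metabolites), name = r$name %||% r$id,
             lower_bound = r$lower_bound %||% 0,
             upper_bound = r$upper_bound %||% 1000,
             subsystem = r$subsystem %||% "",
             genes = unlist(r$genes) %||% character()))
  be <- NULL
  if (length(x$bound_edits))
    be <- bound_edits(
      vapply(x$bound_edits, function(e) e$reaction, character(1)),
      vapply(x$bound_edits, function(e) e$bound, character(1)),
      vapply(x$bound_edits, function(e) as.numeric(e$value), numeric(1)))
  edit_script(remove_subsystems = unlist(x$remove_subsystems) %||% character(),
              remove_reactions = unlist(x$remove_reactions) %||% character(),
              add_reactions = adds, bound_edits = be)
}

# ---- command-line dispatcher (called by inst/cli/ascoflux.R) ----

.cli_opts <- function(args) {
  opts <- list(positional = character())
  for (a in args) {
    if (grepl("^--[A-Za-z0-9_-]+=", a)) {
      key <- sub("^--", "", sub("=.*$", "", a))
      opts[[gsub("-", "_", key)]] <- sub("^--[A-Za-z0-9_-]+=", "", a)
    } else if (grepl("^--", a)) {
      opts[[gsub("-", "_", sub("^--", "", a))]] <- TRUE
    } else {
      opts$positional <- c(opts$positional, a)
    }
  }
  opts
}

.cli_usage <- function() {
  cat("usage: ascoflux <command> [--key=value ...]\n",
      "commands:\n",
      "  toy       --out=<dir>                 write the curated toy model\n",
      "  build     --config=<json>             apply edit script, save model\n",
      "  simulate  --model=<file> [--fix=R=V,...] [--out=<tsv>]\n",
      "  moma      --model=<file> --reference=<tsv> [--fix=R=V,...] [--out=<tsv>]\n",
      "  scan      --config=<json> | --model=<file> [--k=2] [--out=<dir>]\n",
      "  conserve  --hits=<tsv> --query-lengths=<tsv> --subsystem-map=<tsv>\n",
      "            [--min-identity=40] [--min-coverage=0.5] [--max-e=1e-5]\n",
      "            [--out=<dir>]\n", sep = "")
}

.parse_fix <- function(s) {
  if (is.null(s) || isTRUE(s == "")) return(NULL)
  parts <- strsplit(strsplit(s, ",")[[1]], "=")
  stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                  vapply(parts, `[[`, character(1), 1))
}

# returns an exit status; kept free of side effects beyond file output so
# tests can drive it directly
cli_main <- function(args) {
  if (!length(args)) { .cli_usage(); return(1L) }
  cmd <- args[1]
  opts <- .cli_opts(args[-1])
  tryCatch({
    switch(cmd,
      toy = {
        out <- opts$out %||% "."
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        m <- make_core_ascomycin_toy()
        save_model(m, file.path(out, "ascomycin_toy.tsv"), "tsv")
        save_model(m, file.path(out, "ascomycin_toy.xml"), "sbml")
        cat("wrote", file.path(out, "ascomycin_toy.{tsv,xml}"), "\n")
      },
      build = {
        cfg <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
        m <- load_model(cfg$model, cfg$format %||% "guess")
        if (!is.null(cfg$edit_script)) {
          es <- cfg$edit_script
          if (is.character(es)) es <- .read_edit_script_json(es)
          m <- apply_edit_script(m, es)
        }
        out <- opts$out %||% cfg$out %||% "model_built.tsv"
        save_model(m, out)
        cat("wrote", out, "\n")
      },
      simulate = {
        m <- load_model(opts$model)
        if (!is.null(opts$objective)) m$objective_id <- opts$objective
        ref <- reference_flux(m, fix = .parse_fix(opts$fix))
        if (ref$status != "optimal") stop("solution status: ", ref$status)
        cat("objective", m$objective_id, "=", ref$objective_value, "\n")
        if (!is.null(opts$out))
          .write_tsv_with_header(as.data.frame(ref), opts$out,
                                 .config_hash(opts))
      },
      moma = {
        m <- load_model(opts$model)
        ref_df <- utils::read.delim(opts$reference, comment.char = "#")
        ref <- stats::setNames(ref_df$flux, ref_df$reaction)
        sol <- moma(m, ref, fix = .parse_fix(opts$fix))
        cat("status:", sol$status, "\n")
        if (sol$status == "optimal")
          cat("distance_sq:", sol$distance_sq, "\n")
        if (!is.null(opts$out) && sol$status == "optimal")
          .write_tsv_with_header(as.data.frame(sol), opts$out,
                                 .config_hash(opts))
      },
      scan = {
        if (!is.null(opts$config)) {
          run_pipeline(opts$config, dry_run = isTRUE(opts$dry_run))
        } else {
          m <- load_model(opts$model)
          rk <- scan_targets(m, k = as.numeric(opts$k %||% "2"))
          out <- opts$out %||% "."
          dir.create(out, showWarnings = FALSE, recursive = TRUE)
          sc <- cbind(rank = seq_len(nrow(rk$scores)), rk$scores)
          .write_tsv_with_header(sc, file.path(out, "target_ranking.tsv"),
                                 .config_hash(opts))
          cat("wrote", file.path(out, "target_ranking.tsv"), "\n")
        }
      },
      conserve = {
        ql_df <- utils::read.delim(opts$query_lengths)
        ql <- stats::setNames(ql_df$length, ql_df$query_id)
        hits <- parse_hits(opts$hits, ql)
        sm_df <- utils::read.delim(opts$subsystem_map)
        sm <- stats::setNames(sm_df$subsystem, sm_df$query_id)
        calls <- do.call(rbind, lapply(
          unique(hits$subject_strain), function(s)
            call_conservation(best_hit_per_query(hits, s), ql,
              min_identity = as.numeric(opts$min_identity %||% "40"),
              min_coverage = as.numeric(opts$min_coverage %||% "0.5"),
              max_e = as.numeric(opts$max_e %||% "1e-5"))))
        summ <- summarize_conservation(calls, sm)
        out <- opts$out %||% "."
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        h <- .config_hash(opts)
        .write_tsv_with_header(calls, file.path(out, "calls.tsv"), h)
        .write_tsv_with_header(
          data.frame(strain = names(summ$per_strain_fraction),
                     fraction = unname(summ$per_strain_fraction)),
          file.path(out, "per_strain.tsv"), h)
        .write_tsv_with_header(summ$per_subsystem,
                               file.path(out, "per_subsystem.tsv"), h)
        cat("wrote conservation tables to", out, "\n")
      },
      { .cli_usage(); return(1L) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
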