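#' Configuration-driven pipeline runs
#'
#' A run configuration selects stages (`simulate_tmt`, `interactome`,
#' `simulate_volumes`, `match_index`, `simulate_axon`, `axon_stats`,
#' `factin`) and carries their parameters and one seed.  [run_pipeline()]
#' executes the selected stages in dependency order into an output
#' directory, writes every product as a plain-text table or JSON, and
#' emits a manifest tying outputs to a configuration hash so an identical
#' rerun reproduces identical numeric outputs.
#'
#' @param stages character vector of stage names (order-insensitive).
#' @param out_dir output directory.
#' @param seed integer seed applied to every stochastic stage.
#' @param params named list of stage parameters: `tmt` (arguments to
#'   [tmt_sim_config()]), `interactome` (`bait_id`, `min_peptides`,
#'   `top_k`), `volumes` ([volume_sim_config()] arguments), `axon`
#'   ([axon_sim_config()] arguments), `factin` (`method`), `bins`.
#' @return object of class `run_config`.
#' @export
run_config <- function(stages, out_dir, seed = 1L, params = list()) {
  known <- c("simulate_tmt", "interactome", "simulate_volumes", "match_index",
             "simulate_axon", "axon_stats", "factin")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
                 params = params), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with fields `stages`, `out_dir`, `seed`, `params`.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(unlist(y$stages), y$out_dir,
             if (is.null(y$seed)) 1L else y$seed,
             if (is.null(y$params)) list() else y$params)
}

#' Hash of the semantically meaningful configuration content
#'
#' Stages (sorted), seed and parameters are serialized canonically and
#' hashed; the output directory does not enter the hash.
#'
#' @param cfg a [run_config()].
#' @return md5 hex string.
#' @export
config_hash <- function(cfg) {
  canon <- list(stages = sort(cfg$stages), seed = cfg$seed,
                params = cfg$params)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA,
                              pretty = FALSE), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Execute a pipeline run
#'
#' Stages execute in dependency order (simulation stages before the
#' analyses that consume them); a stage failure halts the run with an
#' error naming the stage.  All outputs land in `cfg$out_dir` and are
#' listed in the returned manifest (also written as `manifest.json`).
#'
#' @param cfg a [run_config()].
#' @return list of class `run_manifest`: `config_hash`, `seed`, `stages`,
#'   `outputs` (named file paths), `log` (per-stage messages).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  order_all <- c("simulate_tmt", "interactome", "simulate_volumes",
                 "match_index", "simulate_axon", "axon_stats", "factin")
  stages <- order_all[order_all %in% cfg$stages]
  outputs <- character()
  log <- character()
  state <- new.env(parent = emptyenv())
  p <- cfg$params
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log <<- c(log, paste0("stage ", name, ": ok"))
    res
  }
  for (st in stages) {
    if (st == "simulate_tmt") run_stage(st, function() {
      args <- p$tmt %||% list()
      args$seed <- cfg$seed
      sim <- gen_tmt_dataset(do.call(tmt_sim_config, args))
      state$tmt_sim <- sim
      f1 <- write_tsv(sim$quant, file.path(cfg$out_dir, "tmt_quant.tsv"))
      f2 <- write_tsv(sim$truth, file.path(cfg$out_dir, "tmt_truth.tsv"))
      outputs <<- c(outputs, tmt_quant = f1, tmt_truth = f2)
    })
    if (st == "interactome") run_stage(st, function() {
      if (is.null(state$tmt_sim))
        stop("requires the simulate_tmt stage (or pre-loaded data)")
      fit <- tmt_fit(state$tmt_sim$quant, mode = "precomputed")
      ia <- run_interactome(fit,
                            bait_id = p$interactome$bait_id %||% "BAIT",
                            min_peptides = p$interactome$min_peptides %||% 2L,
                            top_k = p$interactome$top_k %||% 37L)
      paths <- write_interactome(ia, fit, cfg$out_dir)
      outputs <<- c(outputs, paths)
    })
    if (st == "simulate_volumes") run_stage(st, function() {
      args <- p$volumes %||% list()
      args$seed <- cfg$seed
      state$vol_sim <- gen_glomerular_volumes(do.call(volume_sim_config, args))
      f <- file.path(cfg$out_dir, "volume_truth.json")
      jsonlite::write_json(state$vol_sim$truth, f, auto_unbox = TRUE,
                           digits = NA)
      outputs <<- c(outputs, volume_truth = f)
    })
    if (st == "match_index") run_stage(st, function() {
      if (is.null(state$vol_sim))
        stop("requires the simulate_volumes stage")
      sv <- state$vol_sim
      am <- segment_volume(sv$axon, "auto")
      dm <- segment_volume(sv$dendrite, "auto")
      rep <- list(match_index = match_index(am, dm),
                  mismatch_index = mismatch_index(am, dm),
                  threshold_axon = am$threshold_used,
                  threshold_dendrite = dm$threshold_used)
      f <- file.path(cfg$out_dir, "match_report.json")
      jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs, match_report = f)
    })
    if (st == "simulate_axon") run_stage(st, function() {
      args <- p$axon %||% list()
      args$seed <- cfg$seed
      sim <- gen_axon_with_field(do.call(axon_sim_config, args))
      state$axon_sim <- sim
      f1 <- write_swc(sim$tree, file.path(cfg$out_dir, "axon.swc"))
      f2 <- write_tsv(sim$truth, file.path(cfg$out_dir, "axon_truth.tsv"))
      outputs <<- c(outputs, axon_swc = f1, axon_truth = f2)
    })
    if (st == "axon_stats") run_stage(st, function() {
      if (is.null(state$axon_sim)) stop("requires the simulate_axon stage")
      sim <- state$axon_sim
      m <- axon_morphometry(sim$tree, sim$regions, bins = p$bins %||% 20L)
      state$morpho <- m
      f1 <- write_tsv(m$records, file.path(cfg$out_dir, "branch_records.tsv"))
      s <- m$summary
      f2 <- file.path(cfg$out_dir, "axon_summary.json")
      jsonlite::write_json(list(stage = m$stage,
                                stem_length = m$stem$stem_length,
                                branch_density = s$branch_density,
                                total_branches = s$total_branches,
                                contacting_fraction = s$contacting_fraction),
                           f2, auto_unbox = TRUE, digits = NA)
      f3 <- write_tsv(data.frame(bin_lo = attr(s$position_histogram,
                                               "breaks")[-(length(s$position_histogram) + 1L)],
                                 bin_hi = attr(s$position_histogram,
                                               "breaks")[-1L],
                                 count = as.integer(s$position_histogram)),
                      file.path(cfg$out_dir, "position_histogram.tsv"))
      outputs <<- c(outputs, branch_records = f1, axon_summary = f2,
                    position_histogram = f3)
    })
    if (st == "factin") run_stage(st, function() {
      if (is.null(state$axon_sim) || is.null(state$morpho))
        stop("requires the simulate_axon and axon_stats stages")
      sim <- state$axon_sim
      samples <- sample_along_trace(sim$tree, sim$field, radius_vox = 1L,
                                    origin = sim$origin)
      prof <- normalize_profile(samples, axon_id = "sim")
      dens <- branch_densities(sim$tree, prof, state$morpho$records,
                               sim$regions$pn_dendrites,
                               method = p$factin$method %||% "integral")
      cmpr <- factin_compare(dens)
      f1 <- write_tsv(dens, file.path(cfg$out_dir, "branch_densities.tsv"))
      f2 <- file.path(cfg$out_dir, "factin_report.json")
      jsonlite::write_json(list(between = cmpr$between, within = cmpr$within),
                           f2, auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs, branch_densities = f1, factin_report = f2)
    })
  }
  manifest <- structure(list(config_hash = config_hash(cfg),
                             seed = cfg$seed,
                             stages = stages,
                             outputs = as.list(outputs),
                             log = log),
                        class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest %s (seed %d)\n", substr(x$config_hash, 1, 8),
              x$seed))
  cat("  stages:", paste(x$stages, collapse = ", "), "\n")
  cat(sprintf("  outputs: %d files\n", length(x$outputs)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
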