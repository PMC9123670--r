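# End-to-end orchestration: filter -> region means -> RSG detection ->
# network -> eigengenes -> association -> calls -> candidates, with a run
# directory, stage TSVs, structured logs and a JSON manifest.

#' Pipeline configuration
#'
#' All stage parameters with the study's values as defaults: filter threshold
#' 1 (FPKM), RSG fold 3 and quantile 0.75, soft power 5, region-specific
#' call thresholds |r| > 0.60 and p < 1e-2.
#'
#' @param expr_path,meta_path Input tables; both `NULL` switches the run to
#'   simulate-first mode with `sim` as the generator config.
#' @param sim A [sim_config()] for simulate-first mode.
#' @param threshold,scope Expression-filter parameters, see
#'   [filter_expressed()].
#' @param fold,other_mean_ratio,quantile RSG-detector parameters, see
#'   [detect_rsgs()].
#' @param beta,network_type,transform,min_module_size,cut_height,merge_cut_height
#'   Network parameters, see [build_network()].
#' @param r_min,p_max Region-specific call thresholds.
#' @param top_k Hub genes per region-specific module for the candidate list.
#' @param seed RNG seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expr_path = NULL, meta_path = NULL, sim = sim_config(),
                            threshold = 1, scope = "any_region_all_reps",
                            fold = 3, other_mean_ratio = 0.5, quantile = 0.75,
                            beta = 5, network_type = "unsigned",
                            transform = "log2_plus1", min_module_size = 30,
                            cut_height = 0.99, merge_cut_height = 0.25,
                            r_min = 0.60, p_max = 1e-2, top_k = 10, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

log_line <- function(con, stage, level, msg) {
  line <- sprintf("%s\t%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, level, msg)
  writeLines(line, con)
}

fresh_run_dir <- function(out_dir) {
  dir <- out_dir
  i <- 1
  while (dir.exists(dir)) {
    dir <- paste0(out_dir, "-", i)
    i <- i + 1
  }
  dir.create(dir, recursive = TRUE)
  dir
}

write_stage <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  readr::write_tsv(x, path)
  path
}

#' Run the full pipeline
#'
#' Stage order: filter, region means, RSG detection, network construction,
#' eigengenes, module-region association, region-specific calls, candidate
#' merging. Each stage writes a TSV into the run directory; a `manifest.json`
#' records every parameter, input checksums, package and R versions, and
#' per-stage record counts, sufficient to re-run deterministic stages
#' bit-identically. The run directory is never reused: a suffix is appended
#' on collision. On a stage failure a `FAILED` marker naming the stage and
#' cause is left next to the partial outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Run directory to create (default `"regiospec-run"`).
#' @return Invisibly, a list with the run `dir`, the `manifest`, and the
#'   in-memory stage results (`filtered`, `rsgs`, `network`, `assoc`,
#'   `calls`, `candidates`, and `truth`/`recovery` in simulate-first mode).
#' @export
run_pipeline <- function(cfg, out_dir = "regiospec-run") {
  dir <- fresh_run_dir(out_dir)
  logf <- file(file.path(dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  manifest <- list(package = "regiospec",
                   version = as.character(utils::packageVersion("regiospec")),
                   r_version = R.version.string,
                   parameters = unclass(cfg)[setdiff(names(cfg), c("sim", "expr_path", "meta_path"))],
                   seed = cfg$seed,
                   stages = list())
  stage <- "setup"
  result <- list(dir = dir)
  tryCatch({
    stage <- "load"
    if (is.null(cfg$expr_path)) {
      log_line(logf, stage, "INFO", "simulate-first mode")
      sim <- cfg$sim
      sim$seed <- cfg$seed
      ds <- generate_dataset(sim)
      expr <- ds$expr; meta <- ds$meta
      result$truth <- ds$truth
      manifest$parameters$sim <- sim[setdiff(names(sim), "module_region_map")]
      write_stage(meta, dir, "metadata")
    } else {
      if (!file.exists(cfg$meta_path)) rlang::abort("metadata file not found")
      manifest$inputs <- list(
        expr = list(path = cfg$expr_path, md5 = unname(tools::md5sum(cfg$expr_path))),
        meta = list(path = cfg$meta_path, md5 = unname(tools::md5sum(cfg$meta_path))))
      expr <- read_expression(cfg$expr_path)
      meta <- read_metadata(cfg$meta_path)
    }

    stage <- "filter"
    filtered <- filter_expressed(expr, meta, threshold = cfg$threshold, scope = cfg$scope)
    write_stage(filtered, dir, "filtered")
    manifest$stages$filter <- list(n_in = nrow(expr), n_out = nrow(filtered))
    log_line(logf, stage, "INFO", paste(nrow(filtered), "genes pass"))

    stage <- "region_means"
    rm_tbl <- region_means(filtered, meta)
    write_stage(rm_tbl, dir, "region_means")
    manifest$stages$region_means <- list(n = nrow(rm_tbl))

    stage <- "detect_rsgs"
    rsgs <- detect_rsgs(rm_tbl, fold = cfg$fold, other_mean_ratio = cfg$other_mean_ratio,
                        quantile = cfg$quantile)
    write_stage(rsgs, dir, "rsg_records")
    counts <- rsg_region_counts(rsgs, regions = unique(meta$region))
    write_stage(counts, dir, "rsg_counts")
    manifest$stages$detect_rsgs <- list(n_records = nrow(rsgs),
                                        n_rsg = sum(rsgs$is_rsg))
    log_line(logf, stage, "INFO", paste(sum(rsgs$is_rsg), "RSGs"))

    stage <- "network"
    net <- build_network(filtered, beta = cfg$beta, type = cfg$network_type,
                         transform = cfg$transform,
                         min_module_size = cfg$min_module_size,
                         cut_height = cfg$cut_height,
                         merge_cut_height = cfg$merge_cut_height)
    write_stage(net$assignment, dir, "module_assignment")
    manifest$stages$network <- list(n_modules = max(net$assignment$module),
                                    n_unassigned = sum(net$assignment$module == 0))
    log_line(logf, stage, "INFO", paste(max(net$assignment$module), "modules"))

    stage <- "eigengenes"
    write_stage(net$eigengenes, dir, "eigengenes")
    manifest$stages$eigengenes <- list(n = nrow(net$eigengenes))

    stage <- "associate"
    design <- build_design_matrix(meta)
    assoc <- module_trait_correlation(net$eigengenes, design)
    write_stage(assoc, dir, "module_trait_association")
    manifest$stages$associate <- list(n = nrow(assoc))

    stage <- "call"
    calls <- call_region_specific_modules(assoc, r_min = cfg$r_min, p_max = cfg$p_max)
    write_stage(calls, dir, "region_specific_calls")
    manifest$stages$call <- list(n_called = sum(calls$is_region_specific))
    log_line(logf, stage, "INFO", paste(sum(calls$is_region_specific), "region-specific calls"))

    stage <- "candidates"
    kme <- module_membership(filtered, net$eigengenes, transform = cfg$transform)
    cands <- merge_candidates(rsgs, calls, net$assignment, kme,
                              top_k_per_module = cfg$top_k)
    write_stage(cands, dir, "candidates")
    manifest$stages$candidates <- list(n = nrow(cands))
    log_line(logf, stage, "INFO", paste(nrow(cands), "candidate genes"))

    if (!is.null(result$truth)) {
      result$recovery <- evaluate_recovery(rsgs, net$assignment, calls, result$truth)
      write_stage(result$recovery, dir, "recovery")
    }

    result$filtered <- filtered
    result$rsgs <- rsgs
    result$network <- net
    result$assoc <- assoc
    result$calls <- calls
    result$candidates <- cands
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(dir, "FAILED"))
    log_line(logf, stage, "ERROR", conditionMessage(e))
    rlang::abort(paste0("pipeline failed at stage '", stage, "': ",
                        conditionMessage(e)), parent = e)
  })
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}
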