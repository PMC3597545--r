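#' Pipeline configuration
#'
#' Collects every tunable of the normalize -> index -> detect -> evaluate
#' chain with documented defaults; round-trips through YAML.
#'
#' @param lam,shift Box-Cox parameters; ignored when `calibrate = TRUE`
#' @param calibrate estimate the transform from the native data instead of
#'   using `lam`/`shift`
#' @param window_upstream,window_downstream context window
#' @param index_min_cov,index_min_positions homolog-index thresholds
#' @param method detection method
#' @param min_native_cov native coverage floor for scoring
#' @param em_tol,em_max_iter EM settings
#' @param threshold score threshold for GFF emission (`NA` = no GFF)
#' @param eval_tol_bp positional matching tolerance for evaluation
#' @param seed seed recorded in the manifest
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(lam = 0.25, shift = 0, calibrate = FALSE,
                            window_upstream = 6L, window_downstream = 1L,
                            index_min_cov = 10L, index_min_positions = 6L,
                            method = "hier_control", min_native_cov = 3L,
                            em_tol = 1e-8, em_max_iter = 500L,
                            threshold = NA_real_, eval_tol_bp = 5L,
                            seed = 1L) {
  structure(list(lam = lam, shift = shift, calibrate = calibrate,
                 window_upstream = as.integer(window_upstream),
                 window_downstream = as.integer(window_downstream),
                 index_min_cov = as.integer(index_min_cov),
                 index_min_positions = as.integer(index_min_positions),
                 method = method, min_native_cov = as.integer(min_native_cov),
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
                 threshold = threshold, eval_tol_bp = as.integer(eval_tol_bp),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[names(vals) %in%
                                  names(formals(pipeline_config))])
}

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()]
#' @param path output path
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config)[order(names(unclass(config)))], tmp)
  unname(tools::md5sum(tmp))
}

# raw table -> transformed + centered, returning the pieces
.normalize_stage <- function(raw, params) {
  centered <- normalize_movies(transform_ipd_table(raw, params))
  centered
}

#' Run the full detection pipeline
#'
#' normalize -> homolog index -> genome scan -> (optional) evaluation,
#' writing scores (TSV), optional GFF3 calls, an FDR/TPR sweep when truth is
#' supplied, and a JSON run manifest naming the config hash, seed and stage
#' timings. Each stage failure is reported with the stage name.
#'
#' @param config a [pipeline_config()]
#' @param fasta reference FASTA path
#' @param native native IPD TSV path
#' @param control optional control IPD TSV path
#' @param historical character vector of historical IPD TSV paths (used for
#'   the homolog index; defaults to the control when absent)
#' @param truth optional truth BED path
#' @param outdir output directory
#' @return invisibly, a list with `scores`, `roc` (or `NULL`) and `manifest`
#' @export
run_pipeline <- function(config, fasta, native, control = NULL,
                         historical = NULL, truth = NULL, outdir = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$method == "hier_control" && is.null(control))
    stop("stage validate: method 'hier_control' needs --control")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
    message(sprintf("[kinemod] %s done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  genome <- stage("read", read_reference(fasta))
  nat_raw <- stage("read", read_ipd_table(native))
  ctl_raw <- if (!is.null(control)) stage("read", read_ipd_table(control))
  his_raw <- if (!is.null(historical))
    stage("read", lapply(historical, read_ipd_table))
  params <- stage("normalize", {
    if (config$calibrate) {
      pp <- split(nat_raw$ipd, paste(nat_raw$ref_name, nat_raw$position,
                                     nat_raw$strand))
      calibrate_transform(pp)
    } else transform_params(config$lam, config$shift)
  })
  nat <- stage("normalize", .normalize_stage(nat_raw, params))
  ctl <- if (!is.null(ctl_raw))
    stage("normalize", .normalize_stage(ctl_raw, params))
  window <- context_window(config$window_upstream, config$window_downstream)
  index <- stage("index", {
    src <- if (!is.null(his_raw))
      lapply(his_raw, function(t) .normalize_stage(t, params)$table)
    else if (!is.null(ctl)) list(ctl$table)
    else stop("no historical or control data to index")
    build_context_index(src, genome, window,
                        min_cov = config$index_min_cov,
                        min_positions = config$index_min_positions)
  })
  scores <- stage("detect", scan_genome(
    nat$table, control = if (!is.null(ctl)) ctl$table, index = index,
    genome = genome, window = window,
    min_native_cov = config$min_native_cov, method = config$method,
    tol = config$em_tol, max_iter = config$em_max_iter))
  hash <- .config_hash(config)
  score_path <- file.path(outdir, "scores.tsv")
  con <- file(score_path, "w")
  writeLines(sprintf("#kinemod_scores config_hash=%s", hash), con)
  write.table(as.data.frame(scores), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  if (is.finite(config$threshold))
    stage("gff", write_detections_gff(scores, config$threshold,
                                      file.path(outdir, "calls.gff3")))
  roc <- NULL
  if (!is.null(truth)) {
    roc <- stage("evaluate",
                 roc_curve(scores, read_truth_bed(truth),
                           tol_bp = config$eval_tol_bp))
    con <- file(file.path(outdir, "roc.tsv"), "w")
    writeLines(sprintf("#kinemod_roc config_hash=%s", hash), con)
    write.table(roc, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("kinemod")),
                   config = unclass(config), config_hash = hash,
                   seed = config$seed,
                   transform = list(lam = params$lam, shift = params$shift),
                   n_scored = nrow(scores),
                   n_skipped_context = attr(scores, "n_skipped_context"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scores = scores, roc = roc, manifest = manifest))
}
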