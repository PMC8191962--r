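## Pipeline orchestration: synth -> extract -> rank -> report, with a flat
## YAML config, one run-level seed fanned out to per-stage seeds, and a
## config hash + seed stamped into every output header so any stage can be
## reproduced independently.

.STAGES <- c("synth", "extract", "rank")

#' Derive a per-stage seed from the run seed
#'
#' Fixed affine derivation so each pipeline stage is independently
#' reproducible from the single run-level seed.
#'
#' @param seed Integer run seed.
#' @param stage One of `"synth"`, `"extract"`, `"rank"`.
#' @return Integer seed (< 2^31).
#' @export
derive_seed <- function(seed, stage) {
  stage <- match.arg(stage, .STAGES)
  as.integer((as.numeric(seed) * 7 + 1000 * match(stage, .STAGES)) %% 2147483647)
}

#' Assemble a pipeline run configuration
#'
#' @param synth Named list of [cohort_config()] arguments (the stage seed is
#'   supplied by the pipeline).
#' @param rf Named list of [rf_config()] arguments.
#' @param relief_k ReliefF neighbor count.
#' @param rfe_lambda Ridge penalty inside RFE.
#' @param top_k,min_methods CWF combination parameters.
#' @param seed Run-level seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synth = list(), rf = list(),
                       relief_k = 10, rfe_lambda = 1,
                       top_k = 20, min_methods = 3, seed = 1L) {
  structure(list(synth = synth, rf = rf, relief_k = relief_k,
                 rfe_lambda = rfe_lambda, top_k = top_k,
                 min_methods = min_methods, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg A [run_config()].
#' @return The [run_config()] (read); `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' MD5 hash of a run configuration
#'
#' @param cfg A [run_config()].
#' @return Character MD5 digest of the config's YAML form.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.stamp <- function(cfg, stage) {
  c(stage = stage,
    seed = as.character(cfg$seed),
    stage_seed = as.character(derive_seed(cfg$seed, stage)),
    config_hash = config_hash(cfg))
}

#' Pipeline stage: synthesize a cohort to disk
#'
#' Generates a synthetic cohort under the run config and writes the view
#' waveform files plus the cohort manifest; prints the class balance.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return Manifest path, invisibly.
#' @export
cmd_synth <- function(cfg, out_dir) {
  sc <- do.call(cohort_config,
                c(cfg$synth, list(seed = derive_seed(cfg$seed, "synth"))))
  gen <- generate_cohort(sc)
  manifest <- write_cohort(gen$cohort, out_dir, header = .stamp(cfg, "synth"))
  tab <- table(factor(gen$labels, c("responder", "non-responder")))
  message(sprintf("synthesized %d patients: %d responders / %d non-responders",
                  length(gen$cohort), tab[["responder"]],
                  tab[["non-responder"]]))
  invisible(manifest)
}

#' Pipeline stage: extract the cohort feature table
#'
#' @param manifest Cohort manifest path.
#' @param out_file Output feature-table path.
#' @param cfg A [run_config()] (for the output header stamp).
#' @return The feature table, invisibly.
#' @export
cmd_extract <- function(manifest, out_file, cfg = run_config()) {
  cohort <- load_cohort(manifest)
  skipped <- attr(cohort, "skipped")
  if (length(skipped))
    message("skipped ", length(skipped), " patient(s): ",
            paste(skipped, collapse = "; "))
  if (length(cohort) == 0L) {
    tab <- stats::setNames(
      data.frame(matrix(numeric(0), 0, 160)),
      c("patient_id", "response", feature_names()))
  } else {
    tab <- extract_cohort_features(cohort)
  }
  write_feature_table(tab, out_file, header = .stamp(cfg, "extract"))
  invisible(tab)
}

.write_ranking <- function(ranking, path, stamp) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", c(paste0("method: ", attr(ranking, "method")),
                            paste0(names(stamp), ": ", stamp))), con)
  utils::write.csv(as.data.frame(ranking), con, row.names = FALSE)
  invisible(path)
}

#' Pipeline stage: rank features and write the report
#'
#' Runs the out-of-bag random-forest importance, the five filter/wrapper
#' rankers and their CWF combination, and the correlation graph of the OOB
#' top-20; writes per-method ranking files, the CWF table, the correlation
#' edge list and a plain-text report with the top-20 lists, the view census
#' of the OOB top-20 and the OOB/CWF overlap.
#'
#' @param features Feature table (data frame) or path to one.
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return Named list of all rankings plus the correlation graph, invisibly.
#' @export
cmd_rank <- function(features, cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- if (is.character(features)) read_feature_table(features) else features
  fm <- feature_matrix(tab)
  stamp <- .stamp(cfg, "rank")
  rank_seed <- derive_seed(cfg$seed, "rank")

  oob <- oob_importance(fm$X, fm$y,
                        do.call(rf_config, c(cfg$rf, list(seed = rank_seed))))
  methods <- list(
    correlation_with_target = rank_by_target_correlation(fm$X, fm$y),
    welch_t = rank_by_welch_t(fm$X, fm$y),
    kbest_f = rank_by_kbest(fm$X, fm$y),
    rfe = rank_by_rfe(fm$X, fm$y, lambda = cfg$rfe_lambda),
    relief = rank_by_relief(fm$X, fm$y, k_neighbors = cfg$relief_k))
  cwf <- cwf_combine(unname(methods), top_k = cfg$top_k,
                     min_methods = cfg$min_methods)

  .write_ranking(oob, file.path(out_dir, "ranking_oob.csv"), stamp)
  for (m in names(methods))
    .write_ranking(methods[[m]],
                   file.path(out_dir, paste0("ranking_", m, ".csv")), stamp)
  .write_ranking(cwf, file.path(out_dir, "ranking_cwf.csv"), stamp)

  graph <- correlation_graph(fm$X, features = top_features(oob, cfg$top_k))
  con <- file(file.path(out_dir, "correlation_edges.csv"), "w", encoding = "UTF-8")
  writeLines(paste0("# ", names(stamp), ": ", stamp), con)
  utils::write.csv(graph$edges, con, row.names = FALSE)
  close(con)

  census <- view_census(top_features(oob, cfg$top_k))
  overlap <- ranking_overlap(oob, cwf, top_k = cfg$top_k)
  report <- c(
    "strain feature importance report",
    paste0(names(stamp), ": ", stamp),
    "",
    sprintf("patients: %d  features: %d", nrow(fm$X), ncol(fm$X)),
    sprintf("class balance: %s",
            paste(sprintf("%s=%d", names(table(fm$y)), table(fm$y)),
                  collapse = ", ")),
    "",
    sprintf("top %d by OOB importance:", cfg$top_k),
    sprintf("  %2d. %-18s %.4f", seq_len(min(cfg$top_k, nrow(oob))),
            top_features(oob, cfg$top_k),
            oob$score[seq_len(min(cfg$top_k, nrow(oob)))]),
    "",
    unlist(lapply(names(methods), function(m) c(
      sprintf("top %d by %s:", cfg$top_k, m),
      paste0("  ", paste(top_features(methods[[m]], cfg$top_k),
                         collapse = ", ")),
      ""))),
    sprintf("CWF combined ranking (%d eligible features):", nrow(cwf)),
    sprintf("  %2d. %-18s mean rank %.2f", seq_len(nrow(cwf)),
            cwf$feature, cwf$score),
    "",
    sprintf("view census of the OOB top-%d: %s", cfg$top_k,
            paste(sprintf("%s=%d", names(census), census), collapse = ", ")),
    sprintf("overlap of OOB and CWF top-%d sets: %d", cfg$top_k, overlap),
    sprintf("correlation graph of the OOB top-%d: %d edges with |r| > 0.5",
            cfg$top_k, nrow(graph$edges)))
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(c(list(oob = oob), methods,
              list(cwf = cwf, graph = graph, census = census,
                   overlap = overlap)))
}

#' Run the whole pipeline end-to-end
#'
#' Convenience wrapper: synthesize (or reuse an existing manifest), extract
#' features and rank them, leaving all artifacts under `out_dir`.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @param manifest Optional existing manifest; when `NULL` a synthetic
#'   cohort is generated under `out_dir/cohort`.
#' @return The [cmd_rank()] result, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir, manifest = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(manifest))
    manifest <- cmd_synth(cfg, file.path(out_dir, "cohort"))
  tab <- cmd_extract(manifest, file.path(out_dir, "features.csv"), cfg)
  cmd_rank(tab, cfg, out_dir)
}
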