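# End-to-end orchestration: simulate-or-load -> distances -> diversity ->
# entropy -> analyze, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' A single configuration object driving [run_pipeline()]. The source is
#' either a synthetic configuration (`simulate`) or a corpus CSV path
#' (`corpus_csv`); each downstream stage can be toggled.
#'
#' @param simulate A [synthetic_config()], or `NULL` when loading.
#' @param corpus_csv Path to a corpus CSV, or `NULL` when simulating.
#' @param stages Character subset of
#'   `c("distances", "diversity", "entropy", "analyze")` to run.
#' @param seed Integer seed for the analysis stages (SVM split/tuning);
#'   the simulation seed lives in `simulate$seed`.
#' @param svm Logical: run the SVM classification inside `analyze`
#'   (default `TRUE`).
#' @param svm_args List of overrides passed to
#'   [svm_classify_categories()] (e.g. smaller grids).
#' @param export_matrix Logical: write the dense pairwise matrix CSV
#'   (default `FALSE`; the dyad dataset is always written).
#' @return List of class `indri_pipeline_config`.
#' @export
pipeline_config <- function(simulate = synthetic_config(),
                            corpus_csv = NULL,
                            stages = c("distances", "diversity", "entropy",
                                       "analyze"),
                            seed = 1L, svm = TRUE, svm_args = list(),
                            export_matrix = FALSE) {
  all_stages <- c("distances", "diversity", "entropy", "analyze")
  stopifnot(all(stages %in% all_stages))
  if (is.null(simulate) && is.null(corpus_csv)) {
    stop("config needs either `simulate` or `corpus_csv`")
  }
  structure(list(simulate = simulate, corpus_csv = corpus_csv,
                 stages = stages, seed = as.integer(seed), svm = svm,
                 svm_args = svm_args, export_matrix = export_matrix),
            class = "indri_pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with fields mirroring [pipeline_config()];
#'   `simulate` holds [synthetic_config()] arguments.
#' @return An `indri_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- if (!is.null(obj$simulate)) {
    args <- obj$simulate
    if (!is.null(args$concentrations)) {
      args$concentrations <- unlist(args$concentrations)
    }
    do.call(synthetic_config, args)
  } else NULL
  pipeline_config(
    simulate = sim,
    corpus_csv = obj$corpus_csv,
    stages = if (is.null(obj$stages)) {
      c("distances", "diversity", "entropy", "analyze")
    } else unlist(obj$stages),
    seed = if (is.null(obj$seed)) 1L else obj$seed,
    svm = isTRUE(obj$svm) || is.null(obj$svm),
    svm_args = if (is.null(obj$svm_args)) list() else obj$svm_args,
    export_matrix = isTRUE(obj$export_matrix)
  )
}

stage_msg <- function(...) message("[indriflex] ", ...)

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing every intermediate
#' and final product under `out_dir`: the corpus CSV, the dyad-distance
#' CSV (and optionally the dense matrix), the diversity and covariation
#' CSVs, the per-singer entropy CSV, a JSON analysis report (model fits,
#' post-hocs, SVM, Kruskal-Wallis, correlations), and a run manifest with
#' an MD5 checksum per output. Deterministic given the configuration
#' seeds.
#'
#' @param config An `indri_pipeline_config` or a path to its JSON form.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "indri_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  note <- list()

  corpus <- if (!is.null(config$simulate)) {
    stage_msg("simulate: generating synthetic corpus (seed ",
              config$simulate$seed, ")")
    generate_corpus(config$simulate)
  } else {
    stage_msg("load: ", config$corpus_csv)
    read_corpus_csv(config$corpus_csv)
  }
  corpus_path <- file.path(out_dir, "corpus.csv")
  write_corpus_csv(corpus, corpus_path)
  outputs <- c(outputs, corpus_path)

  records <- NULL; jaro_m <- NULL
  if ("distances" %in% config$stages) {
    stage_msg("distances: pairwise Jaro matrix over ",
              nrow(corpus$contributions), " contributions")
    jaro_m <- pairwise_jaro_matrix(corpus)
    records <- build_dyad_dataset(jaro_m, corpus)
    p <- file.path(out_dir, "dyad_distances.csv")
    write.csv(records, p, row.names = FALSE)
    outputs <- c(outputs, p)
    if (config$export_matrix) {
      pm <- file.path(out_dir, "jaro_matrix.csv")
      write.csv(jaro_m, pm)
      outputs <- c(outputs, pm)
    }
  }

  div <- NULL
  if ("diversity" %in% config$stages) {
    stage_msg("diversity: per-contribution table + duet covariation")
    div <- diversity_table(corpus)
    p <- file.path(out_dir, "diversity.csv")
    write.csv(div, p, row.names = FALSE)
    cov <- group_covariation(div, corpus)
    pc <- file.path(out_dir, "duet_covariation.csv")
    write.csv(cov, pc, row.names = FALSE)
    outputs <- c(outputs, p, pc)
  }

  ent <- NULL
  if ("entropy" %in% config$stages) {
    stage_msg("entropy: per-singer Markov entropy rates")
    ent <- entropy_table(corpus)
    p <- file.path(out_dir, "entropy.csv")
    write.csv(ent, p, row.names = FALSE)
    outputs <- c(outputs, p)
  }

  if ("analyze" %in% config$stages) {
    stage_msg("analyze: mixed models, SVM, nonparametric tests")
    report <- list(seed = config$seed)
    if (!is.null(records)) {
      fit_d <- fit_distance_lmm(records)
      report$distance_lmm <- list(
        chisq = fit_d$chisq, df = fit_d$df, p_value = fit_d$p_value,
        df_method = fit_d$df_method, posthoc = fit_d$posthoc)
    }
    if (!is.null(div)) {
      fit_n <- fit_diversity_lmm(div)
      report$diversity_lmm <- list(
        chisq = fit_n$chisq, df = fit_n$df, p_value = fit_n$p_value,
        df_method = fit_n$df_method, posthoc = fit_n$posthoc)
      report$duet_covariation <- group_covariation(div, corpus)
    }
    if (!is.null(ent)) {
      report$entropy_tests <- entropy_group_tests(ent)
    }
    if (config$svm && !is.null(jaro_m)) {
      labels <- singer_category(corpus$singers)[
        match(corpus$contributions$singer_id, corpus$singers$singer_id)]
      svm_args <- c(list(matrix = jaro_m, labels = labels,
                         seed = config$seed), config$svm_args)
      report$svm <- tryCatch({
        r <- do.call(svm_classify_categories, svm_args)
        list(C = r$C, sigma = r$sigma, cv_accuracy = r$cv_accuracy,
             train_accuracy = r$train_accuracy,
             test_accuracy = r$test_accuracy,
             per_class_recall = as.list(r$per_class_recall),
             confusion = as.data.frame.matrix(unclass(r$confusion)))
      }, error = function(e) list(skipped = conditionMessage(e)))
    }
    p <- file.path(out_dir, "analysis_report.json")
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    outputs <- c(outputs, p)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("indriflex")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    stages = config$stages,
    source = if (!is.null(config$simulate)) "simulate" else config$corpus_csv,
    simulate_seed = if (!is.null(config$simulate)) config$simulate$seed
                    else NULL,
    outputs = lapply(setNames(outputs, basename(outputs)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
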