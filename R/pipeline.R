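# End-to-end pipeline driver: simulate -> preprocess -> characterize ->
# match -> ampute -> impute -> evaluate, with stage logging and an output
# manifest carrying checksums.

#' Configure an end-to-end run
#'
#' Validated up front, before any stage executes: enabling `impute` without
#' `ampute`, or `evaluate` without `impute`, is a configuration error.
#'
#' @param stages Character vector of stage names to run, a subset of
#'   `simulate`, `preprocess`, `characterize`, `match`, `ampute`, `impute`,
#'   `evaluate` (order fixed internally).
#' @param seed Master seed; every stochastic stage derives its own seed.
#' @param synth A [synth_config()] for the `simulate` stage.
#' @param min_prevalence Variable prevalence threshold for preprocessing.
#' @param presence_targets Variables whose presence to predict in the
#'   `characterize` stage (`NULL` skips presence prediction).
#' @param match_n Sample size of the representative matching step; default
#'   one fifth of the population.
#' @param ampute Amputation request: list with `mechanism` (`"mcar"`,
#'   `"mar"`, `"mnar"` or `"realistic"`) and that mechanism's parameters.
#' @param methods Imputation methods to run.
#' @param m Completed copies per method.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("simulate", "preprocess", "characterize",
                                       "match", "ampute", "impute", "evaluate"),
                            seed = 1,
                            synth = synth_config(n_patients = 500, seed = derive_seed(seed, "synth")),
                            min_prevalence = 0.005,
                            presence_targets = NULL,
                            match_n = NULL,
                            ampute = list(mechanism = "mcar", p = 0.3),
                            methods = c("mean", "ce_norm"),
                            m = 5) {
  order_all <- c("simulate", "preprocess", "characterize", "match", "ampute",
                 "impute", "evaluate")
  unknown <- setdiff(stages, order_all)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  stages <- order_all[order_all %in% stages]
  needs <- list(preprocess = "simulate", characterize = "preprocess",
                match = "preprocess", ampute = "match", impute = "ampute",
                evaluate = "impute")
  for (s in stages) {
    if (!is.null(needs[[s]]) && !needs[[s]] %in% stages)
      stop("stage '", s, "' requires stage '", needs[[s]], "'", call. = FALSE)
  }
  structure(list(stages = stages, seed = seed, synth = synth,
                 min_prevalence = min_prevalence,
                 presence_targets = presence_targets, match_n = match_n,
                 ampute = ampute, methods = methods, m = m),
            class = "pipeline_config")
}

stage_log <- function(stage, ...) message("[", stage, "] ", ...)

#' Run the end-to-end pipeline
#'
#' Executes the configured stages in order, writing each stage's artifacts
#' under `out_dir` and finishing with a `manifest.csv` listing every output
#' with its MD5 checksum. A stage failure halts the run with a stage-named
#' error; artifacts already written are retained.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `status` (0), `out_dir` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  on_stage <- function(s) s %in% config$stages
  pop <- events <- mat <- cc <- masked <- NULL
  state <- new.env(parent = emptyenv())

  if (on_stage("simulate")) run_stage("simulate", {
    pop <- generate_population(config$synth)
    stage_log("simulate", nrow(pop$demographics), " patients, ",
              nrow(pop$events), " events, seed ", config$synth$seed)
    write_demographics(pop$demographics, file.path(out_dir, "demographics.csv"))
    write_long_events(pop$events, file.path(out_dir, "events.csv"))
    state$pop <- pop
  })

  if (on_stage("preprocess")) run_stage("preprocess", {
    pop <- state$pop
    ev <- filter_records(pop$events, pop$demographics,
                         min_prevalence = config$min_prevalence)
    mat <- window_and_aggregate(ev, panel_map = config$synth$panel_map)
    mat <- boxcox_z(mat)
    stage_log("preprocess", nrow(ev), " events kept; matrix ",
              nrow(mat$values), " x ", ncol(mat$values), " with ",
              sum(is.na(mat$values)), " missing cells")
    write_wide_matrix(mat, file.path(out_dir, "matrix.csv"))
    jsonlite::write_json(mat$transforms,
                         file.path(out_dir, "transform_params.json"),
                         digits = NA)
    state$mat <- mat
  })

  if (on_stage("characterize")) run_stage("characterize", {
    mat <- state$mat
    rk <- missingness_ranking(mat)
    utils::write.csv(rk, file.path(out_dir, "ranking.csv"), row.names = FALSE)
    stage_log("characterize", "ranking over ", nrow(rk), " variables; ",
              sprintf("%.1f%%", utils::tail(rk$pct_complete, 1)),
              " complete cases at full rank")
    for (tg in config$presence_targets) {
      pp <- predict_presence(mat, tg, seed = derive_seed(config$seed, "presence", tg))
      utils::write.csv(data.frame(target = tg, fold = seq_along(pp$auroc),
                                  auroc = pp$auroc),
                       file.path(out_dir, paste0("presence_", tg, ".csv")),
                       row.names = FALSE)
      stage_log("characterize", "presence AUROC for ", tg, ": ",
                sprintf("%.3f", pp$mean_auroc))
    }
  })

  if (on_stage("match")) run_stage("match", {
    mat <- state$mat
    pop <- state$pop
    cc <- extract_complete_cases(mat)
    demo <- pop$demographics
    cc_demo <- demo[demo$patient_id %in% rownames(cc$values), ]
    n <- config$match_n %||% max(1L, nrow(demo) %/% 5L)
    matches <- match_representative_sample(demo, cc_demo, n = n,
                                           seed = derive_seed(config$seed, "match"))
    utils::write.csv(matches, file.path(out_dir, "matches.csv"),
                     row.names = FALSE)
    bench_rows <- unique(matches$match_id)
    bench <- lab_matrix(cc$values[bench_rows, , drop = FALSE],
                        panel_map = cc$panel_map)
    stage_log("match", nrow(cc$values), " complete cases; ",
              length(bench_rows), " distinct matched cases in the benchmark set")
    state$cc <- cc
    state$bench <- bench
  })

  if (on_stage("ampute")) run_stage("ampute", {
    bench <- state$bench
    amp <- config$ampute
    seed_a <- derive_seed(config$seed, "ampute")
    masked <- switch(tolower(amp$mechanism),
      mcar = ampute_mcar(bench, p = amp$p %||% 0.3, seed = seed_a),
      mar = ampute_mar(bench, amp$col_a, amp$col_b, amp$quartile %||% 1,
                       amp$frac %||% 0.5, seed = seed_a),
      mnar = ampute_mnar(bench, amp$col, amp$quartile %||% 1,
                         amp$frac %||% 0.5, seed = seed_a),
      realistic = {
        pop <- state$pop
        demo <- pop$demographics
        cc_demo <- demo[demo$patient_id %in% rownames(bench$values), ]
        ampute_realistic(bench, cc_demo,
                         population_matrix(pop, apply_mask = TRUE), demo)
      },
      stop("unknown amputation mechanism '", amp$mechanism, "'")
    )
    stage_log("ampute", masked$spec$mechanism, ": ", sum(masked$mask),
              " of ", length(masked$mask), " cells removed")
    write_wide_matrix(masked$truth, file.path(out_dir, "truth.csv"))
    write_mask(masked$mask, file.path(out_dir, "mask.csv"))
    spec <- masked$spec
    spec$matches <- NULL
    jsonlite::write_json(spec, file.path(out_dir, "amputation_spec.json"),
                         auto_unbox = TRUE, digits = NA)
    state$masked <- masked
  })

  if (on_stage("impute")) run_stage("impute", {
    masked <- state$masked
    completed <- list()
    for (meth in config$methods) {
      cs <- impute(masked, method = meth, m = config$m,
                   seed = derive_seed(config$seed, "impute", meth))
      for (i in seq_len(cs$m))
        write_wide_matrix(cs$imputations[[i]],
                          file.path(out_dir, sprintf("imputed_%s_%d.csv", meth, i)))
      stage_log("impute", meth, ": ", cs$m, " completed copies")
      completed[[meth]] <- cs
    }
    state$completed <- completed
  })

  if (on_stage("evaluate")) run_stage("evaluate", {
    masked <- state$masked
    rows <- benchmark_imputation(list(run = masked), config$methods,
                                 m = config$m,
                                 seed = derive_seed(config$seed, "evaluate"))
    utils::write.csv(rows, file.path(out_dir, "eval_report.csv"),
                     row.names = FALSE)
    summary <- list(
      md_definition = "mean over variables of (rmse_to_truth - between_imputation_rmse)",
      methods = lapply(split(rows[rows$scope == "overall", ],
                             rows$method[rows$scope == "overall"]),
                       function(r) list(rmse = r$rmse, between_rmse = r$between_rmse,
                                        failed = r$failed)))
    jsonlite::write_json(summary, file.path(out_dir, "eval_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_log("evaluate", nrow(rows), " report rows for ",
              length(config$methods), " methods")
  })

  files <- sort(setdiff(list.files(out_dir), "manifest.csv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(status = 0L, out_dir = out_dir, manifest = manifest))
}
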