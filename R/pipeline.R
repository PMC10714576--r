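# End-to-end pipeline: clean -> normalize -> cluster -> weights -> score
# -> reference -> assess, with per-stage seeds, artifact files and a run
# manifest.

.default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "immunoscore_run",
    input = NULL,                       # list(csv = path) or list(simulate = list(...))
    filters = list(),                   # overrides for apply_health_filters()
    cluster = list(K = 3L, restarts = 5L, max_iter = 100L,
                   tol = 1e-6, ridge = 1e-6, space = "normalized"),
    weights = list(n_repeats = 200L, fraction = 0.8),
    reference = list(orders = 1:4, cv_folds = 5L, final_order = 3L),
    stages = c("clean", "normalize", "cluster", "weights", "score",
               "reference", "assess")
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.stage_deps <- c(clean = "", normalize = "clean", cluster = "normalize",
                 weights = "cluster", score = "weights",
                 reference = "score", assess = "reference")

#' Run the full immune-status scoring pipeline
#'
#' Executes the requested stages in order: health filtering, index
#' statistics and normalization, EM-GMM clustering at K components with
#' semantic ordering, importance-weight estimation over repeated splits,
#' immunity scoring with distribution and age-trend summaries, the
#' age-reference polynomial fit, and the healthy / sub-healthy
#' assessment. All artifacts (CSV tables, YAML parameter files, a JSON
#' manifest with content digests) are written under `out_dir`. Every
#' source of randomness derives from the single `seed`, so a re-run with
#' the same config reproduces identical artifacts.
#'
#' @param config A (possibly partial) configuration list or the path to a
#'   YAML file; see Details. Must provide `input$csv` (a CBC table) or
#'   `input$simulate` (arguments for [cohort_sim_config()]).
#' @return A `run_manifest`: list with the config snapshot, seeds,
#'   per-stage row counts, output paths and their md5 digests.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    # keep YAML-1.1 boolean-like scalars ("n", "y", ...) as literal text:
    # "n" is a config key (cohort size), not FALSE
    config <- yaml::read_yaml(config,
                              handlers = list("bool#no" = function(x) x,
                                              "bool#yes" = function(x) x))
  }
  cfg <- .merge_config(.default_pipeline_config(), config)
  stages <- cfg$stages
  for (st in stages) {
    dep <- .stage_deps[[st]]
    if (nzchar(dep) && !dep %in% stages) {
      stop("stage '", st, "' requires stage '", dep, "'")
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = as.character(utils::packageVersion("immunoscore")),
                   config = cfg, seed = cfg$seed,
                   stages = list(), outputs = list())
  paths <- character(0)
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    paths[[name]] <<- path
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      manifest$error <<- list(stage = stage, message = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, force = TRUE, digits = NA)
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  env <- new.env()
  if ("clean" %in% stages) run_stage("clean", function() {
    if (!is.null(cfg$input$csv)) {
      records <- read_cbc_table(cfg$input$csv)
      input_digest <- unname(tools::md5sum(cfg$input$csv))
    } else if (!is.null(cfg$input$simulate)) {
      sim_args <- cfg$input$simulate
      sim_args$seed <- sim_args$seed %||% derive_seed(cfg$seed, 1L)
      sim <- generate_cohort(do.call(cohort_sim_config, sim_args))
      records <- sim$records
      emit("truth.csv", function(p) write.csv(sim$truth, p, row.names = FALSE))
      input_digest <- NA_character_
    } else {
      stop("config must provide input$csv or input$simulate")
    }
    rep_f <- apply_health_filters(
      records,
      age_range = cfg$filters$age_range %||% c(20, 84),
      pct_max = cfg$filters$pct_max %||% 0.5)
    env$cohort <- rep_f$retained
    emit("clean.csv", function(p) {
      write.csv(as.data.frame(rep_f$retained), p, row.names = FALSE)
    })
    emit("rejects.csv", function(p) {
      rej <- rep_f$rejected[, c("subject_id", "reason"), drop = FALSE]
      write.csv(rej, p, row.names = FALSE)
    })
    note("clean", n_in = rep_f$n_input, n_out = nrow(rep_f$retained),
         input_digest = input_digest)
  })

  if ("normalize" %in% stages) run_stage("normalize", function() {
    env$panels <- derive_panels(env$cohort)
    env$stats <- fit_index_stats(env$panels)
    env$Z <- normalize_cohort(env$panels, env$stats)
    emit("stats.yaml", function(p) write_index_stats(env$stats, p))
    note("normalize", n = nrow(env$Z))
  })

  if ("cluster" %in% stages) run_stage("cluster", function() {
    space <- if (identical(cfg$cluster$space, "log")) {
      log(env$panels)
    } else env$Z
    env$model <- fit_em_gmm(space, K = cfg$cluster$K,
                            seed = derive_seed(cfg$seed, 2L),
                            max_iter = cfg$cluster$max_iter,
                            tol = cfg$cluster$tol,
                            restarts = cfg$cluster$restarts,
                            ridge = cfg$cluster$ridge)
    env$ordering <- order_clusters(env$model, env$cohort$age)
    env$group <- semantic_labels(env$model, env$ordering)
    emit("model.json", function(p) {
      jsonlite::write_json(list(
        K = env$model$K, pi = env$model$pi,
        means = env$model$means,
        covariances = env$model$covariances,
        loglik = env$model$loglik_trace[length(env$model$loglik_trace)],
        n_iter = env$model$n_iter, converged = env$model$converged,
        mapping = as.list(env$ordering$mapping)),
        p, digits = NA, force = TRUE)
    })
    note("cluster", n = nrow(env$Z), K = cfg$cluster$K,
         converged = env$model$converged,
         group_sizes = as.list(table(env$group)))
  })

  if ("weights" %in% stages) run_stage("weights", function() {
    env$weights <- importance_weights(
      env$Z, env$group, n_repeats = cfg$weights$n_repeats,
      fraction = cfg$weights$fraction,
      seed = derive_seed(cfg$seed, 3L))
    emit("weights.yaml", function(p) write_importance_weights(env$weights, p))
    emit("weights_table.csv", function(p) {
      write.csv(weights_table(env$weights), p, row.names = FALSE)
    })
    note("weights", n_repeats = cfg$weights$n_repeats)
  })

  if ("score" %in% stages) run_stage("score", function() {
    env$scores <- score_cohort(env$Z, env$weights)
    scores_df <- data.frame(subject_id = env$cohort$subject_id,
                            age = env$cohort$age, sex = env$cohort$sex,
                            score = env$scores, group = env$group)
    emit("scores.csv", function(p) write.csv(scores_df, p, row.names = FALSE))
    emit("score_distribution.csv", function(p) {
      write.csv(score_distribution(env$scores), p, row.names = FALSE)
    })
    trend <- score_age_trend(env$scores, env$cohort$age)
    emit("score_age_trend.csv", function(p) {
      write.csv(trend$medians, p, row.names = FALSE)
    })
    note("score", n = length(env$scores),
         rho_subjects = trend$rho_subjects, rho_medians = trend$rho_medians)
  })

  if ("reference" %in% stages) run_stage("reference", function() {
    env$reference <- fit_reference(env$cohort$age, env$scores,
                                   orders = cfg$reference$orders,
                                   cv_folds = cfg$reference$cv_folds,
                                   seed = derive_seed(cfg$seed, 4L),
                                   final_order = cfg$reference$final_order)
    emit("reference.yaml", function(p) write_age_reference(env$reference, p))
    note("reference", order = env$reference$order)
  })

  if ("assess" %in% stages) run_stage("assess", function() {
    res <- assess(data.frame(subject_id = env$cohort$subject_id,
                             age = env$cohort$age, score = env$scores),
                  env$reference)
    emit("assessments.csv", function(p) {
      write.csv(as.data.frame(res), p, row.names = FALSE)
    })
    note("assess", n = nrow(res),
         healthy = sum(res$status == "healthy"),
         sub_healthy = sum(res$status == "sub_healthy"))
  })

  manifest$outputs <- lapply(paths, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("immunoscore run manifest\n")
  for (st in names(x$stages)) {
    info <- x$stages[[st]]
    cat(sprintf("  %-10s %s\n", st,
                paste(names(info), vapply(info, function(v) {
                  paste(format(unlist(v)), collapse = "/")
                }, character(1)), sep = "=", collapse = ", ")))
  }
  cat(sprintf("  %d output file(s) in %s\n", length(x$outputs),
              x$config$out_dir))
  invisible(x)
}
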