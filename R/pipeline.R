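# Pipeline orchestration: composable stages with CSV/JSON artifacts on
# disk, so intermediate results can be inspected or consumed by other
# tooling. Stage boundaries are files, not in-memory handoffs.

#' Pipeline configuration
#'
#' A single resolved configuration object consumed by [run_command()].
#' Every run writes the fully resolved config it used next to its
#' artifacts.
#'
#' @param out_dir Output directory for all artifacts.
#' @param preset Synthetic cohort preset for the `simulate` stage
#'   (`"effect"` or `"null"`).
#' @param seed Master seed (cohort generation and CV folds derive from it).
#' @param k_bits,clip_mode Normalization settings.
#' @param f_enter,f_remove,priors,cv_mode Discriminant-analysis settings.
#' @param folds LASSO cross-validation folds.
#' @param hl_bins Hosmer-Lemeshow bins.
#' @param ci_method AUC confidence-interval method.
#' @param cohort Optional explicit [cohort_config()]; overrides `preset`
#'   for the `simulate` stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, preset = "effect", seed = 1L,
                            k_bits = 6L, clip_mode = "mu3sd",
                            f_enter = 3.84, f_remove = 2.71,
                            priors = "equal", cv_mode = "loo",
                            folds = 10L, hl_bins = 10L,
                            ci_method = "delong", cohort = NULL) {
  structure(
    list(out_dir = out_dir, preset = preset, seed = as.integer(seed),
         cohort = cohort,
         k_bits = as.integer(k_bits), clip_mode = clip_mode,
         f_enter = f_enter, f_remove = f_remove, priors = priors,
         cv_mode = cv_mode, folds = as.integer(folds),
         hl_bins = as.integer(hl_bins), ci_method = ci_method),
    class = "pipeline_config"
  )
}

.cfg_path <- function(config, ...) file.path(config$out_dir, ...)

.need_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream artifact ", path,
         "; run the '", producer, "' stage first")
  path
}

#' Run a pipeline stage
#'
#' Stages: `simulate` (synthetic cohort to disk), `extract` (feature table
#' CSV), `sda` (stepwise selection, Fisher model JSON, classification
#' report), `lasso` (pairwise signatures and score CSV), `evaluate`
#' (AUC/CI and Hosmer-Lemeshow summary JSON), `run-all` (all of the above
#' in order). Each stage reads and writes only declared CSV/JSON artifacts
#' under `config$out_dir`.
#'
#' @param name Stage name.
#' @param config A [pipeline_config()].
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_command <- function(name = c("simulate", "extract", "sda", "lasso",
                                 "evaluate", "run-all"),
                        config) {
  name <- match.arg(name)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), .cfg_path(config, "config_used.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  switch(name,
    "simulate" = .stage_simulate(config),
    "extract"  = .stage_extract(config),
    "sda"      = .stage_sda(config),
    "lasso"    = .stage_lasso(config),
    "evaluate" = .stage_evaluate(config),
    "run-all"  = {
      out <- c(.stage_simulate(config), .stage_extract(config),
               .stage_sda(config), .stage_lasso(config),
               .stage_evaluate(config))
      invisible(out)
    })
}

.stage_simulate <- function(config) {
  cc <- if (!is.null(config$cohort)) config$cohort else
    cohort_preset(config$preset, seed = config$seed)
  cohort <- generate_cohort(cc)
  img_dir <- .cfg_path(config, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$images))
    write_image_csv(cohort$images[[key]], file.path(img_dir, paste0(key, ".csv")))
  roi_path <- .cfg_path(config, "roi_table.csv")
  utils::write.csv(cohort$roi_table, roi_path, row.names = FALSE)
  invisible(c(img_dir, roi_path))
}

.stage_extract <- function(config) {
  roi_path <- .need_artifact(.cfg_path(config, "roi_table.csv"), "simulate")
  img_dir <- .need_artifact(.cfg_path(config, "images"), "simulate")
  roi_table <- read_roi_table(roi_path)
  keys <- unique(paste(roi_table$rat_id, roi_table$slice_id, sep = "_"))
  images <- stats::setNames(lapply(keys, function(k)
    load_image(file.path(img_dir, paste0(k, ".csv")), format = "csv")), keys)
  tab <- extract_feature_table(images, roi_table, k_bits = config$k_bits,
                               clip_mode = config$clip_mode)
  out <- .cfg_path(config, "features.csv")
  write_feature_table(tab, out)
  invisible(out)
}

.stage_sda <- function(config) {
  tab <- read_feature_table(.need_artifact(.cfg_path(config, "features.csv"),
                                           "extract"))
  sel <- stepwise_select(tab, f_enter = config$f_enter,
                         f_remove = config$f_remove)
  if (!length(sel)) stop("stepwise selection admitted no feature")
  canon <- fit_canonical(tab, sel)
  fisher <- fit_fisher(tab, sel, priors = config$priors)
  resub <- evaluate_classification(tab, sel, "resubstitution",
                                   priors = config$priors)
  cv <- evaluate_classification(tab, sel, config$cv_mode,
                                priors = config$priors)
  model_path <- .cfg_path(config, "sda_model.json")
  write_fisher_json(fisher, model_path)
  report <- list(
    selected_features = sel,
    eigenvalues = canon$eigenvalues,
    chain = canon$chain,
    resubstitution = list(overall = resub$overall,
                          per_group = as.list(resub$per_group)),
    cross_validated = list(mode = cv$mode, overall = cv$overall,
                           per_group = as.list(cv$per_group)))
  report_path <- .cfg_path(config, "sda_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(c(model_path, report_path))
}

.stage_lasso <- function(config) {
  tab <- read_feature_table(.need_artifact(.cfg_path(config, "features.csv"),
                                           "extract"))
  groups <- unique(tab$group)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  sig_dir <- .cfg_path(config, "signatures")
  dir.create(sig_dir, recursive = TRUE, showWarnings = FALSE)
  scores <- list()
  for (pr in pairs) {
    res <- pairwise_signature_auc(tab, pr[1], pr[2],
                                  seed = config$seed, folds = config$folds)
    pair_tag <- paste(pr, collapse = "_vs_")
    write_signature_json(res$signature,
                         file.path(sig_dir, paste0(pair_tag, ".json")))
    sub <- tab[tab$group %in% pr, c("rat_id", "slice_id", "side", "group")]
    k <- which.min(abs(res$path$lambda - res$path$lambda_min))
    sc <- score_signature(res$signature, tab[tab$group %in% pr, ])
    scores[[pair_tag]] <- cbind(pair = pair_tag, sub,
                                cv_score = res$path$preval[, k],
                                score = sc$score,
                                probability = sc$probability)
  }
  score_path <- .cfg_path(config, "signature_scores.csv")
  utils::write.csv(do.call(rbind, scores), score_path, row.names = FALSE)
  invisible(c(sig_dir, score_path))
}

.stage_evaluate <- function(config) {
  sc <- utils::read.csv(.need_artifact(
    .cfg_path(config, "signature_scores.csv"), "lasso"),
    stringsAsFactors = FALSE)
  out <- lapply(split(sc, sc$pair), function(d) {
    pos <- strsplit(d$pair[1], "_vs_")[[1]][2]
    y <- as.integer(d$group == pos)
    roc_cv <- roc_auc(d$cv_score, y, ci_method = config$ci_method)
    roc_rs <- roc_auc(d$score, y, ci_method = config$ci_method)
    hl <- tryCatch(
      hosmer_lemeshow(pmin(pmax(d$probability, 1e-12), 1 - 1e-12), y,
                      bins = config$hl_bins),
      error = function(e) NULL, warning = function(w) suppressWarnings(
        hosmer_lemeshow(pmin(pmax(d$probability, 1e-12), 1 - 1e-12), y,
                        bins = config$hl_bins)))
    list(n = nrow(d), auc_cv = roc_cv$auc, auc_cv_ci = roc_cv$ci,
         auc_resub = roc_rs$auc, auc_resub_ci = roc_rs$ci,
         hl_statistic = if (!is.null(hl)) hl$statistic else NA,
         hl_p = if (!is.null(hl)) hl$p_value else NA)
  })
  path <- .cfg_path(config, "evaluation_summary.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
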