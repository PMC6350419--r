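# End-to-end experiment driver: synthesize cohorts -> fit the aging model
# -> generate the reference control/patient cohorts -> recover the disease
# parameters by grid search -> extract features and train the classifier
# -> simulate and evaluate the staged progression.

#' Default pipeline configuration
#'
#' Returns the full study-scale configuration: 82-region atlas, 126 core
#' links, 52-subject healthy cohort, 39 + 39 matched reference cohorts,
#' 15 simulated years with weekly Euler steps, the default (alpha,
#' beta_ad) grids, 1000-tree ranking forests and 10-fold cross-validation.
#' Every module seed is derived deterministically from `master_seed`.
#'
#' @param master_seed Integer master seed.
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(master_seed = 1) {
  structure(list(
    master_seed = as.integer(master_seed),
    generator = list(n_region_pairs = 41, n_core_links = 126,
                     n_extra_links_per_subject = 30, noise_sd = 2,
                     weight_scale = 100),
    true_disease = list(seed_label = "A01L", alpha = 0.4, beta_ad = 0.025,
                        x0 = 0.1),
    aging = list(criterion = "bic"),
    simulation = list(years = 15, dt = 1 / 52),
    search = list(alpha_grid = seq(0.1, 1, by = 0.1),
                  beta_grid = seq(0.005, 0.05, by = 0.005),
                  seed_labels = NULL,   # NULL = every bilateral pair
                  dt = 1 / 52),
    reference = list(n_pairs = 39),
    classifier = list(C_grid = c(1, 10, 100), k_folds = 10, n_trees = 1000,
                      n_features_grid = NULL, run_cv = TRUE,
                      n_features = NULL, C = NULL),
    fdr_q = 0.05),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults of [default_run_config()];
#' anything omitted keeps its default.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read configuration files",
         call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(if (!is.null(user$master_seed))
    user$master_seed else 1)
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        merge_into(base[[nm]], upd[[nm]])
      } else upd[[nm]]
    }
    base
  }
  merge_into(cfg, user)
}

#' Run the full analysis pipeline
#'
#' Executes the whole experiment from one configuration: (1) generate the
#' healthy cohort with known aging ground truth; (2) compute the minimum
#' grid mask and fit the link-wise aging regressions; (3) generate matched
#' reference control/patient cohorts by running the disease model at the
#' configured true parameters; (4) recover the disease parameters by grid
#' search against the reference strength-difference vector; (5) extract
#' centrality features, optionally profile (C, n_features) by
#' cross-validation, and fit the final classifier on the reference
#' cohorts; (6) simulate the staged progression of the two healthy-cohort
#' halves at the recovered parameters and evaluate per-stage significance.
#' All artifacts are written under `out_dir` in plain-text formats; rerun
#' with the same configuration reproduces identical outputs.
#'
#' @param config A `run_config`, see [default_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the run summary (also written as `summary.json`).
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = tempfile("adspread_run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$master_seed
  stage_fail <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # (1) healthy cohort with ground truth
  gcfg <- do.call(generator_config,
                  c(config$generator, list(rng_seed = seed)))
  gen <- stage_fail("synthesize", generate_nki_like_cohort(gcfg))
  nki <- gen$cohort
  rt <- nki$region_table
  write_cohort(nki, file.path(out_dir, "nki_cohort"))

  # (2) aging model on the minimum grid mask
  grid <- stage_fail("grid_mask", compute_grid_mask(nki))
  fit <- stage_fail("aging_fit",
                    fit_link_models(nki, grid, config$aging$criterion))
  jsonlite::write_json(fit$models, file.path(out_dir, "aging_fit.json"),
                       digits = NA, pretty = TRUE)

  # (3) reference control/patient cohorts at the true parameters
  true_p <- disease_params(
    seed_pair_for_label(rt, config$true_disease$seed_label),
    config$true_disease$alpha, config$true_disease$beta_ad,
    config$true_disease$x0)
  ref <- stage_fail("reference_cohorts", generate_adni_like_cohorts(
    gcfg, true_p, fit, years = config$simulation$years,
    n_pairs = config$reference$n_pairs, dt = config$simulation$dt))
  target <- strength_diff_vector(ref$controls, ref$patients)

  # (4) inverse fit by grid search over the healthy-cohort halves
  halves <- split_matched_groups(nki)
  seed_cand <- if (is.null(config$search$seed_labels)) NULL else
    t(vapply(config$search$seed_labels, seed_pair_for_label,
             integer(2), region_table = rt))
  fitres <- stage_fail("grid_search", grid_search(
    halves$groupI, halves$groupII, fit, target,
    seed_candidates = seed_cand,
    alpha_grid = config$search$alpha_grid,
    beta_grid = config$search$beta_grid,
    years = config$simulation$years, dt = config$search$dt,
    x0 = config$true_disease$x0))
  data.table::fwrite(fitres$surface, file.path(out_dir, "cost_surface.csv"))

  # (5) classifier on the reference cohorts
  fm <- stage_fail("features", cohort_feature_matrix(ref$controls,
                                                     ref$patients))
  cls <- config$classifier
  if (isTRUE(cls$run_cv)) {
    profile <- stage_fail("cv_profile", cv_auc_profile(
      fm$X, fm$y, C_grid = cls$C_grid,
      n_features_grid = cls$n_features_grid, k_folds = cls$k_folds,
      n_trees = cls$n_trees, rng_seed = seed + 1))
    data.table::fwrite(profile, file.path(out_dir, "cv_profile.csv"))
    op <- select_operating_point(profile)
  } else {
    profile <- NULL
    op <- list(C = if (is.null(cls$C)) 10 else cls$C,
               n_features = if (is.null(cls$n_features)) 86 else
                 cls$n_features,
               mean_auc = NA_real_)
  }
  model <- stage_fail("final_model", fit_final_model(
    fm$X, fm$y, n_features = op$n_features, C = op$C,
    n_trees = cls$n_trees, rng_seed = seed + 2))

  # (6) staged progression at the recovered parameters
  sims_I <- stage_fail("simulate_controls", simulate_normal_aging_cohort(
    halves$groupI, fit, years = config$simulation$years,
    dt = config$simulation$dt))
  sims_II <- stage_fail("simulate_patients", simulate_cohort(
    halves$groupII, fitres$best_params, fit,
    years = config$simulation$years, dt = config$simulation$dt))
  staged_c <- stage_feature_tables(sims_I, rt)
  staged_p <- stage_feature_tables(sims_II, rt)
  report <- stage_fail("stage_report", evaluate_stages(
    model, staged_c, staged_p, q = config$fdr_q))
  data.table::fwrite(report$table, file.path(out_dir, "stage_report.csv"))

  best <- fitres$best_params
  summary <- list(
    master_seed = seed,
    n_regions = nrow(rt),
    n_features = 5L * nrow(rt),
    grid_links = nrow(grid$link_list),
    true_params = list(seed_label = config$true_disease$seed_label,
                       alpha = config$true_disease$alpha,
                       beta_ad = config$true_disease$beta_ad),
    fitted_params = list(seed_label = rt$label[best$seed_pair[1] + 1L],
                         alpha = best$alpha, beta_ad = best$beta_ad,
                         cost = fitres$best_cost),
    classifier = list(C = op$C, n_features = op$n_features,
                      cv_mean_auc = op$mean_auc),
    stage_auc = stats::setNames(report$table$auc,
                                paste0("stage_", report$table$stage)),
    cutoff_stage = report$cutoff)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(summary, list(out_dir = out_dir, report = report,
                            fit_result = fitres, model = model)))
}
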