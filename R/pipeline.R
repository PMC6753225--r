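#' Read and write cohort CSV files
#'
#' Cohort files are plain CSV, UTF-8, \code{"."} decimal separator, one row
#' per subject, empty cells marking missing values. The write/read round
#' trip is lossless, including missing markers.
#'
#' @param path file path.
#' @param data cohort data frame.
#' @return \code{read_cohort}: a data frame; \code{write_cohort}: the path,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  fileEncoding = "UTF-8")
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full classification and comparison pipeline
#'
#' Sequences the package's stages over one cohort: build the POSET model
#' from the battery specification; discretize scores and estimate response
#' distributions; classify all subjects; compare function-level
#' probabilities by amyloid status within age strata (Bonferroni-corrected
#' for the seven functions); tabulate APOE4-by-age majority-class accuracy;
#' and fit an out-of-bag random forest predicting amyloid from test scores
#' and covariates. All outputs are written to \code{out_dir} as plain-text
#' CSV/DOT/JSON, along with a manifest (seeds, settings, package version)
#' sufficient to reproduce the outputs byte for byte. Stages that need an
#' amyloid column are skipped with a warning when the cohort lacks one;
#' classification outputs are still produced.
#'
#' @param cohort a cohort data frame or path to a cohort CSV
#'   (\code{\link{read_cohort}} schema).
#' @param battery a \code{\link{battery}} object or path to a YAML/JSON
#'   battery specification.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed governing every stochastic stage.
#' @param dirichlet_alpha,n_iter,burn_in Gibbs settings.
#' @param ntree,mtry forest settings (defaults 1000 and 4).
#' @param stratify_cognitive also emit the comparison stratified by age
#'   group and cognitive status (exploratory, uncorrected flags apply).
#' @return invisibly, a list with the fitted objects and the manifest.
#' @export
run_pipeline <- function(cohort, battery, out_dir, seed = 1,
                         dirichlet_alpha = 1, n_iter = 2000, burn_in = 500,
                         ntree = 1000, mtry = 4,
                         stratify_cognitive = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(battery)) battery <- read_battery(battery)
  stopifnot(inherits(battery, "battery"), is.data.frame(cohort))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                       row.names = FALSE, na = "")

  model <- poset_model(battery)
  w(state_table(model), "states.csv")
  export_hasse(model, file.path(out_dir, "hasse.dot"))

  fit <- poset_fit(cohort, battery, model, dirichlet_alpha = dirichlet_alpha,
                   n_iter = n_iter, burn_in = burn_in, seed = seed)
  w(data.frame(test = colnames(fit$cutpoints), t(fit$cutpoints)),
    "cutpoints.csv")
  thetas <- data.frame(test = fit$response$tests,
                       group = rep(c("capable", "non_capable"),
                                   each = length(fit$response$tests)),
                       rbind(fit$response$theta_capable,
                             fit$response$theta_noncapable),
                       dominance_ok = rep(fit$response$dominance_ok, 2L))
  w(thetas, "thetas.csv")
  posteriors <- data.frame(id = cohort$id %||% seq_len(nrow(cohort)),
                           fit$posterior, fit$function_high,
                           map_state = fit$map, check.names = FALSE)
  w(posteriors, "posteriors.csv")

  comparison <- accuracy <- forest <- importance <- NULL
  has_amyloid <- "amyloid" %in% names(cohort) &&
    any(!is.na(cohort$amyloid))
  if (!has_amyloid) {
    warning("cohort has no usable 'amyloid' column: comparison, accuracy ",
            "and forest stages skipped")
  } else {
    subjects <- cohort
    if (!"age_group" %in% names(subjects))
      subjects$age_group <- assign_age_group(subjects$age)
    comparison <- compare_by_amyloid(fit$function_high, subjects)
    w(comparison, "comparison_by_age.csv")
    if (stratify_cognitive && "cognitive_status" %in% names(subjects)) {
      cmp2 <- compare_by_amyloid(fit$function_high, subjects,
                                 stratify_by = c("age_group",
                                                 "cognitive_status"))
      w(cmp2, "comparison_by_age_and_status.csv")
    }
    if ("apoe4" %in% names(subjects)) {
      accuracy <- apoe_age_accuracy(subjects)
      w(accuracy, "apoe_age_accuracy.csv")
    }
    # forest on complete records: test scores + covariates
    pred_cols <- c(battery$tests$name,
                   intersect(c("age", "gender", "education_ge13", "apoe4"),
                             names(subjects)))
    Xall <- subjects[, pred_cols, drop = FALSE]
    complete <- stats::complete.cases(Xall) & !is.na(subjects$amyloid)
    if (sum(complete) >= 20L &&
        length(unique(subjects$amyloid[complete])) == 2L) {
      forest <- fit_forest(Xall[complete, , drop = FALSE],
                           subjects$amyloid[complete],
                           ntree = ntree, mtry = min(mtry, ncol(Xall)),
                           seed = seed)
      mda <- oob_mda(forest, Xall[complete, , drop = FALSE],
                     subjects$amyloid[complete], seed = seed)
      importance <- data.frame(variable = names(mda), mda = mda,
                               row.names = NULL)
      importance <- importance[order(-importance$mda), ]
      w(importance, "forest_importance.csv")
      w(data.frame(oob_error_percent = forest$oob_error,
                   n = forest$n, ntree = ntree, mtry = forest$config$mtry),
        "forest_oob.csv")
    } else {
      warning("too few complete records for the forest stage; skipped")
    }
  }

  manifest <- list(
    package = "posetcog",
    version = as.character(utils::packageVersion("posetcog")),
    seed = seed,
    battery = battery$name %||% "unnamed",
    n_tests = nrow(battery$tests),
    n_states = model$n_states,
    n_subjects = nrow(cohort),
    settings = list(dirichlet_alpha = dirichlet_alpha, n_iter = n_iter,
                    burn_in = burn_in, ntree = ntree, mtry = mtry,
                    prior = paste0("uniform 1/", model$n_states)),
    outputs = sort(list.files(out_dir, pattern = "\\.(csv|dot)$")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(model = model, fit = fit, comparison = comparison,
                 accuracy = accuracy, forest = forest,
                 importance = importance, manifest = manifest))
}
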