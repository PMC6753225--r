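#' Fit a POSET cognitive classification model to a cohort
#'
#' The central modelling function. Given a cohort of raw test scores and a
#' battery specification it (1) builds (or reuses) the identifiable POSET
#' model of the battery, (2) discretizes every test into sample quartile
#' categories after orientation alignment, (3) estimates each test's capable
#' and non-capable multinomial response distributions by Gibbs sampling
#' (\code{\link{estimate_multinomials}}), and (4) classifies every subject
#' by Bayes rule from a uniform prior over states, deriving the seven
#' function-level probabilities of high functioning.
#'
#' @param data a data frame with one row per subject and one numeric column
#'   per battery test (missing scores allowed); other columns (covariates)
#'   are carried along untouched.
#' @param battery a \code{\link{battery}} object, or a path to a YAML/JSON
#'   battery specification.
#' @param model optionally a pre-built \code{\link{poset_model}} for the
#'   battery.
#' @param dirichlet_alpha,n_iter,burn_in Gibbs settings, see
#'   \code{\link{estimate_multinomials}}.
#' @param seed optional integer seed controlling the sampler.
#' @return an object of class \code{"poset_fit"} with components
#'   \code{model}, \code{battery}, \code{categories} (n x T),
#'   \code{cutpoints} (3 x T, oriented scale), \code{response} (the fitted
#'   distributions), \code{posterior} (n x S), \code{function_high}
#'   (n x 7), \code{map} (MAP state per subject), \code{data} and
#'   \code{call}. Methods: \code{print}, \code{summary}, \code{coef}
#'   (the two theta matrices), \code{fitted} (function-high
#'   probabilities), \code{predict} (posteriors for new subjects using the
#'   fitted cutpoints and distributions), \code{simulate} (cohorts drawn
#'   from the fitted model).
#' @examples
#' \donttest{
#' model <- poset_model(adni2_battery())
#' sim <- generate_cohort(model, synthetic_config(n = c(40, 40, 20)),
#'                        seed = 1)
#' fit <- poset_fit(sim$cohort, adni2_battery(), model,
#'                  n_iter = 300, burn_in = 100, seed = 1)
#' fit
#' }
#' @export
poset_fit <- function(data, battery, model = NULL, dirichlet_alpha = 1,
                      n_iter = 2000, burn_in = 500, seed = NULL) {
  if (is.character(battery)) battery <- read_battery(battery)
  stopifnot(inherits(battery, "battery"))
  if (is.null(model)) model <- poset_model(battery)
  stopifnot(inherits(model, "poset_model"))

  cc <- categorize_cohort(data, battery)
  resp <- estimate_multinomials(cc$categories, model,
                                dirichlet_alpha = dirichlet_alpha,
                                n_iter = n_iter, burn_in = burn_in,
                                seed = seed)
  post <- posterior_over_states(cc$categories, model, resp)
  fh <- function_high_probabilities(post, model)
  if (!is.null(data$id)) rownames(post) <- rownames(fh) <- NULL

  structure(list(model = model, battery = battery,
                 categories = cc$categories, cutpoints = cc$cutpoints,
                 response = resp, posterior = post, function_high = fh,
                 map = map_state(post), data = data,
                 call = match.call()),
            class = "poset_fit")
}

#' @export
print.poset_fit <- function(x, ...) {
  cat("POSET cognitive classification fit\n")
  cat("  ", nrow(x$posterior), "subjects,", x$model$n_states, "states,",
      length(x$response$tests), "tests\n")
  bad <- x$response$tests[!x$response$dominance_ok]
  cat("  response order structure:",
      if (length(bad) == 0L) "respected by all tests"
      else paste("violated for", paste(bad, collapse = ", ")), "\n")
  cat("  mean function-high probabilities:\n")
  print(round(colMeans(x$function_high), 3))
  invisible(x)
}

#' @export
summary.poset_fit <- function(object, ...) {
  out <- list(
    n = nrow(object$posterior),
    n_states = object$model$n_states,
    theta_capable = object$response$theta_capable,
    theta_noncapable = object$response$theta_noncapable,
    dominance_ok = object$response$dominance_ok,
    function_high = apply(object$function_high, 2L, stats::quantile,
                          probs = c(0.25, 0.5, 0.75)),
    map_table = table(factor(object$map,
                             levels = seq_len(object$model$n_states))))
  class(out) <- "summary.poset_fit"
  out
}

#' @export
print.summary.poset_fit <- function(x, ...) {
  cat("POSET fit:", x$n, "subjects over", x$n_states, "states\n")
  cat("\nCapable response distributions (posterior means):\n")
  print(round(x$theta_capable, 3))
  cat("\nNon-capable response distributions (posterior means):\n")
  print(round(x$theta_noncapable, 3))
  cat("\nFunction-high probability quartiles:\n")
  print(round(x$function_high, 3))
  invisible(x)
}

#' @export
coef.poset_fit <- function(object, ...) {
  list(theta_capable = object$response$theta_capable,
       theta_noncapable = object$response$theta_noncapable)
}

#' @export
fitted.poset_fit <- function(object, ...) object$function_high

#' Classify new subjects with a fitted POSET model
#'
#' New raw scores are discretized against the fitted cohort's quartile
#' cutpoints and classified with the fitted response distributions.
#'
#' @param object a \code{\link{poset_fit}}.
#' @param newdata data frame with the battery's score columns.
#' @param type \code{"state"} for the posterior state matrix,
#'   \code{"function"} for function-high probabilities, \code{"map"} for
#'   MAP state indices.
#' @param ... unused.
#' @return see \code{type}.
#' @export
predict.poset_fit <- function(object, newdata,
                              type = c("state", "function", "map"), ...) {
  type <- match.arg(type)
  cc <- categorize_cohort(newdata, object$battery,
                          cutpoints = object$cutpoints)
  post <- posterior_over_states(cc$categories, object$model, object$response)
  switch(type,
         state = post,
         "function" = function_high_probabilities(post, object$model),
         map = map_state(post))
}

#' Simulate cohorts from a fitted POSET model
#'
#' For each replicate, every subject's state is drawn from their posterior
#' and category responses are drawn from the fitted capable/non-capable
#' distributions; the observed missingness pattern is preserved.
#'
#' @param object a \code{\link{poset_fit}}.
#' @param nsim number of replicate category matrices.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of \code{nsim} category matrices (n x T, values 0-3).
#' @export
simulate.poset_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$posterior)
  Tn <- length(object$response$tests)
  ideal <- object$model$ideal
  obs <- !is.na(object$categories)
  lapply(seq_len(nsim), function(r) {
    st <- vapply(seq_len(n), function(i)
      sample.int(object$model$n_states, 1L, prob = object$posterior[i, ]),
      integer(1L))
    out <- matrix(NA_integer_, n, Tn,
                  dimnames = dimnames(object$categories))
    for (t in seq_len(Tn)) {
      cap <- ideal[st, t] == 1L
      th_c <- object$response$theta_capable[t, ]
      th_n <- object$response$theta_noncapable[t, ]
      draw <- integer(n)
      if (any(cap)) draw[cap] <- sample(0:3, sum(cap), TRUE, prob = th_c)
      if (any(!cap)) draw[!cap] <- sample(0:3, sum(!cap), TRUE, prob = th_n)
      draw[!obs[, t]] <- NA_integer_
      out[, t] <- draw
    }
    out
  })
}
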