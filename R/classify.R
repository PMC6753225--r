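#' Posterior probabilities of state membership
#'
#' Bayes-rule update of the prior over POSET states given a subject's
#' categorized responses: the posterior for state s is proportional to
#' \code{prior(s)} times the product over observed tests of the capable
#' probability of the observed category when s is capable on the test, and
#' the non-capable probability otherwise. Missing responses contribute
#' nothing. Likelihoods are accumulated in log space with an underflow
#' guard. With no observed responses the posterior equals the prior
#' (uniform by default: 1/29 per state for the bundled ADNI2 model, 1/33
#' for AIBL).
#'
#' @param responses for one subject, a named vector of categories (0-3,
#'   \code{NA} = missing, names = test names); or an n x T matrix / data
#'   frame for many subjects.
#' @param model a \code{\link{poset_model}}.
#' @param dists a \code{\link{estimate_multinomials}} fit (may be
#'   \code{NULL} when no responses are observed).
#' @param prior probability vector over states (default uniform).
#' @return a matrix of posterior state probabilities, one row per subject
#'   (a single named vector input gives a 1-row matrix); rows sum to 1.
#' @examples
#' m <- poset_model(adni2_battery())
#' p <- posterior_over_states(setNames(rep(NA_integer_, 9),
#'                                     m$battery$tests$name), m, NULL)
#' p[1, 1]  # 1/29
#' @export
posterior_over_states <- function(responses, model, dists, prior = NULL) {
  stopifnot(inherits(model, "poset_model"))
  S <- model$n_states
  if (is.null(prior)) prior <- rep(1 / S, S)
  if (length(prior) != S || abs(sum(prior) - 1) > 1e-8 || any(prior < 0))
    stop("'prior' must be a probability vector over the ", S, " states")
  if (is.null(dim(responses))) {
    responses <- matrix(responses, nrow = 1L,
                        dimnames = list(NULL, names(responses)))
  }
  responses <- as.matrix(responses)
  tests <- colnames(model$ideal)
  if (is.null(colnames(responses))) {
    if (ncol(responses) != length(tests))
      stop("responses must be named by test or have one column per test")
    colnames(responses) <- tests
  }
  use <- intersect(colnames(responses), tests)
  observed_any <- length(use) > 0L && any(!is.na(responses[, use]))
  if (observed_any && is.null(dists))
    stop("'dists' is required when responses are observed")

  n <- nrow(responses)
  loglik <- matrix(0, n, S)
  if (observed_any) {
    for (tn in use) {
      y <- responses[, tn]
      o <- !is.na(y)
      if (!any(o)) next
      if (any(!(y[o] %in% 0:3)))
        stop("responses for test '", tn, "' must be categories 0..3")
      pc <- dists$theta_capable[tn, y[o] + 1L]
      pn <- dists$theta_noncapable[tn, y[o] + 1L]
      dead <- pc == 0 & pn == 0
      if (any(dead))
        stop("impossible category observed for test '", tn,
             "': zero likelihood under both response distributions")
      s_cap <- model$ideal[, tn] == 1L
      contrib <- matrix(rep(log(pn), S), ncol = S)
      if (any(s_cap)) contrib[, s_cap] <- log(pc)
      loglik[o, ] <- loglik[o, ] + contrib
    }
  }
  lp <- sweep(loglik, 2L, log(prior), "+")
  lp <- lp - apply(lp, 1L, max)
  w <- exp(lp)
  post <- w / rowSums(w)
  colnames(post) <- paste0("state", seq_len(S))
  rownames(post) <- rownames(responses)
  post
}

#' Function-level probabilities of high functioning
#'
#' For each of the seven reported functions (ATT, EM1, EM2, EM3, VF, CF,
#' PS), the probability that the subject functions at a high level is the
#' sum of posterior state probabilities over the states whose profiles are
#' determined high for that function. States where the function is
#' confounded (undetermined) contribute nothing - a conservative "not
#' demonstrably high" convention matching the model's bottom-state
#' reporting - so, e.g., a CF-confounded state adds 0 to the CF
#' probability. Because the EM-high state sets are nested, the EM
#' probabilities are always monotone: P(EM1) >= P(EM2) >= P(EM3).
#'
#' @param posterior a matrix of state probabilities (rows = subjects), as
#'   returned by \code{\link{posterior_over_states}}, or a single vector.
#' @param model a \code{\link{poset_model}}.
#' @return a matrix (subjects x 7) of probabilities in [0, 1].
#' @export
function_high_probabilities <- function(posterior, model) {
  stopifnot(inherits(model, "poset_model"))
  if (is.null(dim(posterior))) posterior <- matrix(posterior, nrow = 1L)
  if (ncol(posterior) != model$n_states)
    stop("posterior must have one column per state")
  out <- posterior %*% model$high
  colnames(out) <- FUNCTION_NAMES
  rownames(out) <- rownames(posterior)
  out
}

#' Maximum a posteriori state
#'
#' The index of the most probable state; exact ties are broken toward the
#' lowest (highest-functioning) index.
#'
#' @param posterior a matrix of state probabilities (rows = subjects) or a
#'   single vector.
#' @return integer vector of state indices.
#' @export
map_state <- function(posterior) {
  if (is.null(dim(posterior))) posterior <- matrix(posterior, nrow = 1L)
  max.col(posterior, ties.method = "first")
}
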