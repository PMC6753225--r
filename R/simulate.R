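#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the covariate, latent-state and response structure
#' of an amyloid screening cohort: subjects in three age groups (<70, 70-80,
#' 81-90 years) and two cognitive-status arms (cognitively normal/SMC and
#' MCI); APOE4 allele counts 0/1/2 with cell-specific mixes; amyloid
#' positivity probabilities per APOE4-by-age cell; a latent cognitive
#' profile per subject; and per-test quartile categories drawn from
#' capable or non-capable multinomials according to the profile's ideal
#' response. Default cell sizes, APOE4 mixes and amyloid prevalences are
#' patterned on the published ADNI2 screening sample; they are configuration
#' values, not assertions about any real cohort.
#'
#' Latent profiles are drawn componentwise: attention and the binary
#' functions are independent Bernoulli draws with status-specific rates,
#' and the episodic memory level comes from a status-specific distribution
#' over levels 0-3. In amyloid-positive subjects the EM level is depressed
#' by the effect parameter \code{delta}: the drawn level is reduced by an
#' independent \code{Binomial(3, delta)} amount (floored at 0), so
#' \code{delta = 0} makes the positive and negative arms identically
#' distributed and larger \code{delta} shifts amyloid-positive mass toward
#' lower-EM states.
#'
#' @param n subjects per age group: either a length-3 vector of per-age
#'   totals (split evenly between cognitive-status arms) or a 2 x 3 matrix
#'   (rows: normal, MCI; columns: age groups). Default: the ADNI2-patterned
#'   cells (89, 129, 26 normal; 90, 90, 21 MCI).
#' @param apoe_probs 3 x 3 matrix of APOE4 = 0/1/2 probabilities (rows) per
#'   age group (columns).
#' @param amyloid_probs 3 x 3 matrix of amyloid-positive probability per
#'   APOE4 count (rows 0/1/2) and age group (columns).
#' @param em_probs named list with elements \code{normal} and \code{mci},
#'   each a probability 4-vector over EM levels 0-3 (amyloid-negative arm).
#' @param p_high named list (\code{normal}, \code{mci}) of Bernoulli rates
#'   for \code{att}, \code{vf}, \code{cf}, \code{ps}.
#' @param delta EM-depression effect in amyloid positives, in [0, 1].
#' @param theta_capable,theta_noncapable probability 4-vectors over
#'   response categories for capable and non-capable subjects (defaults:
#'   strong separation with mass 0.7 on the best and worst category).
#' @param state_distribution \code{"profile"} (default): latent profiles
#'   are drawn componentwise as described above; \code{"uniform"}: each
#'   subject's state is drawn uniformly over the model's states (matching
#'   the classifier's uniform prior - the well-specified case used for
#'   parameter-recovery experiments) and the profile is a uniformly chosen
#'   member of that state. Under \code{"uniform"} the amyloid effect
#'   \code{delta} is ignored.
#' @param missing_rate independent missingness rate applied to scores.
#' @param continuous if \code{TRUE} (default), categories are
#'   back-transformed to continuous scores: category c maps to a draw from
#'   the c-th quartile band of a standard normal (negated for
#'   lower-is-better tests), so quartile categorization recovers the
#'   categories in expectation.
#' @return a list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n = NULL, apoe_probs = NULL,
                             amyloid_probs = NULL, em_probs = NULL,
                             p_high = NULL, delta = 0.3,
                             theta_capable = c(0.1, 0.1, 0.1, 0.7),
                             theta_noncapable = c(0.7, 0.1, 0.1, 0.1),
                             state_distribution = c("profile", "uniform"),
                             missing_rate = 0.02, continuous = TRUE) {
  state_distribution <- match.arg(state_distribution)
  if (is.null(n)) {
    n <- rbind(normal = c(89L, 129L, 26L), mci = c(90L, 90L, 21L))
  } else if (is.null(dim(n))) {
    if (length(n) != 3L) stop("'n' must be length 3 or a 2 x 3 matrix")
    n <- rbind(normal = ceiling(n / 2), mci = floor(n / 2))
  }
  n <- matrix(as.integer(n), 2L, 3L,
              dimnames = list(c("normal", "mci"), AGE_GROUPS))
  if (is.null(apoe_probs))
    apoe_probs <- cbind(c(0.60, 0.35, 0.05), c(0.68, 0.29, 0.03),
                        c(0.70, 0.21, 0.09))
  apoe_probs <- matrix(apoe_probs, 3L, 3L,
                       dimnames = list(paste0("apoe", 0:2), AGE_GROUPS))
  if (is.null(amyloid_probs))
    amyloid_probs <- cbind(c(0.182, 0.492, 0.636), c(0.282, 0.661, 0.750),
                           c(0.462, 0.846, 1.000))
  amyloid_probs <- matrix(amyloid_probs, 3L, 3L,
                          dimnames = list(paste0("apoe", 0:2), AGE_GROUPS))
  if (is.null(em_probs))
    em_probs <- list(normal = c(0.10, 0.15, 0.25, 0.50),
                     mci = c(0.30, 0.25, 0.25, 0.20))
  if (is.null(p_high))
    p_high <- list(normal = c(att = 0.95, vf = 0.70, cf = 0.70, ps = 0.70),
                   mci = c(att = 0.80, vf = 0.55, cf = 0.55, ps = 0.55))
  stopifnot(delta >= 0, delta <= 1,
            abs(sum(theta_capable) - 1) < 1e-8, all(theta_capable >= 0),
            abs(sum(theta_noncapable) - 1) < 1e-8, all(theta_noncapable >= 0),
            missing_rate >= 0, missing_rate < 1,
            all(abs(colSums(apoe_probs) - 1) < 1e-8),
            all(amyloid_probs >= 0 & amyloid_probs <= 1),
            all(vapply(em_probs, function(p)
      abs(sum(p) - 1) < 1e-8 && length(p) == 4L, logical(1L))))
  structure(list(n = n, apoe_probs = apoe_probs,
                 amyloid_probs = amyloid_probs, em_probs = em_probs,
                 p_high = p_high, delta = delta,
                 state_distribution = state_distribution,
                 theta_capable = theta_capable,
                 theta_noncapable = theta_noncapable,
                 missing_rate = missing_rate, continuous = continuous),
            class = "synthetic_config")
}

# category -> continuous score: a draw from the category's quartile band of
# a standard normal, negated for lower-is-better tests.
category_to_score <- function(category, orientation) {
  u <- stats::runif(length(category), category / 4, (category + 1) / 4)
  # keep strictly inside (0, 1)
  u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
  z <- stats::qnorm(u)
  if (orientation == "lower") -z else z
}

#' Generate a seeded synthetic screening cohort
#'
#' Draws a full synthetic cohort under a \code{\link{synthetic_config}}:
#' per-subject covariates (age, age group, gender, education, cognitive
#' status), APOE4 allele count, amyloid status, a latent cognitive profile
#' and its POSET state, and per-test responses drawn from the capable or
#' non-capable category distribution according to the latent state's ideal
#' response. Fully reproducible: the same seed gives a byte-identical
#' cohort.
#'
#' @param model a \code{\link{poset_model}} (its battery supplies test
#'   names and orientations).
#' @param config a \code{\link{synthetic_config}}.
#' @param seed optional integer seed.
#' @return a list with \code{cohort} (data frame: \code{id}, \code{age},
#'   \code{age_group}, \code{gender}, \code{education_ge13}, \code{apoe4},
#'   \code{amyloid}, \code{cognitive_status}, one score column per test)
#'   and \code{truth} (data frame: \code{id}, latent profile levels,
#'   \code{state} index, and the seven true function indicators).
#' @export
generate_cohort <- function(model, config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(model, "poset_model"),
            inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  battery <- model$battery
  cells <- expand.grid(status = c("normal", "mci"), age_group = AGE_GROUPS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$n <- mapply(function(s, a) config$n[s, a],
                    cells$status, cells$age_group)
  n_total <- sum(cells$n)
  if (n_total == 0L) stop("configuration requests an empty cohort")

  status <- rep(cells$status, cells$n)
  age_group <- rep(cells$age_group, cells$n)
  age_lo <- c("<70" = 60, "70-80" = 70, "81-90" = 81)[age_group]
  age_hi <- c("<70" = 69, "70-80" = 80, "81-90" = 90)[age_group]
  age <- floor(stats::runif(n_total, age_lo, age_hi + 1))
  gender <- sample(c("female", "male"), n_total, TRUE)
  education_ge13 <- stats::rbinom(n_total, 1L, 0.85)
  apoe4 <- vapply(seq_len(n_total), function(i)
    sample(0:2, 1L, prob = config$apoe_probs[, age_group[i]]),
    integer(1L))
  p_amy <- config$amyloid_probs[cbind(apoe4 + 1L,
                                      match(age_group, AGE_GROUPS))]
  amyloid <- ifelse(stats::runif(n_total) < p_amy, "positive", "negative")

  # latent profile
  if (config$state_distribution == "uniform") {
    st <- sample.int(model$n_states, n_total, replace = TRUE)
    profiles <- do.call(rbind, lapply(st, function(s) {
      mem <- model$states[[s]]$members
      mem[sample.int(nrow(mem), 1L), , drop = FALSE]
    }))
    rownames(profiles) <- NULL
    return(finish_cohort(model, config, profiles,
                         data.frame(age = age, age_group = age_group,
                                    gender = gender,
                                    education_ge13 = education_ge13,
                                    apoe4 = apoe4, amyloid = amyloid,
                                    cognitive_status = status,
                                    stringsAsFactors = FALSE)))
  }
  att <- vf <- cf <- ps <- integer(n_total)
  em <- integer(n_total)
  for (s in c("normal", "mci")) {
    idx <- which(status == s)
    ph <- config$p_high[[s]]
    att[idx] <- stats::rbinom(length(idx), 1L, ph[["att"]])
    vf[idx] <- stats::rbinom(length(idx), 1L, ph[["vf"]])
    cf[idx] <- stats::rbinom(length(idx), 1L, ph[["cf"]])
    ps[idx] <- stats::rbinom(length(idx), 1L, ph[["ps"]])
    em[idx] <- sample(0:3, length(idx), TRUE, prob = config$em_probs[[s]])
  }
  pos <- amyloid == "positive"
  if (config$delta > 0 && any(pos)) {
    drop <- stats::rbinom(sum(pos), 3L, config$delta)
    em[pos] <- pmax(0L, em[pos] - drop)
  }
  profiles <- data.frame(att = att, em = em, vf = vf, cf = cf, ps = ps)
  finish_cohort(model, config, profiles,
                data.frame(age = age, age_group = age_group,
                           gender = gender, education_ge13 = education_ge13,
                           apoe4 = apoe4, amyloid = amyloid,
                           cognitive_status = status,
                           stringsAsFactors = FALSE))
}

# Draw responses for given latent profiles and assemble cohort + truth.
finish_cohort <- function(model, config, profiles, covars) {
  battery <- model$battery
  n_total <- nrow(profiles)
  # map profiles to states by ideal-pattern lookup
  iv <- ideal_matrix(profiles, battery)
  key <- apply(iv, 1L, paste, collapse = "")
  state_key <- apply(model$ideal, 1L, paste, collapse = "")
  state <- match(key, state_key)

  # responses
  tests <- battery$tests$name
  scores <- matrix(NA_real_, n_total, length(tests),
                   dimnames = list(NULL, tests))
  for (t in seq_along(tests)) {
    cap <- iv[, t] == 1L
    category <- integer(n_total)
    if (any(cap))
      category[cap] <- sample(0:3, sum(cap), TRUE, config$theta_capable)
    if (any(!cap))
      category[!cap] <- sample(0:3, sum(!cap), TRUE, config$theta_noncapable)
    scores[, t] <- if (config$continuous) {
      category_to_score(category, battery$tests$orientation[t])
    } else {
      category
    }
    if (config$missing_rate > 0) {
      gone <- stats::runif(n_total) < config$missing_rate
      scores[gone, t] <- NA_real_
    }
  }
  # guarantee the estimation precondition: at least one observed score
  none <- rowSums(!is.na(scores)) == 0L
  if (any(none)) {
    redraw <- sample(seq_along(tests), sum(none), TRUE)
    for (k in seq_len(sum(none))) {
      i <- which(none)[k]; t <- redraw[k]
      category <- sample(0:3, 1L, prob = if (iv[i, t] == 1L)
        config$theta_capable else config$theta_noncapable)
      scores[i, t] <- if (config$continuous)
        category_to_score(category, battery$tests$orientation[t])
      else category
    }
  }

  covars$age_group <- factor(covars$age_group, levels = AGE_GROUPS)
  cohort <- cbind(data.frame(id = sprintf("S%04d", seq_len(n_total)),
                             stringsAsFactors = FALSE),
                  covars, as.data.frame(scores))
  truth <- cbind(data.frame(id = cohort$id, stringsAsFactors = FALSE),
                 profiles, state = state,
                 as.data.frame(profile_indicators(profiles)))
  list(cohort = cohort, truth = truth)
}

# rank-based AUC of score for binary truth (1 = positive class)
auc_rank <- function(score, truth) {
  pos <- score[truth == 1L]; neg <- score[truth == 0L]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classification recovery metrics on synthetic data
#'
#' Compares classifier output against the generator's latent truth:
#' MAP-state accuracy, the mean posterior mass assigned to the true state,
#' and per-function AUC of the function-high probability against the true
#' function indicator.
#'
#' @param truth the \code{truth} table from \code{\link{generate_cohort}}.
#' @param posterior n x S posterior matrix aligned with \code{truth} (same
#'   subject order).
#' @param model the \code{\link{poset_model}} used for classification.
#' @return a list with \code{map_accuracy}, \code{mean_true_mass} and
#'   \code{auc} (named 7-vector; \code{NA} where a function indicator is
#'   constant in truth).
#' @export
evaluate_recovery <- function(truth, posterior, model) {
  stopifnot(inherits(model, "poset_model"))
  posterior <- as.matrix(posterior)
  if (nrow(posterior) != nrow(truth))
    stop("'truth' and 'posterior' must be aligned row-for-row")
  mapst <- map_state(posterior)
  map_accuracy <- mean(mapst == truth$state)
  mean_true_mass <- mean(posterior[cbind(seq_len(nrow(truth)), truth$state)])
  fh <- function_high_probabilities(posterior, model)
  auc <- vapply(FUNCTION_NAMES, function(f)
    auc_rank(fh[, f], truth[[f]]), numeric(1L))
  list(map_accuracy = map_accuracy, mean_true_mass = mean_true_mass,
       auc = auc)
}
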