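# Shared small fixture: uniform-state cohort with strongly separated
# response distributions (capable mass 0.7 on the best category).
strong_sep_cohort <- function(n3 = c(120, 120, 60), seed = 5) {
  m <- poset_model(adni2_battery())
  cfg <- synthetic_config(n = n3, missing_rate = 0, continuous = FALSE,
                          state_distribution = "uniform")
  sim <- generate_cohort(m, cfg, seed = seed)
  list(model = m, cfg = cfg, sim = sim,
       cats = as.matrix(sim$cohort[, m$battery$tests$name]))
}

test_that("chain-length preconditions are enforced", {
  f <- strong_sep_cohort(c(20, 20, 10))
  expect_error(estimate_multinomials(f$cats, f$model, n_iter = 100,
                                     burn_in = 100),
               "zero post-burn-in")
  expect_error(estimate_multinomials(f$cats, f$model, n_iter = 50,
                                     burn_in = 100),
               "must exceed")
})

test_that("identical seeds reproduce the fit bit for bit", {
  f <- strong_sep_cohort(c(30, 30, 20))
  a <- estimate_multinomials(f$cats, f$model, n_iter = 200, burn_in = 50,
                             seed = 99)
  b <- estimate_multinomials(f$cats, f$model, n_iter = 200, burn_in = 50,
                             seed = 99)
  expect_identical(a$theta_capable, b$theta_capable)
  expect_identical(a$theta_noncapable, b$theta_noncapable)
})

test_that("estimates respect conservation and the identifiability guard", {
  f <- strong_sep_cohort()
  fit <- estimate_multinomials(f$cats, f$model, n_iter = 600, burn_in = 200,
                               seed = 2)
  expect_equal(unname(rowSums(fit$theta_capable)), rep(1, 9),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(fit$theta_noncapable)), rep(1, 9),
               tolerance = 1e-9)
  # capable mean category above non-capable mean category for every test
  mean_cat <- function(theta) as.vector(theta %*% 0:3)
  expect_true(all(mean_cat(fit$theta_capable) >
                    mean_cat(fit$theta_noncapable)))
  # on well-specified data the dominance flag rate is at most 5%
  expect_lte(mean(!fit$dominance_ok), 0.05)
})

test_that("parameter recovery is within sampling error of the truth", {
  # Cell-size-aware bound: each of the 72 multinomial parameters must sit
  # within 6 binomial standard errors (plus the Dirichlet-prior shrinkage)
  # of its generating value, with group sizes taken from the latent truth.
  f <- strong_sep_cohort(c(200, 200, 100), seed = 31)
  fit <- estimate_multinomials(f$cats, f$model, n_iter = 1500, burn_in = 500,
                               seed = 32)
  iv <- f$model$ideal[f$sim$truth$state, ]
  viol <- 0L
  for (t in seq_len(9)) {
    for (g in c(TRUE, FALSE)) {
      n_g <- sum(iv[, t] == as.integer(g))
      truth <- if (g) f$cfg$theta_capable else f$cfg$theta_noncapable
      est <- if (g) fit$theta_capable[t, ] else fit$theta_noncapable[t, ]
      se <- sqrt(truth * (1 - truth) / max(n_g, 1)) + 4 / (n_g + 4)
      if (any(abs(est - truth) > 6 * se + 0.02)) viol <- viol + 1L
    }
  }
  expect_equal(viol, 0L)
  # the mean distribution across tests is tightly recovered
  expect_lt(max(abs(colMeans(fit$theta_capable) - f$cfg$theta_capable)), 0.05)
  expect_lt(max(abs(colMeans(fit$theta_noncapable) -
                      f$cfg$theta_noncapable)), 0.05)
})

test_that("the dominance flag fires when the order structure is violated", {
  # one test generated with a reversed capable distribution among
  # otherwise well-separated tests
  m <- poset_model(adni2_battery())
  cfg <- synthetic_config(n = c(100, 100, 60), missing_rate = 0,
                          continuous = FALSE, state_distribution = "uniform")
  sim <- generate_cohort(m, cfg, seed = 8)
  cats <- as.matrix(sim$cohort[, m$battery$tests$name])
  # overwrite boston: capable subjects draw from the WORST-leaning dist
  iv <- m$ideal[sim$truth$state, ]
  set.seed(9)
  cap <- iv[, "boston"] == 1L
  cats[cap, "boston"] <- sample(0:3, sum(cap), TRUE,
                                prob = c(0.7, 0.1, 0.1, 0.1))
  cats[!cap, "boston"] <- sample(0:3, sum(!cap), TRUE,
                                 prob = c(0.1, 0.1, 0.1, 0.7))
  fit <- estimate_multinomials(cats, m, n_iter = 600, burn_in = 200,
                               seed = 10)
  expect_false(fit$dominance_ok[which(fit$tests == "boston")])
  expect_true(all(fit$dominance_ok[fit$tests != "boston"]))
})

test_that("category counts and inputs are validated", {
  f <- strong_sep_cohort(c(20, 20, 10))
  bad <- f$cats
  bad[1, ] <- NA_integer_
  expect_error(estimate_multinomials(bad, f$model, n_iter = 10, burn_in = 5),
               "at least one non-missing")
  bad2 <- f$cats
  bad2[1, 1] <- 7L
  expect_error(estimate_multinomials(bad2, f$model, n_iter = 10, burn_in = 5),
               "0..3")
})
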