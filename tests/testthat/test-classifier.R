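adni2_model <- poset_model(adni2_battery())

test_that("with no observed responses the posterior equals the prior", {
  m <- adni2_model
  empty <- setNames(rep(NA_integer_, 9), m$battery$tests$name)
  p <- posterior_over_states(empty, m, dists = NULL)
  expect_equal(unname(p[1, ]), rep(1 / 29, 29), tolerance = 1e-12)
  pr <- (1:29) / sum(1:29)
  p2 <- posterior_over_states(empty, m, dists = NULL, prior = pr)
  expect_equal(unname(p2[1, ]), pr, tolerance = 1e-12)
  m_aibl <- poset_model(aibl_battery())
  e2 <- setNames(rep(NA_integer_, 13), m_aibl$battery$tests$name)
  expect_equal(unname(posterior_over_states(e2, m_aibl, NULL)[1, ]),
               rep(1 / 33, 33), tolerance = 1e-12)
})

test_that("uninformative response distributions leave the prior unchanged", {
  m <- adni2_model
  dists <- make_dists(m, rep(0.25, 4), rep(0.25, 4))
  resp <- setNames(sample(0:3, 9, TRUE), m$battery$tests$name)
  p <- posterior_over_states(resp, m, dists)
  expect_equal(unname(p[1, ]), rep(1 / 29, 29), tolerance = 1e-12)
})

test_that("a two-state toy reproduces the hand-computed Bayes update", {
  toy <- poset_model(battery(list(list(name = "only", functions = "ATT",
                                       orientation = "higher"))))
  expect_equal(toy$n_states, 2L)
  dists <- make_dists(toy, c(0.1, 0.1, 0.1, 0.7), c(0.7, 0.1, 0.1, 0.1))
  p <- posterior_over_states(c(only = 3L), toy, dists)
  expect_equal(unname(p[1, 1]), 0.7 / 0.8, tolerance = 1e-12)  # 0.875 top
  expect_equal(map_state(p), 1L)
})

test_that("sequential single-test updates equal the joint update", {
  m <- adni2_model
  set.seed(21)
  dists <- make_dists(m, c(0.05, 0.15, 0.2, 0.6), c(0.5, 0.25, 0.15, 0.1))
  for (rep in 1:5) {
    resp <- setNames(sample(c(0:3, NA), 9, TRUE), m$battery$tests$name)
    joint <- posterior_over_states(resp, m, dists)
    seq_post <- rep(1 / 29, 29)
    for (tn in sample(names(resp))) {       # arbitrary order
      one <- setNames(rep(NA_integer_, 9), names(resp))
      one[tn] <- resp[tn]
      seq_post <- posterior_over_states(one, m, dists,
                                        prior = seq_post)[1, ]
    }
    expect_equal(unname(seq_post), unname(joint[1, ]), tolerance = 1e-10)
  }
})

test_that("episodic memory probabilities are monotone across levels", {
  m <- adni2_model
  set.seed(22)
  for (i in 1:50) {
    p <- rgamma(29, 1)
    p <- p / sum(p)
    fh <- function_high_probabilities(p, m)
    expect_true(fh[, "EM1"] >= fh[, "EM2"] - 1e-12)
    expect_true(fh[, "EM2"] >= fh[, "EM3"] - 1e-12)
  }
})

test_that("function-high sums follow the determined-high convention", {
  m <- adni2_model
  # point mass on the top state: everything high
  top <- replace(rep(0, 29), 1, 1)
  expect_equal(unname(function_high_probabilities(top, m)[1, ]), rep(1, 7))
  # uniform posterior: ATT high in all states but the bottom
  unif <- rep(1 / 29, 29)
  expect_equal(unname(function_high_probabilities(unif, m)[1, "ATT"]),
               28 / 29, tolerance = 1e-12)
  # point mass on the CF-confounded state 7: CF contributes zero, EM3 one
  s7 <- replace(rep(0, 29), 7, 1)
  fh <- function_high_probabilities(s7, m)
  expect_equal(unname(fh[1, "CF"]), 0)
  expect_equal(unname(fh[1, "EM3"]), 1)
  expect_equal(unname(fh[1, "PS"]), 0)
})

test_that("MAP ties break toward the lowest state index", {
  p <- rep(0, 29)
  p[3] <- p[5] <- 0.5
  expect_equal(map_state(p), 3L)
  expect_equal(map_state(replace(rep(0, 29), 17, 1)), 17L)
})

test_that("impossible categories and bad priors are rejected", {
  m <- adni2_model
  dists <- make_dists(m, c(0, 0.2, 0.2, 0.6), c(0, 0.4, 0.3, 0.3))
  resp <- setNames(rep(NA_integer_, 9), m$battery$tests$name)
  resp["boston"] <- 0L
  expect_error(posterior_over_states(resp, m, dists), "boston")
  expect_error(posterior_over_states(resp, m, NULL), "required")
  expect_error(posterior_over_states(resp, m, dists, prior = rep(1, 29)),
               "probability vector")
})

test_that("replicating the battery concentrates mass on the true state", {
  # consistency: more replications of the same specification sharpen the
  # posterior on the generating state
  set.seed(23)
  theta_c <- c(0.1, 0.1, 0.1, 0.7)
  theta_n <- c(0.7, 0.1, 0.1, 0.1)
  base <- yaml::read_yaml(system.file("extdata", "battery_adni2.yaml",
                                      package = "posetcog"))$tests
  mass_at <- sapply(c(1, 3, 10), function(r) {
    tests <- list()
    for (k in seq_len(r)) {
      tests <- c(tests, lapply(base, function(t) {
        t$name <- paste0(t$name, "_r", k)
        t$functions <- unlist(t$functions)
        t
      }))
    }
    b <- battery(tests)
    m <- poset_model(b)
    expect_equal(m$n_states, 29L)  # replication cannot split classes
    dists <- make_dists(m, theta_c, theta_n)
    states <- sample.int(29, 60, TRUE)
    cats <- matrix(NA_integer_, 60, nrow(b$tests),
                   dimnames = list(NULL, b$tests$name))
    for (t in seq_len(nrow(b$tests))) {
      cap <- m$ideal[states, t] == 1L
      cats[cap, t] <- sample(0:3, sum(cap), TRUE, theta_c)
      cats[!cap, t] <- sample(0:3, sum(!cap), TRUE, theta_n)
    }
    post <- posterior_over_states(cats, m, dists)
    mean(post[cbind(seq_len(60), states)])
  })
  expect_true(all(diff(mass_at) > 0))
  expect_gt(mass_at[3], 0.8)
})
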