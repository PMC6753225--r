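test_that("age groups use the inclusive published bounds", {
  expect_equal(as.character(assign_age_group(c(69, 70, 80, 81, 90))),
               c("<70", "70-80", "70-80", "81-90", "81-90"))
  expect_equal(as.character(assign_age_group(80.9)), "70-80")  # floored
  expect_error(assign_age_group(95), "55-90")
  expect_error(assign_age_group(54), "55-90")
})

test_that("age-group z-scores are standardized and oriented", {
  set.seed(31)
  g <- rep(c("<70", "70-80"), each = 30)
  x <- rnorm(60, mean = ifelse(g == "<70", 10, 20), sd = 3)
  z <- zscore_by_age_group(x, g)
  for (gg in unique(g)) {
    expect_equal(mean(z[g == gg]), 0, tolerance = 1e-9)
    expect_equal(sd(z[g == gg]), 1, tolerance = 1e-9)
  }
  # lower-is-better: the fastest time gets the largest z
  times <- c(12, 45, 30, 22, 60)
  zt <- zscore_by_age_group(times, rep("<70", 5), orientation = "lower")
  expect_equal(which.max(zt), which.min(times))
  # missing propagates
  xm <- c(x[1:59], NA)
  expect_true(is.na(zscore_by_age_group(xm, g)[60]))
  expect_error(zscore_by_age_group(c(1, 2), c("a", "b")), "fewer than 2")
  expect_error(zscore_by_age_group(rep(3, 5), rep("a", 5), test = "tt"),
               "zero within-group")
})

test_that("Mann-Whitney matches hand-enumerated and symmetric cases", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$p.value, 2 / 6,
               tolerance = 1e-12)
  # identical multisets: U = n1 n2 / 2
  x <- c(1, 2, 2, 5)
  expect_equal(mann_whitney_u(x, x)$statistic, 8)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("the exact path agrees with the enumeration oracle under ties", {
  set.seed(32)
  for (i in 1:8) {
    x <- sample(1:5, sample(3:8, 1), TRUE)
    y <- sample(1:5, sample(3:8, 1), TRUE)
    got <- mann_whitney_u(x, y)
    expect_equal(got$p.value, oracle_mw_exact(x, y), tolerance = 1e-12)
  }
})

test_that("the approximate path matches independent implementations", {
  set.seed(33)
  x <- rnorm(15)
  y <- rnorm(15, 0.7)
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  # with heavy ties
  xt <- sample(1:4, 25, TRUE)
  yt <- sample(1:5, 25, TRUE)
  expect_equal(mann_whitney_u(xt, yt)$p.value,
               wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
  # Monte Carlo permutation oracle (absolute agreement)
  expect_lt(abs(got$p.value - oracle_mw_mc(x, y, B = 4e4, seed = 2)), 0.02)
})

test_that("U is invariant under strictly monotone transforms", {
  set.seed(34)
  x <- rnorm(12)
  y <- rnorm(18, 0.4)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(exp(x), exp(y))
  cc <- mann_whitney_u(atan(x), atan(y))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p.value, cc$p.value, tolerance = 1e-12)
})

test_that("stratified amyloid comparison applies the Bonferroni rule", {
  m <- poset_model(adni2_battery())
  cfg <- synthetic_config(n = c(140, 140, 60), delta = 0.6,
                          missing_rate = 0, continuous = FALSE)
  sim <- generate_cohort(m, cfg, seed = 41)
  dists <- make_dists(m, cfg$theta_capable, cfg$theta_noncapable)
  fh <- function_high_probabilities(
    posterior_over_states(as.matrix(sim$cohort[, m$battery$tests$name]),
                          m, dists), m)
  cmp <- compare_by_amyloid(fh, sim$cohort)
  expect_equal(attr(cmp, "threshold"), 0.05 / 7)
  expect_equal(round(attr(cmp, "threshold"), 3), 0.007)
  expect_equal(nrow(cmp), 3L * 7L)
  # a strong injected EM depression is detected at the corrected level
  em_rows <- cmp[cmp$`function` %in% c("EM1", "EM2", "EM3") &
                   cmp$stratum != "81-90", ]
  expect_true(any(em_rows$significant_bonferroni))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1, na.rm = TRUE))
  expect_equal(cmp$significant_bonferroni,
               !is.na(cmp$p) & cmp$p < 0.05 / 7)
})

test_that("one-armed strata are flagged, not dropped", {
  fh <- matrix(runif(20 * 7), 20, 7,
               dimnames = list(NULL, c("ATT", "EM1", "EM2", "EM3",
                                       "VF", "CF", "PS")))
  subj <- data.frame(amyloid = rep("negative", 20),
                     age_group = rep(c("<70", "70-80"), 10))
  cmp <- compare_by_amyloid(fh, subj)
  expect_equal(nrow(cmp), 21L)   # three age strata retained
  expect_true(all(!cmp$computable))
  expect_true(all(is.na(cmp$p)))
  expect_error(compare_by_amyloid(fh, subj[, "age_group", drop = FALSE]),
               "amyloid")
})

test_that("majority-class accuracy reproduces the published cells", {
  counts <- apoe_amyloid_counts("ADNI2")
  acc <- apoe_age_accuracy(counts_to_subjects(counts))
  cell <- function(a, g) acc[acc$apoe4 == a & acc$age_group == g, ]
  expect_equal(cell(0, "<70")$accuracy, 81.8)
  expect_equal(cell(0, "<70")$majority, "negative")
  expect_equal(cell(0, "70-80")$accuracy, 71.8)
  expect_equal(cell(1, "81-90")$accuracy, 84.6)
  expect_equal(cell(1, "81-90")$majority, "positive")
  aibl <- apoe_age_accuracy(counts_to_subjects(apoe_amyloid_counts("AIBL")))
  cellb <- function(a, g) aibl[aibl$apoe4 == a & aibl$age_group == g, ]
  expect_equal(cellb(0, "<70")$accuracy, 89.5)
  expect_equal(cellb(0, "70-80")$accuracy, 77.6)
  expect_equal(cellb(1, "70-80")$accuracy, 75.0)
  expect_equal(cellb(2, "70-80")$accuracy, 100.0)
})

test_that("accuracy identities hold on arbitrary tables", {
  set.seed(43)
  subj <- data.frame(apoe4 = sample(0:2, 300, TRUE),
                     age_group = sample(c("<70", "70-80", "81-90"), 300, TRUE),
                     amyloid = sample(c("positive", "negative"), 300, TRUE))
  acc <- apoe_age_accuracy(subj)
  expect_equal(nrow(acc), 9L)
  expect_equal(sum(acc$n), 300L)
  nonempty <- acc$n > 0
  expect_equal(acc$accuracy[nonempty],
               round(100 * pmax(acc$n_negative, acc$n_positive)[nonempty] /
                       acc$n[nonempty], 1))
  empty <- data.frame(apoe4 = 0, age_group = "<70", amyloid = "negative")
  acc2 <- apoe_age_accuracy(empty)
  expect_true(is.na(acc2$accuracy[acc2$apoe4 == 2 & acc2$age_group == "81-90"]))
})
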