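test_that("profile enumeration covers the domain exactly once", {
  p <- enumerate_profiles()
  expect_equal(nrow(p), 64L)
  expect_equal(nrow(unique(p)), 64L)
  expect_setequal(names(p), c("att", "em", "vf", "cf", "ps"))
  expect_equal(nrow(enumerate_profiles("ATT")), 2L)
  expect_equal(nrow(enumerate_profiles("EM")), 4L)
  expect_error(enumerate_profiles("XX"), "unknown")
  expect_error(enumerate_profiles(character(0)), "at least one")
})

test_that("ideal responses follow the conjunctive requirement rule", {
  b <- adni2_battery()
  top <- list(att = 1, em = 3, vf = 1, cf = 1, ps = 1)
  expect_equal(unname(ideal_response(top, b)), rep(1L, 9L))
  # attention low fails every test (all tests involve ATT)
  no_att <- list(att = 0, em = 3, vf = 1, cf = 1, ps = 1)
  expect_equal(unname(ideal_response(no_att, b)), rep(0L, 9L))
  # EM1-capable subject passes word recognition but not list B (needs EM2)
  em1 <- list(att = 1, em = 1, vf = 1, cf = 1, ps = 1)
  iv <- ideal_response(em1, b)
  expect_equal(iv[["adas_wr"]], 1L)
  expect_equal(iv[["avlt_listb"]], 0L)
  expect_equal(iv[["adas_dr"]], 0L)
})

test_that("the two panels produce the published state structure", {
  m_adni <- poset_model(adni2_battery())
  m_aibl <- poset_model(aibl_battery())
  expect_equal(m_adni$n_states, 29L)
  expect_equal(m_aibl$n_states, 33L)
  expect_equal(state_labels(m_adni, collapse = " "), adni2_state_labels)
  expect_equal(state_labels(m_aibl, collapse = " "), aibl_state_labels)
  # CF is confounded exactly in states 7, 14, 21, 28 (plus the bottom state
  # where everything but ATT is undetermined)
  conf <- detect_confounding(m_adni)
  cf_states <- which(vapply(conf, function(u) identical(u, "CF"), logical(1)))
  expect_equal(unname(cf_states), c(7L, 14L, 21L, 28L))
  # AIBL: no confounding beyond the bottom state
  conf_aibl <- detect_confounding(m_aibl)
  beyond <- setdiff(which(lengths(conf_aibl) > 0), m_aibl$bottom_index)
  expect_length(beyond, 0L)
  # top and bottom
  expect_equal(m_adni$top_index, 1L)
  expect_equal(m_adni$bottom_index, 29L)
  expect_equal(m_adni$states[[29]]$label, character(0))
  expect_length(m_adni$states[[1]]$undetermined, 0L)
})

test_that("a CF-confounded state merges the expected profile pair", {
  m <- poset_model(adni2_battery())
  s7 <- m$states[[7L]]
  mem <- s7$members[order(s7$members$cf), ]
  expect_equal(nrow(mem), 2L)
  expect_equal(mem$att, c(1L, 1L))
  expect_equal(mem$em, c(3L, 3L))
  expect_equal(mem$vf, c(0L, 0L))
  expect_equal(mem$ps, c(0L, 0L))
  expect_equal(mem$cf, c(0L, 1L))
  expect_equal(s7$label, c("ATT", "EM1", "EM2", "EM3", "CF*"))
})

test_that("state members partition the 64 profiles", {
  for (m in list(poset_model(adni2_battery()), poset_model(aibl_battery()))) {
    rows <- sort(unlist(lapply(m$states, `[[`, "member_rows")))
    expect_equal(rows, 1:64)
  }
})

test_that("degenerate batteries are handled", {
  expect_error(poset_model(structure(list(name = NULL,
                                          tests = adni2_battery()$tests[0, ]),
                                     class = "battery")), "no tests")
  one <- battery(list(list(name = "only", functions = "ATT",
                           orientation = "higher")))
  m <- poset_model(one)
  expect_equal(m$n_states, 2L)
  expect_equal(nrow(m$hasse), 1L)
})

test_that("random batteries agree with the brute-force grouping oracle", {
  set.seed(20251001)
  for (i in 1:40) {
    b <- random_battery()
    m <- poset_model(b)
    oracle <- oracle_profile_groups(b)
    expect_equal(m$n_states, length(oracle))
    got <- vapply(m$states, function(s)
      paste(sort(s$member_rows), collapse = ","), "")
    want <- unname(vapply(oracle, function(g)
      paste(sort(g), collapse = ","), ""))
    expect_setequal(got, want)
  }
})

test_that("the state order is sound, monotone and linearly extended", {
  set.seed(42)
  bats <- c(list(adni2_battery(), aibl_battery()),
            replicate(8, random_battery(), simplify = FALSE))
  for (b in bats) {
    m <- poset_model(b)
    S <- m$n_states
    # monotone ideal vectors: s >= t implies ideal(s) >= ideal(t)
    viol <- 0L
    for (s in seq_len(S)) for (t in seq_len(S)) {
      if (m$order[s, t] && !all(m$ideal[s, ] >= m$ideal[t, ]))
        viol <- viol + 1L
    }
    expect_equal(viol, 0L)
    # order properties
    expect_true(all(diag(m$order)))                      # reflexive
    expect_false(any(m$order & t(m$order) & !diag(S)))   # antisymmetric
    expect_true(all((m$order %*% m$order > 0) <= m$order))  # transitive
    # indices are a linear extension from the top
    strict <- m$order & !t(m$order)
    idx <- which(strict, arr.ind = TRUE)
    expect_true(all(idx[, 1L] < idx[, 2L]))
    # profile dominance implies state order
    prof <- m$profiles
    ind <- cbind(prof$att, prof$em, prof$vf, prof$cf, prof$ps)
    key <- apply(posetcog::ideal_response(prof, b), 1L, paste, collapse = "")
    skey <- apply(m$ideal, 1L, paste, collapse = "")
    st_of <- match(key, skey)
    pick <- sample(64, 20)
    dom_viol <- 0L
    for (p in pick) for (q in pick) {
      if (all(ind[p, ] >= ind[q, ]) && !m$order[st_of[p], st_of[q]])
        dom_viol <- dom_viol + 1L
    }
    expect_equal(dom_viol, 0L)
  }
})

test_that("Hasse edges equal the brute-force transitive reduction", {
  set.seed(7)
  bats <- c(list(adni2_battery(), aibl_battery()),
            replicate(5, random_battery(), simplify = FALSE))
  for (b in bats) {
    m <- poset_model(b)
    expect_equal(unname(m$hasse), oracle_transitive_reduction(m$order))
  }
})

test_that("DOT export mirrors the model", {
  m <- poset_model(adni2_battery())
  dot <- export_hasse(m)
  expect_equal(length(gregexpr("label=", dot)[[1]]), 29L)
  expect_equal(length(gregexpr("->", dot)[[1]]), nrow(m$hasse))
  f <- file.path(tempdir(), "hasse.dot")
  export_hasse(m, f)
  expect_identical(paste(readLines(f), collapse = "\n"), dot)
  toy <- poset_model(battery(list(list(name = "a", functions = "ATT",
                                       orientation = "higher"))))
  expect_equal(length(gregexpr("->", export_hasse(toy))[[1]]), 1L)
})

test_that("the state table mirrors the label conventions", {
  m <- poset_model(adni2_battery())
  tab <- state_table(m)
  expect_equal(nrow(tab), 29L)
  expect_equal(tab$CF[7], "*")
  expect_equal(tab$ATT[29], "")
  expect_equal(sum(as.integer(tab$n_profiles)), 64L)
})
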