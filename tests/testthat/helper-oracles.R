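# Independent brute-force oracles used to cross-check the implementation.

# Group the 64 profiles of the full domain by their ideal response pattern,
# computed here from first principles (no package internals).
oracle_profile_groups <- function(battery) {
  req <- battery$tests
  grid <- expand.grid(att = 0:1, em = 0:3, vf = 0:1, cf = 0:1, ps = 0:1)
  pattern <- apply(grid, 1L, function(p) {
    ok <- vapply(seq_len(nrow(req)), function(t) {
      (req$att[t] == 0 || p[["att"]] == 1) &&
        p[["em"]] >= req$em[t] &&
        (req$vf[t] == 0 || p[["vf"]] == 1) &&
        (req$cf[t] == 0 || p[["cf"]] == 1) &&
        (req$ps[t] == 0 || p[["ps"]] == 1)
    }, logical(1L))
    paste(as.integer(ok), collapse = "")
  })
  split(seq_len(nrow(grid)), pattern)
}

# Transitive reduction of a strict partial order by direct definition:
# keep (s, t) iff s > t and no u exists with s > u > t.
oracle_transitive_reduction <- function(ge) {
  S <- nrow(ge)
  strict <- ge & !t(ge)
  edges <- NULL
  for (s in seq_len(S)) for (t in seq_len(S)) {
    if (!strict[s, t]) next
    has_mid <- FALSE
    for (u in seq_len(S)) {
      if (u != s && u != t && strict[s, u] && strict[u, t]) {
        has_mid <- TRUE
        break
      }
    }
    if (!has_mid) edges <- rbind(edges, c(s, t))
  }
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

# Exact two-sided Mann-Whitney p by full enumeration, recomputing midranks
# for every group assignment from the raw pooled values.
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  mu <- n1 * length(y) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  combos <- utils::combn(N, n1)
  devs <- apply(combos, 2L, function(idx) abs(u_of(idx) - mu))
  mean(devs >= obs - 1e-9)
}

# Monte Carlo permutation version of the same two-sided p.
oracle_mw_mc <- function(x, y, B = 1e5, seed = 1) {
  set.seed(seed)
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  mu <- n1 * length(y) / 2
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu)
  devs <- vapply(seq_len(B), function(b) {
    idx <- sample.int(length(pooled), n1)
    abs(sum(r[idx]) - n1 * (n1 + 1) / 2 - mu)
  }, numeric(1L))
  mean(devs >= obs - 1e-9)
}

# A random valid battery specification over the full 7-function domain.
random_battery <- function(n_tests = sample(2:8, 1)) {
  tests <- lapply(seq_len(n_tests), function(i) {
    repeat {
      fns <- c(if (runif(1) < 0.8) "ATT",
               {
                 em <- sample(0:3, 1)
                 if (em > 0) paste0("EM", seq_len(em))
               },
               if (runif(1) < 0.4) "VF",
               if (runif(1) < 0.4) "CF",
               if (runif(1) < 0.4) "PS")
      if (length(fns)) break
    }
    list(name = paste0("t", i), functions = fns,
         orientation = sample(c("higher", "lower"), 1))
  })
  battery(tests)
}

# Wrap true generating thetas in the structure posterior_over_states expects.
make_dists <- function(model, theta_cap, theta_non) {
  tests <- colnames(model$ideal)
  Tn <- length(tests)
  list(theta_capable = matrix(theta_cap, Tn, 4L, byrow = TRUE,
                              dimnames = list(tests, paste0("cat", 0:3))),
       theta_noncapable = matrix(theta_non, Tn, 4L, byrow = TRUE,
                                 dimnames = list(tests, paste0("cat", 0:3))),
       tests = tests)
}
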