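#' Enumerate cognitive profiles
#'
#' A profile assigns a level to each cognitive function: binary levels for
#' ATT, VF, CF, PS and an ordinal level 0-3 for episodic memory (EM), where
#' level k implies capability at all lower EM levels. The full domain has
#' 2 x 4 x 2 x 2 x 2 = 64 profiles. Profiles are returned in a canonical
#' order: \code{expand.grid} order over (att, em, vf, cf, ps) with att
#' varying fastest.
#'
#' @param functions which functions to include (a subset of
#'   \code{c("ATT", "EM", "VF", "CF", "PS")}); EM contributes levels 0-3,
#'   each other function levels 0-1.
#' @return a data frame with one integer column per included function
#'   (lower case), one row per profile.
#' @examples
#' nrow(enumerate_profiles())             # 64
#' nrow(enumerate_profiles("EM"))         # 4
#' @export
enumerate_profiles <- function(functions = c("ATT", "EM", "VF", "CF", "PS")) {
  all_fns <- c("ATT", "EM", "VF", "CF", "PS")
  bad <- setdiff(functions, all_fns)
  if (length(bad)) stop("unknown function(s): ", paste(bad, collapse = ", "))
  if (length(functions) == 0L) stop("at least one function must be included")
  levs <- list(ATT = 0:1, EM = 0:3, VF = 0:1, CF = 0:1, PS = 0:1)
  grid <- expand.grid(levs[all_fns[all_fns %in% functions]],
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- tolower(names(grid))
  grid
}

# Expand profiles (data frame with att, em, vf, cf, ps) to the 7 reported
# indicators ATT, EM1, EM2, EM3, VF, CF, PS. EMj = 1 iff em >= j, so the
# triple is monotone: EM1 >= EM2 >= EM3.
profile_indicators <- function(profiles) {
  m <- cbind(ATT = profiles$att,
             EM1 = as.integer(profiles$em >= 1L),
             EM2 = as.integer(profiles$em >= 2L),
             EM3 = as.integer(profiles$em >= 3L),
             VF = profiles$vf, CF = profiles$cf, PS = profiles$ps)
  storage.mode(m) <- "integer"
  m
}

#' Ideal response pattern of a profile
#'
#' The ideal response of a profile under a battery is the binary vector with
#' a 1 for every test whose requirements the profile meets in full
#' (conjunctive rule: attention if required, EM level at least the test's EM
#' demand, and every required binary function at high level), and 0
#' otherwise. Subjects are expected to perform well exactly on the tests
#' their profile's ideal response marks.
#'
#' @param profile a single profile: a list or one-row data frame with fields
#'   \code{att}, \code{em}, \code{vf}, \code{cf}, \code{ps}; or a data frame
#'   of several profiles (one row each).
#' @param battery a \code{\link{battery}} object.
#' @return an integer vector of length \code{nrow(battery$tests)} (or a
#'   matrix with one row per profile), named by test.
#' @examples
#' b <- adni2_battery()
#' ideal_response(list(att = 1, em = 3, vf = 1, cf = 1, ps = 1), b)  # all 1
#' ideal_response(list(att = 0, em = 3, vf = 1, cf = 1, ps = 1), b)  # all 0
#' @export
ideal_response <- function(profile, battery) {
  req <- battery_requirements(battery)
  if (is.data.frame(profile) && nrow(profile) > 1L) {
    m <- ideal_matrix(profile, battery)
    return(m)
  }
  p <- as.list(profile)
  v <- as.integer((req$att == 0L | p$att == 1L) &
                  (p$em >= req$em) &
                  (req$vf == 0L | p$vf == 1L) &
                  (req$cf == 0L | p$cf == 1L) &
                  (req$ps == 0L | p$ps == 1L))
  names(v) <- battery$tests$name
  v
}

# Ideal responses for all rows of a profile data frame: n x T matrix.
ideal_matrix <- function(profiles, battery) {
  req <- battery_requirements(battery)
  m <- sapply(seq_len(nrow(req)), function(t) {
    as.integer((req$att[t] == 0L | profiles$att == 1L) &
               (profiles$em >= req$em[t]) &
               (req$vf[t] == 0L | profiles$vf == 1L) &
               (req$cf[t] == 0L | profiles$cf == 1L) &
               (req$ps[t] == 0L | profiles$ps == 1L))
  })
  m <- matrix(m, nrow = nrow(profiles))
  colnames(m) <- battery$tests$name
  m
}

#' Build the POSET classification model for a battery
#'
#' Enumerates all 64 cognitive profiles, computes each profile's ideal
#' response pattern under the battery, and groups profiles with identical
#' patterns into equivalence classes: profiles in the same class cannot be
#' statistically distinguished by the battery, so the classes - the model's
#' states - are the finest identifiable classification the battery supports.
#' Within a state, a function whose level varies across member profiles is
#' confounded (undetermined); its level cannot be inferred from any response
#' pattern.
#'
#' States are partially ordered by entrywise dominance of their ideal
#' response vectors: one state is at least as high as another when it is
#' expected to succeed on every test the other does. The order is well
#' defined on equivalence classes (unlike profile dominance) and, for
#' conjunctive requirements, preserves profile dominance. The Hasse edges
#' are the transitive reduction of this order.
#'
#' State indices are a linear extension from the top: states are sorted in
#' descending lexicographic order of their determined-high signature over
#' (ATT, EM1, EM2, EM3, VF, CF, PS), undetermined functions counting as
#' low. For the bundled ADNI2 panel this yields 29 states with the four
#' CF-confounded non-bottom states at indices 7, 14, 21, 28; for the AIBL
#' panel, 33 states with confounding only in the bottom state.
#'
#' In the bottom state (all-zero ideal response; when every test requires
#' attention this is exactly the ATT-low profiles) all functions other than
#' ATT are technically undetermined, but the model reports them as low by
#' convention: nothing can be demonstrated from a subject who is expected
#' to fail every test.
#'
#' @param battery a \code{\link{battery}} object with at least one test.
#' @return an object of class \code{"poset_model"} with components
#'   \describe{
#'     \item{states}{list of states; each has \code{index}, \code{members}
#'       (data frame of member profiles), \code{determined} (named 0/1
#'       vector over the 7 indicators, \code{NA} = undetermined),
#'       \code{undetermined} (character vector), \code{label} (character
#'       vector of high functions, undetermined ones suffixed \code{"*"}),
#'       \code{ideal} (shared ideal response vector).}
#'     \item{ideal}{S x T matrix of state ideal responses.}
#'     \item{high}{S x 7 matrix: 1 where a function is determined high
#'       (used for function-level probability summation).}
#'     \item{order}{S x S logical matrix, \code{order[s, t]} = state s >=
#'       state t.}
#'     \item{hasse}{two-column integer matrix of Hasse edges (higher state
#'       first).}
#'     \item{bottom_index, top_index}{indices of the all-fail and all-pass
#'       states (\code{NA} if absent).}
#'   }
#' @examples
#' m <- poset_model(adni2_battery())
#' m$n_states                      # 29
#' state_labels(m)[c(1, 7, 29)]
#' @export
poset_model <- function(battery) {
  stopifnot(inherits(battery, "battery"))
  if (nrow(battery$tests) == 0L)
    stop("battery has no tests: the model would be a single all-confounded class")
  profiles <- enumerate_profiles()
  iv <- ideal_matrix(profiles, battery)
  key <- apply(iv, 1L, paste, collapse = "")
  groups <- split(seq_len(nrow(profiles)), key)

  ind <- profile_indicators(profiles)
  states <- lapply(groups, function(g) {
    sub <- ind[g, , drop = FALSE]
    det <- apply(sub, 2L, function(col)
      if (all(col == col[1L])) col[1L] else NA_integer_)
    list(members = profiles[g, , drop = FALSE],
         member_rows = g,
         ideal = iv[g[1L], ],
         determined = det)
  })

  # Index: descending lexicographic order of determined-high signature,
  # undetermined treated as low. Reproduces the published state numbering.
  sig <- t(vapply(states, function(s) {
    d <- s$determined; d[is.na(d)] <- 0L; d
  }, integer(7L)))
  ord <- do.call(order, c(lapply(seq_len(7L), function(j) sig[, j]),
                          list(decreasing = TRUE)))
  states <- states[ord]
  names(states) <- NULL

  S <- length(states)
  ideal <- do.call(rbind, lapply(states, `[[`, "ideal"))
  storage.mode(ideal) <- "integer"
  colnames(ideal) <- battery$tests$name
  bottom <- which(rowSums(ideal) == 0L)
  top <- which(rowSums(ideal) == ncol(ideal))
  bottom_index <- if (length(bottom) == 1L) bottom else NA_integer_
  top_index <- if (length(top) == 1L) top else NA_integer_

  for (s in seq_len(S)) {
    st <- states[[s]]
    st$index <- s
    det <- st$determined
    st$undetermined <- names(det)[is.na(det)]
    if (!is.na(bottom_index) && s == bottom_index) {
      # Bottom-state convention: report all functions low.
      det[is.na(det)] <- 0L
      st$label <- character(0L)
    } else {
      st$label <- c(names(det)[!is.na(det) & det == 1L],
                    if (any(is.na(det))) paste0(names(det)[is.na(det)], "*"))
    }
    st$determined <- det
    states[[s]] <- st
  }

  high <- t(vapply(states, function(s) {
    d <- s$determined
    as.integer(!is.na(d) & d == 1L)
  }, integer(7L)))
  colnames(high) <- FUNCTION_NAMES

  # Partial order by entrywise ideal dominance; Hasse = transitive reduction.
  ge <- matrix(FALSE, S, S)
  for (s in seq_len(S)) for (t in seq_len(S))
    ge[s, t] <- all(ideal[s, ] >= ideal[t, ])
  strict <- ge & !t(ge)
  hasse <- which(strict & !(strict %*% strict > 0), arr.ind = TRUE)
  hasse <- unname(hasse[order(hasse[, 1L], hasse[, 2L]), , drop = FALSE])
  colnames(hasse) <- c("from", "to")

  structure(list(battery = battery, profiles = profiles, states = states,
                 ideal = ideal, high = high, order = ge, hasse = hasse,
                 n_states = S, bottom_index = bottom_index,
                 top_index = top_index),
            class = "poset_model")
}

#' State labels of a POSET model
#'
#' Each state is labelled by the functions its member profiles agree are at
#' a high level; a confounded function (one whose level varies across the
#' state's members) is suffixed with \code{"*"}. The bottom state has an
#' empty label by convention.
#'
#' @param model a \code{\link{poset_model}}.
#' @param collapse if non-\code{NULL}, paste each label with this separator.
#' @return a list of character vectors (or a character vector when
#'   \code{collapse} is given), in state-index order.
#' @export
state_labels <- function(model, collapse = NULL) {
  stopifnot(inherits(model, "poset_model"))
  labs <- lapply(model$states, `[[`, "label")
  if (!is.null(collapse)) vapply(labs, paste, "", collapse = collapse) else labs
}

#' Confounded (undetermined) functions per state
#'
#' Returns, for every state, the cognitive functions whose level cannot be
#' determined because it varies across the state's member profiles. For the
#' bottom state this lists every non-attention function even though the
#' model reports them as low by convention.
#'
#' @param model a \code{\link{poset_model}}.
#' @return a named list (one element per state index) of character vectors.
#' @examples
#' conf <- detect_confounding(poset_model(adni2_battery()))
#' which(vapply(conf, function(u) identical(u, "CF"), logical(1)))  # 7 14 21 28
#' @export
detect_confounding <- function(model) {
  stopifnot(inherits(model, "poset_model"))
  out <- lapply(model$states, `[[`, "undetermined")
  names(out) <- seq_along(out)
  out
}

#' State table mirroring the published layout
#'
#' One row per state, one column per cognitive function, with \code{"X"}
#' marking a determined-high function, \code{"*"} a confounded one and
#' \code{""} a low one.
#'
#' @param model a \code{\link{poset_model}}.
#' @return a data frame with columns \code{state}, \code{ATT}, \code{EM1},
#'   \code{EM2}, \code{EM3}, \code{VF}, \code{CF}, \code{PS},
#'   \code{n_profiles}.
#' @export
state_table <- function(model) {
  stopifnot(inherits(model, "poset_model"))
  rows <- t(vapply(model$states, function(s) {
    d <- s$determined
    mark <- ifelse(is.na(d), "*", ifelse(d == 1L, "X", ""))
    if (s$index == model$bottom_index %||% -1L) mark[] <- ifelse(d == 1L, "X", "")
    mark
  }, character(7L)))
  out <- data.frame(state = seq_len(model$n_states), rows,
                    n_profiles = vapply(model$states, function(s)
                      nrow(s$members), integer(1L)))
  names(out)[2:8] <- FUNCTION_NAMES
  out
}

#' Export a POSET model's Hasse diagram as Graphviz DOT
#'
#' One node per state (labelled by its high functions) and one directed edge
#' per Hasse edge, drawn from the higher state to the lower: the transitive
#' reduction of the model's partial order.
#'
#' @param model a \code{\link{poset_model}}.
#' @param file optional path; when given the DOT text is written there.
#' @return the DOT source, invisibly when \code{file} is given.
#' @export
export_hasse <- function(model, file = NULL) {
  stopifnot(inherits(model, "poset_model"))
  labs <- state_labels(model, collapse = " ")
  labs[labs == ""] <- "(none)"
  nodes <- sprintf("  s%d [label=\"%d: %s\"];",
                   seq_len(model$n_states), seq_len(model$n_states), labs)
  edges <- sprintf("  s%d -> s%d;", model$hasse[, "from"], model$hasse[, "to"])
  dot <- paste(c("digraph poset {", "  rankdir=TB;", nodes, edges, "}"),
               collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}

#' @export
print.poset_model <- function(x, ...) {
  cat("POSET classification model:", x$n_states, "states from",
      nrow(x$battery$tests), "tests\n")
  n_conf <- sum(vapply(x$states, function(s)
    length(s$undetermined) > 0L && s$index != (x$bottom_index %||% -1L),
    logical(1L)))
  cat("  top state:", x$top_index, " bottom state:", x$bottom_index, "\n")
  cat("  states with confounding beyond the bottom state:", n_conf, "\n")
  cat("  Hasse edges:", nrow(x$hasse), "\n")
  invisible(x)
}

#' @export
summary.poset_model <- function(object, ...) {
  tab <- state_table(object)
  tab$label <- state_labels(object, collapse = " ")
  class(tab) <- c("summary.poset_model", "data.frame")
  tab
}

#' Plot a POSET model as a layered Hasse diagram
#'
#' Base-graphics rendering with states placed on horizontal layers by their
#' longest chain distance from the top, higher states above lower ones.
#'
#' @param x a \code{\link{poset_model}}.
#' @param cex label size.
#' @param ... passed to \code{plot.default}.
#' @export
plot.poset_model <- function(x, cex = 0.6, ...) {
  S <- x$n_states
  # layer = longest path from a maximal state, computed by relaxation
  depth <- rep(0L, S)
  repeat {
    new <- depth
    for (e in seq_len(nrow(x$hasse))) {
      f <- x$hasse[e, 1L]; t <- x$hasse[e, 2L]
      if (new[t] < depth[f] + 1L) new[t] <- depth[f] + 1L
    }
    if (identical(new, depth)) break
    depth <- new
  }
  xs <- numeric(S)
  for (d in unique(sort(depth))) {
    idx <- which(depth == d)
    xs[idx] <- seq_along(idx) - (length(idx) + 1) / 2
  }
  ys <- -depth
  graphics::plot(xs, ys, type = "n", axes = FALSE, xlab = "", ylab = "", ...)
  graphics::segments(xs[x$hasse[, 1L]], ys[x$hasse[, 1L]],
                     xs[x$hasse[, 2L]], ys[x$hasse[, 2L]], col = "grey60")
  labs <- state_labels(x, collapse = "\n")
  graphics::points(xs, ys, pch = 21, bg = "white", cex = 3)
  graphics::text(xs, ys, seq_len(S), cex = cex)
  invisible(list(x = xs, y = ys, depth = depth))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
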