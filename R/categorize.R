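#' Categorize scores into sample quartile groups
#'
#' Response values are discretized into four groups demarcated by the sample
#' quartiles, after orientation alignment (scores from tests where lower is
#' better, e.g. timed tests, are negated first so that category 3 always
#' means best performance). Cutpoints are the 25/50/75 sample percentiles
#' under the linear-interpolation definition (\code{quantile} type 7); a
#' value's category is the number of cutpoints strictly below it, so tied
#' values always share a category and the categorization depends only on the
#' ordering of the scores.
#'
#' @param x numeric scores; \code{NA} allowed (propagated).
#' @param orientation \code{"higher"} (default) if larger scores are better,
#'   \code{"lower"} otherwise.
#' @param cutpoints optionally, three pre-computed cutpoints (on the
#'   oriented scale) to apply instead of the sample's own quartiles - used
#'   when categorizing new subjects against a reference cohort.
#' @return a list of class \code{"quartile_categories"}:
#'   \code{category} (integer 0-3, 0 = worst quartile, \code{NA} preserved),
#'   \code{cutpoints} (the three percentiles on the oriented scale) and
#'   \code{orientation}.
#' @examples
#' quartile_categorize(1:8)$category  # 0 0 1 1 2 2 3 3
#' @export
quartile_categorize <- function(x, orientation = c("higher", "lower"),
                                cutpoints = NULL) {
  orientation <- match.arg(orientation)
  v <- if (orientation == "lower") -x else x
  obs <- v[!is.na(v)]
  if (is.null(cutpoints)) {
    if (length(obs) < 4L)
      stop("need at least 4 non-missing scores to form quartile groups (got ",
           length(obs), ")")
    if (length(unique(obs)) == 1L)
      warning("all scores identical: degenerate single-category distribution")
    cutpoints <- unname(stats::quantile(obs, c(0.25, 0.5, 0.75),
                                        type = 7, names = FALSE))
  } else if (length(cutpoints) != 3L || is.unsorted(cutpoints)) {
    stop("'cutpoints' must be three non-decreasing values")
  }
  category <- rowSums(outer(v, cutpoints, ">"))
  category[is.na(v)] <- NA_integer_
  structure(list(category = as.integer(category), cutpoints = cutpoints,
                 orientation = orientation),
            class = "quartile_categories")
}

# Categorize every battery test column of a cohort data frame.
# Returns list(categories = n x T integer matrix, cutpoints = 3 x T matrix).
categorize_cohort <- function(data, battery, cutpoints = NULL) {
  tests <- battery$tests$name
  missing_cols <- setdiff(tests, names(data))
  if (length(missing_cols))
    stop("cohort data lacks score column(s): ",
         paste(missing_cols, collapse = ", "))
  cats <- matrix(NA_integer_, nrow(data), length(tests),
                 dimnames = list(NULL, tests))
  cps <- matrix(NA_real_, 3L, length(tests), dimnames = list(
    c("q25", "q50", "q75"), tests))
  for (j in seq_along(tests)) {
    qc <- quartile_categorize(data[[tests[j]]],
                              orientation = battery$tests$orientation[j],
                              cutpoints = if (is.null(cutpoints)) NULL
                                          else cutpoints[, tests[j]])
    cats[, j] <- qc$category
    cps[, j] <- qc$cutpoints
  }
  list(categories = cats, cutpoints = cps)
}
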