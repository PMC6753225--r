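AGE_GROUPS <- c("<70", "70-80", "81-90")

#' Assign study age groups
#'
#' Ages are stratified into three groups: under 70 years, 70 up to 80
#' years (inclusive bounds) and 81 up to 90 years. Non-integer ages are
#' floored first. Ages outside the accepted study range 55-90 are an error.
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels \code{"<70"}, \code{"70-80"}, \code{"81-90"}.
#' @examples
#' assign_age_group(c(69, 70, 80, 81, 90))
#' @export
assign_age_group <- function(age) {
  if (!is.numeric(age)) stop("'age' must be numeric")
  a <- floor(age)
  bad <- !is.na(a) & (a < 55 | a > 90)
  if (any(bad))
    stop("age(s) outside the accepted 55-90 study range: ",
         paste(utils::head(age[bad], 5L), collapse = ", "))
  g <- ifelse(a < 70, AGE_GROUPS[1L],
              ifelse(a <= 80, AGE_GROUPS[2L], AGE_GROUPS[3L]))
  factor(g, levels = AGE_GROUPS)
}

#' Z-score test scores within age groups
#'
#' Age-normed scores: within each age group, \code{z = (x - group mean) /
#' group sd}, computed after orientation alignment (scores from
#' lower-is-better tests are negated first, so a larger z always means
#' better performance). Missing scores propagate as missing.
#'
#' @param x numeric raw scores.
#' @param age_group factor/vector of group labels, same length as \code{x}.
#' @param orientation \code{"higher"} or \code{"lower"}.
#' @param test optional test name used in error messages.
#' @return numeric vector of z-scores.
#' @export
zscore_by_age_group <- function(x, age_group, orientation = c("higher", "lower"),
                                test = NULL) {
  orientation <- match.arg(orientation)
  if (length(x) != length(age_group))
    stop("'x' and 'age_group' lengths differ")
  v <- if (orientation == "lower") -x else x
  z <- rep(NA_real_, length(v))
  lbl <- if (is.null(test)) "" else paste0(" for test '", test, "'")
  for (g in unique(as.character(age_group[!is.na(age_group)]))) {
    idx <- which(as.character(age_group) == g)
    obs <- idx[!is.na(v[idx])]
    if (length(obs) < 2L)
      stop("age group '", g, "'", lbl,
           " has fewer than 2 non-missing scores")
    s <- stats::sd(v[obs])
    if (s == 0)
      stop("zero within-group standard deviation", lbl,
           " in age group '", g, "'")
    z[idx] <- (v[idx] - mean(v[obs])) / s
  }
  z
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with midrank tie
#' handling. For small samples (n1 + n2 <= 20) the p-value is computed by
#' exact enumeration of all assignments of the pooled values to the two
#' groups (which accommodates ties exactly); for larger samples, by the
#' normal approximation with tie-corrected variance and continuity
#' correction. The U statistic (and hence the p-value) is invariant under
#' any strictly monotone transform of the pooled data.
#'
#' @param x,y numeric samples (non-empty; \code{NA} dropped).
#' @param exact force (\code{TRUE}) or suppress (\code{FALSE}) exact
#'   enumeration; default: exact iff n1 + n2 <= 20.
#' @return a list with \code{statistic} (U for the first sample),
#'   \code{p.value} and \code{method}.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p.value  # 1/3 by enumeration
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  if (is.null(exact)) exact <- (n1 + n2) <= 20L
  pooled <- c(x, y)
  r <- rank(pooled)   # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (exact) {
    dev_obs <- abs(U - mu)
    sums <- utils::combn(r, n1, sum)
    devs <- abs(sums - n1 * (n1 + 1) / 2 - mu)
    p <- mean(devs >= dev_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
      p <- min(1, p)
    }
    method <- "normal approximation, tie-corrected, continuity-corrected"
  }
  list(statistic = unname(U), p.value = p, method = method)
}

#' Compare function-high probabilities by amyloid status within strata
#'
#' Within every stratum (age group, optionally crossed with cognitive
#' status), each of the seven function-level probabilities of high
#' functioning is compared between amyloid-positive and amyloid-negative
#' subjects by a two-sided Mann-Whitney test. Significance is reported both
#' at the Bonferroni-corrected threshold for the seven functions,
#' 0.05/7 = 0.007, and (for exploratory use) at the nominal 0.05 level. A
#' stratum with fewer than 2 subjects in either amyloid arm is flagged as
#' not computable rather than dropped.
#'
#' @param function_high an n x 7 matrix as returned by
#'   \code{\link{function_high_probabilities}} (or \code{fitted} on a
#'   \code{\link{poset_fit}}).
#' @param subjects data frame aligned with \code{function_high}, with
#'   columns \code{amyloid} (\code{"positive"}/\code{"negative"}),
#'   \code{age_group} (or \code{age}, from which groups are derived) and,
#'   if stratified on it, \code{cognitive_status}.
#' @param stratify_by stratification columns, default \code{"age_group"}.
#' @param alpha nominal significance level (default 0.05).
#' @return a data frame with one row per stratum x function: columns
#'   \code{stratum}, \code{function}, \code{n_positive}, \code{n_negative},
#'   \code{U}, \code{p}, \code{significant_bonferroni},
#'   \code{significant_nominal}, \code{computable}. The Bonferroni
#'   threshold is attached as attribute \code{"threshold"}.
#' @export
compare_by_amyloid <- function(function_high, subjects,
                               stratify_by = "age_group", alpha = 0.05) {
  function_high <- as.matrix(function_high)
  if (nrow(function_high) != nrow(subjects))
    stop("'function_high' and 'subjects' must have the same number of rows")
  if (is.null(subjects$amyloid))
    stop("'subjects' must contain an 'amyloid' column")
  if (!"age_group" %in% names(subjects) && "age" %in% names(subjects))
    subjects$age_group <- assign_age_group(subjects$age)
  missing_strat <- setdiff(stratify_by, names(subjects))
  if (length(missing_strat))
    stop("stratification column(s) not in 'subjects': ",
         paste(missing_strat, collapse = ", "))
  if ("age_group" %in% stratify_by &&
      all(as.character(subjects$age_group) %in% AGE_GROUPS))
    subjects$age_group <- factor(as.character(subjects$age_group),
                                 levels = AGE_GROUPS)
  fns <- colnames(function_high) %||% FUNCTION_NAMES
  k <- ncol(function_high)
  threshold <- alpha / k
  amy <- as.character(subjects$amyloid)
  if (!all(amy %in% c("positive", "negative", NA)))
    stop("'amyloid' must be \"positive\" or \"negative\"")

  strata <- interaction(subjects[stratify_by], sep = " / ", drop = FALSE)
  levels_used <- levels(strata)
  rows <- list()
  for (st in levels_used) {
    idx <- which(strata == st & !is.na(amy))
    pos <- idx[amy[idx] == "positive"]
    neg <- idx[amy[idx] == "negative"]
    computable <- length(pos) >= 2L && length(neg) >= 2L
    for (j in seq_len(k)) {
      if (computable) {
        mw <- mann_whitney_u(function_high[pos, j], function_high[neg, j])
        U <- mw$statistic; p <- mw$p.value
      } else {
        U <- NA_real_; p <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, fn = fns[j],
        n_positive = length(pos), n_negative = length(neg),
        U = U, p = p,
        significant_bonferroni = !is.na(p) && p < threshold,
        significant_nominal = !is.na(p) && p < alpha,
        computable = computable,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "fn"] <- "function"
  attr(out, "threshold") <- threshold
  out
}

#' APOE4-by-age majority-class prediction of amyloid status
#'
#' Cross-tabulates amyloid status by APOE4 allele count (0/1/2) and age
#' group, and reports for each cell the majority-class prediction rule and
#' its accuracy, \code{max(n_positive, n_negative) / total}, as a
#' percentage with one decimal. Empty cells report \code{NA} accuracy.
#' Subjects with unknown APOE4 count or amyloid status are excluded.
#'
#' @param subjects data frame with columns \code{apoe4} (0, 1, 2 or
#'   \code{NA}), \code{amyloid} and \code{age_group} (or \code{age}).
#' @return a data frame with one row per APOE4 x age-group cell: columns
#'   \code{apoe4}, \code{age_group}, \code{n_negative}, \code{n_positive},
#'   \code{n}, \code{majority}, \code{accuracy} (percent, 1 decimal).
#' @examples
#' subj <- data.frame(apoe4 = rep(0, 99), age_group = "<70",
#'                    amyloid = rep(c("negative", "positive"), c(81, 18)))
#' apoe_age_accuracy(subj)[1, "accuracy"]  # 81.8
#' @export
apoe_age_accuracy <- function(subjects) {
  if (is.null(subjects$apoe4) || is.null(subjects$amyloid))
    stop("'subjects' must contain 'apoe4' and 'amyloid' columns")
  if (!"age_group" %in% names(subjects) && "age" %in% names(subjects))
    subjects$age_group <- assign_age_group(subjects$age)
  ag <- factor(as.character(subjects$age_group), levels = AGE_GROUPS)
  ap <- suppressWarnings(as.integer(as.character(subjects$apoe4)))
  amy <- as.character(subjects$amyloid)
  keep <- !is.na(ap) & ap %in% 0:2 & amy %in% c("positive", "negative") &
    !is.na(ag)
  rows <- expand.grid(apoe4 = 0:2, age_group = AGE_GROUPS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[order(rows$apoe4), ]
  res <- lapply(seq_len(nrow(rows)), function(i) {
    sel <- keep & ap == rows$apoe4[i] & as.character(ag) == rows$age_group[i]
    n_neg <- sum(amy[sel] == "negative")
    n_pos <- sum(amy[sel] == "positive")
    n <- n_neg + n_pos
    if (n == 0L) {
      maj <- NA_character_; acc <- NA_real_
    } else {
      maj <- if (n_pos > n_neg) "positive" else "negative"
      acc <- round(100 * max(n_neg, n_pos) / n, 1L)
    }
    data.frame(apoe4 = rows$apoe4[i], age_group = rows$age_group[i],
               n_negative = n_neg, n_positive = n_pos, n = n,
               majority = maj, accuracy = acc, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
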