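# Recursive binary classification tree with Gini splits and per-split
# random variable subsetting (mtry). X is a numeric matrix, y integer
# class codes 1/2. Nodes are stored in a flat data frame: terminal nodes
# have var = 0 and carry the majority class (ties toward class 1).
grow_tree <- function(X, y, mtry, min_leaf) {
  p <- ncol(X)
  nodes <- list()
  new_node <- function(idx) {
    n1 <- sum(y[idx] == 1L)
    pred <- if (n1 >= length(idx) - n1) 1L else 2L
    list(var = 0L, split = NA_real_, left = 0L, right = 0L, pred = pred,
         idx = idx)
  }
  best_split <- function(idx, vars) {
    n <- length(idx)
    best <- NULL; best_dec <- 1e-12
    y1 <- y[idx] == 1L
    n1_tot <- sum(y1)
    g_parent <- 1 - (n1_tot / n)^2 - ((n - n1_tot) / n)^2
    for (v in vars) {
      x <- X[idx, v]
      o <- order(x)
      xs <- x[o]; ys <- y1[o]
      distinct <- which(diff(xs) > 0)    # candidate cuts between values
      if (!length(distinct)) next
      cum1 <- cumsum(ys)
      nl <- distinct
      n1l <- cum1[distinct]
      nr <- n - nl
      n1r <- n1_tot - n1l
      ok <- nl >= min_leaf & nr >= min_leaf
      if (!any(ok)) next
      gl <- 1 - (n1l / nl)^2 - ((nl - n1l) / nl)^2
      gr <- 1 - (n1r / nr)^2 - ((nr - n1r) / nr)^2
      dec <- g_parent - (nl * gl + nr * gr) / n
      dec[!ok] <- -Inf
      k <- which.max(dec)
      if (dec[k] > best_dec) {
        best_dec <- dec[k]
        best <- list(var = v, split = (xs[distinct[k]] + xs[distinct[k] + 1L]) / 2,
                     dec = dec[k])
      }
    }
    best
  }
  build <- function(idx) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- new_node(idx)
    n1 <- sum(y[idx] == 1L)
    if (n1 == 0L || n1 == length(idx) || length(idx) < 2L * min_leaf)
      return(id)
    vars <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    sp <- best_split(idx, vars)
    if (is.null(sp)) return(id)
    go_left <- X[idx, sp$var] <= sp$split
    l <- build(idx[go_left])
    r <- build(idx[!go_left])
    nodes[[id]]$var <<- sp$var
    nodes[[id]]$split <<- sp$split
    nodes[[id]]$left <<- l
    nodes[[id]]$right <<- r
    id
  }
  build(seq_len(nrow(X)))
  data.frame(var = vapply(nodes, `[[`, 0L, "var"),
             split = vapply(nodes, `[[`, 0, "split"),
             left = vapply(nodes, `[[`, 0L, "left"),
             right = vapply(nodes, `[[`, 0L, "right"),
             pred = vapply(nodes, `[[`, 0L, "pred"))
}

# Predict class codes for rows of X down one tree.
predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  for (i in seq_len(n)) {
    node <- 1L
    while (tree$var[node] != 0L) {
      node <- if (X[i, tree$var[node]] <= tree$split[node])
        tree$left[node] else tree$right[node]
    }
    out[i] <- tree$pred[node]
  }
  out
}

prepare_forest_xy <- function(X, y) {
  X <- as.data.frame(X)
  num <- vapply(X, function(col) {
    if (is.numeric(col)) return(TRUE)
    if (is.logical(col) || is.factor(col) || is.character(col)) return(FALSE)
    NA
  }, logical(1L))
  for (j in which(!num)) X[[j]] <- as.numeric(as.factor(X[[j]]))
  Xm <- as.matrix(X)
  storage.mode(Xm) <- "double"
  if (anyNA(Xm)) stop("predictors must not contain missing values")
  y <- factor(y)
  if (anyNA(y)) stop("labels must not contain missing values")
  list(X = Xm, y = y)
}

#' Fit a bootstrap classification forest with explicit OOB bookkeeping
#'
#' An ensemble of \code{ntree} classification trees, each grown on a
#' bootstrap sample (n draws with replacement) with \code{mtry} randomly
#' selected candidate variables at every split (Gini impurity). The
#' out-of-bag (OOB) rows of each tree - the complement of its bootstrap
#' multiset, about a third of the sample - are stored explicitly, and the
#' OOB error is the misclassification rate of the per-subject majority vote
#' over the trees for which the subject is out of bag (vote ties broken
#' toward the first class level). Deterministic given \code{seed}.
#'
#' @param X predictor table (data frame or matrix); factors and logicals
#'   are integer-encoded, no missing values allowed.
#' @param y class labels (two levels; a single-class input yields OOB error
#'   0 with a warning).
#' @param ntree number of trees (default 1000).
#' @param mtry variables sampled per split (default 4; must not exceed the
#'   number of predictors).
#' @param min_leaf minimum rows per leaf (default 1).
#' @param seed optional integer seed.
#' @return an object of class \code{"oob_forest"}: \code{trees},
#'   \code{boot} and \code{oob} (per-tree index sets),
#'   \code{oob_error} (percent), \code{oob_pred}, \code{votes},
#'   \code{predictors}, \code{classes}, \code{config}.
#' @examples
#' set.seed(1)
#' X <- data.frame(a = rnorm(80), b = rep(0:1, 40))
#' y <- ifelse(X$b == 1, "pos", "neg")
#' fit_forest(X, y, ntree = 25, mtry = 1, seed = 1)$oob_error
#' @export
fit_forest <- function(X, y, ntree = 1000, mtry = 4, min_leaf = 1,
                       seed = NULL) {
  d <- prepare_forest_xy(X, y)
  Xm <- d$X; yf <- d$y
  n <- nrow(Xm); p <- ncol(Xm)
  if (mtry < 1 || mtry > p)
    stop("'mtry' must be between 1 and the number of predictors (", p, ")")
  if (ntree < 1) stop("'ntree' must be >= 1")
  if (nlevels(yf) > 2L) stop("'y' must have at most two classes")
  single_class <- nlevels(droplevels(yf)) < 2L
  if (single_class)
    warning("single-class labels: OOB error is 0 by construction")
  yc <- as.integer(yf)
  if (!is.null(seed)) set.seed(seed)

  trees <- vector("list", ntree)
  boot <- vector("list", ntree)
  oob <- vector("list", ntree)
  votes <- matrix(0L, n, 2L)
  for (b in seq_len(ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    out <- setdiff(seq_len(n), idx)
    boot[[b]] <- idx
    oob[[b]] <- out
    tr <- grow_tree(Xm[idx, , drop = FALSE], yc[idx], mtry, min_leaf)
    trees[[b]] <- tr
    if (length(out)) {
      pred <- predict_tree(tr, Xm[out, , drop = FALSE])
      votes[cbind(out, pred)] <- votes[cbind(out, pred)] + 1L
    }
  }
  covered <- rowSums(votes) > 0L
  if (!all(covered))
    warning(sum(!covered), " subject(s) were never out of bag; they are ",
            "excluded from the OOB error")
  oob_pred <- ifelse(votes[, 1L] >= votes[, 2L], 1L, 2L)
  oob_pred[!covered] <- NA_integer_
  oob_error <- if (single_class) 0 else
    100 * mean(oob_pred[covered] != yc[covered])
  structure(list(trees = trees, boot = boot, oob = oob,
                 oob_error = oob_error,
                 oob_pred = factor(levels(yf)[oob_pred], levels = levels(yf)),
                 votes = votes, predictors = colnames(Xm),
                 classes = levels(yf), y = yf, n = n,
                 config = list(ntree = ntree, mtry = mtry,
                               min_leaf = min_leaf, seed = seed)),
            class = "oob_forest")
}

#' Permutation variable importance (mean decrease in accuracy)
#'
#' For every tree and every variable, classification accuracy on the tree's
#' out-of-bag rows is measured before and after randomly permuting that
#' variable's values within the OOB rows; the variable's importance is the
#' mean accuracy drop over trees, in percentage points. Uninformative
#' variables center at zero and may come out negative; a constant variable
#' is exactly zero (permutation cannot change it).
#'
#' @param forest a \code{\link{fit_forest}} result.
#' @param X,y the predictor table and labels the forest was fitted to.
#' @param seed optional integer seed for the permutations.
#' @return named numeric vector of mean decrease in accuracy (percentage
#'   points), one entry per predictor.
#' @export
oob_mda <- function(forest, X, y, seed = NULL) {
  stopifnot(inherits(forest, "oob_forest"))
  d <- prepare_forest_xy(X, y)
  Xm <- d$X
  if (!identical(colnames(Xm), forest$predictors))
    stop("predictor columns do not match the fitted forest")
  yc <- as.integer(factor(as.character(d$y), levels = forest$classes))
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(Xm)
  ntree <- length(forest$trees)
  drop_sum <- numeric(p)
  used <- 0L
  for (b in seq_len(ntree)) {
    out <- forest$oob[[b]]
    if (length(out) < 2L) next
    used <- used + 1L
    Xo <- Xm[out, , drop = FALSE]
    base_acc <- mean(predict_tree(forest$trees[[b]], Xo) == yc[out])
    for (v in seq_len(p)) {
      if (length(unique(Xo[, v])) == 1L) next  # constant: identical by ties
      Xp <- Xo
      Xp[, v] <- Xo[sample.int(nrow(Xo)), v]
      perm_acc <- mean(predict_tree(forest$trees[[b]], Xp) == yc[out])
      drop_sum[v] <- drop_sum[v] + (base_acc - perm_acc)
    }
  }
  mda <- 100 * drop_sum / max(used, 1L)
  names(mda) <- forest$predictors
  mda
}

#' @export
print.oob_forest <- function(x, ...) {
  cat("Bootstrap classification forest:", x$config$ntree, "trees, mtry =",
      x$config$mtry, "\n")
  cat("  classes:", paste(x$classes, collapse = " / "), " n =", x$n, "\n")
  cat("  OOB error rate:", sprintf("%.2f%%", x$oob_error), "\n")
  frac <- mean(vapply(x$oob, length, 0L)) / x$n
  cat("  mean OOB fraction per tree:", sprintf("%.3f", frac), "\n")
  invisible(x)
}
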