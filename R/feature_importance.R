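## Feature-importance stage: out-of-bag random-forest permutation
## importance, a thresholded correlation graph, five filter/wrapper rankers
## and their combination by top-20 membership and mean rank (CWF).

#' Construct an importance ranking
#'
#' @param method Label of the producing method.
#' @param feature Character vector of feature names (no duplicates).
#' @param score Numeric scores, one per feature.
#' @param normalized Logical; `TRUE` when scores are scaled so the most
#'   important feature equals 1.
#' @param decreasing Sort order: `TRUE` (default) when larger scores mean
#'   more important, `FALSE` when smaller scores do (e.g. mean ranks).
#' @return An object of class `importance_ranking`: a data frame with
#'   columns `rank`, `feature`, `score`, ordered by descending importance
#'   (ties broken lexicographically by feature name).
#' @export
importance_ranking <- function(method, feature, score,
                               normalized = FALSE, decreasing = TRUE) {
  stopifnot(length(feature) == length(score), !anyDuplicated(feature))
  ord <- order(if (decreasing) -score else score, feature)
  out <- data.frame(rank = seq_along(feature),
                    feature = feature[ord],
                    score = score[ord],
                    stringsAsFactors = FALSE)
  structure(out, method = method, normalized = normalized,
            class = c("importance_ranking", "data.frame"))
}

#' @export
print.importance_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<importance_ranking: %s, %d features%s>\n",
              attr(x, "method"), nrow(x),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}

#' Top-k feature names of a ranking
#'
#' @param ranking An [importance_ranking()] (or character vector, returned
#'   head unchanged).
#' @param k Number of leading features.
#' @return Character vector of at most `k` names.
#' @export
top_features <- function(ranking, k = 20) {
  if (is.character(ranking)) return(utils::head(ranking, k))
  utils::head(ranking$feature, k)
}

#' Split a feature table into design matrix and labels
#'
#' Missing values (e.g. timing statistics of low-quality views) are median
#' imputed per column, with a message giving the count.
#'
#' @param tab Feature table from [extract_cohort_features()] or
#'   [read_feature_table()].
#' @return List with `X` (numeric matrix, patients x features) and `y`
#'   (factor with levels `non-responder`, `responder`).
#' @export
feature_matrix <- function(tab) {
  meta <- intersect(c("patient_id", "response"), names(tab))
  X <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  storage.mode(X) <- "double"
  n_na <- sum(is.na(X))
  if (n_na > 0) {
    message("imputing ", n_na, " missing feature values with column medians")
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- stats::median(X[, j], na.rm = TRUE)
    }
  }
  y <- NULL
  if ("response" %in% meta)
    y <- factor(tab$response, levels = c("non-responder", "responder"))
  list(X = X, y = y)
}

#' Random-forest configuration
#'
#' Defaults follow the configuration used for the out-of-bag analysis:
#' 700 trees, Gini split criterion (the criterion of the underlying
#' implementation), 10 candidate features per split, unlimited depth, and
#' inverse-class-frequency weights to cope with the unbalanced
#' responder/non-responder classes.
#'
#' @param n_trees Number of trees.
#' @param max_features Candidate features per split.
#' @param seed Integer seed.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 700, max_features = 10, seed = 1L) {
  stopifnot(n_trees >= 1, max_features >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_features = as.integer(max_features),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Out-of-bag random-forest permutation importance
#'
#' Fits a classification random forest and scores each feature by the mean
#' decrease in out-of-bag accuracy when that feature is permuted over each
#' tree's out-of-bag samples, averaged over trees (Breiman's permutation
#' importance, unscaled). Scores are normalized so the most important
#' feature equals 1 (when any score is positive). Class imbalance is
#' handled by inverse-class-frequency weights.
#'
#' @param X Numeric matrix (patients x features) without missing values.
#' @param y Two-level factor of response labels.
#' @param cfg An [rf_config()].
#' @return An [importance_ranking()] with `method = "OOB"`.
#' @export
oob_importance <- function(X, y, cfg = rf_config()) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need two classes to estimate importance")
  if (nrow(X) < 2) stop("need at least two patients")
  if (anyNA(X)) stop("X contains missing values; impute first (see feature_matrix)")
  classwt <- as.numeric(1 / table(y))
  names(classwt) <- levels(y)
  set.seed(cfg$seed)
  fit <- randomForest::randomForest(
    x = X, y = y,
    ntree = cfg$n_trees,
    mtry = min(cfg$max_features, ncol(X)),
    classwt = classwt,
    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  if (max(imp) > 0) {
    imp <- imp / max(imp)
    normalized <- TRUE
  } else normalized <- FALSE
  importance_ranking("OOB", colnames(X), unname(imp), normalized = normalized)
}

#' Correlation graph of a feature subset
#'
#' Pearson correlation between each pair of the given features; pairs with
#' absolute correlation strictly above the threshold become edges, drawn
#' with thickness `10 * |r| - 5` (so |r| = 1 gives 5 points and edges at or
#' below 0.5 are not shown). Zero-variance features are excluded with a
#' warning.
#'
#' @param X Numeric matrix or feature table (patients x features).
#' @param features Character vector of column names to include (default:
#'   all).
#' @param threshold Absolute-correlation cutoff (default 0.5, strict).
#' @return An object of class `correlation_graph`: list with `nodes`
#'   (character) and `edges` (data frame `a`, `b`, `abs_r`, `thickness`).
#' @export
correlation_graph <- function(X, features = colnames(X), threshold = 0.5) {
  X <- as.matrix(X[, features, drop = FALSE])
  if (nrow(X) < 3) stop("need at least 3 samples to estimate correlations")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    drop <- colnames(X)[sds == 0 | is.na(sds)]
    warning("excluding zero-variance feature(s): ", paste(drop, collapse = ", "))
    X <- X[, !(colnames(X) %in% drop), drop = FALSE]
  }
  nodes <- colnames(X)
  r <- stats::cor(X)
  idx <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    a = nodes[idx[, 1]],
    b = nodes[idx[, 2]],
    abs_r = abs(r[idx]),
    stringsAsFactors = FALSE)
  edges$thickness <- 10 * edges$abs_r - 5
  edges <- edges[order(-edges$abs_r, edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("<correlation_graph: %d nodes, %d edges (|r| > 0.5)>\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print.data.frame(utils::head(x$edges, 10), row.names = FALSE)
  invisible(x)
}

.binary_y <- function(y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  y
}

#' Filter ranker: correlation with the target
#'
#' Ranks features by absolute point-biserial correlation between the
#' feature and the binary response indicator. Zero-variance features score
#' 0 and fall to the bottom.
#'
#' @param X Numeric matrix (patients x features).
#' @param y Two-level factor.
#' @return An [importance_ranking()].
#' @export
rank_by_target_correlation <- function(X, y) {
  y <- .binary_y(y)
  yn <- as.numeric(y) - 1
  score <- suppressWarnings(abs(as.numeric(stats::cor(X, yn))))
  score[!is.finite(score)] <- 0
  importance_ranking("correlation_with_target", colnames(X), score)
}

#' Filter ranker: Welch's t statistic
#'
#' Ranks features by the absolute unequal-variance two-sample t statistic
#' between the two response groups.
#'
#' @inheritParams rank_by_target_correlation
#' @return An [importance_ranking()].
#' @export
rank_by_welch_t <- function(X, y) {
  y <- .binary_y(y)
  score <- apply(X, 2, function(x) {
    tryCatch(abs(unname(stats::t.test(x[y == levels(y)[1]],
                                      x[y == levels(y)[2]])$statistic)),
             error = function(e) 0)
  })
  score[!is.finite(score)] <- 0
  importance_ranking("welch_t", colnames(X), unname(score))
}

#' Filter ranker: univariate ANOVA F (K-Best)
#'
#' Ranks features by the one-way ANOVA F statistic of the feature against
#' the response groups (for two classes, the square of the pooled-variance
#' t statistic).
#'
#' @inheritParams rank_by_target_correlation
#' @return An [importance_ranking()].
#' @export
rank_by_kbest <- function(X, y) {
  y <- .binary_y(y)
  score <- apply(X, 2, function(x) {
    tryCatch(unname(stats::oneway.test(x ~ y, var.equal = TRUE)$statistic),
             error = function(e) 0)
  })
  score[!is.finite(score)] <- 0
  importance_ranking("kbest_f", colnames(X), unname(score))
}

## ridge (L2) least-squares classifier weights on standardized features;
## the elimination criterion inside RFE
.ridge_weights <- function(X, y01, lambda) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- Inf              # zero-variance -> weight exactly 0
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  yv <- ifelse(y01 == 1, 1, -1)
  p <- ncol(Xs)
  beta <- solve(crossprod(Xs) + diag(lambda, p), crossprod(Xs, yv))
  as.numeric(beta)
}

#' Wrapper ranker: recursive feature elimination
#'
#' Repeatedly fits an L2-regularized linear classifier on standardized
#' features and drops the feature with the smallest absolute weight (ties
#' broken lexicographically) until none remain. The ranking is the reverse
#' elimination order: the last survivor ranks first. Deterministic.
#'
#' @inheritParams rank_by_target_correlation
#' @param lambda Ridge penalty of the internal classifier.
#' @param step Features removed per round (default 1).
#' @return An [importance_ranking()]; the score is `p - elimination position
#'   + 1`, so later-eliminated (more important) features score higher.
#' @export
rank_by_rfe <- function(X, y, lambda = 1, step = 1L) {
  y <- .binary_y(y)
  y01 <- as.numeric(y) - 1
  remaining <- colnames(X)
  eliminated <- character(0)
  while (length(remaining) > 1) {
    w <- abs(.ridge_weights(X[, remaining, drop = FALSE], y01, lambda))
    ord <- order(w, remaining)
    drop <- remaining[ord[seq_len(min(step, length(remaining) - 1L))]]
    eliminated <- c(eliminated, drop)
    remaining <- setdiff(remaining, drop)
  }
  order_out <- c(eliminated, remaining)     # first eliminated = least important
  p <- length(order_out)
  score <- stats::setNames(seq_len(p), order_out)[colnames(X)]
  importance_ranking("rfe", colnames(X), unname(score))
}

#' Wrapper ranker: ReliefF
#'
#' Multi-neighbor Relief: features are min-max scaled, then for every
#' sample the k nearest hits (same class) and k nearest misses (other
#' class) under Euclidean distance are found; each feature's weight
#' accumulates the mean absolute difference to the misses minus the mean
#' absolute difference to the hits, averaged over samples. Positive weights
#' mark features that separate the classes locally; Relief also rewards
#' interacting feature pairs that are marginally uninformative.
#'
#' @inheritParams rank_by_target_correlation
#' @param k_neighbors Neighbors per class (default 10); capped at the
#'   available class counts.
#' @return An [importance_ranking()] with the ReliefF weights as scores.
#' @export
rank_by_relief <- function(X, y, k_neighbors = 10) {
  y <- .binary_y(y)
  X <- as.matrix(X)
  rng <- apply(X, 2, function(x) diff(range(x)))
  rng[rng == 0] <- Inf              # constant feature -> scaled to 0
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  n <- nrow(Xs)
  d <- as.matrix(stats::dist(Xs))
  w <- numeric(ncol(Xs))
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    upd <- function(idx) {
      if (length(idx) == 0) return(0)
      k <- min(k_neighbors, length(idx))
      nb <- idx[order(d[i, idx], idx)][seq_len(k)]
      colMeans(abs(Xs[nb, , drop = FALSE] -
                     matrix(Xs[i, ], k, ncol(Xs), byrow = TRUE)))
    }
    w <- w + upd(other) - upd(same)
  }
  importance_ranking("relief", colnames(X), w / n)
}

#' Combine filter/wrapper rankings (CWF)
#'
#' Builds the combined ranking of the five filter and wrapper methods:
#' a feature is eligible when it appears in the top-`top_k` of at least
#' `min_methods` of the rankings; its combined score is the mean of its
#' ranks within the top-`top_k` lists of the methods where it appears.
#' Smaller mean rank means more important; ties are broken
#' lexicographically.
#'
#' @param rankings List of exactly 5 [importance_ranking()]s over the same
#'   feature universe.
#' @param top_k Size of each method's head list (default 20).
#' @param min_methods Minimum number of methods a feature must appear in
#'   (default 3).
#' @return An [importance_ranking()] with `method = "CWF"` over the
#'   eligible features; score = mean rank (ascending = more important).
#' @export
cwf_combine <- function(rankings, top_k = 20, min_methods = 3) {
  if (length(rankings) != 5)
    stop("cwf_combine expects exactly 5 rankings, got ", length(rankings))
  tops <- lapply(rankings, top_features, k = top_k)
  univ <- sort(unique(unlist(tops)))
  n_in <- vapply(univ, function(f)
    sum(vapply(tops, function(tl) f %in% tl, logical(1))), integer(1))
  eligible <- univ[n_in >= min_methods]
  if (length(eligible) == 0)
    return(importance_ranking("CWF", character(0), numeric(0),
                              decreasing = FALSE))
  mean_rank <- vapply(eligible, function(f) {
    r <- vapply(tops, function(tl) match(f, tl), numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  importance_ranking("CWF", eligible, unname(mean_rank), decreasing = FALSE)
}

#' Count top features per echocardiographic view
#'
#' @param features Character vector of feature names.
#' @return Named integer vector with counts for `4ch`, `3ch`, `2ch` and
#'   `none` (viewless clinical scalars such as QRS and LVEF).
#' @export
view_census <- function(features) {
  v <- factor(feature_view(features), levels = c(strain_views(), "none"))
  stats::setNames(as.integer(table(v)), levels(v))
}

#' Overlap of two rankings' top-k sets
#'
#' @param a,b [importance_ranking()]s or character vectors of feature names.
#' @param top_k Head size (default 20).
#' @return Integer: size of the intersection of the two top-k name sets.
#' @export
ranking_overlap <- function(a, b, top_k = 20) {
  length(intersect(top_features(a, top_k), top_features(b, top_k)))
}

#' Reference top-20 importance lists from a published 130-patient CRT cohort
#'
#' The 20 most important features reported by the out-of-bag random-forest
#' analysis and by the combined filter/wrapper (CWF) method on a
#' 130-patient multicenter clinical CRT cohort, translated into this
#' package's feature-name grammar. Useful as a structural reference: their
#' view census (12/5/3 across 4ch/2ch/3ch for the OOB list) and mutual
#' top-20 overlap (10 features) characterize the published result.
#'
#' @return Data frame with columns `rank`, `oob`, `cwf`.
#' @export
reference_top20 <- function() {
  path <- system.file("extdata", "reference_top20.csv", package = "strainsel")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
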