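make_labeled_data <- function(n = 100, p = 20, effect = 3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("non-responder", "responder"), length.out = n),
              levels = c("non-responder", "responder"))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  X[, 1] <- X[, 1] + effect * (as.numeric(y) - 1)
  list(X = X, y = y)
}

test_that("rankings are permutations of the feature universe", {
  d <- make_labeled_data(n = 60, p = 12, seed = 4)
  rankers <- list(rank_by_target_correlation, rank_by_welch_t,
                  rank_by_kbest, rank_by_rfe, rank_by_relief)
  for (rk in rankers) {
    r <- rk(d$X, d$y)
    expect_setequal(r$feature, colnames(d$X))
    expect_identical(r$rank, seq_len(ncol(d$X)))
  }
})

test_that("oob_importance recovers a strong feature and normalizes to 1", {
  top1 <- replicate(20, {
    s <- sample.int(1e6, 1)
    d <- make_labeled_data(n = 100, p = 158, effect = 3, seed = s)
    r <- oob_importance(d$X, d$y, rf_config(seed = s))
    expect_equal(max(r$score), 1)
    r$feature[1] == "f01"
  })
  expect_gte(mean(top1), 0.95)
})

test_that("oob_importance on permuted labels shows no spurious recovery", {
  d <- make_labeled_data(n = 100, p = 50, effect = 3, seed = 11)
  set.seed(99)
  null_rank_of_f01 <- replicate(10, {
    yp <- sample(d$y)
    r <- oob_importance(d$X, yp, rf_config(seed = sample.int(1e6, 1)))
    match("f01", r$feature)
  })
  # under label permutation the formerly strong feature is unremarkable
  expect_gt(median(null_rank_of_f01), 5)
  expect_error(oob_importance(d$X, factor(rep("a", 100))), "two classes")
})

test_that("correlation_graph applies the strict threshold and thickness map", {
  set.seed(8)
  n <- 200
  x <- rnorm(n)
  X <- cbind(a = x, b = 2 * x + 3, c = rnorm(n))     # |r(a,b)| = 1
  g <- correlation_graph(X)
  expect_identical(sort(g$nodes), c("a", "b", "c"))
  ab <- g$edges[g$edges$a == "a" & g$edges$b == "b", ]
  expect_equal(ab$abs_r, 1, tolerance = 1e-12)
  expect_equal(ab$thickness, 5, tolerance = 1e-12)

  # |r| = 0.75 gives thickness 2.5: mix an exact copy with orthogonal noise
  # until the sample correlation is moderate, then check the linear map
  set.seed(12)
  u <- rnorm(100); w <- rnorm(100)
  X <- cbind(a = u, b = 0.8 * u + w)
  r_ab <- abs(cor(X)[1, 2])
  g <- correlation_graph(X)
  if (r_ab > 0.5) expect_equal(g$edges$thickness, 10 * r_ab - 5,
                               tolerance = 1e-12)
  # a pair with |r| exactly at the threshold is excluded (strict >)
  x1 <- c(1, 2, 3); x2 <- c(2, 1, 3)           # cor = 0.5 exactly
  expect_identical(cor(x1, x2), 0.5)
  g <- correlation_graph(cbind(a = x1, b = x2), threshold = 0.5)
  expect_identical(nrow(g$edges), 0L)

  # zero-variance feature excluded with a warning
  X <- cbind(a = rnorm(10), z = rep(1, 10))
  expect_warning(g <- correlation_graph(X), "zero-variance")
  expect_false("z" %in% g$nodes)
  expect_error(correlation_graph(matrix(1:4, 2)), "3 samples")
})

test_that("target-correlation ranker behaves at the extremes", {
  set.seed(14)
  n <- 1000
  y <- factor(rep(c("non-responder", "responder"), each = n / 2),
              levels = c("non-responder", "responder"))
  X <- cbind(ind = as.numeric(y) - 1,   # identical to the label indicator
             noise = rnorm(n),
             const = rep(2, n))
  r <- rank_by_target_correlation(X, y)
  expect_identical(r$feature[1], "ind")
  expect_equal(r$score[1], 1, tolerance = 1e-12)
  expect_lt(r$score[r$feature == "noise"], 0.1)
  expect_identical(r$feature[3], "const")
  expect_identical(r$score[3], 0)
})

test_that("welch ranker reproduces closed-form t on constructed moments", {
  # two groups built to exact mean/sd: 67.1 +/- 10.5 (n=83) vs
  # 65.6 +/- 12.3 (n=47); Welch's t from the summary formula
  mk <- function(n, m, s) {
    z <- scale(rnorm(n))[, 1]          # exact mean 0, sd 1
    m + s * z
  }
  set.seed(6)
  g1 <- mk(83, 67.1, 10.5)
  g2 <- mk(47, 65.6, 12.3)
  t_closed <- (67.1 - 65.6) / sqrt(10.5^2 / 83 + 12.3^2 / 47)
  X <- cbind(age = c(g1, g2))
  y <- factor(c(rep("responder", 83), rep("non-responder", 47)),
              levels = c("non-responder", "responder"))
  r <- rank_by_welch_t(X, y)
  expect_equal(r$score[1], abs(t_closed), tolerance = 1e-9)
  # the difference is not significant, consistent with the cohort report
  expect_gt(2 * pt(-abs(t_closed), df = 100), 0.05)

  # strong separation: N(0,1) vs N(3,1) with n = 50/50 gives |t| >> 8
  d <- make_labeled_data(n = 100, p = 3, effect = 3, seed = 2)
  r <- rank_by_welch_t(d$X, d$y)
  expect_identical(r$feature[1], "f01")
  expect_gt(r$score[1], 8)
})

test_that("kbest F equals squared pooled t and agrees on ordering", {
  d <- make_labeled_data(n = 80, p = 6, effect = 2, seed = 9)
  rF <- rank_by_kbest(d$X, d$y)
  t_pooled <- apply(d$X, 2, function(x)
    unname(t.test(x ~ d$y, var.equal = TRUE)$statistic))
  f_expected <- t_pooled^2
  expect_equal(rF$score[match(names(f_expected), rF$feature)],
               unname(f_expected), tolerance = 1e-9)
  expect_identical(rF$feature[1], "f01")

  Xc <- cbind(d$X, const = rep(1, nrow(d$X)))
  rF <- rank_by_kbest(Xc, d$y)
  expect_identical(rF$feature[nrow(rF)], "const")
  expect_identical(rF$score[nrow(rF)], 0)
})

test_that("rfe keeps a separating feature to the last round", {
  ok <- replicate(20, {
    s <- sample.int(1e6, 1)
    d <- make_labeled_data(n = 60, p = 25, effect = 4, seed = s)
    rank_by_rfe(d$X, d$y)$feature[1] == "f01"
  })
  expect_gte(mean(ok), 0.95)

  # duplicated feature pair: deterministic lexicographic tie-break
  set.seed(3)
  x <- rnorm(40)
  X <- cbind(dupA = x, dupB = x, other = rnorm(40))
  y <- factor(rep(c("a", "b"), 20))
  r1 <- rank_by_rfe(X, y)
  r2 <- rank_by_rfe(X, y)
  expect_identical(r1, r2)
  expect_gt(match("dupB", r1$feature), match("dupA", r1$feature) - 3)

  # single feature: trivial ranking of length 1
  r <- rank_by_rfe(X[, "dupA", drop = FALSE], y)
  expect_identical(nrow(r), 1L)
})

test_that("relief matches the hand-traced two-sample update", {
  X <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "f"))
  y <- factor(c("A", "B"))
  r <- rank_by_relief(X, y, k_neighbors = 1)
  expect_equal(r$score, 1)
})

test_that("relief matches a naive neighbor scan on small instances", {
  set.seed(17)
  for (i in 1:6) {
    n <- sample(10:30, 1); p <- sample(2:5, 1); k <- sample(1:5, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("v%d", 1:p)))
    y <- factor(sample(c("a", "b"), n, replace = TRUE,
                       prob = c(0.5, 0.5)))
    if (nlevels(droplevels(y)) < 2) next
    r <- rank_by_relief(X, y, k_neighbors = k)
    w <- relief_naive(X, y, k)
    expect_equal(r$score[match(colnames(X), r$feature)], unname(w),
                 tolerance = 1e-12)
  }
})

test_that("relief scores label-independent features near zero and detects XOR", {
  set.seed(23)
  n <- 500
  y <- factor(sample(c("a", "b"), n, replace = TRUE))
  X <- cbind(noise = rnorm(n), n2 = rnorm(n))
  r <- rank_by_relief(X, y, k_neighbors = 10)
  expect_lt(max(abs(r$score)), 0.05)

  # parity pair: marginally uninformative, jointly decisive
  n <- 400
  x1 <- sample(0:1, n, TRUE); x2 <- sample(0:1, n, TRUE)
  y <- factor(ifelse(xor(x1, x2), "a", "b"))
  X <- cbind(x1 = x1 + rnorm(n, 0, 0.05), x2 = x2 + rnorm(n, 0, 0.05),
             m1 = rnorm(n), m2 = rnorm(n), m3 = rnorm(n))
  r <- rank_by_relief(X, y, k_neighbors = 10)
  expect_setequal(r$feature[1:2], c("x1", "x2"))
})

test_that("cwf_combine implements the membership-and-mean-rank rule", {
  universe <- sprintf("g%02d", 1:40)
  mk_rank <- function(order_head) {
    rest <- setdiff(universe, order_head)
    importance_ranking("m", c(order_head, rest),
                       seq(length(universe), 1))
  }
  # target feature at ranks 1, 3, 5 in three methods, absent from two
  r1 <- mk_rank(c("g01", "g02", "g03"))
  r2 <- mk_rank(c("g02", "g04", "g01"))
  r3 <- mk_rank(c("g03", "g04", "g05", "g06", "g01"))
  r4 <- mk_rank(setdiff(universe, c("g01", "g02"))[1:20])
  r5 <- mk_rank(setdiff(universe, c("g01", "g02"))[18:37])
  cwf <- cwf_combine(list(r1, r2, r3, r4, r5))
  expect_equal(cwf$score[cwf$feature == "g01"], 3)

  # with top_k = 3, g02 sits in only two head lists and is excluded,
  # while g01 (three head lists) stays eligible
  cwf3 <- cwf_combine(list(r1, r2, r3, r4, r5), top_k = 3)
  expect_false("g02" %in% cwf3$feature)
  expect_false("g01" %in% cwf3$feature)  # ranks 1, 3, 5: only two within 3
  r3c <- mk_rank(c("g01", "g04", "g05"))
  cwf3 <- cwf_combine(list(r1, r2, r3c, r4, r5), top_k = 3)
  expect_true("g01" %in% cwf3$feature)
  expect_equal(cwf3$score[cwf3$feature == "g01"], mean(c(1, 3, 1)))

  # five identical rankings: CWF top-20 equals that ranking's top-20
  r <- mk_rank(universe[1:20])
  cwf <- cwf_combine(list(r, r, r, r, r))
  expect_identical(top_features(cwf, 20), top_features(r, 20))

  expect_error(cwf_combine(list(r, r, r)), "exactly 5")
})

test_that("cwf_combine agrees with the brute-force oracle", {
  set.seed(31)
  universe <- sprintf("h%02d", 1:30)
  for (i in 1:100) {
    rks <- lapply(1:5, function(j) random_ranking(universe))
    got <- cwf_combine(rks, top_k = 10, min_methods = 3)
    want <- cwf_naive(rks, top_k = 10, min_methods = 3)
    expect_identical(got$feature, want$feature)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("view_census and ranking_overlap read the name grammar", {
  expect_identical(view_census(character(0)),
                   c("4ch" = 0L, "3ch" = 0L, "2ch" = 0L, none = 0L))
  expect_identical(view_census(c("QRS", "LVEF")),
                   c("4ch" = 0L, "3ch" = 0L, "2ch" = 0L, none = 2L))
  expect_identical(view_census(c("E_4ch_BS", "Tavc_2ch", "dP_3ch", "QRS")),
                   c("4ch" = 1L, "3ch" = 1L, "2ch" = 1L, none = 1L))

  a <- sprintf("x%d", 1:25)
  expect_identical(ranking_overlap(a, a), 20L)
  expect_identical(ranking_overlap(a[1:20], sprintf("y%d", 1:20)), 0L)
})

test_that("feature_matrix imputes missing values with column medians", {
  tab <- data.frame(patient_id = c("a", "b", "c"),
                    response = c("responder", "non-responder", "responder"),
                    f1 = c(1, NA, 3), f2 = c(2, 2, 2))
  expect_message(fm <- feature_matrix(tab), "imputing 1 missing")
  expect_equal(unname(fm$X[2, "f1"]), 2)
  expect_identical(levels(fm$y), c("non-responder", "responder"))
})
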