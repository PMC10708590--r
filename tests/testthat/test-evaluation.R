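brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf; best_cols <- NULL
  for (p in perms(seq_len(m))) {
    cols <- p[seq_len(n)]
    tot <- sum(cost[cbind(seq_len(n), cols)])
    if (tot < best) { best <- tot; best_cols <- cols }
  }
  list(cost = best, cols = best_cols)
}

test_that("Hungarian solver matches brute-force enumeration", {
  set.seed(4)
  for (i in 1:30) {
    n <- sample(1:5, 1); m <- n + sample(0:2, 1)
    cost <- matrix(round(runif(n * m, 0, 10), 2), n, m)
    got <- mrncl:::hungarian_solve(cost)
    want <- brute_force_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), want$cost)
    expect_equal(length(unique(got)), n)  # one-to-one
  }
})

test_that("Hungarian accuracy reproduces the worked examples", {
  expect_equal(hungarian_accuracy(c(0, 0, 1, 1), c("B", "B", "A", "A"))$acc, 1)
  expect_equal(hungarian_accuracy(c(0, 0, 1), c("A", "B", "B"))$acc, 2 / 3)
  expect_equal(hungarian_accuracy(rep(0, 10),
                                  rep(c("A", "B"), 5))$acc, 0.5)
})

test_that("accuracy is invariant under relabeling of clusters and classes", {
  set.seed(8)
  for (i in 1:10) {
    n <- 40
    pred <- sample(1:4, n, TRUE)
    truth <- sample(letters[1:4], n, TRUE)
    base <- hungarian_accuracy(pred, truth)$acc
    pp <- c(9, 7, 5, 3)[pred]
    tt <- LETTERS[4:1][match(truth, letters[1:4])]
    expect_equal(hungarian_accuracy(pp, tt)$acc, base)
  }
})

test_that("rectangular case: surplus clusters count as errors", {
  # 4 clusters, 2 classes: at most 2 clusters can be matched
  pred <- c(1, 1, 2, 2, 3, 3, 4, 4)
  truth <- c("A", "A", "B", "B", "A", "A", "B", "B")
  expect_equal(hungarian_accuracy(pred, truth)$acc, 0.5)
  mp <- hungarian_accuracy(pred, truth)$mapping
  expect_equal(sum(is.na(mp)), 2)
})

test_that("pairwise F-score reproduces the worked examples", {
  r <- pairwise_f(c(1, 2, 3, 4), c("A", "B", "C", "D"))
  expect_equal(c(r$f, r$fp, r$fr), c(1, 1, 1))
  r <- pairwise_f(c(1, 1, 2, 2), c("A", "A", "B", "B"))
  expect_equal(c(r$f, r$fp, r$fr), c(1, 1, 1))
  r <- pairwise_f(c(1, 1, 1, 2), c("A", "A", "B", "B"))
  expect_equal(r$fp, 1 / 3)
  expect_equal(r$fr, 1 / 2)
  expect_equal(r$f, 0.4)
  r <- pairwise_f(c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(r$fp, 1 / 3)
  expect_equal(r$fr, 1)
  expect_equal(r$f, 0.5)
})

test_that("pairwise F-score is invariant under cluster relabeling and matches
           a direct pair enumeration", {
  set.seed(12)
  for (i in 1:10) {
    n <- 25
    pred <- sample(1:3, n, TRUE)
    truth <- sample(c("x", "y", "z"), n, TRUE)
    r <- pairwise_f(pred, truth)
    expect_equal(unlist(pairwise_f(c(7, 5, 3)[pred], truth)), unlist(r))
    # direct enumeration oracle
    tp <- fpp <- fn <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      sc <- pred[a] == pred[b]; st <- truth[a] == truth[b]
      tp <- tp + (sc && st); fpp <- fpp + (sc && !st); fn <- fn + (!sc && st)
    }
    expect_equal(r$fp, if (tp + fpp > 0) tp / (tp + fpp) else 1)
    expect_equal(r$fr, if (tp + fn > 0) tp / (tp + fn) else 1)
  }
})

test_that("evaluate_clustering combines ACC and F consistently", {
  set.seed(2)
  pred <- sample(1:3, 30, TRUE); truth <- sample(letters[1:3], 30, TRUE)
  rep <- evaluate_clustering(pred, truth)
  expect_equal(rep$acc, hungarian_accuracy(pred, truth)$acc)
  expect_equal(rep$f, 2 * rep$fp * rep$fr / (rep$fp + rep$fr))
  tf <- tempfile()
  write_cluster_report(rep, tf)
  tab <- read.delim(tf)
  expect_equal(tab$value[tab$metric == "acc"], rep$acc)
})

test_that("hungarian accuracy is at least the greedy-mapping lower bound", {
  set.seed(31)
  for (i in 1:10) {
    n <- 30
    pred <- sample(1:3, n, TRUE); truth <- sample(1:3, n, TRUE)
    tab <- table(pred, truth)
    greedy <- sum(apply(tab, 1, max)) / n  # allows many-to-one, >= bijective
    acc <- hungarian_accuracy(pred, truth)$acc
    expect_true(acc <= greedy + 1e-12)
    # identity is one bijective mapping, so it lower-bounds the optimum
    expect_true(acc >= mean(pred == truth) - 1e-12)
  }
})

test_that("knn purity matches hand counts on constructed banks", {
  q <- rbind(c(1, 0), c(0, 1))
  bank <- rbind(c(1, 0.01), c(1, -0.01), c(0.01, 1), c(-1, 0))
  blab <- c("a", "a", "b", "c")
  expect_equal(knn_purity(q, c("a", "b"), bank, blab, 2), 0.75)
  expect_equal(knn_purity(q, c("a", "b"), bank, blab, 2, "cosine"), 0.75)
  # all-same and none-same banks
  expect_equal(knn_purity(q, c("a", "a"), bank[1:2, ], c("a", "a"), 2), 1)
  expect_equal(knn_purity(q, c("z", "z"), bank, blab, 3), 0)
})
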