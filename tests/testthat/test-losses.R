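test_that("cross-entropy worked examples", {
  # near-one-hot prediction
  expect_lt(ce_loss(matrix(c(50, 0, 0), 1), 1), 1e-10)
  # uniform logits over C classes -> ln C
  expect_equal(ce_loss(matrix(0, 1, 3), 1), log(3))
  expect_equal(ce_loss(matrix(1, 2, 5), c(2, 4)), log(5))
  # hand example: logits (2,0,0), true class 1
  expect_equal(ce_loss(matrix(c(2, 0, 0), 1), 1), log(1 + 2 * exp(-2)),
               tolerance = 1e-12)
  expect_error(ce_loss(matrix(0, 1, 3), 4), "outside")
})

test_that("pairwise pseudo-labels threshold inclusively at lambda", {
  mk <- function(cos_val) {
    # two unit vectors at a chosen cosine
    rbind(c(1, 0), c(cos_val, sqrt(1 - cos_val^2)))
  }
  expect_equal(pairwise_pseudo_labels(mk(0.96), 0.95)[1, 2], 1)
  expect_equal(pairwise_pseudo_labels(mk(0.94), 0.95)[1, 2], 0)
  # boundary is inclusive: cosine exactly equal to lambda assigns 1
  zb <- rbind(c(1, 0), c(1, sqrt(3)))   # cosine exactly 1/2
  expect_equal(pairwise_pseudo_labels(zb, 0.5)[1, 2], 1)
  y <- pairwise_pseudo_labels(matrix(rnorm(12), 4), 0.9)
  expect_true(isSymmetric(y))
})

test_that("pairwise BCE worked examples and hand enumeration", {
  # single pair with yhat = 1 and p ~ 1: loss ~ 0
  p1 <- rbind(c(1 - 1e-9, 1e-9), c(1 - 1e-9, 1e-9))
  expect_lt(bce_loss(p1, matrix(1, 2, 2)), 1e-5)
  # p = 0.5 on one pair
  ph <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(bce_loss(ph, matrix(1, 2, 2)), log(2), tolerance = 1e-6)
  # 3-sample hand enumeration
  probs <- rbind(c(0.7, 0.3), c(0.6, 0.4), c(0.1, 0.9))
  yhat <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
  p12 <- 0.7 * 0.6 + 0.3 * 0.4
  p13 <- 0.7 * 0.1 + 0.3 * 0.9
  p23 <- 0.6 * 0.1 + 0.4 * 0.9
  hand <- -(log(p12) + log(1 - p13) + log(1 - p23)) / 3
  expect_equal(bce_loss(probs, yhat), hand, tolerance = 1e-12)
})

test_that("instance contrastive loss degenerate and oracle cases", {
  q <- c(1, 0); a <- c(1, 0)
  # one bank entry with the same similarity as the augmented view
  expect_equal(instance_contrastive_loss(q, a, rbind(c(1, 0)), tau = 0.1),
               log(2), tolerance = 1e-12)
  # perfectly aligned positive, antipodal negatives, small tau -> ~0
  expect_lt(instance_contrastive_loss(q, a, rbind(c(-1, 0), c(-1, 0)),
                                      tau = 0.02), 1e-10)
  expect_error(instance_contrastive_loss(q, a, matrix(numeric(0), 0, 2)),
               "non-empty")
  set.seed(0)
  for (i in 1:5) {
    q <- rnorm(5); a <- rnorm(5); bank <- matrix(rnorm(15), 3)
    expect_equal(instance_contrastive_loss(q, a, bank, 0.05),
                 oracle_contrastive(q, a, bank, integer(0), TRUE, 0.05),
                 tolerance = 1e-10)
  }
})

test_that("neighborhood contrastive loss: degenerate, oracle and positivity", {
  q <- c(0, 1); a <- c(0, 1)
  expect_equal(ncl_loss(q, a, rbind(c(0, 1)), k = 1, tau = 0.05), log(2),
               tolerance = 1e-12)
  set.seed(0)
  for (i in 1:5) {
    q <- rnorm(6); a <- rnorm(6); bank <- matrix(rnorm(60), 10)
    want_idx <- oracle_knn(q, bank, 3, "combined")
    expect_equal(ncl_loss(q, a, bank, 3, 0.05),
                 oracle_contrastive(q, a, bank, want_idx, FALSE, 0.05),
                 tolerance = 1e-10)
    expect_gt(ncl_loss(q, a, bank, 3, 0.05), 0)
    # cosine-selection variant against its own oracle
    want_cos <- oracle_knn(q, bank, 3, "cosine")
    expect_equal(ncl_loss(q, a, bank, 3, 0.05, metric = "cosine"),
                 oracle_contrastive(q, a, bank, want_cos, FALSE, 0.05),
                 tolerance = 1e-10)
  }
})

test_that("ncl and cosine-metric ncl agree when the rankings agree", {
  # construct a bank where both metrics produce the same ordering:
  # unit vectors at increasing angle from the query
  q <- c(1, 0); a <- c(1, 0)
  ang <- c(0.1, 0.5, 0.9, 1.3, 1.7)
  bank <- cbind(cos(ang), sin(ang))
  expect_identical(select_knn(q, bank, 3, "combined"),
                   select_knn(q, bank, 3, "cosine"))
  expect_equal(ncl_loss(q, a, bank, 3, 0.05, "combined"),
               ncl_loss(q, a, bank, 3, 0.05, "cosine"))
})

test_that("raising a selected neighbor's similarity lowers the loss when its
           softmax share is below 1/k", {
  # geometric construction: neighbors on the unit circle, one angle moves
  q <- c(1, 0); a <- c(0.8, 0.6)
  base_ang <- c(0.2, 0.3, 1.0, 2.0, 2.5)
  loss_at <- function(delta) {
    ang <- base_ang; ang[3] <- ang[3] - delta  # raise neighbor 3's cosine
    bank <- cbind(cos(ang), sin(ang))
    ncl_loss(q, a, bank, k = 3, tau = 0.5)
  }
  l0 <- loss_at(0)
  for (d in c(0.05, 0.1, 0.2)) expect_lt(loss_at(d), l0)
})

test_that("warm-up: undersized bank contributes zero with a log message", {
  q <- matrix(rnorm(4), 1); a <- matrix(rnorm(4), 1)
  expect_message(v <- ncl_loss(q, a, matrix(rnorm(8), 2), k = 5), "warm-up")
  expect_equal(v, 0)
})

test_that("supervised contrastive loss degenerate and oracle cases", {
  q <- c(1, 1); a <- c(1, 1)
  empty <- feature_queue(10, 2, labeled = TRUE)
  expect_equal(scl_loss(q, a, 1, empty, 0.05), 0)
  one <- queue_push(empty, matrix(c(1, 1), 1), labels = 1)
  expect_equal(scl_loss(q, a, 1, one, 0.05), log(2), tolerance = 1e-12)
  # 6-entry labeled bank, 2 same-label: direct transcription oracle
  set.seed(0)
  bank <- matrix(rnorm(36), 6)
  labs <- c(1, 2, 1, 3, 2, 2)
  bq <- queue_push(feature_queue(10, 6, labeled = TRUE), bank, labs)
  q <- rnorm(6); a <- rnorm(6)
  expect_equal(scl_loss(q, a, 1, bq, 0.05),
               oracle_contrastive(q, a, bank, c(1, 3), TRUE, 0.05),
               tolerance = 1e-10)
  expect_error(scl_loss(q, a, 1, feature_queue(5, 6), 0.05), "labeled")
})

test_that("consistency loss follows the mean-squared-difference contract", {
  ol <- matrix(rnorm(6), 2); ou <- matrix(rnorm(8), 2)
  expect_equal(consistency_loss(ol, ol, ou, ou), 0)
  d <- 0.3
  expect_equal(consistency_loss(ol, ol + d, ou, ou), d^2)
  expect_equal(consistency_loss(ol, ol + d, ou, ou - d), 2 * d^2)
  set.seed(1)
  o2 <- matrix(rnorm(6), 2); u2 <- matrix(rnorm(8), 2)
  expect_equal(consistency_loss(ol, o2, ou, u2),
               mean((ol - o2)^2) + mean((ou - u2)^2))
  expect_error(consistency_loss(ol, ol[1, , drop = FALSE], ou, ou), "shape")
})

test_that("overall loss applies the epoch schedule and ablation flags", {
  cfg <- loss_config()
  parts <- list(ce = 1, bce = 2, scl = 3, ncl = 4, cs = 5, ap = 6)
  r1 <- overall_loss(parts, cfg, epoch = 1)
  expect_equal(r1$total, 3)
  expect_false(r1$contrastive_active)
  r2 <- overall_loss(parts, cfg, epoch = 2)
  expect_equal(r2$total, 10)
  expect_false(r2$cs_active)
  expect_false(r2$ap_active)
  all_on <- loss_config(use_cs = TRUE, use_ap = TRUE)
  expect_equal(overall_loss(parts, all_on, 5)$total, 21)
  expect_equal(overall_loss(list(ce = 1, bce = 2, scl = 3, ncl = 4),
                            all_on, 5)$total, 10)
})

test_that("the pseudo-positive count rule floors correctly", {
  expect_equal(pseudo_positive_count(200, 3), 33)
  expect_equal(pseudo_positive_count(500, 6), 41)
  expect_equal(pseudo_positive_count(4, 6), 1)
})

test_that("batch losses are permutation invariant", {
  set.seed(2)
  n <- 6; H <- 5
  Q <- matrix(rnorm(n * H), n); A <- matrix(rnorm(n * H), n)
  bank <- matrix(rnorm(40), 8)
  perm <- sample(n)
  expect_equal(ncl_loss(Q, A, bank, 3, 0.05),
               ncl_loss(Q[perm, ], A[perm, ], bank, 3, 0.05),
               tolerance = 1e-12)
  logits <- matrix(rnorm(n * 3), n); labs <- sample(1:3, n, TRUE)
  expect_equal(ce_loss(logits, labs), ce_loss(logits[perm, ], labs[perm]))
  probs <- mrncl:::softmax_rows(logits)
  yh <- pairwise_pseudo_labels(Q, 0.5)
  expect_equal(bce_loss(probs, yh),
               bce_loss(probs[perm, ], yh[perm, perm]), tolerance = 1e-12)
})
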