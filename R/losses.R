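#' Loss configuration
#'
#' Collects the knobs of the training objective. Defaults follow the
#' framework's reference settings: pseudo-label threshold
#' \eqn{\lambda = 0.95}, contrastive temperature \eqn{\tau = 0.05},
#' contrastive losses introduced at epoch 2, neighbor selection by the
#' combined similarity, and both ablation terms (consistency loss,
#' augmented-positive contrastive loss) off.
#'
#' @param lambda cosine threshold for pairwise pseudo-labels, in (0, 1].
#' @param tau contrastive temperature, > 0.
#' @param metric neighbor-selection metric: `"combined"` or `"cosine"`.
#' @param k pseudo-positive count; `NULL` applies the rule
#'   `floor(bank_capacity / n_novel / 2)` at training time.
#' @param start_epoch first epoch at which the contrastive losses are
#'   active.
#' @param use_cs include the consistency (view-agreement) loss.
#' @param use_ap include the augmented-positive instance contrastive loss.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(lambda = 0.95, tau = 0.05,
                        metric = c("combined", "cosine"), k = NULL,
                        start_epoch = 2L, use_cs = FALSE, use_ap = FALSE) {
  metric <- match.arg(metric)
  stopifnot(lambda > 0, lambda <= 1, tau > 0, start_epoch >= 1,
            is.null(k) || k >= 1)
  structure(list(lambda = lambda, tau = tau, metric = metric, k = k,
                 start_epoch = as.integer(start_epoch),
                 use_cs = isTRUE(use_cs), use_ap = isTRUE(use_ap)),
            class = "loss_config")
}

#' Default pseudo-positive count rule
#'
#' `K = floor(|M_u| / C_u / 2)`: half the expected per-class share of the
#' unlabeled memory bank (floored to stay integral, never below 1).
#'
#' @param bank_capacity unlabeled bank capacity |M_u|.
#' @param n_novel number of novel classes C_u.
#' @return integer K.
#' @export
pseudo_positive_count <- function(bank_capacity, n_novel) {
  max(1L, as.integer(floor(bank_capacity / n_novel / 2)))
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

#' Cross-entropy loss on the labeled head
#'
#' Mean over the batch of the negative log softmax probability of the true
#' class.
#'
#' @param logits_l batch x C_l logits of the labeled head.
#' @param labels integer class labels in 1..C_l.
#' @return scalar loss.
#' @export
ce_loss <- function(logits_l, labels) {
  ce_loss_grad(logits_l, labels)$loss
}

ce_loss_grad <- function(logits_l, labels) {
  if (is.null(dim(logits_l))) logits_l <- matrix(logits_l, nrow = 1)
  n <- nrow(logits_l)
  stopifnot(length(labels) == n)
  if (any(labels < 1 | labels > ncol(logits_l)))
    stop("label outside the known class set")
  p <- softmax_rows(logits_l)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  d <- p
  d[idx] <- d[idx] - 1
  list(loss = loss, dlogits = d / n)
}

#' Pairwise pseudo-labels from feature similarity
#'
#' Two unlabeled windows are pseudo-labeled as the same latent class when
#' the cosine similarity of their extractor features reaches the threshold
#' `lambda` (inclusive).
#'
#' @param z batch x H feature matrix.
#' @param lambda threshold in (0, 1].
#' @return symmetric binary matrix; the diagonal is 1 by construction and
#'   is excluded from downstream pair averaging.
#' @export
pairwise_pseudo_labels <- function(z, lambda = 0.95) {
  stopifnot(is.matrix(z))
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) stop("zero feature vector: pseudo-labels undefined")
  cosm <- (z %*% t(z)) / (nrm %o% nrm)
  (cosm >= lambda) * 1
}

#' Pairwise binary cross-entropy on the unlabeled head
#'
#' For every distinct pair of unlabeled windows the inner product of their
#' unlabeled-head probability rows is compared to the pairwise
#' pseudo-label with binary cross-entropy; the loss is the mean over pairs.
#' Inner products are clamped to `[eps, 1 - eps]` so the logs stay finite.
#'
#' @param probs_u batch x C_u rows on the probability simplex (softmax of
#'   the unlabeled head).
#' @param yhat binary pseudo-label matrix from
#'   [pairwise_pseudo_labels()].
#' @param eps clamping constant.
#' @return scalar loss.
#' @export
bce_loss <- function(probs_u, yhat, eps = 1e-7) {
  bce_loss_grad_probs(probs_u, yhat, eps)$loss
}

bce_loss_grad_probs <- function(probs_u, yhat, eps = 1e-7) {
  n <- nrow(probs_u)
  stopifnot(n >= 2, all(dim(yhat) == c(n, n)))
  P <- probs_u %*% t(probs_u)
  if (!all(is.finite(P))) stop("non-finite pair probabilities")
  Pc <- pmin(pmax(P, eps), 1 - eps)
  ut <- upper.tri(P)
  npairs <- sum(ut)
  loss <- -sum((yhat[ut] * log(Pc[ut]) + (1 - yhat[ut]) * log(1 - Pc[ut]))) / npairs
  # gradient wrt probability rows; clamped pairs pass no gradient
  G <- matrix(0, n, n)
  live <- P > eps & P < 1 - eps
  G[live] <- -(yhat[live] / Pc[live] - (1 - yhat[live]) / (1 - Pc[live])) / npairs
  diag(G) <- 0
  list(loss = loss, dprobs = G %*% probs_u)
}

## gradient of row-wise softmax: given dL/dprobs, return dL/dlogits
softmax_backprop <- function(probs, dprobs) {
  probs * (dprobs - rowSums(dprobs * probs))
}

## Shared machinery for the contrastive losses.
## Q, A: n x H query and augmented-view embeddings; bank: m x H (may have
## zero rows); pos: list of n integer vectors of bank indices;
## include_a: logical n-vector, whether the augmented view belongs to the
## positive set. delta is cosine similarity; each positive contributes
## -log( e^{delta(q,p)/tau} / (e^{delta(q,a)/tau} + sum_m e^{delta(q,b_m)/tau}) ),
## averaged within the positive set and then over the batch.
contrastive_batch <- function(Q, A, bank, pos, include_a, tau,
                              want_grad = FALSE) {
  n <- nrow(Q); m <- nrow(bank)
  qn <- sqrt(rowSums(Q^2)); an <- sqrt(rowSums(A^2))
  if (any(qn == 0) || any(an == 0)) stop("zero embedding in contrastive loss")
  s_a <- rowSums(Q * A) / (qn * an)
  if (m > 0) {
    bn <- sqrt(rowSums(bank^2))
    if (any(bn == 0)) stop("zero embedding in memory bank")
    S <- (Q %*% t(bank)) / (qn %o% bn)
    E <- exp(S / tau)
  } else {
    S <- matrix(0, n, 0); E <- matrix(0, n, 0)
  }
  e_a <- exp(s_a / tau)
  D <- e_a + if (m > 0) rowSums(E) else 0
  ksize <- vapply(seq_len(n), function(i) length(pos[[i]]) + include_a[i],
                  numeric(1))
  if (any(ksize == 0)) stop("empty positive set")
  pos_sum <- vapply(seq_len(n), function(i) sum(S[i, pos[[i]]]), numeric(1))
  loss_i <- log(D) - (pos_sum + ifelse(include_a, s_a, 0)) / (tau * ksize)
  loss <- mean(loss_i)
  if (!want_grad) return(list(loss = loss))
  # weights on each similarity: dL/dS and dL/ds_a (before the 1/n batch mean)
  W <- E / (D * tau)
  for (i in seq_len(n)) W[i, pos[[i]]] <- W[i, pos[[i]]] - 1 / (ksize[i] * tau)
  w_a <- e_a / (D * tau) - ifelse(include_a, 1 / (ksize * tau), 0)
  # chain through cosine: dcos(q,x)/dq = x/(|q||x|) - cos * q/|q|^2
  dQ <- matrix(0, n, ncol(Q))
  if (m > 0) {
    dQ <- sweep(W, 2, bn, "/") %*% bank / qn - Q * (rowSums(W * S) / qn^2)
  }
  dQ <- dQ + A * (w_a / (qn * an)) - Q * (w_a * s_a / qn^2)
  dA <- Q * (w_a / (qn * an)) - A * (w_a * s_a / an^2)
  list(loss = loss, dQ = dQ / n, dA = dA / n)
}

as_bank_matrix <- function(bank) {
  if (inherits(bank, "feature_queue")) queue_matrix(bank) else
    if (is.null(dim(bank))) matrix(bank, nrow = 1) else bank
}

as_row_matrix <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else x

#' Neighborhood contrastive loss
#'
#' For each unlabeled query, the `k` most similar memory-bank entries under
#' `metric` form its pseudo-positive set; each is pulled toward the query
#' against a denominator containing the augmented view and every bank
#' entry. The similarity inside the loss is cosine, regardless of the
#' selection metric — the composite measure only decides *which* neighbors
#' are positives. Strictly positive whenever defined, since each numerator
#' term also appears in the denominator.
#'
#' @param z query embeddings (vector or batch rows).
#' @param zhat matching augmented-view embeddings.
#' @param bank unlabeled memory bank ([feature_queue()] or matrix).
#' @param k pseudo-positive count.
#' @param tau temperature.
#' @param metric selection metric, `"combined"` (default) or `"cosine"`.
#' @return mean loss over the batch; 0 (with a message) while the bank
#'   holds fewer than `k` entries (warm-up).
#' @export
ncl_loss <- function(z, zhat, bank, k, tau = 0.05,
                     metric = c("combined", "cosine")) {
  metric <- match.arg(metric)
  ncl_loss_grad(z, zhat, bank, k, tau, metric, want_grad = FALSE)$loss
}

ncl_loss_grad <- function(z, zhat, bank, k, tau, metric, want_grad = TRUE,
                          select_z = NULL) {
  Q <- as_row_matrix(z); A <- as_row_matrix(zhat)
  Qsel <- if (is.null(select_z)) Q else as_row_matrix(select_z)
  mat <- as_bank_matrix(bank)
  stopifnot(k >= 1)
  if (nrow(mat) < k) {
    message(sprintf("ncl_loss: bank occupancy %d < k = %d; warm-up skip",
                    nrow(mat), k))
    return(list(loss = 0, dQ = 0 * Q, dA = 0 * A, skipped = TRUE))
  }
  pos <- lapply(seq_len(nrow(Q)), function(i) select_knn(Qsel[i, ], mat, k, metric))
  out <- contrastive_batch(Q, A, mat, pos, rep(FALSE, nrow(Q)), tau,
                           want_grad = want_grad)
  out$skipped <- FALSE
  out$neighbors <- pos
  out
}

#' Supervised contrastive loss on labeled data
#'
#' The positive set of a labeled query is every bank entry carrying the
#' same class label plus the query's augmented view; negatives are all
#' bank entries. With an empty bank the positive set is just the augmented
#' view and the loss is exactly 0.
#'
#' @param z labeled query embeddings (vector or batch rows).
#' @param zhat matching augmented-view embeddings.
#' @param labels class label per query.
#' @param bank labeled memory bank ([feature_queue()]).
#' @param tau temperature.
#' @return mean loss over the batch.
#' @export
scl_loss <- function(z, zhat, labels, bank, tau = 0.05) {
  scl_loss_grad(z, zhat, labels, bank, tau, want_grad = FALSE)$loss
}

scl_loss_grad <- function(z, zhat, labels, bank, tau, want_grad = TRUE) {
  Q <- as_row_matrix(z); A <- as_row_matrix(zhat)
  stopifnot(length(labels) == nrow(Q))
  if (inherits(bank, "feature_queue") && !bank$labeled)
    stop("scl_loss requires a labeled bank")
  mat <- as_bank_matrix(bank)
  blab <- if (inherits(bank, "feature_queue")) bank$labels else
    attr(bank, "labels")
  pos <- lapply(seq_len(nrow(Q)), function(i) {
    if (nrow(mat) == 0) integer(0) else which(blab == labels[i])
  })
  contrastive_batch(Q, A, mat, pos, rep(TRUE, nrow(Q)), tau,
                    want_grad = want_grad)
}

#' Instance contrastive loss on augmented positives
#'
#' The classical single-positive contrastive loss: the only positive of a
#' query is its augmented view, all bank entries are negatives. Kept as an
#' ablation component (`use_ap`); the default framework omits it.
#'
#' @inheritParams ncl_loss
#' @return mean loss over the batch.
#' @export
instance_contrastive_loss <- function(z, zhat, bank, tau = 0.05) {
  instance_contrastive_grad(z, zhat, bank, tau, want_grad = FALSE)$loss
}

instance_contrastive_grad <- function(z, zhat, bank, tau, want_grad = TRUE) {
  Q <- as_row_matrix(z); A <- as_row_matrix(zhat)
  mat <- as_bank_matrix(bank)
  if (nrow(mat) == 0) stop("instance contrastive loss requires a non-empty bank")
  pos <- rep(list(integer(0)), nrow(Q))
  contrastive_batch(Q, A, mat, pos, rep(TRUE, nrow(Q)), tau,
                    want_grad = want_grad)
}

#' Consistency loss between two augmented views (ablation)
#'
#' Mean squared difference between the head outputs of the two views,
#' labeled and unlabeled terms summed. Kept as an ablation component
#' (`use_cs`); the default framework omits it.
#'
#' @param out_l,out_l_hat labeled-head outputs of the two views.
#' @param out_u,out_u_hat unlabeled-head outputs of the two views.
#' @return scalar loss.
#' @export
consistency_loss <- function(out_l, out_l_hat, out_u, out_u_hat) {
  if (!all(dim(as_row_matrix(out_l)) == dim(as_row_matrix(out_l_hat))) ||
      !all(dim(as_row_matrix(out_u)) == dim(as_row_matrix(out_u_hat))))
    stop("consistency loss: view shapes differ")
  mean((out_l - out_l_hat)^2) + mean((out_u - out_u_hat)^2)
}

#' Assemble the overall training loss
#'
#' Before `start_epoch` the objective is the baseline `ce + bce`; from
#' `start_epoch` on, the supervised and neighborhood contrastive losses
#' join the sum, plus the consistency and augmented-positive terms if their
#' ablation flags are set. All components are reported either way.
#'
#' @param parts named list/vector with elements `ce`, `bce`, `scl`, `ncl`
#'   and optionally `cs`, `ap`.
#' @param config a [loss_config()].
#' @param epoch current epoch (1-based).
#' @return object of class `loss_report`: the components, the active
#'   flags, and `total`.
#' @export
overall_loss <- function(parts, config, epoch) {
  stopifnot(inherits(config, "loss_config"), epoch >= 1)
  gv <- function(nm) if (!is.null(parts[[nm]])) parts[[nm]] else 0
  contrastive_on <- epoch >= config$start_epoch
  total <- gv("ce") + gv("bce")
  if (contrastive_on) {
    total <- total + gv("scl") + gv("ncl")
    if (config$use_cs) total <- total + gv("cs")
    if (config$use_ap) total <- total + gv("ap")
  }
  structure(list(ce = gv("ce"), bce = gv("bce"), scl = gv("scl"),
                 ncl = gv("ncl"), cs = gv("cs"), ap = gv("ap"),
                 total = total, epoch = epoch,
                 contrastive_active = contrastive_on,
                 cs_active = contrastive_on && config$use_cs,
                 ap_active = contrastive_on && config$use_ap),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(
    "epoch %d: total %.4f (ce %.4f, bce %.4f, scl %.4f, ncl %.4f%s%s)\n",
    x$epoch, x$total, x$ce, x$bce, x$scl, x$ncl,
    if (x$cs_active) sprintf(", cs %.4f", x$cs) else "",
    if (x$ap_active) sprintf(", ap %.4f", x$ap) else ""))
  invisible(x)
}
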