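#' Training configuration
#'
#' Defaults mirror the framework's reference schedule: SGD with momentum
#' 0.9, initial learning rate 0.01, batch size 128, 100 epochs, memory
#' banks of 200 entries, contrastive losses from epoch 2, pseudo-label
#' threshold 0.95, temperature 0.05, resampling augmentation with factors
#' in [0.8, 1.2], and the pseudo-positive count rule
#' `K = floor(|M_u| / C_u / 2)`.
#'
#' @param epochs training epochs.
#' @param batch_size windows per joint batch (labeled + unlabeled mixed
#'   proportionally to set sizes).
#' @param lr initial SGD learning rate.
#' @param momentum SGD momentum.
#' @param lr_drop_epoch optional epoch after which the learning rate is
#'   divided by 10 (`NULL` = constant rate).
#' @param bank_labeled,bank_unlabeled capacities of the labeled and
#'   unlabeled memory banks |M_l|, |M_u|.
#' @param lambda,tau,metric,k,start_epoch,use_cs,use_ap see
#'   [loss_config()].
#' @param clip_norm global gradient-norm clip: when the L2 norm of the
#'   full gradient exceeds this value it is rescaled to it. The contrastive
#'   losses carry a 1/tau factor (20 at the default temperature), so
#'   unclipped steps can saturate the LSTM gates; `Inf` disables clipping.
#' @param augment_range resampling factor range of the augmentation.
#' @param standardize z-score channels using labeled-train statistics.
#' @param normalize_bank L2-normalize embedding snapshots before banking
#'   and queries before neighbor selection. The cosine similarity inside
#'   the contrastive losses is scale-invariant either way; this keeps the
#'   magnitude-sensitive components of the composite measure (Lorentzian,
#'   Dice, Jaccard) in the regime where they are informative.
#' @param track_purity record per-epoch KNN true-positive purity of the
#'   pseudo-positive selection (evaluation-only diagnostic).
#' @param track_test_acc record per-epoch Hungarian accuracy on the
#'   unlabeled test set (evaluation-only diagnostic).
#' @param seed integer seed; the full run is reproducible under it.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 128, lr = 0.01,
                         momentum = 0.9, lr_drop_epoch = NULL,
                         bank_labeled = 200, bank_unlabeled = 200,
                         lambda = 0.95, tau = 0.05,
                         metric = c("combined", "cosine"), k = NULL,
                         start_epoch = 2L, use_cs = FALSE, use_ap = FALSE,
                         clip_norm = 5,
                         augment_range = c(0.8, 1.2), standardize = TRUE,
                         normalize_bank = TRUE,
                         track_purity = FALSE, track_test_acc = FALSE,
                         seed = 0L) {
  metric <- match.arg(metric)
  stopifnot(epochs >= 1, batch_size >= 2, lr > 0, momentum >= 0,
            length(augment_range) == 2, all(augment_range > 0),
            augment_range[1] <= augment_range[2])
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, lr_drop_epoch = lr_drop_epoch,
                 bank_labeled = as.integer(bank_labeled),
                 bank_unlabeled = as.integer(bank_unlabeled),
                 loss = loss_config(lambda, tau, metric, k, start_epoch,
                                    use_cs, use_ap),
                 clip_norm = clip_norm,
                 augment_range = augment_range,
                 standardize = isTRUE(standardize),
                 normalize_bank = isTRUE(normalize_bank),
                 track_purity = isTRUE(track_purity),
                 track_test_acc = isTRUE(track_test_acc),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Resampling augmentation of a sensor window
#'
#' Emulates recording the same movement at a different speed: a factor `f`
#' drawn uniformly from `factor_range` rescales the time axis, so the
#' window is linearly interpolated at positions spaced `f` samples apart
#' (mirror-reflected at the right edge when `f > 1` pushes past the end).
#' A pure tone at frequency `v` cycles/window maps to approximately
#' `v * f`; a factor of exactly 1 is the identity, and constant signals
#' are preserved for every factor. All channels are transformed jointly
#' with the same factor.
#'
#' @param window channels x length numeric matrix.
#' @param factor_range interval to draw the factor from.
#' @param factor optional fixed factor (bypasses the draw).
#' @return augmented window, same shape.
#' @export
resample_augment <- function(window, factor_range = c(0.8, 1.2),
                             factor = NULL) {
  stopifnot(is.matrix(window))
  if (is.null(factor))
    factor <- stats::runif(1, factor_range[1], factor_range[2])
  stopifnot(factor > 0)
  L <- ncol(window)
  if (factor == 1 || L == 1) return(window)
  pos <- 1 + (seq_len(L) - 1) * factor
  per <- 2 * (L - 1)                      # mirror-reflection period
  pr <- (pos - 1) %% per
  pr <- ifelse(pr > (L - 1), per - pr, pr) + 1
  out <- window
  for (c in seq_len(nrow(window)))
    out[c, ] <- stats::approx(seq_len(L), window[c, ], xout = pr)$y
  out
}

augment_array <- function(x, factor_range) {
  for (i in seq_len(dim(x)[3]))
    x[, , i] <- resample_augment(x[, , i], factor_range)
  x
}

l2_normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

bind3 <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

#' Forward a window array in evaluation batches
#'
#' @param model a `model_state`.
#' @param x window array.
#' @param chunk evaluation batch size.
#' @return list with `z`, `logits_l`, `logits_u`, `pred` (argmax of the
#'   unlabeled head, the cluster assignment).
#' @export
predict_model <- function(model, x, chunk = 512L) {
  n <- dim(x)[3]
  outs <- lapply(split(seq_len(n), ceiling(seq_len(n) / chunk)), function(idx) {
    model_forward(model, x[, , idx, drop = FALSE], keep_cache = FALSE)
  })
  z <- do.call(rbind, lapply(outs, `[[`, "z"))
  ll <- do.call(rbind, lapply(outs, `[[`, "logits_l"))
  lu <- do.call(rbind, lapply(outs, `[[`, "logits_u"))
  list(z = z, logits_l = ll, logits_u = lu, pred = max.col(lu, "first"))
}

#' Train the novel-class-discovery model
#'
#' Joint training loop: every step samples a batch mixing labeled and
#' unlabeled windows proportionally to their set sizes, builds two
#' augmented views by resampling, runs both through the encoder, and takes
#' one SGD step on the scheduled objective (cross-entropy on labeled
#' windows, pairwise BCE on unlabeled windows from epoch 1; supervised and
#' neighborhood contrastive losses from `start_epoch`). After the step the
#' first view's embeddings are pushed into the memory banks as detached
#' snapshots. Runs are fully reproducible under `cfg$seed`.
#'
#' @param split an `ncd_split`.
#' @param encoder_cfg an [encoder_config()]; its head widths must match
#'   the split's class counts.
#' @param cfg a [train_config()].
#' @return object of class `train_history`: per-epoch mean loss
#'   components (`epoch_table`), the per-step log (`step_log`), optional
#'   purity trace, the final `model`, and the final unlabeled-test
#'   evaluation (`eval`, a `cluster_eval_report`).
#' @export
train_mrncl <- function(split, encoder_cfg, cfg = train_config()) {
  stopifnot(inherits(split, "ncd_split"), inherits(cfg, "train_config"))
  known <- split$class_sets$known
  novel <- split$class_sets$novel
  if (encoder_cfg$n_known != length(known) ||
      encoder_cfg$n_novel != length(novel))
    stop("encoder head widths do not match the split's class counts")
  nl <- dim(split$labeled_train$x)[3]
  nu <- dim(split$unlabeled_train$x)[3]
  if (nl == 0 || nu == 0) stop("empty labeled or unlabeled training set")

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(cfg$seed)

  if (cfg$standardize) split <- standardize_split(split)
  xl <- split$labeled_train$x
  yl <- match(split$labeled_train$y, known)
  xu <- split$unlabeled_train$x
  yu_shadow <- split$heldout$unlabeled_train_y  # evaluation-only

  model <- build_model(encoder_cfg, seed = cfg$seed)
  H <- encoder_cfg$feature_dim
  lcfg <- cfg$loss
  K <- if (is.null(lcfg$k))
    pseudo_positive_count(cfg$bank_unlabeled, length(novel)) else lcfg$k
  Ml <- feature_queue(cfg$bank_labeled, H, labeled = TRUE)
  Mu <- feature_queue(cfg$bank_unlabeled, H, labeled = FALSE)
  mu_shadow <- character(0)  # held-out classes of Mu entries (diagnostics)

  velocity <- lapply(model$params, function(p) p * 0)
  lr <- cfg$lr
  B <- cfg$batch_size
  bl <- max(1L, min(B - 1L, round(B * nl / (nl + nu))))
  bu <- B - bl
  steps <- max(1L, ceiling((nl + nu) / B))

  step_rows <- list()
  epoch_rows <- list()
  purity_rows <- list()
  acc_trace <- numeric(0)
  step_purity <- NULL

  for (epoch in seq_len(cfg$epochs)) {
    if (!is.null(cfg$lr_drop_epoch) && epoch == cfg$lr_drop_epoch + 1L)
      lr <- lr / 10
    contrastive_on <- epoch >= lcfg$start_epoch
    for (step in seq_len(steps)) {
      il <- sample.int(nl, bl, replace = bl > nl)
      iu <- sample.int(nu, bu, replace = bu > nu)
      xb <- bind3(xl[, , il, drop = FALSE], xu[, , iu, drop = FALSE])
      v1 <- augment_array(xb, cfg$augment_range)
      v2 <- augment_array(xb, cfg$augment_range)
      out <- model_forward(model, bind3(v1, v2), keep_cache = TRUE)
      n2 <- 2L * B
      rl <- c(seq_len(bl), B + seq_len(bl))            # labeled rows (both views)
      ru <- c(bl + seq_len(bu), B + bl + seq_len(bu))  # unlabeled rows
      lab2 <- c(yl[il], yl[il])

      dz <- matrix(0, n2, H)
      dLl <- matrix(0, n2, encoder_cfg$n_known)
      dLu <- matrix(0, n2, encoder_cfg$n_novel)

      ce <- ce_loss_grad(out$logits_l[rl, , drop = FALSE], lab2)
      dLl[rl, ] <- ce$dlogits

      probs_u <- softmax_rows(out$logits_u[ru, , drop = FALSE])
      yhat <- pairwise_pseudo_labels(out$z[ru, , drop = FALSE], lcfg$lambda)
      bce <- bce_loss_grad_probs(probs_u, yhat)
      dLu[ru, ] <- softmax_backprop(probs_u, bce$dprobs)

      scl_v <- 0; ncl_v <- 0; cs_v <- 0; ap_v <- 0
      if (contrastive_on) {
        q_l <- out$z[seq_len(bl), , drop = FALSE]
        a_l <- out$z[B + seq_len(bl), , drop = FALSE]
        scl <- scl_loss_grad(q_l, a_l, yl[il], Ml, lcfg$tau)
        scl_v <- scl$loss
        dz[seq_len(bl), ] <- dz[seq_len(bl), ] + scl$dQ
        dz[B + seq_len(bl), ] <- dz[B + seq_len(bl), ] + scl$dA

        q_u <- out$z[bl + seq_len(bu), , drop = FALSE]
        a_u <- out$z[B + bl + seq_len(bu), , drop = FALSE]
        q_sel <- if (cfg$normalize_bank) l2_normalize_rows(q_u) else NULL
        ncl <- ncl_loss_grad(q_u, a_u, Mu, K, lcfg$tau, lcfg$metric,
                             select_z = q_sel)
        ncl_v <- ncl$loss
        if (!isTRUE(ncl$skipped)) {
          dz[bl + seq_len(bu), ] <- dz[bl + seq_len(bu), ] + ncl$dQ
          dz[B + bl + seq_len(bu), ] <- dz[B + bl + seq_len(bu), ] + ncl$dA
          if (cfg$track_purity) {
            # true-positive fraction of the pseudo-positives (held-out
            # labels, evaluation-only), under both selection metrics on
            # the same queries and bank for a paired comparison
            qy <- as.character(yu_shadow[iu])
            qq <- if (is.null(q_sel)) q_u else q_sel
            pur_of <- function(metric) {
              mean(vapply(seq_along(qy), function(i) {
                idx <- select_knn(qq[i, ], Mu, K, metric)
                mean(mu_shadow[idx] == qy[i])
              }, numeric(1)))
            }
            step_purity <- rbind(step_purity,
                                 c(pur_of("combined"), pur_of("cosine")))
          }
        }
        if (lcfg$use_ap && queue_occupancy(Mu) > 0) {
          ap <- instance_contrastive_grad(q_u, a_u, Mu, lcfg$tau)
          ap_v <- ap$loss
          dz[bl + seq_len(bu), ] <- dz[bl + seq_len(bu), ] + ap$dQ
          dz[B + bl + seq_len(bu), ] <- dz[B + bl + seq_len(bu), ] + ap$dA
        }
        if (lcfg$use_cs) {
          pl1 <- softmax_rows(out$logits_l[seq_len(bl), , drop = FALSE])
          pl2 <- softmax_rows(out$logits_l[B + seq_len(bl), , drop = FALSE])
          pu1 <- softmax_rows(out$logits_u[bl + seq_len(bu), , drop = FALSE])
          pu2 <- softmax_rows(out$logits_u[B + bl + seq_len(bu), , drop = FALSE])
          cs_v <- consistency_loss(pl1, pl2, pu1, pu2)
          dl1 <- 2 * (pl1 - pl2) / length(pl1)
          du1 <- 2 * (pu1 - pu2) / length(pu1)
          dLl[seq_len(bl), ] <- dLl[seq_len(bl), ] + softmax_backprop(pl1, dl1)
          dLl[B + seq_len(bl), ] <- dLl[B + seq_len(bl), ] + softmax_backprop(pl2, -dl1)
          dLu[bl + seq_len(bu), ] <- dLu[bl + seq_len(bu), ] + softmax_backprop(pu1, du1)
          dLu[B + bl + seq_len(bu), ] <- dLu[B + bl + seq_len(bu), ] + softmax_backprop(pu2, -du1)
        }
      }

      report <- overall_loss(list(ce = ce$loss, bce = bce$loss, scl = scl_v,
                                  ncl = ncl_v, cs = cs_v, ap = ap_v),
                             lcfg, epoch)
      grads <- model_backward(model, dz, dLl, dLu)
      if (is.finite(cfg$clip_norm)) {
        gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (gnorm > cfg$clip_norm)
          grads <- lapply(grads, function(g) g * (cfg$clip_norm / gnorm))
      }
      for (nm in names(model$params)) {
        velocity[[nm]] <- cfg$momentum * velocity[[nm]] - lr * grads[[nm]]
        model$params[[nm]] <- model$params[[nm]] + velocity[[nm]]
      }

      # detached first-view snapshots into the banks
      snap_l <- out$z[seq_len(bl), , drop = FALSE]
      snap_u <- out$z[bl + seq_len(bu), , drop = FALSE]
      if (cfg$normalize_bank) {
        snap_l <- l2_normalize_rows(snap_l)
        snap_u <- l2_normalize_rows(snap_u)
      }
      Ml <- queue_push(Ml, snap_l, yl[il])
      Mu <- queue_push(Mu, snap_u)
      mu_shadow <- c(mu_shadow, as.character(yu_shadow[iu]))
      if (length(mu_shadow) > cfg$bank_unlabeled)
        mu_shadow <- mu_shadow[(length(mu_shadow) - cfg$bank_unlabeled + 1L):
                                 length(mu_shadow)]

      step_rows[[length(step_rows) + 1L]] <-
        data.frame(epoch = epoch, step = step, ce = report$ce,
                   bce = report$bce, scl = report$scl, ncl = report$ncl,
                   cs = report$cs, ap = report$ap, total = report$total)
    }
    er <- do.call(rbind, step_rows[(length(step_rows) - steps + 1L):
                                     length(step_rows)])
    epoch_rows[[epoch]] <- data.frame(
      epoch = epoch, ce = mean(er$ce), bce = mean(er$bce),
      scl = mean(er$scl), ncl = mean(er$ncl), cs = mean(er$cs),
      ap = mean(er$ap), total = mean(er$total))

    if (cfg$track_purity) {
      pc <- if (!is.null(step_purity)) mean(step_purity[, 1]) else NA_real_
      pk <- if (!is.null(step_purity)) mean(step_purity[, 2]) else NA_real_
      step_purity <- NULL
      purity_rows[[length(purity_rows) + 1L]] <-
        data.frame(epoch = epoch,
                   purity = if (lcfg$metric == "combined") pc else pk,
                   purity_combined = pc, purity_cosine = pk)
    }
    if (cfg$track_test_acc) {
      ep <- predict_model(model, split$unlabeled_test$x)
      acc_trace[epoch] <- hungarian_accuracy(ep$pred,
                                             split$unlabeled_test$y)$acc
    }
  }

  test_pred <- predict_model(model, split$unlabeled_test$x)
  eval <- evaluate_clustering(novel[test_pred$pred], split$unlabeled_test$y)

  structure(list(
    epoch_table = do.call(rbind, epoch_rows),
    step_log = do.call(rbind, step_rows),
    purity = if (cfg$track_purity) do.call(rbind, purity_rows) else NULL,
    test_acc = if (cfg$track_test_acc) acc_trace else NULL,
    model = model, eval = eval, k_used = K,
    banks = list(labeled = Ml, unlabeled = Mu),
    config = cfg), class = "train_history")
}

#' @export
print.train_history <- function(x, ...) {
  et <- x$epoch_table
  cat(sprintf("<train_history: %d epochs, final total loss %.4f, test ACC %.4f>\n",
              nrow(et), et$total[nrow(et)], x$eval$acc))
  invisible(x)
}

#' Write the per-epoch training log as delimited text
#'
#' One row per epoch with the mean loss components
#' (epoch, ce, bce, scl, ncl, cs, ap, total).
#'
#' @param history a `train_history`.
#' @param file output path.
#' @param per_step write the per-step log instead of per-epoch means.
#' @return `file`, invisibly.
#' @export
write_training_log <- function(history, file, per_step = FALSE) {
  stopifnot(inherits(history, "train_history"))
  tab <- if (per_step) history$step_log else history$epoch_table
  utils::write.table(format(tab, digits = 17), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Plot the training loss trajectory
#'
#' @param x a `train_history`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.train_history <- function(x, ...) {
  et <- x$epoch_table
  graphics::plot(et$epoch, et$total, type = "l", xlab = "epoch",
                 ylab = "mean loss", ...)
  graphics::lines(et$epoch, et$ce + et$bce, lty = 2)
  graphics::legend("topright", legend = c("total", "ce + bce"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
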