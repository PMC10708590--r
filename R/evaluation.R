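#' Solve the linear assignment problem (Hungarian algorithm)
#'
#' Minimizes the total cost of a one-to-one assignment of rows to columns of
#' a rectangular cost matrix with `nrow(cost) <= ncol(cost)`. O(n^2 m)
#' shortest-augmenting-path formulation with row/column potentials.
#'
#' @param cost numeric cost matrix, rows <= columns.
#' @return integer vector: for each row, the assigned column.
#' @keywords internal
hungarian_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n >= 1, n <= m, all(is.finite(cost)))
  u <- numeric(n + 1)        # row potentials (index i+1 for row i, 0 = virtual)
  v <- numeric(m + 1)        # column potentials (index j+1 for column j)
  p <- integer(m + 1)        # p[j+1]: row assigned to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_col <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) assign_col[p[j + 1]] <- j
  assign_col
}

#' Clustering accuracy under the optimal cluster-to-class mapping
#'
#' Computes the fraction of windows whose predicted cluster, after the best
#' one-to-one relabeling of clusters to classes, matches the held-out class.
#' The relabeling maximizes total agreement over the cluster/class
#' contingency table and is solved by the Hungarian algorithm. When there
#' are more clusters than classes the assignment is rectangular and
#' unmatched clusters count entirely as errors.
#'
#' @param pred vector of predicted cluster ids.
#' @param truth vector of true class labels, same length.
#' @return list with `acc` (fraction correct) and `mapping` (named vector
#'   cluster -> class; `NA` for unmatched clusters).
#' @examples
#' hungarian_accuracy(c(0, 0, 1, 1), c("B", "B", "A", "A"))$acc  # 1
#' @export
hungarian_accuracy <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  tab <- table(cluster = as.character(pred), class = as.character(truth))
  cnt <- matrix(as.numeric(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  transposed <- nrow(cnt) > ncol(cnt)
  work <- if (transposed) t(cnt) else cnt
  cost <- max(work) - work
  assign_col <- hungarian_solve(cost)
  matched <- sum(work[cbind(seq_len(nrow(work)), assign_col)])
  mapping <- rep(NA_character_, nrow(cnt))
  names(mapping) <- rownames(cnt)
  if (transposed) {
    # rows of `work` are classes; invert the assignment to cluster -> class
    mapping[colnames(work)[assign_col]] <- rownames(work)
  } else {
    mapping[] <- colnames(work)[assign_col]
  }
  list(acc = matched / length(pred), mapping = mapping)
}

#' Pairwise F-score, precision and recall of a clustering
#'
#' Over all unordered pairs of windows: a true positive is a pair with the
#' same true class placed in the same cluster; pair precision is TP over all
#' same-cluster pairs, pair recall is TP over all same-class pairs, and the
#' F-score is their harmonic mean. Conventions: precision is 1 when no pair
#' is predicted positive, recall is 1 when no pair is truly positive.
#'
#' @inheritParams hungarian_accuracy
#' @return list with `f`, `fp` (precision), `fr` (recall).
#' @examples
#' pairwise_f(c(1, 1, 1, 2), c("A", "A", "B", "B"))  # fp 1/3, fr 1/2, f 0.4
#' @export
pairwise_f <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  tab <- table(as.character(pred), as.character(truth))
  choose2 <- function(x) sum(x * (x - 1) / 2)
  tp <- choose2(as.numeric(tab))
  same_cluster <- choose2(rowSums(tab))
  same_class <- choose2(colSums(tab))
  fp <- if (same_cluster > 0) tp / same_cluster else 1
  fr <- if (same_class > 0) tp / same_class else 1
  f <- if (fp + fr > 0) 2 * fp * fr / (fp + fr) else 0
  list(f = f, fp = fp, fr = fr)
}

#' Evaluate cluster assignments against held-out classes
#'
#' Convenience wrapper combining [hungarian_accuracy()] and [pairwise_f()]
#' into one report.
#'
#' @inheritParams hungarian_accuracy
#' @return object of class `cluster_eval_report`: list with `acc`, `f`,
#'   `fp`, `fr`, `mapping`, `n`.
#' @export
evaluate_clustering <- function(pred, truth) {
  ha <- hungarian_accuracy(pred, truth)
  pf <- pairwise_f(pred, truth)
  structure(list(acc = ha$acc, f = pf$f, fp = pf$fp, fr = pf$fr,
                 mapping = ha$mapping, n = length(pred)),
            class = "cluster_eval_report")
}

#' @export
print.cluster_eval_report <- function(x, ...) {
  cat(sprintf(
    "Cluster evaluation (n = %d)\n  ACC: %.4f\n  F:   %.4f  (precision %.4f, recall %.4f)\n",
    x$n, x$acc, x$f, x$fp, x$fr))
  invisible(x)
}

#' @param file path for the delimited report.
#' @rdname evaluate_clustering
#' @export
write_cluster_report <- function(x, file) {
  stopifnot(inherits(x, "cluster_eval_report"))
  df <- data.frame(metric = c("acc", "f", "fp", "fr"),
                   value = c(x$acc, x$f, x$fp, x$fr))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' KNN true-positive purity of pseudo-positive selection
#'
#' Diagnostic for the reliability of neighbor selection: for each query
#' embedding, select the `k` most similar bank entries under `metric` and
#' measure the fraction whose held-out class equals the query's held-out
#' class; the result is averaged over queries. Labels here are evaluation
#' ground truth only — they play no role in the selection itself.
#'
#' @param z numeric matrix of query embeddings (one per row).
#' @param labels held-out classes of the queries.
#' @param bank numeric matrix of bank embeddings (or a [feature_queue()]).
#' @param bank_labels held-out classes of the bank entries.
#' @param k number of neighbors per query.
#' @param metric `"combined"` or `"cosine"`.
#' @return mean fraction of same-class neighbors, in \eqn{[0, 1]}.
#' @export
knn_purity <- function(z, labels, bank, bank_labels, k,
                       metric = c("combined", "cosine")) {
  metric <- match.arg(metric)
  mat <- if (inherits(bank, "feature_queue")) queue_matrix(bank) else bank
  stopifnot(nrow(z) == length(labels), nrow(mat) == length(bank_labels),
            k >= 1, k <= nrow(mat))
  fr <- vapply(seq_len(nrow(z)), function(i) {
    idx <- select_knn(z[i, ], mat, k, metric)
    mean(bank_labels[idx] == labels[i])
  }, numeric(1))
  mean(fr)
}
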