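#' Fixed-capacity FIFO queue of embedding snapshots
#'
#' The memory banks M_l (labeled) and M_u (unlabeled) store the feature
#' representations of recent training batches. Entries are plain numeric
#' snapshots: they are never updated by the optimizer, only evicted
#' first-in-first-out once the queue is full. The labeled variant carries a
#' parallel vector of class labels so that same-class positives can be
#' retrieved for the supervised contrastive loss.
#'
#' @param capacity maximum number of stored embeddings.
#' @param dim embedding dimensionality H.
#' @param labeled logical; whether a parallel label vector is kept.
#' @return an object of class `feature_queue`.
#' @export
feature_queue <- function(capacity, dim, labeled = FALSE) {
  stopifnot(capacity >= 1, dim >= 1)
  structure(
    list(capacity = as.integer(capacity), dim = as.integer(dim),
         labeled = isTRUE(labeled),
         entries = matrix(numeric(0), nrow = 0, ncol = dim),
         labels = if (isTRUE(labeled)) integer(0) else NULL),
    class = "feature_queue")
}

#' Append a batch of embeddings to a feature queue
#'
#' Rows of `features` are appended in order; the oldest entries are evicted
#' so that occupancy never exceeds capacity.
#'
#' @param queue a [feature_queue()].
#' @param features numeric matrix, one embedding per row.
#' @param labels integer/character labels, required iff the queue is labeled.
#' @return the updated queue.
#' @export
queue_push <- function(queue, features, labels = NULL) {
  stopifnot(inherits(queue, "feature_queue"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (nrow(features) == 0L) return(queue)
  if (ncol(features) != queue$dim)
    stop(sprintf("feature dim %d does not match queue dim %d",
                 ncol(features), queue$dim))
  if (queue$labeled && is.null(labels))
    stop("labeled queue requires labels")
  if (!queue$labeled && !is.null(labels))
    stop("unlabeled queue does not accept labels")
  if (queue$labeled && length(labels) != nrow(features))
    stop("labels length must match number of features")
  ent <- rbind(queue$entries, features)
  lab <- if (queue$labeled) c(queue$labels, labels) else NULL
  if (nrow(ent) > queue$capacity) {
    keep <- seq.int(nrow(ent) - queue$capacity + 1L, nrow(ent))
    ent <- ent[keep, , drop = FALSE]
    if (queue$labeled) lab <- lab[keep]
  }
  queue$entries <- ent
  queue$labels <- lab
  queue
}

#' @export
print.feature_queue <- function(x, ...) {
  cat(sprintf("<feature_queue: %d/%d entries, dim %d%s>\n",
              queue_occupancy(x), x$capacity, x$dim,
              if (x$labeled) ", labeled" else ""))
  invisible(x)
}

#' Queue occupancy and contents
#'
#' @param queue a [feature_queue()].
#' @return `queue_occupancy()` the number of stored entries;
#'   `queue_matrix()` the stored embeddings as a matrix (oldest first).
#' @export
queue_occupancy <- function(queue) nrow(queue$entries)

#' @rdname queue_occupancy
#' @export
queue_matrix <- function(queue) queue$entries

#' Indices of bank entries sharing a class label
#'
#' Retrieves every entry of a labeled queue whose stored class equals
#' `label` — the bank part of the positive set for the supervised
#' contrastive loss (the augmented view of the query is added separately).
#'
#' @param queue a labeled [feature_queue()].
#' @param label class label to match.
#' @return integer indices into the queue (possibly empty).
#' @export
positives_by_label <- function(queue, label) {
  stopifnot(inherits(queue, "feature_queue"))
  if (!queue$labeled) stop("positives_by_label() requires a labeled queue")
  which(queue$labels == label)
}
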