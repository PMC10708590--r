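#' Similarity measures for embedding vectors
#'
#' The composite similarity used to rank memory-bank entries when selecting
#' pseudo-positive neighbors is the sum of four component scores between a
#' query embedding \eqn{a} and a bank entry \eqn{b} (both length-\eqn{n}
#' vectors):
#'
#' \itemize{
#'   \item Gower: \eqn{1 - \frac{1}{n}\|a/\|a\| - b/\|b\|\|_1} — the mean
#'     absolute coordinate difference of the unit-normalized vectors,
#'     subtracted from one.
#'   \item Lorentzian: \eqn{1 - \sum_i \log(1 + |a_i - b_i|)} on the raw
#'     (un-normalized) vectors; the \eqn{+1} keeps the log argument positive.
#'   \item Dice: \eqn{2 a^\top b / (\|a\| + \|b\|)}.
#'   \item Jaccard: \eqn{a^\top b / (\|a\| + \|b\| - |a^\top b|)}.
#' }
#'
#' Only the Gower score normalizes its inputs; the other three operate on the
#' raw embeddings. All four are symmetric in their arguments.
#'
#' @param a,b numeric vectors of equal length with positive norm.
#' @return `simi_components()` returns a list with elements `gow`, `lor`,
#'   `dice`, `jac` and `combined` (their sum). `simi_combined()` returns the
#'   sum only.
#' @examples
#' a <- c(1, 0); b <- c(0, 1)
#' simi_components(a, b)$combined   # 1 - 2*log(2)
#' @export
simi_components <- function(a, b) {
  check_embedding_pair(a, b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  n <- length(a)
  gow <- 1 - sum(abs(a / na - b / nb)) / n
  lor <- 1 - sum(log1p(abs(a - b)))
  dot <- sum(a * b)
  dice <- 2 * dot / (na + nb)
  jden <- na + nb - abs(dot)
  if (abs(jden) <= 1e-12)
    stop("degenerate pair: Jaccard denominator ~ 0")
  jac <- dot / jden
  list(gow = gow, lor = lor, dice = dice, jac = jac,
       combined = gow + lor + dice + jac)
}

#' @rdname simi_components
#' @export
simi_combined <- function(a, b) simi_components(a, b)$combined

#' Cosine similarity between two embedding vectors
#'
#' @param a,b numeric vectors of equal length with positive norm.
#' @return scalar in \eqn{[-1, 1]}.
#' @export
cosine_sim <- function(a, b) {
  check_embedding_pair(a, b)
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

check_embedding_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("embedding vectors must have equal length")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("embedding vectors must be finite")
  if (sum(a^2) == 0 || sum(b^2) == 0)
    stop("zero vector: similarity undefined")
  invisible(TRUE)
}

## Vectorized scores of one query against the rows of a bank matrix.
## Used on the training hot path; semantics identical to simi_components()
## applied row-wise.
simi_scores_matrix <- function(query, bank, metric = c("combined", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(bank), ncol(bank) == length(query))
  nq <- sqrt(sum(query^2))
  nb <- sqrt(rowSums(bank^2))
  if (nq == 0 || any(nb == 0)) stop("zero vector: similarity undefined")
  # row-consistent dot products: BLAS gemv may round identical rows
  # differently by memory alignment, which would break exact ties
  dots <- rowSums(sweep(bank, 2, query, "*"))
  if (metric == "cosine") return(dots / (nq * nb))
  n <- length(query)
  qa <- query / nq
  gow <- 1 - rowSums(abs(sweep(bank / nb, 2, qa, "-"))) / n
  lor <- 1 - rowSums(log1p(abs(sweep(bank, 2, query, "-"))))
  dice <- 2 * dots / (nq + nb)
  jac <- dots / (nq + nb - abs(dots))
  gow + lor + dice + jac
}

#' Select the top-k most similar memory-bank entries
#'
#' Ranks the occupied entries of a feature queue against a query embedding
#' and returns the indices of the `k` highest-scoring entries in descending
#' score order. Ties are broken deterministically in favor of the lower bank
#' index. This is the pseudo-positive selection step: the returned entries
#' are treated as positives of the query in the neighborhood contrastive
#' loss.
#'
#' @param query numeric embedding vector.
#' @param bank a [feature_queue()] or a numeric matrix with one entry per row.
#' @param k number of neighbors; clipped (with a warning) to the bank
#'   occupancy when larger.
#' @param metric `"combined"` (Gower + Lorentzian + Dice + Jaccard, the
#'   default) or `"cosine"`.
#' @return integer vector of bank indices, highest score first.
#' @export
select_knn <- function(query, bank, k, metric = c("combined", "cosine")) {
  metric <- match.arg(metric)
  mat <- if (inherits(bank, "feature_queue")) queue_matrix(bank) else bank
  m <- nrow(mat)
  if (is.null(m) || m == 0L) stop("empty bank: no neighbors to select")
  if (k <= 0) stop("k must be >= 1")
  if (k > m) {
    warning(sprintf("k = %d exceeds bank occupancy %d; clipping", k, m))
    k <- m
  }
  scores <- simi_scores_matrix(query, mat, metric)
  ord <- order(-scores, seq_len(m))
  ord[seq_len(k)]
}
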