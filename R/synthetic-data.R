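#' Configuration for the synthetic activity-signal generator
#'
#' Each activity class is a family of quasi-periodic multichannel signals:
#' channel `c` of a window from class `k` is
#' `amp[k, c] * sin(2*pi*f_k*t/L + phase) + N(0, sigma^2)` with one uniform
#' random phase per window (shared across channels) and `f_k` the class base
#' frequency in cycles per window. Distinct base frequencies make classes
#' separable; moving them closer emulates the inter-activity-similarity
#' regime in which neighbor selection gets harder.
#'
#' @param n_channels number of sensor channels per window.
#' @param window_len samples per window (L).
#' @param n_known_classes number of labeled (known) classes C_l.
#' @param n_novel_classes number of unlabeled (novel) classes C_u.
#' @param windows_per_class windows generated per class.
#' @param base_freqs one frequency (cycles/window) per class, known classes
#'   first; defaults interleave known at 2, 4, 6, ... and novel at 3, 5, 7,
#'   ... so all classes are spectrally distinct.
#' @param amp_matrix per-class (rows) per-channel (columns) amplitudes;
#'   default gives each class a distinct deterministic amplitude profile.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param test_fraction fraction of each class held out as the test set.
#' @param seed integer RNG seed; identical seeds give bit-identical splits.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 3, window_len = 64,
                             n_known_classes = 3, n_novel_classes = 3,
                             windows_per_class = 200,
                             base_freqs = NULL, amp_matrix = NULL,
                             noise_sigma = 0.3, test_fraction = 0.2,
                             seed = 0L) {
  stopifnot(n_channels >= 1, window_len >= 2, n_known_classes >= 1,
            n_novel_classes >= 1, windows_per_class >= 1, noise_sigma >= 0,
            test_fraction > 0, test_fraction < 1)
  n_classes <- n_known_classes + n_novel_classes
  if (is.null(base_freqs)) {
    base_freqs <- c(seq(2, by = 2, length.out = n_known_classes),
                    seq(3, by = 2, length.out = n_novel_classes))
  }
  stopifnot(length(base_freqs) == n_classes, all(base_freqs > 0))
  if (is.null(amp_matrix)) {
    amp_matrix <- outer(seq_len(n_classes), seq_len(n_channels),
                        function(k, c) 0.6 + 0.2 * ((k * 7 + c * 3) %% 5))
  }
  stopifnot(is.matrix(amp_matrix), nrow(amp_matrix) == n_classes,
            ncol(amp_matrix) == n_channels)
  structure(list(n_channels = n_channels, window_len = window_len,
                 n_known_classes = n_known_classes,
                 n_novel_classes = n_novel_classes,
                 windows_per_class = windows_per_class,
                 base_freqs = base_freqs, amp_matrix = amp_matrix,
                 noise_sigma = noise_sigma, test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic novel-class-discovery split
#'
#' Draws `windows_per_class` windows per class from the signal families
#' described by `config`, labels the first `n_known_classes` classes as
#' known and the rest as novel, and packages them as an NCD split: the
#' labeled part covers only known classes, the unlabeled part only novel
#' classes, and the novel training windows carry no label field — their
#' ground truth is stored separately under `$heldout` for evaluation only.
#' Train/test partitions are stratified per class at `test_fraction`.
#'
#' @param config a [synthetic_config()].
#' @return an `ncd_split` (see [make_ncd_split()]): list with
#'   `labeled_train`, `labeled_test` (fields `x`, `y`), `unlabeled_train`
#'   (field `x` only), `unlabeled_test` (fields `x`, `y`), `heldout`
#'   (`unlabeled_train_y`), and `class_sets`. Window arrays have dimension
#'   `(channels, window_len, n)`.
#' @export
generate_synthetic_split <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n_classes <- cfg$n_known_classes + cfg$n_novel_classes
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)
  L <- cfg$window_len
  tgrid <- (seq_len(L) - 1) / L
  n_total <- n_classes * cfg$windows_per_class
  x <- array(0, dim = c(cfg$n_channels, L, n_total))
  y <- integer(n_total)
  i <- 0L
  for (k in seq_len(n_classes)) {
    for (w in seq_len(cfg$windows_per_class)) {
      i <- i + 1L
      phase <- stats::runif(1, 0, 2 * pi)
      base <- sin(2 * pi * cfg$base_freqs[k] * tgrid + phase)
      sig <- cfg$amp_matrix[k, ] %o% base
      if (cfg$noise_sigma > 0)
        sig <- sig + matrix(stats::rnorm(length(sig), 0, cfg$noise_sigma),
                            nrow = cfg$n_channels)
      x[, , i] <- sig
      y[i] <- k
    }
  }
  known <- seq_len(cfg$n_known_classes)
  novel <- cfg$n_known_classes + seq_len(cfg$n_novel_classes)
  make_ncd_split(x, y, known = known, novel = novel,
                 test_fraction = cfg$test_fraction, seed = cfg$seed)
}

#' Export a synthetic split as delimited rows in the WISDM layout
#'
#' Writes every window of a 3-channel split as consecutive rows
#' `user,activity,timestamp,x,y,z;` (the accelerometer layout used by the
#' WISDM raw file), one synthetic "subject" per class, windows concatenated
#' in time. Re-reading the file with [load_dataset()] and re-windowing at
#' the original window length recovers the windows exactly. Held-out novel
#' labels are written too: the export is a reader fixture, not a blinded
#' release.
#'
#' @param split an `ncd_split` with 3 channels.
#' @param file output path.
#' @param sample_rate nominal rate used to synthesize timestamps (Hz).
#' @return `file`, invisibly.
#' @export
export_wisdm <- function(split, file, sample_rate = 20) {
  stopifnot(inherits(split, "ncd_split"))
  parts <- list(
    list(x = split$labeled_train$x, y = split$labeled_train$y),
    list(x = split$labeled_test$x, y = split$labeled_test$y),
    list(x = split$unlabeled_train$x, y = split$heldout$unlabeled_train_y),
    list(x = split$unlabeled_test$x, y = split$unlabeled_test$y))
  con <- file(file, "w")
  on.exit(close(con))
  step_ns <- round(1e9 / sample_rate)
  for (p in parts) {
    if (length(p$y) == 0) next
    if (dim(p$x)[1] != 3) stop("WISDM export requires exactly 3 channels")
    ord <- order(p$y)
    for (i in ord) {
      w <- p$x[, , i]
      ts <- (seq_len(ncol(w)) - 1) * step_ns
      rows <- sprintf("%d,class%d,%d,%.17g,%.17g,%.17g;",
                      p$y[i], p$y[i], ts, w[1, ], w[2, ], w[3, ])
      writeLines(rows, con)
    }
  }
  invisible(file)
}
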