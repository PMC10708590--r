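#' Construct a raw sensor recording
#'
#' @param signal numeric matrix, channels x time (sensor units).
#' @param sample_rate sampling rate in Hz.
#' @param subject subject identifier.
#' @param activity activity class label.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(signal, sample_rate, subject, activity) {
  stopifnot(is.matrix(signal), all(is.finite(signal)), sample_rate > 0)
  structure(list(signal = signal, sample_rate = sample_rate,
                 subject = subject, activity = activity),
            class = "raw_recording")
}

#' Segment a recording into fixed-length sliding windows
#'
#' Windows are 0-based half-open intervals `[start, start + length)` taken
#' at stride `round(length * (1 - overlap_fraction))`; a trailing partial
#' window is discarded. Each window inherits the recording's activity
#' label.
#'
#' @param recording a [raw_recording()].
#' @param length window length in samples.
#' @param overlap_fraction fraction of overlap between adjacent windows,
#'   in `[0, 1)`; 0 gives non-overlapping windows.
#' @return list of windows, each a list with `values` (channels x length
#'   matrix), `label`, and `origin` (subject, 0-based offset). A recording
#'   shorter than `length` yields an empty list with a warning.
#' @examples
#' rec <- raw_recording(matrix(rnorm(200), 1), 20, "s1", "walking")
#' length(slide_windows(rec, 90, 0))  # 2 windows at offsets 0 and 90
#' @export
slide_windows <- function(recording, length, overlap_fraction = 0) {
  stopifnot(inherits(recording, "raw_recording"),
            overlap_fraction >= 0, overlap_fraction < 1, length >= 1)
  tt <- ncol(recording$signal)
  if (length > tt) {
    warning(sprintf("recording of %d samples shorter than window %d: no windows",
                    tt, length))
    return(list())
  }
  stride <- max(1L, as.integer(round(length * (1 - overlap_fraction))))
  starts <- seq.int(0L, tt - length, by = stride)
  lapply(starts, function(s) {
    list(values = recording$signal[, (s + 1L):(s + length), drop = FALSE],
         label = recording$activity,
         origin = list(subject = recording$subject, offset = s))
  })
}

#' Segment many recordings into a window array
#'
#' Applies [slide_windows()] to each recording and stacks the results into
#' a `(channels, length, n)` array with parallel label and subject vectors.
#'
#' @param recordings list of [raw_recording()] objects.
#' @inheritParams slide_windows
#' @return list with `x` (array), `y` (labels), `subject`.
#' @export
segment_recordings <- function(recordings, length, overlap_fraction = 0) {
  wins <- unlist(lapply(recordings, slide_windows, length = length,
                        overlap_fraction = overlap_fraction),
                 recursive = FALSE)
  if (length(wins) == 0) stop("no windows produced from the recordings")
  ch <- nrow(wins[[1]]$values)
  x <- array(0, dim = c(ch, length, base::length(wins)))
  for (i in seq_along(wins)) x[, , i] <- wins[[i]]$values
  list(x = x,
       y = vapply(wins, function(w) as.character(w$label), character(1)),
       subject = vapply(wins, function(w) as.character(w$origin$subject),
                        character(1)))
}

#' Build a novel-class-discovery split from labeled windows
#'
#' Partitions a labeled window array into the four NCD partitions: labeled
#' train/test over the known classes, and unlabeled train/test over the
#' novel classes. Known and novel class sets must be disjoint and cover
#' every window's class. Splitting is stratified per class at
#' `test_fraction`; novel-class training windows have their labels hidden
#' (kept only under `$heldout` for evaluation).
#'
#' @param x window array `(channels, length, n)`.
#' @param y class label per window.
#' @param known,novel disjoint class sets partitioning `unique(y)`.
#' @param test_fraction held-out fraction per class (default 0.2, i.e. an
#'   80/20 train/test split).
#' @param seed integer seed controlling split membership.
#' @return object of class `ncd_split`.
#' @export
make_ncd_split <- function(x, y, known, novel, test_fraction = 0.2,
                           seed = 0L) {
  stopifnot(base::length(dim(x)) == 3, dim(x)[3] == base::length(y),
            test_fraction > 0, test_fraction < 1)
  if (base::length(intersect(known, novel)) > 0)
    stop("known and novel class sets overlap")
  if (!all(y %in% c(known, novel)))
    stop("every window's class must be in the known or novel set")
  counts <- table(y)
  if (any(counts < 2))
    stop(sprintf("class with fewer than 2 windows: %s",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(as.integer(seed))
  test_idx <- unlist(lapply(unique(y), function(k) {
    idx <- which(y == k)
    n_test <- max(1L, round(base::length(idx) * test_fraction))
    sample(idx, n_test)
  }))
  is_test <- seq_along(y) %in% test_idx
  is_known <- y %in% known
  take <- function(sel) {
    list(x = x[, , sel, drop = FALSE], y = y[sel])
  }
  lt <- take(is_known & !is_test)
  lv <- take(is_known & is_test)
  ut <- take(!is_known & !is_test)
  uv <- take(!is_known & is_test)
  structure(list(
    labeled_train = lt,
    labeled_test = lv,
    unlabeled_train = list(x = ut$x),     # no label field: labels withheld
    unlabeled_test = uv,
    heldout = list(unlabeled_train_y = ut$y),
    class_sets = list(known = known, novel = novel)),
    class = "ncd_split")
}

#' @export
print.ncd_split <- function(x, ...) {
  nn <- function(p) if (is.null(dim(p$x))) 0 else dim(p$x)[3]
  cat(sprintf(
    paste0("<ncd_split: %d known classes (%d train / %d test windows), ",
           "%d novel classes (%d train / %d test windows)>\n"),
    base::length(x$class_sets$known), nn(x$labeled_train), nn(x$labeled_test),
    base::length(x$class_sets$novel), nn(x$unlabeled_train),
    nn(x$unlabeled_test)))
  invisible(x)
}

#' Standardize a split channel-wise
#'
#' Z-scores every partition per channel using mean and standard deviation
#' computed on the labeled training windows only, so no statistic leaks
#' from test or unlabeled data.
#'
#' @param split an `ncd_split`.
#' @return the split with standardized windows and a `$scaling` element.
#' @export
standardize_split <- function(split) {
  stopifnot(inherits(split, "ncd_split"))
  ref <- split$labeled_train$x
  mu <- apply(ref, 1, mean)
  sd <- apply(ref, 1, stats::sd)
  sd[sd == 0] <- 1
  scale_arr <- function(a) {
    for (c in seq_along(mu)) a[c, , ] <- (a[c, , ] - mu[c]) / sd[c]
    a
  }
  split$labeled_train$x <- scale_arr(split$labeled_train$x)
  split$labeled_test$x <- scale_arr(split$labeled_test$x)
  split$unlabeled_train$x <- scale_arr(split$unlabeled_train$x)
  split$unlabeled_test$x <- scale_arr(split$unlabeled_test$x)
  split$scaling <- list(mean = mu, sd = sd)
  split
}

#' Read a public HAR dataset layout
#'
#' Supported layouts:
#' \describe{
#'   \item{`wisdm`}{A raw delimited accelerometer file with rows
#'     `user,activity,timestamp,x,y,z;` at 20 Hz, 3 channels. `path` may be
#'     the file itself or a directory containing a single `*.txt`.
#'     Malformed rows are skipped and counted in a message. Returns
#'     recordings grouped by subject and activity, in file order.}
#'   \item{`ucihar`}{The pre-windowed inertial-signal layout: `train/` and
#'     `test/` directories each holding `y_*.txt` and an
#'     `Inertial Signals/` directory with nine whitespace-delimited matrix
#'     files (one row per 128-sample window). Channel order is fixed as
#'     body_acc x/y/z, body_gyro x/y/z, total_acc x/y/z. Returns windows
#'     directly; no re-windowing is applied (the native 50% overlap is
#'     kept).}
#'   \item{`uschad`}{Per-trial MAT-files under `Subject*/` directories,
#'     each with a `sensor_readings` matrix (samples x 6 channels at
#'     100 Hz) and an `activity_number` (or `activity`) variable. Returns
#'     one recording per trial.}
#' }
#'
#' @param name one of `"wisdm"`, `"ucihar"`, `"uschad"`.
#' @param path dataset directory (or raw file for `wisdm`).
#' @return object of class `har_dataset`: for `wisdm`/`uschad` a list with
#'   `$recordings`; for `ucihar` a list with `$x` (9 x 128 x n array), `$y`
#'   and `$partition`. All variants carry `$name`, `$sample_rate`,
#'   `$window_len` (the conventional window length for the dataset).
#' @export
load_dataset <- function(name = c("wisdm", "ucihar", "uschad"), path) {
  name <- match.arg(name)
  switch(name,
         wisdm = load_wisdm(path),
         ucihar = load_ucihar(path),
         uschad = load_uschad(path))
}

load_wisdm <- function(path) {
  file <- path
  if (dir.exists(path)) {
    cand <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    if (base::length(cand) == 0)
      stop("WISDM layout: no .txt raw file found in ", path)
    file <- cand[1]
  }
  if (!file.exists(file)) stop("WISDM layout: raw file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(gsub(";", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",")
  ok <- vapply(parts, function(p) base::length(p) == 6 &&
                 !anyNA(suppressWarnings(as.numeric(p[4:6]))), logical(1))
  n_bad <- sum(!ok)
  if (n_bad > 0)
    message(sprintf("load_dataset(wisdm): skipped %d malformed rows", n_bad))
  parts <- parts[ok]
  if (base::length(parts) == 0) stop("WISDM layout: no valid rows in ", file)
  tab <- do.call(rbind, parts)
  subject <- tab[, 1]; activity <- tab[, 2]
  vals <- matrix(as.numeric(tab[, 4:6]), ncol = 3)
  key <- paste(subject, activity, sep = "\r")
  recs <- lapply(unique(key), function(k) {
    sel <- key == k
    raw_recording(t(vals[sel, , drop = FALSE]), sample_rate = 20,
                  subject = subject[sel][1], activity = activity[sel][1])
  })
  structure(list(name = "wisdm", recordings = recs, sample_rate = 20,
                 n_channels = 3, window_len = 90),
            class = "har_dataset")
}

load_ucihar <- function(path) {
  channel_files <- c("body_acc_x", "body_acc_y", "body_acc_z",
                     "body_gyro_x", "body_gyro_y", "body_gyro_z",
                     "total_acc_x", "total_acc_y", "total_acc_z")
  read_part <- function(part) {
    pdir <- file.path(path, part)
    isdir <- file.path(pdir, "Inertial Signals")
    if (!dir.exists(isdir))
      stop("UCI-HAR layout: missing directory ", isdir)
    yfile <- file.path(pdir, sprintf("y_%s.txt", part))
    if (!file.exists(yfile))
      stop("UCI-HAR layout: missing label file ", yfile)
    y <- scan(yfile, quiet = TRUE)
    mats <- lapply(channel_files, function(ch) {
      f <- file.path(isdir, sprintf("%s_%s.txt", ch, part))
      if (!file.exists(f)) stop("UCI-HAR layout: missing channel file ", f)
      as.matrix(utils::read.table(f))
    })
    n <- nrow(mats[[1]]); L <- ncol(mats[[1]])
    if (base::length(y) != n)
      stop("UCI-HAR layout: label count does not match window count")
    x <- array(0, dim = c(base::length(channel_files), L, n))
    for (c in seq_along(mats)) x[c, , ] <- t(mats[[c]])
    list(x = x, y = as.character(y))
  }
  tr <- read_part("train"); te <- read_part("test")
  x <- array(0, dim = c(dim(tr$x)[1], dim(tr$x)[2],
                        dim(tr$x)[3] + dim(te$x)[3]))
  x[, , seq_len(dim(tr$x)[3])] <- tr$x
  x[, , dim(tr$x)[3] + seq_len(dim(te$x)[3])] <- te$x
  structure(list(name = "ucihar", x = x, y = c(tr$y, te$y),
                 partition = c(rep("train", base::length(tr$y)),
                               rep("test", base::length(te$y))),
                 channels = channel_files, sample_rate = 50,
                 n_channels = 9, window_len = 128),
            class = "har_dataset")
}

load_uschad <- function(path) {
  subdirs <- list.dirs(path, recursive = FALSE)
  subdirs <- subdirs[grepl("Subject", basename(subdirs))]
  if (base::length(subdirs) == 0)
    stop("USC-HAD layout: no Subject* directories under ", path)
  recs <- list()
  for (sd in subdirs) {
    mats <- list.files(sd, pattern = "\\.mat$", full.names = TRUE)
    for (f in mats) {
      v <- read_mat5(f)
      sig <- v[["sensor_readings"]]
      if (is.null(sig)) {
        message("load_dataset(uschad): no sensor_readings in ", f, "; skipped")
        next
      }
      if (ncol(sig) != 6)
        stop("USC-HAD layout: expected 6 channels in ", f)
      act <- v[["activity_number"]]
      if (is.null(act)) act <- v[["activity"]]
      if (is.null(act)) act <- sub("t[0-9]+\\.mat$", "", basename(f))
      recs[[base::length(recs) + 1L]] <-
        raw_recording(t(sig), sample_rate = 100,
                      subject = basename(sd), activity = as.character(act)[1])
    }
  }
  if (base::length(recs) == 0)
    stop("USC-HAD layout: no readable .mat trials under ", path)
  structure(list(name = "uschad", recordings = recs, sample_rate = 100,
                 n_channels = 6, window_len = 200),
            class = "har_dataset")
}

#' Cache windows to disk and back
#'
#' Stores a window array with labels and partition tags as a single-file
#' container with arrays `windows`, `labels`, `partition`.
#'
#' @param x window array `(channels, length, n)`.
#' @param labels label per window.
#' @param partition partition tag per window.
#' @param file cache path.
#' @return `file` (save) or the restored list (load).
#' @export
save_window_cache <- function(x, labels, partition, file) {
  stopifnot(dim(x)[3] == base::length(labels),
            base::length(labels) == base::length(partition))
  saveRDS(list(windows = x, labels = labels, partition = partition), file)
  invisible(file)
}

#' @rdname save_window_cache
#' @export
load_window_cache <- function(file) readRDS(file)
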