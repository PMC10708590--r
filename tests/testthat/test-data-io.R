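test_that("sliding windows follow the stride arithmetic", {
  rec <- raw_recording(matrix(seq_len(200), 1), 20, "s1", "walk")
  w <- slide_windows(rec, 90, 0)
  expect_length(w, 2)
  expect_equal(vapply(w, function(x) x$origin$offset, numeric(1)), c(0, 90))
  expect_equal(w[[1]]$values[1, ], 1:90)
  expect_equal(w[[2]]$values[1, ], 91:180)
  expect_equal(w[[1]]$label, "walk")

  rec2 <- raw_recording(matrix(rnorm(128), 1), 50, "s", "a")
  expect_length(slide_windows(rec2, 128, 0.5), 1)

  rec3 <- raw_recording(matrix(rnorm(256), 1), 50, "s", "a")
  w3 <- slide_windows(rec3, 128, 0.5)
  expect_length(w3, 3)
  expect_equal(vapply(w3, function(x) x$origin$offset, numeric(1)),
               c(0, 64, 128))
})

test_that("a recording shorter than the window yields an empty warning", {
  rec <- raw_recording(matrix(rnorm(50), 1), 20, "s", "a")
  expect_warning(w <- slide_windows(rec, 90, 0), "shorter")
  expect_length(w, 0)
})

test_that("WISDM rows parse and malformed rows are skipped with a count", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c(
    "33,Jogging,49105962326000,-0.69,12.68,0.50;",
    "33,Jogging,49106062271000,5.01,11.26,0.95;",
    "badline",
    "17,Sitting,100,1.0,2.0,3.0;",
    "17,Sitting,200,not,a,number;"), tf)
  expect_message(ds <- load_dataset("wisdm", tf), "skipped 2")
  expect_s3_class(ds, "har_dataset")
  expect_length(ds$recordings, 2)
  r1 <- ds$recordings[[1]]
  expect_equal(r1$subject, "33")
  expect_equal(r1$activity, "Jogging")
  expect_equal(r1$signal[, 1], c(-0.69, 12.68, 0.50))
  expect_equal(ncol(r1$signal), 2)
})

test_that("missing layouts raise errors naming the missing element", {
  empty <- file.path(tempfile(), "nothing")
  dir.create(empty, recursive = TRUE)
  expect_error(load_dataset("wisdm", empty), "raw file")
  expect_error(load_dataset("ucihar", empty), "Inertial Signals")
  expect_error(load_dataset("uschad", empty), "Subject")
  expect_error(load_dataset("nope", empty))
})

test_that("the UCI-HAR pre-windowed layout is read with fixed channel order", {
  dir <- tempfile()
  set.seed(5)
  made <- make_ucihar_layout(dir, n_train = 4, n_test = 2, L = 16)
  ds <- load_dataset("ucihar", dir)
  expect_equal(dim(ds$x), c(9, 16, 6))
  expect_equal(ds$partition, c(rep("train", 4), rep("test", 2)))
  expect_equal(ds$y, as.character(c(1, 2, 3, 1, 1, 2)))
  # channel 1 is body_acc_x, window 2 of train
  expect_equal(ds$x[1, , 2], unname(made[["train body_acc_x"]][2, ]),
               tolerance = 1e-6)
  # channel 9 is total_acc_z
  expect_equal(ds$x[9, , 5], unname(made[["test total_acc_z"]][1, ]),
               tolerance = 1e-6)
})

test_that("MAT v5 files round-trip through the reader", {
  tf <- tempfile(fileext = ".mat")
  sig <- matrix(rnorm(30), 5, 6)
  write_mat5(list(sensor_readings = sig, activity_number = matrix(7, 1, 1),
                  title = "USC-HAD synthetic trial"), tf)
  v <- read_mat5(tf)
  expect_equal(v$sensor_readings, sig)
  expect_equal(as.numeric(v$activity_number), 7)
  expect_equal(v$title, "USC-HAD synthetic trial")
  # compressed variant
  tfc <- tempfile(fileext = ".mat")
  write_mat5(list(sensor_readings = sig), tfc, compress = TRUE)
  expect_equal(read_mat5(tfc)$sensor_readings, sig)
})

test_that("the reader agrees with files written by an independent tool", {
  dir <- tempfile(); dir.create(dir)
  py <- sprintf("
import numpy as np, scipy.io
x = np.arange(24, dtype=float).reshape(4, 6) / 7.0
scipy.io.savemat('%s/u.mat', {'sensor_readings': x, 'activity_number': 3.0})
scipy.io.savemat('%s/c.mat', {'sensor_readings': x}, do_compression=True)
", dir, dir)
  res <- system2("python", c("-c", shQuote(py)))
  expect_equal(res, 0L)
  want <- matrix(seq(0, 23) / 7, 4, 6, byrow = TRUE)
  expect_equal(read_mat5(file.path(dir, "u.mat"))$sensor_readings, want)
  expect_equal(read_mat5(file.path(dir, "c.mat"))$sensor_readings, want)
})

test_that("the USC-HAD directory layout is assembled into recordings", {
  root <- tempfile()
  for (s in c("Subject1", "Subject2")) {
    dir.create(file.path(root, s), recursive = TRUE)
    for (t in 1:2) {
      write_mat5(list(sensor_readings = matrix(rnorm(60), 10, 6),
                      activity_number = matrix(t, 1, 1)),
                 file.path(root, s, sprintf("a%dt1.mat", t)))
    }
  }
  ds <- load_dataset("uschad", root)
  expect_length(ds$recordings, 4)
  expect_equal(ds$recordings[[1]]$subject, "Subject1")
  expect_equal(nrow(ds$recordings[[1]]$signal), 6)
  expect_equal(ds$sample_rate, 100)
})

test_that("NCD splits partition windows without overlap and stratify", {
  set.seed(6)
  x <- array(rnorm(2 * 8 * 60), dim = c(2, 8, 60))
  y <- rep(c("a", "b", "c", "d"), each = 15)
  s <- make_ncd_split(x, y, known = c("a", "b"), novel = c("c", "d"),
                      test_fraction = 0.2, seed = 4)
  expect_equal(dim(s$labeled_train$x)[3] + dim(s$labeled_test$x)[3], 30)
  expect_equal(sum(s$labeled_test$y == "a"), 3)  # 20% of 15
  expect_equal(sum(s$unlabeled_test$y == "c"), 3)
  # no window in two partitions: fingerprint all windows
  key <- function(a) if (dim(a)[3] == 0) character(0) else
    apply(a, 3, function(w) paste(signif(w, 8), collapse = ","))
  keys <- c(key(s$labeled_train$x), key(s$labeled_test$x),
            key(s$unlabeled_train$x), key(s$unlabeled_test$x))
  expect_equal(anyDuplicated(keys), 0)
  # determinism
  s2 <- make_ncd_split(x, y, c("a", "b"), c("c", "d"), 0.2, seed = 4)
  expect_identical(s, s2)
})

test_that("invalid split requests are rejected", {
  x <- array(rnorm(2 * 4 * 6), dim = c(2, 4, 6))
  y <- c("a", "a", "b", "b", "c", "c")
  expect_error(make_ncd_split(x, y, c("a", "b"), c("b", "c")), "overlap")
  expect_error(make_ncd_split(x, y, "a", "b"), "known or novel")
  y2 <- c("a", "a", "b", "b", "c", "b")
  expect_error(make_ncd_split(x, y2, c("a", "b"), "c"), "fewer than 2")
})

test_that("channel standardization uses labeled-train statistics only", {
  s <- tiny_split(windows_per_class = 20)
  st <- standardize_split(s)
  ref <- st$labeled_train$x
  for (c in 1:2) {
    expect_equal(mean(ref[c, , ]), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(ref[c, , ])), 1, tolerance = 1e-2)
  }
  # test partitions transformed with the same statistics, not their own
  mu <- st$scaling$mean
  expect_equal(st$unlabeled_test$x[1, 1, 1],
               (s$unlabeled_test$x[1, 1, 1] - mu[1]) / st$scaling$sd[1])
})

test_that("window caches round-trip", {
  x <- array(rnorm(24), dim = c(2, 3, 4))
  tf <- tempfile()
  save_window_cache(x, letters[1:4], rep("train", 4), tf)
  got <- load_window_cache(tf)
  expect_equal(got$windows, x)
  expect_equal(got$labels, letters[1:4])
})
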