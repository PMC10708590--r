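# Shared fixtures: everything is generated in code at test time.

# small, fast synthetic split (classes stay well separated)
tiny_split <- function(windows_per_class = 30, noise_sigma = 0.3, seed = 0,
                       window_len = 32) {
  generate_synthetic_split(synthetic_config(
    n_channels = 2, window_len = window_len, n_known_classes = 2,
    n_novel_classes = 2, windows_per_class = windows_per_class,
    noise_sigma = noise_sigma, seed = seed))
}

tiny_encoder <- function(split_channels = 2, window_len = 32,
                         n_known = 2, n_novel = 2) {
  encoder_config(split_channels, window_len, n_known, n_novel,
                 preset = "tiny", conv_filters = c(8, 8),
                 conv_kernels = c(3, 3), conv_strides = c(2, 2),
                 lstm_hidden = 8, feature_dim = 8)
}

# independent scalar-arithmetic oracle for the similarity components,
# written as literal formula transcriptions
oracle_simi <- function(a, b) {
  n <- length(a)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  gow <- 1 - (1 / n) * sum(abs(a / na - b / nb))
  lor <- 1 - sum(log(1 + abs(a - b)))
  dice <- 2 * sum(a * b) / (na + nb)
  jac <- sum(a * b) / (na + nb - abs(sum(a * b)))
  c(gow = gow, lor = lor, dice = dice, jac = jac,
    combined = gow + lor + dice + jac)
}

# brute-force top-k by exhaustive score sort (lower index wins ties)
oracle_knn <- function(query, bank, k, metric) {
  scores <- apply(bank, 1, function(b) {
    if (metric == "cosine") sum(query * b) /
      (sqrt(sum(query^2)) * sqrt(sum(b^2)))
    else unname(oracle_simi(query, b)["combined"])
  })
  order(-scores, seq_len(nrow(bank)))[seq_len(k)]
}

# direct transcription of the contrastive quotient for one query
oracle_contrastive <- function(q, a, bank, pos_idx, include_a, tau) {
  cosv <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  sims <- apply(bank, 1, cosv, y = q)
  sa <- cosv(q, a)
  denom <- exp(sa / tau) + sum(exp(sims / tau))
  terms <- c(if (length(pos_idx)) sims[pos_idx], if (include_a) sa)
  -mean(log(exp(terms / tau) / denom))
}

# minimal MAT v5 writer (little-endian, miDOUBLE matrices and char vectors)
# used to build synthetic .mat fixtures for the reader tests
write_mat5 <- function(vars, path, compress = FALSE) {
  con <- rawConnection(raw(0), "w")
  pad8 <- function(n) (8 - n %% 8) %% 8
  for (nm in names(vars)) {
    v <- vars[[nm]]
    body <- rawConnection(raw(0), "w")
    if (is.character(v)) {
      dat <- utf8ToInt(v)                      # mxCHAR as miUINT16
      writeBin(c(6L, 8L), body, size = 4, endian = "little")
      writeBin(c(4L, 0L), body, size = 4, endian = "little")  # flags: mxCHAR
      writeBin(c(5L, 8L), body, size = 4, endian = "little")
      writeBin(c(1L, length(dat)), body, size = 4, endian = "little")
      writeBin(c(1L, nchar(nm, "bytes")), body, size = 4, endian = "little")
      writeBin(charToRaw(nm), body)
      writeBin(raw(pad8(nchar(nm, "bytes"))), body)
      writeBin(c(4L, 2L * length(dat)), body, size = 4, endian = "little")
      writeBin(as.integer(dat), body, size = 2, endian = "little")
      writeBin(raw(pad8(2 * length(dat))), body)
    } else {
      m <- as.matrix(v)
      writeBin(c(6L, 8L), body, size = 4, endian = "little")
      writeBin(c(6L, 0L), body, size = 4, endian = "little")  # flags: mxDOUBLE
      writeBin(c(5L, 8L), body, size = 4, endian = "little")
      writeBin(dim(m), body, size = 4, endian = "little")
      writeBin(c(1L, nchar(nm, "bytes")), body, size = 4, endian = "little")
      writeBin(charToRaw(nm), body)
      writeBin(raw(pad8(nchar(nm, "bytes"))), body)
      writeBin(c(9L, 8L * length(m)), body, size = 4, endian = "little")
      writeBin(as.numeric(m), body, size = 8, endian = "little")
    }
    el <- rawConnectionValue(body); close(body)
    if (compress) {
      payload <- c(writeBin_raw(c(14L, length(el))), el)
      zz <- memCompress(payload, type = "gzip")
      writeBin(c(15L, length(zz)), con, size = 4, endian = "little")
      writeBin(zz, con)
      writeBin(raw(pad8(length(zz))), con)
    } else {
      writeBin(c(14L, length(el)), con, size = 4, endian = "little")
      writeBin(el, con)
    }
  }
  payload <- rawConnectionValue(con); close(con)
  header <- raw(128)
  txt <- charToRaw("MATLAB 5.0 MAT-file, synthetic test fixture")
  header[seq_along(txt)] <- txt
  header[125:126] <- writeBin_raw(256L, size = 2)      # version 0x0100
  header[127:128] <- charToRaw("IM")                   # little-endian
  writeBin(c(header, payload), path)
  invisible(path)
}

writeBin_raw <- function(x, size = 4) {
  con <- rawConnection(raw(0), "w")
  writeBin(as.integer(x), con, size = size, endian = "little")
  on.exit(close(con))
  rawConnectionValue(con)
}

# tiny UCI-HAR-style directory layout
make_ucihar_layout <- function(dir, n_train = 4, n_test = 2, L = 16) {
  channels <- c("body_acc_x", "body_acc_y", "body_acc_z",
                "body_gyro_x", "body_gyro_y", "body_gyro_z",
                "total_acc_x", "total_acc_y", "total_acc_z")
  made <- list()
  for (part in c("train", "test")) {
    n <- if (part == "train") n_train else n_test
    isdir <- file.path(dir, part, "Inertial Signals")
    dir.create(isdir, recursive = TRUE)
    for (ch in channels) {
      m <- matrix(round(rnorm(n * L), 4), n, L)
      made[[paste(part, ch)]] <- m
      write.table(format(m, digits = 6),
                  file.path(isdir, sprintf("%s_%s.txt", ch, part)),
                  row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
    writeLines(as.character(rep_len(1:3, n)),
               file.path(dir, part, sprintf("y_%s.txt", part)))
  }
  made
}

bind_windows <- function(xs) {
  n <- sum(vapply(xs, function(x) dim(x)[3], numeric(1)))
  out <- array(0, dim = c(dim(xs[[1]])[1], dim(xs[[1]])[2], n))
  i <- 0
  for (x in xs) {
    if (dim(x)[3] == 0) next
    out[, , i + seq_len(dim(x)[3])] <- x
    i <- i + dim(x)[3]
  }
  out
}
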