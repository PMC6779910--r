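# Independent reference implementations and tiny fixture builders used
# across the test files. Everything here is deliberately naive: the oracles
# must not share code paths with the package.

# ---- naive agglomerative clustering ------------------------------------
# Clusters kept as explicit member lists; for single/complete/average the
# inter-cluster dissimilarity is recomputed at every step straight from its
# definition over the ORIGINAL distances. Ward is expressed through the
# Lance-Williams update on a running matrix (its defining recurrence on raw
# dissimilarities), maintained with plain lists.
naive_linkage <- function(D, linkage) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), function(i) i)     # member sets (1-based)
  ids <- seq_len(n) - 1L                            # external node ids
  cur <- D                                          # running dissimilarities (ward)
  heights <- numeric(0)
  partitions <- list()
  merges <- list()
  cluster_diss <- function(a, b) {
    vals <- as.vector(D[clusters[[a]], clusters[[b]]])
    switch(linkage, single = min(vals), complete = max(vals), average = mean(vals))
  }
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        dab <- if (linkage == "ward") cur[a, b] else cluster_diss(a, b)
        key <- sort(c(ids[a], ids[b]))
        if (is.null(best) || dab < best$d - 1e-15 ||
            (abs(dab - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(a = a, b = b, d = dab, key = key)
        }
      }
    }
    a <- best$a
    b <- best$b
    if (linkage == "ward") {
      ni <- length(clusters[[a]])
      nj <- length(clusters[[b]])
      new_row <- vapply(seq_len(m), function(k2) {
        if (k2 %in% c(a, b)) return(NA_real_)
        nk <- length(clusters[[k2]])
        s <- ni + nj + nk
        ((ni + nk) * cur[a, k2] + (nj + nk) * cur[b, k2] - nk * cur[a, b]) / s
      }, numeric(1))
    }
    heights <- c(heights, best$d)
    merges[[step]] <- best$key
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    ids[a] <- n + step - 1L
    if (linkage == "ward") {
      cur[a, ] <- new_row
      cur[, a] <- new_row
      cur <- cur[-b, -b, drop = FALSE]
    }
    clusters <- clusters[-b]
    ids <- ids[-b]
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[step]] <- canon_partition(lab)
  }
  list(heights = heights, partitions = partitions, merges = merges)
}

# canonical labelling: components numbered by first appearance
canon_partition <- function(labels) {
  match(labels, unique(labels))
}

# partition of the package dendrogram after `step` merges
dendro_partition <- function(dendro, step) {
  canon_partition(cut_dendrogram(dendro, dendro$n - step))
}

# ---- rank-based AUC -----------------------------------------------------
# Mann-Whitney statistic with mean ranks for ties.
rank_auc <- function(response, predictor) {
  r <- rank(predictor)
  n1 <- sum(response)
  n0 <- sum(!response)
  (sum(r[response]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- tiny image files ---------------------------------------------------
write_gray_png <- function(m, path) {
  png::writePNG(m, path)
  path
}

write_tiff16 <- function(m, path) {
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  path
}

# minimal uncompressed 24-bit BMP writer (bottom-up rows, BGR, 4-byte pad)
write_bmp24 <- function(rgb, path) {
  h <- dim(rgb)[1]
  w <- dim(rgb)[2]
  row_bytes <- ((w * 3 + 3) %/% 4) * 4
  px <- raw(row_bytes * h)
  pos <- 1L
  for (r in seq(h, 1L)) { # bottom-up
    for (c in seq_len(w)) {
      px[pos:(pos + 2L)] <- as.raw(round(255 * rgb[r, c, 3:1]))
      pos <- pos + 3L
    }
    pos <- pos + (row_bytes - w * 3L)
  }
  le32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256, x %/% 16777216))
  le16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  header <- c(as.raw(c(0x42, 0x4d)), le32(54 + length(px)), as.raw(rep(0, 4)),
              le32(54),
              le32(40), le32(w), le32(h), le16(1), le16(24), le32(0),
              le32(length(px)), le32(2835), le32(2835), le32(0), le32(0))
  writeBin(c(header, px), path)
  path
}

# ---- fixture measurements ----------------------------------------------
# luminance of a generated grayscale PNG
load_luminance <- function(path) {
  img <- load_image(path)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# disc-centred radial masks for ring/diffuse measurements; the centre is
# recovered from the image itself (intensity centroid of the disc mask)
ring_band_stats <- function(L, S) {
  mask <- L > 0.15
  rows <- matrix(rep(seq_len(nrow(L)), times = ncol(L)), nrow(L))
  cols <- matrix(rep(seq_len(ncol(L)), each = nrow(L)), nrow(L))
  cy <- mean(rows[mask])
  cx <- mean(cols[mask])
  r <- sqrt((rows - cy)^2 + (cols - cx)^2)
  r0 <- 0.15 * S
  w <- 0.03 * S
  band <- abs(r - r0) <= w
  interior <- r <= 0.35 * S - 2 & !band
  c(band = mean(L[band]), interior = mean(L[interior]))
}

count_bright_components <- function(L, threshold = 0.5) {
  max(EBImage::bwlabel(L > threshold))
}

# random symmetric distance matrix with zero diagonal
random_distance_matrix <- function(n) {
  m <- matrix(runif(n * n, 0.1, 2), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# quick labelled embedding matrix built from raw values (no image files)
synthetic_embedding <- function(values, labels) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  n <- nrow(values)
  paths <- if (is.null(labels)) {
    file.path(dir, sprintf("img%03d.png", seq_len(n)))
  } else {
    file.path(dir, labels, sprintf("img%03d.png", seq_len(n)))
  }
  tbl <- imagemine:::new_image_table(
    paths, if (is.null(labels)) rep(NA_character_, n) else labels,
    rep(0, n),
    if (is.null(labels)) character() else sort(unique(labels), method = "radix")
  )
  b <- imagemine:::backend_info("synthetic", ncol(values), NA_integer_, FALSE)
  imagemine:::new_embedding_matrix(as.matrix(values), b, tbl)
}

# two well-separated gaussian clouds, labelled A/B
separable_embedding <- function(n_per_class = 10, d = 4, gap = 10, seed = 42) {
  set.seed(seed)
  values <- rbind(
    matrix(rnorm(n_per_class * d), n_per_class, d),
    matrix(rnorm(n_per_class * d, mean = gap), n_per_class, d)
  )
  synthetic_embedding(values, rep(c("A", "B"), each = n_per_class))
}
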