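# Embedding backends: turn each image into a fixed-length feature vector.
#
# Deep backends (penultimate-layer activations of pre-trained convolutional
# networks) sit behind a uniform adapter contract and require a locally
# supplied model; the built-in "filterbank" backend is a deterministic
# hand-crafted-feature profiler that needs no model file and anchors all
# offline testing.

the_registry <- new.env(parent = emptyenv())

backend_info <- function(name, feature_dim, input_size, requires_external_model,
                         embed_fun = NULL, preprocess = "bilinear resize to input_size, RGB in [0,1]") {
  structure(list(name = name, feature_dim = feature_dim,
                 input_size = input_size,
                 requires_external_model = requires_external_model,
                 embed_fun = embed_fun, preprocess = preprocess),
            class = "backend_info")
}

register_default_backends <- function() {
  # Penultimate-layer dims: InceptionV3 is 2048 by construction; the other
  # deep backends take their dimensionality from the supplied model file,
  # so it is unknown (NA) until an adapter is attached.
  the_registry$inceptionv3 <- backend_info("inceptionv3", 2048L, 299L, TRUE)
  the_registry$squeezenet <- backend_info("squeezenet", NA_integer_, 227L, TRUE)
  the_registry$vgg16 <- backend_info("vgg16", NA_integer_, 224L, TRUE)
  the_registry$vgg19 <- backend_info("vgg19", NA_integer_, 224L, TRUE)
  the_registry$filterbank <- backend_info(
    "filterbank", 96L, 128L, FALSE, embed_fun = filterbank_embed,
    preprocess = "bilinear resize to 128x128, luminance 0.299R+0.587G+0.114B"
  )
}

.onLoad <- function(libname, pkgname) {
  register_default_backends()
}

#' List registered embedding backends
#'
#' @return A data frame with one row per backend: `name`, `feature_dim`
#'   (`NA` for deep backends whose dimensionality comes from the model file
#'   of a not-yet-attached adapter), `input_size` and
#'   `requires_external_model`.
#' @export
list_backends <- function() {
  names <- sort_bytewise(ls(the_registry))
  # stable, curated order: built-in last-resort-free backend first is not
  # required; keep registry in name order for determinism
  do.call(rbind, lapply(names, function(nm) {
    b <- the_registry[[nm]]
    data.frame(name = b$name, feature_dim = b$feature_dim,
               input_size = b$input_size,
               requires_external_model = b$requires_external_model,
               stringsAsFactors = FALSE)
  }))
}

#' Look up one embedding backend
#'
#' @param name Backend name, e.g. `"inceptionv3"` or `"filterbank"`.
#' @return The `backend_info` entry.
#' @export
get_backend <- function(name) {
  b <- the_registry[[name]]
  if (is.null(b)) {
    abort_input(sprintf("unknown embedding backend '%s' (registered: %s)",
                        name, paste(sort_bytewise(ls(the_registry)), collapse = ", ")))
  }
  b
}

#' Attach a local model adapter to a deep embedding backend
#'
#' Deep backends embed an image as the penultimate-layer activation vector
#' of a pre-trained network. This package does not ship network weights;
#' instead an adapter closure — "given a decoded image resized to
#' `input_size`, return the activation vector" — is attached to a registry
#' entry, typically wrapping an ONNX or similar runtime over a locally
#' supplied model file.
#'
#' @param name Registered backend name.
#' @param embed_fun Function taking a `height x width x 3` array in `[0,1]`
#'   and returning a numeric vector.
#' @param feature_dim Length of the returned vector; required if the
#'   registry entry does not already know it.
#' @return The updated `backend_info`, invisibly.
#' @export
register_backend_adapter <- function(name, embed_fun, feature_dim = NULL) {
  b <- get_backend(name)
  if (!is.function(embed_fun)) abort_input("`embed_fun` must be a function")
  b$embed_fun <- embed_fun
  if (!is.null(feature_dim)) {
    stopifnot_count(feature_dim, "feature_dim", min = 1L)
    b$feature_dim <- as.integer(feature_dim)
  }
  if (is.na(b$feature_dim)) {
    abort_input(sprintf(
      "backend '%s' has unknown feature_dim; pass `feature_dim` (taken from the model file)", name))
  }
  the_registry[[name]] <- b
  invisible(b)
}

#' Register a new embedding backend
#'
#' @inheritParams register_backend_adapter
#' @param input_size Square input side in pixels the adapter expects.
#' @param requires_external_model Whether the backend depends on a locally
#'   supplied model file.
#' @return The new `backend_info`, invisibly.
#' @export
register_backend <- function(name, feature_dim, input_size, embed_fun = NULL,
                             requires_external_model = is.null(embed_fun)) {
  stopifnot_count(feature_dim, "feature_dim", min = 1L)
  b <- backend_info(name, as.integer(feature_dim), input_size,
                    requires_external_model, embed_fun)
  the_registry[[name]] <- b
  invisible(b)
}

# ---- filter-bank embedder ----------------------------------------------

# Bilinear resize of one channel to size x size (EBImage treats the first
# array dimension as x; with square targets and no transposition this keeps
# row/column semantics of the input).
resize_channel <- function(m, size) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  as.matrix(EBImage::resize(m, w = size, h = size, filter = "bilinear"))
}

# Gradients by central differences with replicated borders.
image_gradients <- function(L) {
  h <- nrow(L)
  w <- ncol(L)
  gx <- (L[, c(2:w, w)] - L[, c(1, 1:(w - 1))]) / 2
  gy <- (L[c(2:h, h), ] - L[c(1, 1:(h - 1)), ]) / 2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

orientation_hist <- function(gr, nbins = 16L) {
  total <- sum(gr$mag)
  if (total == 0) return(numeric(nbins)) # constant image: all-zero by convention
  theta <- atan2(gr$gy, gr$gx)                   # (-pi, pi]
  bin <- pmin(floor((theta + pi) / (2 * pi) * nbins) + 1L, nbins)
  h <- vapply(seq_len(nbins), function(b) sum(gr$mag[bin == b]), numeric(1))
  h / total
}

downsample2 <- function(L) {
  h <- 2L * (nrow(L) %/% 2L)
  w <- 2L * (ncol(L) %/% 2L)
  L <- L[seq_len(h), seq_len(w)]
  (L[seq(1L, h, 2L), seq(1L, w, 2L)] + L[seq(2L, h, 2L), seq(1L, w, 2L)] +
    L[seq(1L, h, 2L), seq(2L, w, 2L)] + L[seq(2L, h, 2L), seq(2L, w, 2L)]) / 4
}

#' Deterministic filter-bank image embedding (96 features)
#'
#' A hand-crafted whole-image profiler combining intensity, gradient and
#' radial structure, in this fixed order:
#' \itemize{
#'   \item 32-bin luminance histogram, normalized to sum 1;
#'   \item gradient-orientation histograms (16 bins, weighted by gradient
#'     magnitude) at full resolution and after 2x block downsampling, each
#'     normalized to sum 1 (all-zero for constant images);
#'   \item radial mean-luminance profile over 24 equal-width annuli from the
#'     image center to half the image diagonal;
#'   \item 8 scalars: mean, (population) sd, skewness and excess kurtosis of
#'     luminance; Shannon entropy (nats) of the 32-bin histogram; edge
#'     density (fraction of pixels with gradient magnitude > 0.1); ring
#'     contrast (max annulus mean minus mean of annulus means); and the
#'     distance of the intensity centroid from the geometric center,
#'     normalized by the image side.
#' }
#' The image is first bilinearly resized to 128 x 128 and converted to
#' luminance `0.299 R + 0.587 G + 0.114 B`. On a constant image the sd is 0
#' and skewness/kurtosis are defined as 0.
#'
#' @param img A `height x width x 3` array in `[0, 1]` (see [load_image()]).
#' @return Numeric vector of length 96.
#' @export
filterbank_embed <- function(img) {
  size <- 128L
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3L] == 1L) img <- array(img[, , 1L], c(dim(img)[1:2], 3L))
  L <- 0.299 * resize_channel(img[, , 1L], size) +
    0.587 * resize_channel(img[, , 2L], size) +
    0.114 * resize_channel(img[, , 3L], size)
  L[L < 0] <- 0
  L[L > 1] <- 1

  # 32-bin luminance histogram
  bin <- pmin(floor(L * 32) + 1L, 32L)
  hist32 <- tabulate(bin, nbins = 32L) / length(L)

  # gradient-orientation histograms at two scales
  gr <- image_gradients(L)
  ohist_full <- orientation_hist(gr)
  ohist_half <- orientation_hist(image_gradients(downsample2(L)))

  # radial profile: 24 equal-width annuli, center to half the diagonal
  cy <- (nrow(L) + 1) / 2
  cx <- (ncol(L) + 1) / 2
  row_i <- matrix(rep(seq_len(nrow(L)), times = ncol(L)), nrow(L))
  col_i <- matrix(rep(seq_len(ncol(L)), each = nrow(L)), nrow(L))
  r <- sqrt((row_i - cy)^2 + (col_i - cx)^2)
  rmax <- sqrt(nrow(L)^2 + ncol(L)^2) / 2
  rbin <- pmin(floor(r / rmax * 24) + 1L, 24L)
  radial <- vapply(seq_len(24L), function(b) {
    inb <- rbin == b
    if (any(inb)) mean(L[inb]) else 0
  }, numeric(1))

  # scalar summaries
  m <- mean(L)
  s <- sqrt(mean((L - m)^2))
  if (s > 0) {
    z <- (L - m) / s
    skew <- mean(z^3)
    kurt <- mean(z^4) - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  p <- hist32[hist32 > 0]
  entropy <- -sum(p * log(p))
  edge_density <- mean(gr$mag > 0.1)
  ring_contrast <- max(radial) - mean(radial)
  total <- sum(L)
  centroid_offset <- if (total > 0) {
    sqrt((sum(L * row_i) / total - cy)^2 + (sum(L * col_i) / total - cx)^2) / size
  } else 0

  c(hist32, ohist_full, ohist_half, radial,
    m, s, skew, kurt, entropy, edge_density, ring_contrast, centroid_offset)
}

# ---- embedding a whole table -------------------------------------------

new_embedding_matrix <- function(values, backend, table) {
  stopifnot(nrow(values) == nrow(table))
  colnames(values) <- sprintf("f%04d", seq_len(ncol(values)))
  structure(list(values = values, backend = backend, table = table),
            class = "embedding_matrix")
}

#' @method print embedding_matrix
#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d images x %d features (backend: %s)\n",
              nrow(x$values), ncol(x$values), x$backend$name))
  invisible(x)
}

#' Embed every image of a table as a feature vector
#'
#' Runs the named backend over each record of `table`, row `i` of the result
#' describing record `i` (row alignment is the contract every downstream
#' matrix relies on). With `cache_dir` set, vectors are keyed by the SHA-256
#' of the file bytes plus the backend name and recomputed only for unseen
#' keys, so re-embedding an unchanged image set is free; cached and fresh
#' vectors are bit-identical.
#'
#' @param table An `image_table`.
#' @param backend Backend name (see [list_backends()]); default
#'   `"filterbank"`, the built-in model-free profiler.
#' @param cache_dir Optional directory for the embedding cache.
#' @param verbose Log cache hits and progress via [message()].
#' @return An `embedding_matrix` (fields `values`, `backend`, `table`), with
#'   attribute `n_computed` counting vectors actually computed (as opposed
#'   to served from cache).
#' @export
embed_images <- function(table, backend = "filterbank", cache_dir = NULL,
                         verbose = FALSE) {
  b <- get_backend(backend)
  if (is.null(b$embed_fun)) {
    abort_input(sprintf(
      paste0("backend '%s' requires an external model file; supply one and ",
             "attach it with register_backend_adapter(\"%s\", embed_fun, ",
             "feature_dim) before embedding"), b$name, b$name))
  }
  n <- nrow(table)
  if (n == 0L) abort_input("cannot embed an empty image table")
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  }
  rows <- vector("list", n)
  n_computed <- 0L
  for (i in seq_len(n)) {
    path <- table$path[[i]]
    cache_file <- NULL
    if (!is.null(cache_dir)) {
      key <- digest::digest(path, algo = "sha256", file = TRUE)
      cache_file <- file.path(cache_dir, sprintf("%s-%s.rds", b$name, key))
      if (file.exists(cache_file)) {
        rows[[i]] <- readRDS(cache_file)
        if (verbose) message(sprintf("cache hit: %s", path))
        next
      }
    }
    v <- as.numeric(b$embed_fun(load_image(path)))
    if (!is.na(b$feature_dim) && length(v) != b$feature_dim) {
      abort(sprintf("backend '%s' returned %d features for '%s', expected %d",
                    b$name, length(v), path, b$feature_dim))
    }
    if (!all(is.finite(v))) {
      abort(sprintf("backend '%s' produced non-finite features for '%s'",
                    b$name, path))
    }
    n_computed <- n_computed + 1L
    if (!is.null(cache_file)) saveRDS(v, cache_file)
    rows[[i]] <- v
  }
  values <- do.call(rbind, rows)
  out <- new_embedding_matrix(values, b, table)
  attr(out, "n_computed") <- n_computed
  out
}

# subset rows of an embedding, keeping the full class universe of the table
subset_embedding <- function(E, rows) {
  out <- new_embedding_matrix(E$values[rows, , drop = FALSE], E$backend,
                              subset_image_table(E$table, rows))
  out
}

#' Write an embedding matrix to CSV
#'
#' Columns `image_path,label,f0001..f{d}`, one row per image in table order.
#'
#' @param E An `embedding_matrix`.
#' @param out Output CSV path.
#' @return `out`, invisibly.
#' @export
write_embedding_csv <- function(E, out) {
  df <- data.frame(image_path = E$table$path, label = E$table$label,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(E$values))
  write.csv(df, out, row.names = FALSE, na = "")
  invisible(out)
}

#' Read an embedding matrix from CSV
#'
#' Inverse of [write_embedding_csv()]; accepts any CSV whose first two
#' columns are `image_path,label` followed by numeric feature columns.
#'
#' @param path CSV path.
#' @param backend_name Name recorded as provenance (default `"csv"`).
#' @return An `embedding_matrix`.
#' @export
read_embedding_csv <- function(path, backend_name = "csv") {
  if (!file.exists(path)) abort_input(sprintf("no such embeddings file: '%s'", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3L || !identical(colnames(df)[1:2], c("image_path", "label"))) {
    abort_input(sprintf("'%s' is not an embedding CSV (image_path,label,f...)", path))
  }
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    abort_input(sprintf("non-finite feature values in '%s'", path))
  }
  label <- as.character(df$label)
  label[!is.na(label) & label == ""] <- NA_character_
  tbl <- new_image_table(df$image_path, label,
                         ifelse(file.exists(df$image_path), file.size(df$image_path), NA_real_),
                         sort_bytewise(unique(label[!is.na(label)])))
  b <- backend_info(backend_name, ncol(values), NA_integer_, FALSE)
  new_embedding_matrix(values, b, tbl)
}
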