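# Pairwise dissimilarities between embedded images.

new_distance_matrix <- function(values, metric, table) {
  stopifnot(nrow(values) == ncol(values), nrow(values) == nrow(table))
  diag(values) <- 0
  values <- (values + t(values)) / 2 # enforce exact symmetry
  values[values < 0] <- 0            # clamp negative rounding residue
  if (!all(is.finite(values))) abort("non-finite entries in distance matrix")
  structure(list(values = values, metric = metric, table = table),
            class = "distance_matrix")
}

#' @method print distance_matrix
#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d x %d (%s)\n",
              nrow(x$values), ncol(x$values), x$metric))
  invisible(x)
}

#' Pairwise distances between embedded images
#'
#' Cosine distance `1 - (u . v) / (|u||v|)` — the default throughout the
#' package, scale-invariant and well suited to high-dimensional embedding
#' vectors — or plain euclidean distance. The result keeps the source image
#' table so clustering/projection selections can be traced back to images.
#'
#' @param E An `embedding_matrix` (or plain numeric matrix).
#' @param metric `"cosine"` or `"euclidean"`.
#' @return A `distance_matrix`: symmetric `n x n` values with zero
#'   diagonal, plus `metric` and the source `table`.
#' @export
pairwise_distances <- function(E, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (inherits(E, "embedding_matrix")) {
    V <- E$values
    table <- E$table
  } else {
    V <- as.matrix(E)
    table <- new_image_table(sprintf("row%04d", seq_len(nrow(V))),
                             rep(NA_character_, nrow(V)), rep(NA_real_, nrow(V)),
                             character())
  }
  if (metric == "cosine") {
    norms <- sqrt(rowSums(V^2))
    if (any(norms == 0)) {
      bad <- table$path[which(norms == 0)[1L]]
      abort_input(sprintf(
        "cosine distance undefined for zero-norm feature vector of '%s'", bad))
    }
    D <- 1 - (V %*% t(V)) / outer(norms, norms)
    D[D > 2] <- 2 # numerical guard; cosine distance is bounded by 2
  } else {
    D <- as.matrix(dist(V, method = "euclidean"))
  }
  new_distance_matrix(unname(D), metric, table)
}

#' Write a distance matrix to CSV
#'
#' Square matrix with image paths as header row and first column.
#'
#' @param D A `distance_matrix`.
#' @param out Output CSV path.
#' @return `out`, invisibly.
#' @export
write_distance_csv <- function(D, out) {
  m <- D$values
  dimnames(m) <- list(D$table$path, D$table$path)
  write.csv(as.data.frame(m, check.names = FALSE), out, row.names = TRUE)
  invisible(out)
}
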