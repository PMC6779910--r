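# Metric multidimensional scaling into the plane by SMACOF stress
# majorization, the "projection" view of an image set.

#' Project a distance matrix into 2-D by stress majorization
#'
#' Metric MDS minimizing the raw stress
#' \deqn{\sigma(X) = \sum_{i<j} (d_{ij}(X) - \delta_{ij})^2}
#' over planar configurations `X`, where `delta` are the input
#' dissimilarities and `d(X)` the embedded euclidean distances. Starting
#' from classical scaling (double-centered Gram eigendecomposition, via
#' [stats::cmdscale()]) or a seeded random configuration, the SMACOF
#' Guttman transform is iterated; raw stress is non-increasing across
#' iterations by construction, and iteration stops when the relative stress
#' decrease drops below `tol` or after `max_iter` iterations.
#'
#' An all-zero distance matrix is a degenerate but valid input: all points
#' are placed at the origin with zero stress.
#'
#' @param D A `distance_matrix` (or plain symmetric matrix), `n >= 2`.
#' @param max_iter Maximum majorization iterations (default 300).
#' @param tol Relative raw-stress decrease below which iteration stops
#'   (default 1e-6).
#' @param seed Seed for the random initialization (default 0; unused with
#'   classical init on well-posed inputs).
#' @param init `"classical"` (default) or `"random"`.
#' @return An `mds_projection`: `coords` (`n x 2`), `stress_raw`, `stress1`
#'   (Kruskal stress-1, `sqrt(stress_raw / sum(delta^2))`), `n_iter`, and
#'   the source `table`.
#' @export
mds_project <- function(D, max_iter = 300L, tol = 1e-6, seed = 0L,
                        init = c("classical", "random")) {
  init <- match.arg(init)
  if (!inherits(D, "distance_matrix")) {
    D <- new_distance_matrix(as.matrix(D), "custom",
                             new_image_table(sprintf("row%04d", seq_len(nrow(as.matrix(D)))),
                                             rep(NA_character_, nrow(as.matrix(D))),
                                             rep(NA_real_, nrow(as.matrix(D))), character()))
  }
  stopifnot_count(max_iter, "max_iter", min = 1L)
  if (!is.numeric(tol) || tol <= 0) abort_input("`tol` must be > 0")
  delta <- D$values
  n <- nrow(delta)
  if (n < 2L) abort_input("MDS needs at least 2 images")
  upper <- upper.tri(delta)
  ss_delta <- sum(delta[upper]^2)

  if (ss_delta == 0) { # all-zero input: all points coincide, stress 0
    return(new_mds_projection(matrix(0, n, 2L), 0, 0, 0L, D$table))
  }

  X <- if (init == "classical") {
    cs <- tryCatch(cmdscale(delta, k = 2L), error = function(e) NULL)
    if (is.null(cs) || nrow(cs) != n) {
      set.seed(seed)
      matrix(rnorm(n * 2L, sd = mean(delta[upper])), n, 2L)
    } else if (ncol(cs) < 2L) {
      cbind(cs, matrix(0, n, 2L - ncol(cs)))
    } else {
      cs
    }
  } else {
    set.seed(seed)
    matrix(rnorm(n * 2L, sd = mean(delta[upper])), n, 2L)
  }

  raw_stress <- function(X) {
    d <- as.matrix(dist(X))
    sum((d[upper] - delta[upper])^2)
  }
  stress <- raw_stress(X)
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    d <- as.matrix(dist(X))
    ratio <- matrix(0, n, n)
    pos <- d > 0
    ratio[pos] <- delta[pos] / d[pos]
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X_new <- (B %*% X) / n # Guttman transform (unit weights)
    stress_new <- raw_stress(X_new)
    n_iter <- it
    improved <- (stress - stress_new) / max(stress, .Machine$double.eps)
    X <- X_new
    stress <- stress_new
    if (improved < tol) break
  }
  new_mds_projection(X, stress, sqrt(stress / ss_delta), n_iter, D$table)
}

new_mds_projection <- function(coords, stress_raw, stress1, n_iter, table) {
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, stress_raw = stress_raw, stress1 = stress1,
                 n_iter = n_iter, table = table),
            class = "mds_projection")
}

#' @method print mds_projection
#' @export
print.mds_projection <- function(x, ...) {
  cat(sprintf("<mds_projection> %d points, stress-1 = %.4g (%d iterations)\n",
              nrow(x$coords), x$stress1, x$n_iter))
  invisible(x)
}

#' Flag which projected points belong to a subset
#'
#' The programmatic analogue of highlighting a data subset in a projection
#' plot: given a subset of the projection's source table (e.g. the output of
#' [select_branch()] or [select_cell()]), returns one logical per point.
#'
#' @param result An `mds_projection` (or any object with a `table` field).
#' @param subset An `image_table` whose records all come from the source
#'   table.
#' @return Logical vector, `TRUE` where the point's record is in `subset`.
#' @export
mark_subset <- function(result, subset) {
  table <- result$table
  keys <- table$path
  sub_keys <- subset$path
  missing <- setdiff(sub_keys, keys)
  if (length(missing)) {
    abort_input(sprintf("subset contains records foreign to the projection: %s",
                        paste(utils::head(missing, 3), collapse = ", ")))
  }
  keys %in% sub_keys
}

#' Write MDS coordinates to CSV
#'
#' Columns `image_path,label,x,y`, preceded by a comment line recording the
#' Kruskal stress-1 of the configuration.
#'
#' @param proj An `mds_projection`.
#' @param out Output CSV path.
#' @return `out`, invisibly.
#' @export
write_projection_csv <- function(proj, out) {
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(sprintf("# stress1 = %.10g", proj$stress1), con)
  df <- data.frame(image_path = proj$table$path, label = proj$table$label,
                   x = proj$coords[, 1L], y = proj$coords[, 2L],
                   stringsAsFactors = FALSE)
  write.csv(df, con, row.names = FALSE, na = "")
  invisible(out)
}
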