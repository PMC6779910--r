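# Synthetic labelled image sets emulating the class structure of two
# bioimage case studies: nuclear chromatin organized as a perinucleolar ring
# versus dispersed foci (two classes), and aggregate morphologies of
# developing amoebae (three classes). The generators are first-class,
# deterministic, and strong enough that the downstream pipeline separates
# the classes — they are the offline stand-in for real image sets.

#' Specify a synthetic image set
#'
#' @param kind `"ring_diffuse"` (two classes, `SN`/`NSN`) or `"aggregates"`
#'   (three classes, `STR`/`LAG`/`TAG`).
#' @param n_per_class Images per class (>= 1).
#' @param image_size Side of the square images in pixels (>= 32).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   intensity units on `[0, 1]`.
#' @param seed Integer seed; a single seeded generator drives all per-image
#'   randomness in file order, so a fixed spec reproduces byte-identical
#'   files.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(kind = c("ring_diffuse", "aggregates"),
                         n_per_class, image_size = 128L, noise_sd = 0.05,
                         seed = 0L) {
  kind <- match.arg(kind)
  stopifnot_count(n_per_class, "n_per_class", min = 1L)
  stopifnot_count(image_size, "image_size", min = 32L)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    abort_input("`noise_sd` must be a single nonnegative number")
  }
  stopifnot_count(abs(seed), "seed")
  structure(list(kind = kind, n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Pixel-center coordinate grids for a square field.
fixture_grid <- function(S) {
  xx <- matrix(rep(seq_len(S), each = S), S, S) # column index
  yy <- matrix(rep(seq_len(S), times = S), S, S) # row index
  list(x = xx, y = yy)
}

finish_fixture_image <- function(img, noise_sd, path) {
  if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
  img[img < 0] <- 0
  img[img > 1] <- 1
  # 8-bit grayscale PNG: quantization here is the only lossy step
  png::writePNG(img, path)
}

#' Generate a two-class ring-versus-dispersed nuclear image set
#'
#' Emulates chromatin phenotyping of fully grown oocytes: every image holds
#' one bright "nucleus" disc (radius ~0.35 of the image side, jittered
#' center) on a dark field. In the `SN` class the extra chromatin intensity
#' is concentrated in a thin annulus (Gaussian radial profile, center radius
#' ~0.15, width ~0.03 of the image side) surrounding the nucleolus; in the
#' `NSN` class the same total intensity budget is dispersed into 6–10
#' broad Gaussian foci (sd ~0.08 of the image side) scattered through the
#' outer nucleoplasm, outward of the perinucleolar annulus — dispersed
#' chromatin that does not surround the nucleolus. Images are written as 8-bit grayscale PNGs under `out/NSN`
#' and `out/SN` and rescanned into an [image_table][scan_image_directory].
#'
#' @param spec A [fixture_spec()] with `kind = "ring_diffuse"`.
#' @param out Output directory (created if needed).
#' @return The `image_table` of the generated set.
#' @export
generate_ring_diffuse_set <- function(spec, out) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$kind != "ring_diffuse") {
    abort_input("`spec$kind` must be 'ring_diffuse'")
  }
  S <- spec$image_size
  g <- fixture_grid(S)
  set.seed(spec$seed)
  # classes visited in file (lexicographic) order: NSN before SN
  for (cls in c("NSN", "SN")) {
    dir.create(file.path(out, cls), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(file.path(out, cls))) {
      abort(sprintf("cannot create output directory '%s'", file.path(out, cls)))
    }
    for (i in seq_len(spec$n_per_class)) {
      img <- render_ring_diffuse(cls, S, g)
      finish_fixture_image(img, spec$noise_sd,
                           file.path(out, cls, sprintf("%s_%04d.png", cls, i)))
    }
  }
  scan_image_directory(out)
}

render_ring_diffuse <- function(cls, S, g) {
  cx <- S / 2 + runif(1, -0.03, 0.03) * S
  cy <- S / 2 + runif(1, -0.03, 0.03) * S
  r <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  R <- 0.35 * S           # nucleus radius
  r0 <- 0.15 * S          # annulus center radius
  w <- 0.03 * S           # annulus width
  img <- 0.05 + 0.25 * (r <= R) # dark field + nucleus disc
  ring <- 0.55 * exp(-(r - r0)^2 / (2 * w^2))
  if (cls == "SN") {
    img + ring
  } else {
    # NSN: same intensity budget, dispersed into broad foci in the outer
    # nucleoplasm, outward of the perinucleolar band (chromatin not
    # surrounding the nucleolus). Broad foci keep the class homogeneous:
    # individual placements average out instead of dominating the profile.
    budget <- sum(ring)
    k <- sample(6:10, 1L)
    sd_blob <- 0.08 * S
    centers <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      repeat {
        px <- cx + runif(1, -R, R)
        py <- cy + runif(1, -R, R)
        d <- sqrt((px - cx)^2 + (py - cy)^2)
        if (d <= R - 2 * w && d >= r0 + 3 * w) break
      }
      centers[j, ] <- c(px, py)
    }
    blobs <- matrix(0, S, S)
    for (j in seq_len(k)) {
      d2 <- (g$x - centers[j, 1L])^2 + (g$y - centers[j, 2L])^2
      blobs <- blobs + exp(-d2 / (2 * sd_blob^2))
    }
    img + blobs * (budget / sum(blobs))
  }
}

#' Generate a three-class aggregate-morphology image set
#'
#' Emulates developmental stages of aggregating amoebae: `STR` (streaming)
#' images contain 3–5 bright piecewise-linear streams (random-walk
#' polylines, ~2 px wide); `LAG` (loose aggregate) images scatter 20–30
#' small discs (radius 2–4 px) over the field; `TAG` (tight aggregate)
#' images hold 2–4 large compact discs (radius ~0.12 of the image side).
#' Images are written as 8-bit grayscale PNGs under `out/STR`, `out/LAG`,
#' `out/TAG` and rescanned.
#'
#' @inheritParams generate_ring_diffuse_set
#' @param spec A [fixture_spec()] with `kind = "aggregates"`.
#' @return The `image_table` of the generated set.
#' @export
generate_aggregate_set <- function(spec, out) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$kind != "aggregates") abort_input("`spec$kind` must be 'aggregates'")
  S <- spec$image_size
  g <- fixture_grid(S)
  set.seed(spec$seed)
  # file order: LAG, STR, TAG
  for (cls in c("LAG", "STR", "TAG")) {
    dir.create(file.path(out, cls), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(file.path(out, cls))) {
      abort(sprintf("cannot create output directory '%s'", file.path(out, cls)))
    }
    for (i in seq_len(spec$n_per_class)) {
      img <- render_aggregate(cls, S, g)
      finish_fixture_image(img, spec$noise_sd,
                           file.path(out, cls, sprintf("%s_%04d.png", cls, i)))
    }
  }
  scan_image_directory(out)
}

render_aggregate <- function(cls, S, g) {
  img <- matrix(0.05, S, S)
  add_disc <- function(img, cx, cy, radius, amp = 0.8) {
    d <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
    img + amp * (d <= radius)
  }
  if (cls == "LAG") {
    n <- sample(20:30, 1L)
    for (i in seq_len(n)) {
      img <- add_disc(img, runif(1, 5, S - 5), runif(1, 5, S - 5),
                      runif(1, 2, 4))
    }
  } else if (cls == "TAG") {
    n <- sample(2:4, 1L)
    R <- 0.12 * S
    for (i in seq_len(n)) {
      img <- add_disc(img, runif(1, R + 2, S - R - 2), runif(1, R + 2, S - R - 2), R)
    }
  } else { # STR: random-walk polylines of width ~2 px
    n <- sample(3:5, 1L)
    for (i in seq_len(n)) {
      x <- runif(1, 0.1 * S, 0.9 * S)
      y <- runif(1, 0.1 * S, 0.9 * S)
      heading <- runif(1, 0, 2 * pi)
      stream <- matrix(0, S, S)
      for (seg in seq_len(8L)) {
        len <- 0.1 * S
        x2 <- x + len * cos(heading)
        y2 <- y + len * sin(heading)
        stream <- pmax(stream, segment_mask(g, x, y, x2, y2, half_width = 1))
        x <- x2
        y <- y2
        heading <- heading + runif(1, -0.6, 0.6)
      }
      img <- img + 0.8 * stream
    }
  }
  pmin(img, 1)
}

# 0/1 mask of pixels within `half_width` of the segment (x1,y1)-(x2,y2)
segment_mask <- function(g, x1, y1, x2, y2, half_width = 1) {
  vx <- x2 - x1
  vy <- y2 - y1
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(pmax(((g$x - x1) * vx + (g$y - y1) * vy) / len2, 0), 1)
  d2 <- (g$x - (x1 + t * vx))^2 + (g$y - (y1 + t * vy))^2
  (d2 <= half_width^2) * 1
}

#' Generate a synthetic image set from a spec
#'
#' Dispatches on `spec$kind` to [generate_ring_diffuse_set()] or
#' [generate_aggregate_set()].
#'
#' @inheritParams generate_ring_diffuse_set
#' @return The `image_table` of the generated set.
#' @export
generate_fixture_set <- function(spec, out) {
  switch(spec$kind,
    ring_diffuse = generate_ring_diffuse_set(spec, out),
    aggregates = generate_aggregate_set(spec, out)
  )
}
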