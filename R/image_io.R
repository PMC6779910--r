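# Image-set loading with directory-as-label semantics.

IMAGE_EXTENSIONS <- c("png", "jpg", "jpeg", "tif", "tiff", "bmp")

new_image_table <- function(path, label, size_bytes, class_values) {
  stopifnot(length(path) == length(label), length(path) == length(size_bytes))
  df <- data.frame(
    id = seq_along(path) - 1L,
    path = path,
    label = label,
    size_bytes = as.numeric(size_bytes),
    stringsAsFactors = FALSE
  )
  structure(df,
    class_values = as.character(class_values),
    class = c("image_table", "data.frame")
  )
}

#' Class labels of an image table
#'
#' @param table An `image_table`.
#' @return Character vector of distinct class labels, lexicographically
#'   sorted; empty when the table is unlabeled.
#' @export
class_values <- function(table) {
  attr(table, "class_values") %||% character()
}

#' @method print image_table
#' @export
print.image_table <- function(x, ...) {
  cv <- class_values(x)
  cat(sprintf(
    "<image_table> %d images, %s\n", nrow(x),
    if (length(cv)) paste0(length(cv), " classes: ", paste(cv, collapse = ", "))
    else "unlabeled"
  ))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Keep the image_table contract when subsetting rows: ids are re-assigned to
# 0..n-1 (position within the table is the alignment key downstream), the
# original class universe is retained.
subset_image_table <- function(table, rows) {
  df <- as.data.frame(table)[rows, , drop = FALSE]
  new_image_table(df$path, df$label, df$size_bytes, class_values(table))
}

#' Scan a directory tree into an image table
#'
#' Collects every file with a recognized image extension (`.png`, `.jpg`,
#' `.jpeg`, `.tif`, `.tiff`, `.bmp`, case-insensitive) under `root`, sorted
#' lexicographically (byte-wise) by relative path so that repeated scans are
#' reproducible across machines and locales. The name of the first-level
#' subdirectory containing a file becomes its class label — the usual layout
#' for curated image sets where, e.g., `SN/` and `NSN/` hold the two
#' phenotypes. Files directly under `root` are unlabeled; deeper nesting is
#' flattened into the first-level label.
#'
#' @param root Directory to scan.
#' @param recursive Descend into subdirectories (default `TRUE`). With
#'   `FALSE` only files directly under `root` are listed (all unlabeled).
#' @return An `image_table`: a data frame with columns `id` (0-based row
#'   index), `path`, `label` (`NA` when unlabeled) and `size_bytes`, plus a
#'   `class_values` attribute holding the sorted distinct labels.
#' @examples
#' \dontrun{
#' tbl <- scan_image_directory("oocytes/")
#' class_values(tbl)  # e.g. "NSN" "SN"
#' }
#' @export
scan_image_directory <- function(root, recursive = TRUE) {
  if (length(root) != 1L || !dir.exists(root)) {
    abort_input(sprintf("image directory does not exist: '%s'", root))
  }
  rel <- list.files(root, recursive = recursive, full.names = FALSE,
                    include.dirs = FALSE)
  ext <- tolower(tools::file_ext(rel))
  rel <- sort_bytewise(rel[ext %in% IMAGE_EXTENSIONS])
  if (length(rel) == 0L) {
    abort_input(sprintf("no images with recognized extensions (%s) under '%s'",
                        paste0(".", IMAGE_EXTENSIONS, collapse = " "), root))
  }
  parts <- strsplit(rel, "/", fixed = TRUE)
  label <- vapply(parts, function(p) if (length(p) > 1L) p[[1L]] else NA_character_,
                  character(1))
  path <- file.path(root, rel)
  new_image_table(path, label, file.size(path),
                  sort_bytewise(unique(label[!is.na(label)])))
}

#' Decode one image to a normalized pixel array
#'
#' Decodes PNG, JPEG, TIFF or uncompressed BMP into an `height x width x 3`
#' numeric array with intensities in `[0, 1]`. Integer images are rescaled by
#' their bit-depth maximum (255 or 65535), grayscale is replicated across the
#' three channels, and any alpha channel is dropped. Of a multi-page TIFF
#' only the first page is used (with a warning).
#'
#' @param x An `image_table` row (1-row data frame), or a file path.
#' @return Numeric array `c(height, width, 3)`, values in `[0, 1]`.
#' @export
load_image <- function(x) {
  path <- if (is.character(x)) x[[1L]] else x$path[[1L]]
  if (!file.exists(path)) {
    abort_input(sprintf("image file does not exist: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      tif = ,
      tiff = {
        pages <- tiff::readTIFF(path, all = TRUE)
        if (length(pages) > 1L) {
          warning(sprintf("multi-page TIFF '%s': using first page only", path))
        }
        pages[[1L]]
      },
      bmp = read_bmp(path),
      abort_input(sprintf("unrecognized image extension: '%s'", path))
    ),
    error = function(e) {
      abort(sprintf("cannot decode image '%s': %s", path, conditionMessage(e)),
            class = "imagemine_decode_error")
    }
  )
  as_pixel_array(raw)
}

# Normalize decoder output (matrix or 3-d array, values already in [0,1])
# to height x width x 3: replicate grayscale, drop alpha.
as_pixel_array <- function(raw) {
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  nc <- dim(raw)[3L]
  img <- if (nc == 1L) {
    array(raw[, , 1L], c(dim(raw)[1:2], 3L))
  } else if (nc == 2L) { # gray + alpha
    array(raw[, , 1L], c(dim(raw)[1:2], 3L))
  } else {
    raw[, , 1:3, drop = FALSE] # RGB or RGBA with alpha dropped
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Write an image table to a metadata CSV
#'
#' One row per record, in table order, with columns `image_path,label`
#' (`label` empty for unlabeled records). Round-trips exactly: reading the
#' CSV back reproduces the `(path, label)` pairs.
#'
#' @param table A nonempty `image_table`.
#' @param out Output CSV path.
#' @return `out`, invisibly.
#' @export
write_metadata_table <- function(table, out) {
  if (nrow(table) == 0L) abort_input("cannot write an empty image table")
  df <- data.frame(image_path = table$path, label = table$label,
                   stringsAsFactors = FALSE)
  tryCatch(
    write.csv(df, out, row.names = FALSE, na = ""),
    error = function(e) abort(sprintf("cannot write '%s': %s", out,
                                      conditionMessage(e)))
  )
  invisible(out)
}
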