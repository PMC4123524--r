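# Image and result-table input/output.
#
# Internal numeric model: intensities are kept as float64 on their native
# range [0, L] (L = dynamic range, 255 for 8-bit data); they are never
# rescaled to [0, 1] because the structural-similarity stabilizing constants
# are defined relative to the dynamic range. Coordinates are (row, col) with
# row 1 at the top of the raster.

#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of pixel intensities together with its
#' declared dynamic range `L` (the maximum representable intensity). All
#' values must lie in `[0, L]`.
#'
#' @param pixels Numeric matrix of intensities (rows x cols).
#' @param dynamic_range Maximum representable intensity `L` (default 255).
#' @return An object of class `gray_image` with fields `pixels` and
#'   `dynamic_range`.
#' @examples
#' img <- gray_image(matrix(0:24 * 10, 5, 5), dynamic_range = 255)
#' dim(img)
#' @export
gray_image <- function(pixels, dynamic_range = 255) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("`pixels` must be a numeric matrix")
  if (length(pixels) == 0L)
    stopf("zero-sized image")
  if (!is_scalar_num(dynamic_range) || dynamic_range <= 0)
    stopf("`dynamic_range` must be a positive scalar")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stopf("pixel values must be finite")
  if (min(pixels) < 0 || max(pixels) > dynamic_range)
    stopf("pixel values must lie in [0, %s]", format(dynamic_range))
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, dynamic_range = as.numeric(dynamic_range)),
            class = "gray_image")
}

#' Coerce to a gray_image
#'
#' @param x A `gray_image` or numeric matrix.
#' @param dynamic_range Dynamic range used when `x` is a plain matrix.
#' @return A `gray_image`.
#' @export
as_gray_image <- function(x, dynamic_range = 255) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(as.matrix(x), dynamic_range)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, dynamic range [0, %s], intensities [%s, %s]\n",
              nrow(x$pixels), ncol(x$pixels), format(x$dynamic_range),
              format(min(x$pixels)), format(max(x$pixels))))
  invisible(x)
}

#' Validate a binary edge map
#'
#' Edge maps are plain logical matrices (`TRUE` = edge pixel). This checks
#' type and, optionally, that the shape matches the annotated image.
#'
#' @param mask Logical matrix (numeric matrices are coerced, nonzero = edge).
#' @param expected_shape Optional integer vector `c(rows, cols)`.
#' @return A logical matrix.
#' @export
as_edge_map <- function(mask, expected_shape = NULL) {
  if (!is.matrix(mask)) stopf("edge map must be a matrix")
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stopf("edge map must be logical or numeric")
  if (anyNA(mask)) stopf("edge map must not contain NA")
  if (!is.null(expected_shape) && !identical(dim(mask), as.integer(expected_shape)))
    stopf("edge map shape (%d x %d) does not match expected shape (%d x %d)",
          nrow(mask), ncol(mask), expected_shape[1], expected_shape[2])
  mask
}

pnm_space <- as.raw(c(9L, 10L, 11L, 12L, 13L, 32L))

# Parse PGM/PBM (P1, P2, P4, P5) from disk. Returns list(pixels, maxval).
read_pnm <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 2) stopf("cannot read PNM file: %s", path)
  raw <- readBin(path, "raw", n = sz)
  n <- length(raw)
  pos <- 1L
  next_token <- function() {
    repeat {
      while (pos <= n && raw[pos] %in% pnm_space) pos <<- pos + 1L
      if (pos <= n && raw[pos] == as.raw(35L)) { # '#' comment to end of line
        while (pos <= n && !(raw[pos] %in% as.raw(c(10L, 13L)))) pos <<- pos + 1L
      } else break
    }
    if (pos > n) stopf("truncated PNM header: %s", path)
    start <- pos
    while (pos <= n && !(raw[pos] %in% pnm_space)) pos <<- pos + 1L
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P1", "P2", "P4", "P5"))
    stopf("unsupported PNM magic '%s' in %s", magic, path)
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    stopf("invalid PNM dimensions in %s", path)
  maxval <- if (magic %in% c("P2", "P5")) as.integer(next_token()) else 1L
  data <- switch(magic,
    P1 = {
      txt <- rawToChar(raw[pos:n])
      txt <- gsub("#[^\n]*", "", txt)
      bits <- strsplit(gsub("[^01]", "", txt), "")[[1]]
      as.integer(bits)
    },
    P2 = {
      txt <- rawToChar(raw[pos:n])
      txt <- gsub("#[^\n]*", "", txt)
      as.integer(scan(text = txt, what = integer(), quiet = TRUE))
    },
    P4 = {
      pos <- pos + 1L # single whitespace after header
      bpr <- ceiling(w / 8)
      need <- bpr * h
      if (pos + need - 1L > n) stopf("truncated P4 data in %s", path)
      bytes <- as.integer(raw[pos:(pos + need - 1L)])
      bits <- matrix(0L, nrow = h, ncol = bpr * 8L)
      for (b in 0:7) bits[, seq(8L - b, bpr * 8L, by = 8L)] <- bitwAnd(bytes, bitwShiftL(1L, b)) > 0
      as.integer(t(bits[, seq_len(w), drop = FALSE]))
    },
    P5 = {
      pos <- pos + 1L
      bps <- if (maxval > 255L) 2L else 1L
      need <- w * h * bps
      if (pos + need - 1L > n) stopf("truncated P5 data in %s", path)
      bytes <- as.integer(raw[pos:(pos + need - 1L)])
      if (bps == 2L) bytes <- bytes[c(TRUE, FALSE)] * 256L + bytes[c(FALSE, TRUE)]
      bytes
    })
  if (length(data) < w * h) stopf("PNM pixel data shorter than %d x %d in %s", h, w, path)
  px <- matrix(as.numeric(data[seq_len(w * h)]), nrow = h, ncol = w, byrow = TRUE)
  list(pixels = px, maxval = as.numeric(maxval))
}

# snap floating-point dust from decoders that normalize to [0, 1]
snap_intensities <- function(px) round(px, 9)

collapse_channels <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  nc <- dim(a)[3]
  if (nc == 2L) return(a[, , 1]) # gray + alpha
  if (nc >= 3L) { # RGB(+alpha): unweighted channel mean
    return((a[, , 1] + a[, , 2] + a[, , 3]) / 3)
  }
  a[, , 1]
}

#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM/PBM rasters into a [gray_image]. Multi-channel
#' (RGB) inputs are collapsed by the unweighted channel mean; alpha channels
#' are dropped. PNG intensities are restored to the native `[0, L]` scale.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.pgm` or `.pbm` file.
#' @param dynamic_range Dynamic range `L` of the stored data. Defaults to
#'   255 for PNG/TIFF (pass 65535 for 16-bit PNGs); for PGM the header's
#'   `maxval` is authoritative and this argument is ignored.
#' @return A [gray_image].
#' @export
read_gray_image <- function(path, dynamic_range = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    L <- if (is.null(dynamic_range)) 255 else dynamic_range
    a <- collapse_channels(png::readPNG(path))
    return(gray_image(snap_intensities(a * L), L))
  }
  if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE)
    a <- collapse_channels(a)
    if (max(a) <= 1 && !all(a == round(a))) { # float TIFF normalized to [0,1]
      L <- if (is.null(dynamic_range)) 255 else dynamic_range
      return(gray_image(snap_intensities(a * L), L))
    }
    L <- if (!is.null(dynamic_range)) dynamic_range else if (max(a) > 255) 65535 else 255
    return(gray_image(a + 0, L))
  }
  if (ext %in% c("pgm", "pbm", "pnm")) {
    p <- read_pnm(path)
    return(gray_image(p$pixels, p$maxval))
  }
  stopf("unsupported image format '.%s' (%s)", ext, path)
}

#' Write a grayscale image
#'
#' Writes PNG (8-bit), TIFF or ASCII PGM (`P2`). PGM stores rounded integer
#' intensities with the image's dynamic range as `maxval`, so integer-valued
#' images round-trip losslessly.
#'
#' @param image A [gray_image] (or numeric matrix).
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image$pixels / image$dynamic_range, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image$pixels / image$dynamic_range, where = path)
  } else if (ext == "pgm") {
    maxval <- max(1L, round(image$dynamic_range))
    vals <- as.integer(round(t(image$pixels))) # raster scan order
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(image$pixels), nrow(image$pixels)),
                 sprintf("%d", maxval)), con)
    writeLines(apply(matrix(sprintf("%d", vals), nrow = ncol(image$pixels)), 2,
                     paste, collapse = " "), con)
  } else {
    stopf("unsupported output format '.%s' (%s)", ext, path)
  }
  invisible(path)
}

#' Read a binary edge map
#'
#' Decodes a raster and marks every nonzero stored value as an edge pixel.
#'
#' @param path Path to PNG/TIFF/PGM/PBM file.
#' @param expected_shape Optional `c(rows, cols)`; a mismatch is an error
#'   naming both shapes.
#' @return Logical matrix (`TRUE` = edge).
#' @export
read_edge_map <- function(path, expected_shape = NULL) {
  img <- read_gray_image(path)
  as_edge_map(img$pixels != 0, expected_shape)
}

#' Write a binary edge map
#'
#' PNG output stores edges as white (1.0); `.pbm` output is ASCII `P1` with
#' bit 1 on edge pixels.
#'
#' @param mask Logical matrix.
#' @param path Output path (`.png` or `.pbm`).
#' @return `path`, invisibly.
#' @export
write_edge_map <- function(mask, path) {
  mask <- as_edge_map(mask)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(mask * 1, target = path)
  } else if (ext == "pbm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P1", sprintf("%d %d", ncol(mask), nrow(mask))), con)
    writeLines(apply(matrix(as.character(as.integer(t(mask))), nrow = ncol(mask)), 2,
                     paste, collapse = " "), con)
  } else {
    stopf("unsupported edge-map format '.%s' (%s)", ext, path)
  }
  invisible(path)
}

result_table_columns <- c("candidate_id", "Ne", "MGSSIM", "penalty", "NREM")

#' Assemble a result table
#'
#' Builds the canonical score table (one row per scored candidate) from a
#' list of [nrem_score()] results.
#'
#' @param results List of `nrem_result` objects.
#' @return A `data.frame` with columns `candidate_id`, `Ne`, `MGSSIM`,
#'   `penalty`, `NREM`, of class `result_table`.
#' @export
result_table <- function(results = list()) {
  ids <- vapply(results, function(r) as.character(r$candidate_id), character(1))
  if (anyDuplicated(ids)) stopf("duplicate candidate_id in result table")
  tab <- data.frame(
    candidate_id = ids,
    Ne = vapply(results, function(r) as.numeric(r$ne), numeric(1)),
    MGSSIM = vapply(results, function(r) r$mgssim, numeric(1)),
    penalty = vapply(results, function(r) r$penalty, numeric(1)),
    NREM = vapply(results, function(r) r$nrem, numeric(1)),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("result_table", "data.frame")
  tab
}

#' Write a result table as CSV
#'
#' Floats are printed with 17 significant digits so that a round-trip
#' through [read_result_table()] recovers identical doubles.
#'
#' @param table A `result_table` (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(result_table_columns, collapse = ","), con)
  if (nrow(table) > 0) {
    rows <- sprintf("%s,%.17g,%.17g,%.17g,%.17g",
                    table$candidate_id, table$Ne, table$MGSSIM,
                    table$penalty, table$NREM)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path CSV path.
#' @return A `result_table` data frame.
#' @export
read_result_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(candidate_id = "character"))
  class(tab) <- c("result_table", "data.frame")
  tab
}

#' Write a result table as JSON
#'
#' @param table A `result_table`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(table, path) {
  jsonlite::write_json(as.data.frame(table), path, dataframe = "rows",
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}
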