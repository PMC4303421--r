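# ---------------------------------------------------------------------------
# Readers and writers: PNG/TIFF/JPEG images, numbered frame sequences, and
# plain-text signal files with optional header/unit lines.
#
# PNG and TIFF round-trip 8/16-bit grey and 24-bit RGB losslessly; JPEG is
# read-faithful but lossy on write (documented).  The installed PNG writer
# only emits 8-bit files, so 16-bit greyscale PNG output uses a minimal
# built-in encoder (uncompressed-strategy zlib via memCompress + CRC32).
# ---------------------------------------------------------------------------

# --- CRC32 (table-driven), needed for PNG chunks ---------------------------

# 32-bit xor on doubles (values may exceed .Machine$integer.max)
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8)
          c <- if (c %% 2 == 1) xor32(3988292384, c %/% 2) else c %/% 2
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- 4294967295
  for (x in as.integer(bytes))
    crc <- xor32(tab[bitwXor(as.integer(crc %% 256), x) + 1L], crc %/% 256)
  4294967295 - crc  # final xor with 0xffffffff
}

u32be <- function(x) {
  as.raw(c(floor(x / 16777216) %% 256, floor(x / 65536) %% 256,
           floor(x / 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

# Minimal 16-bit greyscale PNG writer (filter 0 scanlines, zlib IDAT).
write_png16_grey <- function(pixels, path) {
  M <- nrow(pixels); N <- ncol(pixels)
  v <- as.vector(t(pixels))                 # row-major scanlines
  hi <- as.raw(floor(v / 256)); lo <- as.raw(v %% 256)
  samples <- as.vector(rbind(hi, lo))       # big-endian sample bytes
  rows <- matrix(samples, nrow = 2L * N, ncol = M)
  scan <- as.raw(rbind(matrix(as.raw(0), 1L, M), rows))  # filter byte 0
  idat <- memCompress(as.raw(scan), type = "gzip")       # zlib stream
  ihdr <- c(u32be(N), u32be(M), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L ||
      !identical(as.integer(hdr[1:8]), c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)))
    return(NULL)
  list(bit_depth = as.integer(hdr[25]), color_type = as.integer(hdr[26]))
}

file_ext_lower <- function(path) tolower(tools::file_ext(path))

# --- images ----------------------------------------------------------------

#' Read an image file
#'
#' Supports PNG and TIFF (8/16-bit grey, 24-bit RGB; lossless) and JPEG
#' (decoded via EBImage).  The sample model is inferred from the file.
#'
#' @param path Image path; the format is chosen by extension.
#' @return An `image_item`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop_format(sprintf("image file '%s' does not exist", path))
  ext <- file_ext_lower(path)
  name <- tools::file_path_sans_ext(basename(path))
  arr <- switch(ext,
    png = {
      info <- png_bit_depth(path)
      if (is.null(info))
        stop_format(sprintf("'%s' is not a valid PNG file", path))
      a <- tryCatch(png::readPNG(path), error = function(e)
        stop_format(sprintf("failed to decode PNG '%s': %s", path,
                            conditionMessage(e))))
      L <- if (info$bit_depth == 16L) 65535 else 255
      round(a * L)
    },
    tif = ,
    tiff = {
      a <- tryCatch(suppressWarnings(
        tiff::readTIFF(path, as.is = TRUE, info = TRUE)),
        error = function(e)
          stop_format(sprintf("failed to decode TIFF '%s': %s", path,
                              conditionMessage(e))))
      # as.is is honoured only for some layouts; when the decoder fell
      # back to normalized [0, 1] values, rescale by the recorded depth
      if (max(a) <= 1 &&
          identical(as.vector(a),
                    as.vector(suppressWarnings(tiff::readTIFF(path))))) {
        bits <- attr(a, "bits.per.sample") %||% 8L
        a2 <- round(a * (2^bits - 1))
        attributes(a2) <- attributes(a)
        a <- a2
      }
      a
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop_format("JPEG decoding requires the EBImage package")
      img <- tryCatch(EBImage::readImage(path), error = function(e)
        stop_format(sprintf("failed to decode JPEG '%s': %s", path,
                            conditionMessage(e))))
      a <- as.array(img)
      a <- if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
      round(a * 255)
    },
    stop_format(sprintf("unsupported image extension '.%s' for '%s'", ext,
                        path)))
  d <- dim(arr)
  if (length(d) == 3L) {
    if (d[3] >= 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(arr)[3] == 1L) {
      arr <- arr[, , 1L]
    } else if (dim(arr)[3] == 2L) {
      arr <- arr[, , 1L]                                # grey + alpha
    }
  }
  if (is.matrix(arr)) {
    depth16 <- switch(ext,
      png = png_bit_depth(path)$bit_depth == 16L,
      tif = ,
      tiff = isTRUE(attr(arr, "bits.per.sample") == 16L),
      FALSE)
    attributes(arr) <- list(dim = dim(arr))
    image_item(arr, if (depth16) "grey16" else "grey8",
               name = name, source_path = path)
  } else {
    attributes(arr) <- list(dim = dim(arr))
    image_item(arr, "rgb24", name = name, source_path = path)
  }
}

#' Write an image file
#'
#' PNG and TIFF preserve all sample models losslessly (16-bit greyscale PNG
#' through the built-in encoder).  JPEG writing is lossy and provided for
#' interoperability only.
#'
#' @param image An `image_item`.
#' @param path Destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (!inherits(image, "image_item"))
    stop_parameter("write_image requires an image item")
  ext <- file_ext_lower(path)
  px <- image$pixels
  L <- sample_model_max(image$sample_model)
  switch(ext,
    png = {
      if (image$sample_model == "grey16") write_png16_grey(px, path)
      else png::writePNG(px / L, path)
    },
    tif = ,
    tiff = {
      bits <- if (image$sample_model == "grey16") 16L else 8L
      tiff::writeTIFF(px / L, path, bits.per.sample = bits,
                      compression = "none")
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop_format("JPEG writing requires the EBImage package")
      a <- if (image$sample_model == "rgb24") aperm(px / L, c(2L, 1L, 3L))
           else t(px / L)
      EBImage::writeImage(EBImage::Image(a,
        colormode = if (image$sample_model == "rgb24") "Color" else "Grayscale"),
        path, quality = 90L)
    },
    stop_format(sprintf("unsupported image extension '.%s'", ext)))
  invisible(path)
}

# --- numbered sequences ----------------------------------------------------

natural_index <- function(paths) {
  nums <- regmatches(basename(paths), gregexpr("[0-9]+", basename(paths)))
  vapply(nums, function(n)
    if (length(n) == 0L) NA_real_ else as.numeric(n[length(n)]), 0)
}

#' Read a numbered frame sequence from a directory
#'
#' Files are ordered by the numeric run index in their names (natural
#' sort: `img_2` before `img_10`), not lexicographically.
#'
#' @param dir Directory containing the frames.
#' @param pattern Regular expression filter (default: PNG/TIFF/JPEG files).
#' @return List of `image_item`s in frame order.
#' @export
read_sequence <- function(dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$") {
  paths <- list.files(dir, pattern = pattern, full.names = TRUE,
                      ignore.case = TRUE)
  if (length(paths) == 0L)
    stop_not_found(sprintf("no files matching '%s' under '%s'", pattern, dir))
  idx <- natural_index(paths)
  paths <- paths[order(idx, paths)]
  lapply(paths, read_image)
}

#' Write images as a numbered sequence
#'
#' Emits `prefix_0000.<format>`, `prefix_0001.<format>`, ... (running file
#' index, zero-padded to 4 digits).
#'
#' @param items List of `image_item`s.
#' @param dir Destination directory (created if needed).
#' @param prefix Filename prefix.
#' @param format `"png"` (default) or `"tiff"`.
#' @return Character vector of written paths, invisibly.
#' @export
write_sequence <- function(items, dir, prefix = "out", format = "png") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%04d.%s", prefix,
                                  seq_along(items) - 1L, format))
  for (i in seq_along(items)) write_image(item_payload(items[[i]]), paths[i])
  invisible(paths)
}

# --- plain-text signals ----------------------------------------------------

#' Plain-text signal file dialect
#'
#' @param comment_prefix Lines starting with this are skipped (default "#").
#' @param header Are a name line and a unit line present?  `"auto"`
#'   detects them (non-numeric first fields), `TRUE`/`FALSE` force.
#' @param delimiter `"whitespace"` or `","`.
#' @return A `signal_dialect` list.
#' @export
signal_dialect <- function(comment_prefix = "#", header = "auto",
                           delimiter = "whitespace") {
  structure(list(comment_prefix = comment_prefix, header = header,
                 delimiter = delimiter),
            class = "signal_dialect")
}

split_fields <- function(line, dialect) {
  if (identical(dialect$delimiter, "whitespace"))
    strsplit(trimws(line), "[ \t]+")[[1]]
  else
    trimws(strsplit(line, dialect$delimiter, fixed = TRUE)[[1]])
}

#' Read signals from a plain-text file
#'
#' Columns are signals.  An optional header line supplies names and an
#' optional second header line supplies units; `columns` selects a subset.
#'
#' @param path File path.
#' @param dialect A [signal_dialect()].
#' @param columns Optional column indices to load.
#' @return List of `signal_item`s.
#' @export
read_signal <- function(path, dialect = signal_dialect(), columns = NULL) {
  if (!file.exists(path))
    stop_format(sprintf("signal file '%s' does not exist", path))
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), dialect$comment_prefix) &
    nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop_format(sprintf("signal file '%s' contains no data", path))
  fields <- lapply(lines, split_fields, dialect = dialect)
  is_numeric_row <- function(f) !anyNA(suppressWarnings(as.numeric(f)))
  nms <- NULL; units <- NULL
  header <- dialect$header
  take_header <- if (identical(header, "auto")) !is_numeric_row(fields[[1]])
                 else isTRUE(header)
  if (take_header) {
    nms <- fields[[1]]; fields <- fields[-1]; lineno <- lineno[-1]
    if (length(fields) > 0L && !is_numeric_row(fields[[1]])) {
      units <- fields[[1]]; fields <- fields[-1]; lineno <- lineno[-1]
    }
  }
  if (length(fields) == 0L)
    stop_format(sprintf("signal file '%s' has headers but no data", path))
  nc <- length(fields[[1]])
  for (i in seq_along(fields))
    if (length(fields[[i]]) != nc)
      stop_format(sprintf(
        "line %d of '%s' has %d fields, expected %d", lineno[i], path,
        length(fields[[i]]), nc))
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = nc,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop_format(sprintf("line %d of '%s' has non-numeric data", lineno[bad],
                        path))
  }
  sel <- columns %||% seq_len(nc)
  if (any(sel < 1L | sel > nc))
    stop_parameter(sprintf("column selection outside 1..%d", nc))
  lapply(sel, function(j) signal_item(
    m[, j],
    unit = if (!is.null(units)) units[j] else NULL,
    name = if (!is.null(nms)) nms[j] else sprintf("col%d", j)))
}

#' Write signals to a plain-text file
#'
#' Writes a name line, a unit line when any signal carries a unit, and one
#' row per sample.  `read_signal()` of the result restores values, names
#' and units.
#'
#' @param signals A `signal_item` or list of equal-length `signal_item`s.
#' @param path Destination path.
#' @param dialect A [signal_dialect()].
#' @return `path`, invisibly.
#' @export
write_signal <- function(signals, path, dialect = signal_dialect()) {
  if (inherits(signals, "signal_item")) signals <- list(signals)
  lens <- vapply(signals, length, 1L)
  if (length(unique(lens)) != 1L)
    stop_parameter("all signals in one file must have equal length")
  sep <- if (identical(dialect$delimiter, "whitespace")) " "
         else dialect$delimiter
  nms <- vapply(signals, function(s) gsub("[ \t,]", "_", s$name), "")
  units <- vapply(signals, function(s) s$unit %||% "1", "")
  vals <- do.call(cbind, lapply(signals, `[[`, "values"))
  rows <- apply(vals, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = sep))
  lines <- c(paste(nms, collapse = sep))
  if (any(vapply(signals, function(s) !is.null(s$unit), TRUE)))
    lines <- c(lines, paste(units, collapse = sep))
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Write a table item as CSV
#' @param table A `table_item`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table$data, path, row.names = FALSE)
  invisible(path)
}
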