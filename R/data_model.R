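# ---------------------------------------------------------------------------
# Typed data items: images, signals, tables, and their tagged union.
#
# Coordinate convention (used everywhere in the package): (row, col),
# 0-based, row 0 at the top of the image.  Pixel matrices are stored in the
# native R orientation pixels[row + 1, col + 1].
# ---------------------------------------------------------------------------

SAMPLE_MODELS <- c("grey8", "grey16", "rgb24")

#' Maximum intensity of a sample model
#'
#' @param sample_model One of `"grey8"`, `"grey16"`, `"rgb24"`.
#' @return Top of the intensity range (255 or 65535; 255 per band for RGB).
#' @export
sample_model_max <- function(sample_model) {
  switch(sample_model,
    grey8 = 255, grey16 = 65535, rgb24 = 255,
    stop_parameter(sprintf("unknown sample model '%s'", sample_model))
  )
}

#' Create an image item
#'
#' An image item holds a 2-D grid of unsigned integer intensities together
#' with its sample model.  Greyscale images are `M x N` matrices; 24-bit RGB
#' images are `M x N x 3` arrays.  The sample model is fixed at
#' construction; conversions (e.g. [convert_to_grey()]) return new items.
#'
#' @param pixels Numeric matrix (grey) or `M x N x 3` array (rgb24) of
#'   integer intensities within the sample model's range.
#' @param sample_model `"grey8"`, `"grey16"` or `"rgb24"`.
#' @param name Display name.
#' @param source_path Optional path the image was loaded from.
#' @return An object of class `image_item`.
#' @export
image_item <- function(pixels, sample_model = "grey8", name = "image",
                       source_path = NULL) {
  if (!sample_model %in% SAMPLE_MODELS)
    stop_parameter(sprintf("unknown sample model '%s'", sample_model))
  if (sample_model == "rgb24") {
    if (!(is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L))
      stop_parameter("rgb24 image requires an M x N x 3 array")
  } else {
    if (!is.matrix(pixels))
      stop_parameter(sprintf("%s image requires an M x N matrix", sample_model))
  }
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop_parameter("image must have M >= 1 rows and N >= 1 columns")
  L <- sample_model_max(sample_model)
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > L || any(pixels != floor(pixels)))
    stop_parameter(sprintf(
      "intensities must be integers in [0, %d] for sample model %s", L,
      sample_model))
  structure(
    list(pixels = pixels, sample_model = sample_model, name = name,
         source_path = source_path),
    class = "image_item")
}

#' @export
print.image_item <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_item '%s' %dx%d %s>\n", x$name, d[1], d[2],
              x$sample_model))
  invisible(x)
}

#' @export
dim.image_item <- function(x) dim(x$pixels)[1:2]

is_grey <- function(image) image$sample_model %in% c("grey8", "grey16")

check_grey <- function(image, what = "operator") {
  if (!inherits(image, "image_item"))
    stop_validation(sprintf("%s requires an image item", what))
  if (!is_grey(image))
    stop_validation(sprintf(
      "%s requires a single-band grey value image (got %s)", what,
      image$sample_model))
  invisible(image)
}

#' Create a signal item
#'
#' A signal is an ordered sequence of real numbers, optionally annotated
#' with a unit and a sampling interval (e.g. minutes per sample).
#'
#' @param values Numeric vector, length >= 1.
#' @param unit Optional unit string.
#' @param name Display name.
#' @param sample_interval Optional positive sampling interval.
#' @return An object of class `signal_item`.
#' @export
signal_item <- function(values, unit = NULL, name = "signal",
                        sample_interval = NULL) {
  if (length(values) < 1L || !is.numeric(values))
    stop_parameter("signal requires a numeric vector of length >= 1")
  if (!is.null(sample_interval) &&
      (!is.numeric(sample_interval) || sample_interval <= 0))
    stop_parameter("sample_interval must be a positive real")
  structure(
    list(values = as.numeric(values), unit = unit, name = name,
         sample_interval = sample_interval),
    class = "signal_item")
}

#' @export
print.signal_item <- function(x, ...) {
  cat(sprintf("<signal_item '%s' n=%d%s>\n", x$name, length(x$values),
              if (is.null(x$unit)) "" else paste0(" [", x$unit, "]")))
  invisible(x)
}

#' @export
length.signal_item <- function(x) length(x$values)

#' Create a table item
#'
#' @param column_names Character vector of column names.
#' @param rows List of equal-length row tuples (or a data.frame).
#' @param name Display name.
#' @return An object of class `table_item`.
#' @export
table_item <- function(column_names, rows = list(), name = "table") {
  if (is.data.frame(rows)) {
    df <- rows
    names(df) <- column_names
  } else {
    nc <- length(column_names)
    if (length(rows) > 0L) {
      bad <- which(vapply(rows, length, 1L) != nc)
      if (length(bad) > 0L)
        stop_parameter(sprintf(
          "row %d has %d fields, expected %d", bad[1],
          length(rows[[bad[1]]]), nc))
      df <- as.data.frame(do.call(rbind, lapply(rows, function(r)
        as.data.frame(as.list(r), col.names = column_names))))
      names(df) <- column_names
    } else {
      df <- as.data.frame(matrix(nrow = 0, ncol = nc,
                                 dimnames = list(NULL, column_names)))
    }
  }
  structure(list(data = df, name = name), class = "table_item")
}

#' @export
print.table_item <- function(x, ...) {
  cat(sprintf("<table_item '%s' %d x %d>\n", x$name, nrow(x$data),
              ncol(x$data)))
  invisible(x)
}

#' Create a data item (tagged union of image / signal / table)
#'
#' Data items are the unit of stack processing.  A *virtual* item has been
#' flushed to disk (see [virtualize()]) and carries only a store reference;
#' its payload is restored on demand by [materialize()].
#'
#' @param payload An `image_item`, `signal_item` or `table_item`.
#' @return An object of class `data_item` with fields `kind`, `payload`,
#'   `virtual`, `store_ref`.
#' @export
data_item <- function(payload) {
  kind <- if (inherits(payload, "image_item")) "image"
          else if (inherits(payload, "signal_item")) "signal"
          else if (inherits(payload, "table_item")) "table"
          else stop_parameter("payload must be an image, signal or table item")
  structure(list(kind = kind, payload = payload, virtual = FALSE,
                 store_ref = NULL),
            class = "data_item")
}

#' @export
print.data_item <- function(x, ...) {
  cat(sprintf("<data_item kind=%s%s>\n", x$kind,
              if (x$virtual) paste0(" virtual @", x$store_ref) else ""))
  invisible(x)
}

as_data_item <- function(x) {
  if (inherits(x, "data_item")) x else data_item(x)
}

# Extract the in-memory payload regardless of virtualization state.
item_payload <- function(x) {
  if (inherits(x, "data_item")) {
    if (x$virtual) materialize(x)$payload else x$payload
  } else x
}

# ---------------------------------------------------------------------------
# Virtualization: flush payloads to a store directory (payload container +
# JSON metadata sidecar), restore them bit-exactly on demand.
# ---------------------------------------------------------------------------

#' Flush a data item to disk ("virtual" mode)
#'
#' Serializes the item's payload to a file under `store_dir` together with a
#' JSON metadata sidecar, and returns a copy with `virtual = TRUE` and an
#' empty payload slot.  Virtualizing an already-virtual item is a no-op.
#' The round trip `materialize(virtualize(x))` restores the payload
#' bit-exactly for all three item kinds.
#'
#' @param item A `data_item` (or bare payload, which is wrapped).
#' @param store_dir Writable directory for the serialized form.
#' @return The virtualized `data_item`.
#' @seealso [materialize()]
#' @export
virtualize <- function(item, store_dir = virtual_store_dir()) {
  item <- as_data_item(item)
  if (isTRUE(item$virtual)) return(item)
  if (!dir.exists(store_dir))
    dir.create(store_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(store_dir) || file.access(store_dir, 2L) != 0L)
    stop_storage(sprintf("store directory '%s' is not writable", store_dir))
  # A process-wide counter (not the RNG) names store files, so virtual mode
  # never perturbs seeded computations.
  n <- (.stackops_state$store_counter %||% 0L) + 1L
  .stackops_state$store_counter <- n
  stem <- file.path(store_dir, sprintf("item-%s-%06d-%d", item$kind, n,
                                       Sys.getpid()))
  payload_file <- paste0(stem, ".rds")
  meta_file <- paste0(stem, ".json")
  ok <- tryCatch({
    saveRDS(item$payload, payload_file)
    meta <- list(kind = item$kind,
                 name = item$payload$name,
                 class = class(item$payload),
                 payload_file = basename(payload_file))
    if (item$kind == "image") {
      meta$dims <- dim(item$payload$pixels)
      meta$sample_model <- item$payload$sample_model
    }
    if (item$kind == "signal") {
      meta$n <- length(item$payload$values)
      meta$unit <- item$payload$unit
    }
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
               meta_file)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop_storage(sprintf("failed to serialize item to '%s'", store_dir))
  item$virtual <- TRUE
  item$store_ref <- payload_file
  item$payload <- NULL
  item
}

#' Restore a virtual data item into memory
#'
#' @param item A virtual `data_item`.
#' @return The item with `virtual = FALSE` and its payload restored exactly.
#' @seealso [virtualize()]
#' @export
materialize <- function(item) {
  if (!inherits(item, "data_item"))
    stop_parameter("materialize requires a data_item")
  if (!isTRUE(item$virtual)) return(item)
  if (is.null(item$store_ref) || !file.exists(item$store_ref))
    stop_storage(sprintf("store file '%s' is missing",
                         if (is.null(item$store_ref)) "<unset>"
                         else item$store_ref))
  payload <- tryCatch(readRDS(item$store_ref), error = function(e) NULL)
  if (is.null(payload))
    stop_storage(sprintf("store file '%s' is corrupt", item$store_ref))
  item$payload <- payload
  item$virtual <- FALSE
  item
}

# Default store directory for the session (created lazily under tempdir()).
.stackops_state <- new.env(parent = emptyenv())

#' Session store directory for virtual items
#' @return Path to the current virtual-item store directory.
#' @export
virtual_store_dir <- function() {
  d <- .stackops_state$store_dir
  if (is.null(d)) {
    d <- file.path(tempdir(), "stackops-store")
    .stackops_state$store_dir <- d
  }
  d
}

#' Enable or disable session-wide virtual mode
#'
#' In virtual mode, [execute()] re-virtualizes its results after running an
#' operator, trading speed for memory.
#'
#' @param enabled Logical.
#' @param store_dir Optional store directory.
#' @return Previous state, invisibly.
#' @export
virtual_mode <- function(enabled = TRUE, store_dir = NULL) {
  prev <- isTRUE(.stackops_state$virtual_mode)
  .stackops_state$virtual_mode <- isTRUE(enabled)
  if (!is.null(store_dir)) .stackops_state$store_dir <- store_dir
  invisible(prev)
}

virtual_mode_enabled <- function() isTRUE(.stackops_state$virtual_mode)

# ---------------------------------------------------------------------------
# Colour conversion
# ---------------------------------------------------------------------------

#' Convert an image to single-band grey
#'
#' Grey images are returned unchanged.  24-bit RGB is converted to grey8 by
#' the ITU-R BT.601 luminance formula
#' `Y = 0.299 R + 0.587 G + 0.114 B`, rounded half-up.
#'
#' @param image An `image_item`.
#' @return A grey `image_item`.
#' @export
convert_to_grey <- function(image) {
  if (!inherits(image, "image_item"))
    stop_parameter("convert_to_grey requires an image item")
  if (is_grey(image)) return(image)
  px <- image$pixels
  y <- round_half_up(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
  y <- pmin(pmax(y, 0), 255)
  image_item(matrix(y, nrow = dim(px)[1]), "grey8",
             name = image$name, source_path = image$source_path)
}
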