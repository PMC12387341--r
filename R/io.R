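# Readers/writers for the tabular and image formats the pipeline consumes:
# typed measurement CSVs (comma-separated, UTF-8, "." decimal, mandatory
# header) and 8-bit RGB TIFF/PNG leaf images.

# Column layout and numeric columns for each measurement schema.
measurement_schemas <- list(
  weights = list(
    cols = c("species", "replicate", "time_min", "fresh_g", "turgid_g",
             "dry_g"),
    numeric = c("replicate", "time_min", "fresh_g", "turgid_g", "dry_g")
  ),
  conductivity = list(
    cols = c("species", "replicate", "condition", "cond_treatment_uS",
             "cond_positive_uS"),
    numeric = c("replicate", "cond_treatment_uS", "cond_positive_uS")
  ),
  absorbance = list(
    cols = c("species", "replicate", "abs_h", "abs_nc", "abs_pc"),
    numeric = c("replicate", "abs_h", "abs_nc", "abs_pc")
  ),
  dab_series = list(
    cols = c("species", "phase", "replicate", "value"),
    numeric = c("replicate", "value")
  )
)

#' Read a typed measurement table
#'
#' Reads one of the four measurement CSV layouts used throughout the
#' pipeline and validates it: all schema columns must be present and the
#' numeric columns must parse.  Extra columns are rejected so that schema
#' mix-ups surface early.
#'
#' @param path path to a CSV file (comma-separated, UTF-8, "." decimal,
#'   header row mandatory).
#' @param schema one of \code{"weights"} (leaf fresh/turgid/dry weights over
#'   a dehydration time course), \code{"conductivity"} (electrical
#'   conductivities of treated and autoclaved leaf disks),
#'   \code{"absorbance"} (Evans-blue absorbances at 500 nm), or
#'   \code{"dab_series"} (per-replicate DAB saturation values by phase).
#' @return A data frame with the schema's columns, numeric columns typed.
#' @export
read_measurements_csv <- function(path,
                                  schema = c("weights", "conductivity",
                                             "absorbance", "dab_series")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stopf("file not found: %s", path)
  sch <- measurement_schemas[[schema]]
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  missing <- setdiff(sch$cols, names(raw))
  if (length(missing))
    stopf("schema '%s': missing column(s) %s", schema,
          paste(sprintf("'%s'", missing), collapse = ", "))
  extra <- setdiff(names(raw), sch$cols)
  if (length(extra))
    stopf("schema '%s': unexpected column(s) %s", schema,
          paste(sprintf("'%s'", extra), collapse = ", "))
  out <- raw[sch$cols]
  for (col in sch$numeric) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]) & nzchar(out[[col]]) &
                   toupper(out[[col]]) != "NA")
    if (length(bad))
      stopf("schema '%s': non-numeric value '%s' in column '%s', row %d",
            schema, out[[col]][bad[1]], col, bad[1])
    out[[col]] <- v
  }
  out
}

#' Write a typed measurement table
#'
#' Counterpart of [read_measurements_csv()]; validates the table against the
#' schema before writing, so that write-then-read is the identity on valid
#' tables.
#'
#' @param table data frame matching the schema's columns.
#' @param path output path.
#' @inheritParams read_measurements_csv
#' @return Invisibly, the path written.
#' @export
write_measurements_csv <- function(table, path,
                                   schema = c("weights", "conductivity",
                                              "absorbance", "dab_series")) {
  schema <- match.arg(schema)
  sch <- measurement_schemas[[schema]]
  missing <- setdiff(sch$cols, names(table))
  if (length(missing))
    stopf("schema '%s': missing column(s) %s", schema,
          paste(sprintf("'%s'", missing), collapse = ", "))
  utils::write.csv(table[sch$cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# --- images ---------------------------------------------------------------

# Validate an in-memory 8-bit RGB raster: H x W x 3 array, values 0..255.
assert_rgb_image <- function(img, min_dim = 1L) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stopf("expected an H x W x 3 RGB array")
  if (dim(img)[1] < min_dim || dim(img)[2] < min_dim)
    stopf("image smaller than required minimum dimension %d", min_dim)
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stopf("pixel values must lie in [0, 255]")
  if (any(img != floor(img)))
    stopf("pixel values must be 8-bit integers")
  invisible(img)
}

# Minimal TIFF header inspection: bits-per-sample (tag 258) and
# samples-per-pixel (tag 277) of the first image directory.  The tiff
# package build in use does not expose these, and the unsupported-format
# contract (reject grayscale and 16-bit input explicitly) needs them.
tiff_meta <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- readChar(con, 2, useBytes = TRUE)
  endian <- switch(order_bytes, II = "little", MM = "big",
                   stopf("not a TIFF file: %s", path))
  magic <- readBin(con, "integer", 1, size = 2, endian = endian)
  if (magic != 42L) stopf("not a TIFF file: %s", path)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)
  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                       endian = endian)
  bits <- NULL
  spp <- 1L  # TIFF default
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                   endian = endian)
    type <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                    endian = endian)
    count <- readBin(con, "integer", 1, size = 4, endian = endian)
    value_pos <- seek(con)  # start of the 4-byte value/offset field
    if (tag == 258L || tag == 277L) {
      if (type != 3L) stopf("unexpected TIFF tag type for tag %d", tag)
      if (count <= 2L) {
        vals <- readBin(con, "integer", count, size = 2, signed = FALSE,
                        endian = endian)
      } else {
        off <- readBin(con, "integer", 1, size = 4, endian = endian)
        seek(con, off)
        vals <- readBin(con, "integer", count, size = 2, signed = FALSE,
                        endian = endian)
      }
      if (tag == 258L) bits <- vals else spp <- vals[1]
    }
    seek(con, value_pos + 4)
  }
  list(bits_per_sample = if (is.null(bits)) 1L else bits,
       samples_per_pixel = spp)
}

#' Read an 8-bit RGB leaf image
#'
#' Reads a TIFF or PNG image into an integer H x W x 3 array with values in
#' 0..255.  Only 8-bit, 3-channel input is accepted: grayscale, paletted,
#' alpha-carrying or 16-bit images raise an unsupported-format error rather
#' than being converted silently, since silent conversion would change the
#' downstream saturation values.
#'
#' @param path path to a \code{.tif}, \code{.tiff} or \code{.png} file.
#' @return Integer array of dimension height x width x 3.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    meta <- tiff_meta(path)
    if (!all(meta$bits_per_sample == 8L))
      stopf("unsupported format: TIFF with %s bits per sample (need 8)",
            paste(unique(meta$bits_per_sample), collapse = "/"))
    if (meta$samples_per_pixel != 3L)
      stopf("unsupported format: TIFF with %d channel(s) (need 3-channel RGB)",
            meta$samples_per_pixel)
    x <- tiff::readTIFF(path)
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8L)
      stopf("unsupported format: %d-bit PNG (need 8)", info$bit.depth)
    if (!is.null(info$color.type) && !identical(info$color.type, "RGB"))
      stopf("unsupported format: PNG color type '%s' (need 3-channel RGB)",
            info$color.type)
  } else {
    stopf("unsupported image extension '%s' (use TIFF or PNG)", ext)
  }
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    stopf("unsupported format: need a 3-channel RGB image")
  img <- array(as.integer(round(x * 255)), dim = dim(x))
  assert_rgb_image(img)
  img
}

#' Write an 8-bit RGB image losslessly
#'
#' @param path output path ending in \code{.tif}, \code{.tiff} or
#'   \code{.png}.
#' @param img integer H x W x 3 array with values in 0..255.
#' @return Invisibly, the path written.  A write-then-read round trip
#'   reproduces the array bit for bit.
#' @export
write_image <- function(path, img) {
  assert_rgb_image(img)
  ext <- tolower(tools::file_ext(path))
  norm <- img / 255
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L, compression = "LZW",
                    reduce = FALSE)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else {
    stopf("unsupported image extension '%s' (use TIFF or PNG)", ext)
  }
  invisible(path)
}
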