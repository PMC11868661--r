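#' Read a 2-D scan from TIFF or delimited text
#'
#' Depth is the first axis (rows), 1-based pixel semantics. TIFF scans
#' written by [write_scan()] carry their value range in a JSON sidecar
#' `<path>.json` and are mapped back to physical values on read (accurate
#' to 2^-32 of the range); foreign integer TIFFs are returned with their
#' stored integer values as floats. Sidecar contents are attached as
#' metadata.
#'
#' @param path File path; `.tif`/`.tiff` is read as TIFF, anything else as
#'   comma-delimited text.
#' @return Numeric matrix (depth x lateral) with attribute `metadata`
#'   (list, possibly empty); a list of matrices for a multi-page TIFF.
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("cannot read scan: ", path, " does not exist")
  ext <- tolower(tools::file_ext(path))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  if (ext %in% c("tif", "tiff")) {
    scaled <- !is.null(meta$value_range)
    img <- tiff::readTIFF(path, all = TRUE, as.is = !scaled)
    img <- lapply(img, function(page) {
      if (length(dim(page)) != 2)
        stop("scan must be a single-channel 2-D image")
      m <- matrix(as.numeric(page), nrow(page), ncol(page))
      if (scaled) {
        lo <- meta$value_range[1]; hi <- meta$value_range[2]
        m <- lo + m * (hi - lo)
      }
      m
    })
    m <- if (length(img) == 1L) img[[1L]] else img
  } else {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    if (!is.numeric(m)) stop("delimited scan contains non-numeric values")
  }
  attr(m, "metadata") <- meta
  m
}

#' Write a 2-D scan as 32-bit TIFF (or CSV)
#'
#' TIFF pages are stored scaled to the unit interval over the data's value
#' range at 32 bits per sample; the range is recorded in the JSON sidecar
#' `<path>.json` so [read_scan()] restores physical values (resolution
#' 2^-32 of the range). Delimited output is written at full precision.
#'
#' @param scan Numeric matrix (depth x lateral); for multi-page TIFF output
#'   a list of matrices (all pages share one value range).
#' @param path Destination; `.tif`/`.tiff` writes TIFF, anything else
#'   comma-delimited text.
#' @param metadata Optional list merged into the JSON sidecar `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, metadata = NULL) {
  ext <- tolower(tools::file_ext(path))
  meta <- metadata
  if (ext %in% c("tif", "tiff")) {
    imgs <- if (is.list(scan)) scan else list(scan)
    lo <- min(vapply(imgs, min, numeric(1)))
    hi <- max(vapply(imgs, max, numeric(1)))
    span <- if (hi > lo) hi - lo else 1
    norm <- lapply(imgs, function(m) (m - lo) / span)
    tiff::writeTIFF(norm, path, bits.per.sample = 32L, reduce = FALSE)
    meta <- c(list(value_range = c(lo, if (hi > lo) hi else lo + 1)),
              meta)
  } else {
    if (is.list(scan)) stop("multi-page output requires a TIFF path")
    utils::write.table(scan, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write/read a per-pixel curve as two-column delimited text
#'
#' Full-precision, lossless round trip of a depth curve (e.g. an estimated
#' `g` or a measured fall-off). The header line names the columns.
#'
#' @param curve Numeric vector (values at pixels `1..p`) or a two-column
#'   data frame (pixel, value).
#' @param path Destination text file.
#' @param value_name Column name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, value_name = "value") {
  df <- if (is.data.frame(curve)) {
    stats::setNames(curve[, 1:2], c("pixel", value_name))
  } else {
    stats::setNames(data.frame(seq_along(curve), curve),
                    c("pixel", value_name))
  }
  utils::write.table(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @return `read_curve` returns the curve as a numeric vector ordered by
#'   pixel, with the value column name as attribute `value_name`.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("cannot read curve: ", path, " does not exist")
  df <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t"),
                 error = function(e) stop("malformed curve file: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2) stop("curve file must have two columns")
  ord <- order(df[[1]])
  out <- as.numeric(df[[2]][ord])
  attr(out, "value_name") <- names(df)[2]
  out
}
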