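# Readers and writers for the pipeline's artifact formats. All writers are
# deterministic (fixed column order, fixed decimal formatting); all readers
# validate and reject malformed input rather than coercing it.

.loc_columns <- c("cell_id", "channel", "frame", "x_nm", "y_nm",
                  "intensity", "background")

#' Construct a validated localization table
#'
#' One row per detected emitter per frame per channel. Coordinates are in
#' nm with the origin at the field corner, x rightward and y downward;
#' frames are 0-based.
#'
#' @param cell_id Character cell identifier.
#' @param channel `"A"` or `"B"`.
#' @param frame 0-based frame index.
#' @param x_nm,y_nm Position (nm).
#' @param intensity Non-negative integrated intensity above background
#'   (camera units).
#' @param background Background level (camera units per pixel).
#' @return A `data.frame` with the canonical column order.
#' @export
localization_table <- function(cell_id = character(), channel = character(),
                               frame = integer(), x_nm = numeric(),
                               y_nm = numeric(), intensity = numeric(),
                               background = numeric()) {
  tab <- data.frame(cell_id = as.character(cell_id),
                    channel = as.character(channel),
                    frame = as.integer(frame),
                    x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                    intensity = as.numeric(intensity),
                    background = as.numeric(background),
                    stringsAsFactors = FALSE)
  validate_localizations(tab)
}

#' Validate a localization table
#'
#' @param tab A data frame with the localization schema.
#' @param n_frames Optional movie length; frames must lie in
#'   `[0, n_frames)`.
#' @return The validated table (column order normalized).
#' @export
validate_localizations <- function(tab, n_frames = NULL) {
  missing_cols <- setdiff(.loc_columns, names(tab))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab <- tab[, .loc_columns]
  if (nrow(tab) == 0) return(tab)
  if (!all(tab$channel %in% c("A", "B")))
    stop("schema error: channel must be 'A' or 'B'")
  for (col in c("x_nm", "y_nm", "intensity", "background")) {
    if (!is.numeric(tab[[col]]))
      stop("parse error: non-numeric values in column ", col)
    bad <- which(!is.finite(tab[[col]]))
    if (length(bad) > 0)
      stop("parse error: non-finite ", col, " at row ", bad[1])
  }
  if (any(tab$frame < 0)) stop("schema error: negative frame index")
  if (!is.null(n_frames) && any(tab$frame >= n_frames))
    stop("schema error: frame index beyond movie length")
  tab
}

#' Read a localization table from CSV
#'
#' @param path CSV file with the header
#'   `cell_id,channel,frame,x_nm,y_nm,intensity,background`.
#' @return A validated localization table; row order is preserved.
#' @export
read_localizations <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(cell_id = "character", channel = "character"))
  missing_cols <- setdiff(.loc_columns, names(tab))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), " in ", path)
  for (col in c("frame", "x_nm", "y_nm", "intensity", "background")) {
    v <- tab[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad) > 0)
        stop("parse error: non-numeric value '", v[bad[1]], "' in column ",
             col, " at row ", bad[1])
      tab[[col]] <- conv
    }
  }
  tab$frame <- as.integer(tab$frame)
  validate_localizations(tab)
}

#' Write a localization table to CSV
#'
#' Deterministic output: canonical column order, coordinates formatted to
#' 0.01 nm, intensities to 0.1 camera units. Writing the same table twice
#' yields byte-identical files.
#'
#' @param tab A localization table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(tab, path) {
  tab <- validate_localizations(tab)
  out <- data.frame(cell_id = tab$cell_id, channel = tab$channel,
                    frame = tab$frame,
                    x_nm = sprintf("%.2f", tab$x_nm),
                    y_nm = sprintf("%.2f", tab$y_nm),
                    intensity = sprintf("%.1f", tab$intensity),
                    background = sprintf("%.1f", tab$background),
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")             # binary: fixed EOL across platforms
  on.exit(close(con))
  writeLines(paste(.loc_columns, collapse = ","), con, sep = "\n")
  if (nrow(out) > 0)
    writeLines(do.call(paste, c(out, sep = ",")), con, sep = "\n")
  invisible(path)
}

#' Read a single-channel movie from a multi-page 16-bit TIFF
#'
#' @param path TIFF path.
#' @param pixel_size Pixel size (nm), carried as an attribute (TIFF
#'   metadata beyond pixel counts is not interpreted).
#' @return A `frame_stack`: list of integer matrices (counts) with
#'   attributes `pixel_size` and `n_frames`.
#' @export
read_stack <- function(path, pixel_size = NA_real_) {
  imgs <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                   error = function(e) stop("format error reading ", path,
                                            ": ", conditionMessage(e)))
  if (!is.list(imgs)) imgs <- list(imgs)
  dims <- vapply(imgs, function(m) dim(m)[1:2], integer(2))
  if (ncol(dims) > 1 && (length(unique(dims[1, ])) > 1 ||
                         length(unique(dims[2, ])) > 1))
    stop("format error: inconsistent frame shapes in ", path)
  frames <- lapply(imgs, function(m) {
    m <- m[, , drop = TRUE]
    if (length(dim(m)) != 2) stop("format error: frames must be single-plane")
    storage.mode(m) <- "integer"
    m
  })
  structure(frames, class = "frame_stack", pixel_size = pixel_size,
            n_frames = length(frames))
}

#' Write a movie as a multi-page 16-bit TIFF
#'
#' @param stack A `frame_stack` or list of integer matrices in
#'   `[0, 65535]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  frames <- lapply(stack, function(m) {
    m <- pmax(pmin(m, 65535L), 0L)
    matrix(as.numeric(m) / 65535, nrow(m), ncol(m))   # tiff writes [0,1] scale
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}
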