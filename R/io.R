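#' Read an en face angiogram with its metadata sidecar
#'
#' Accepts 8- or 16-bit grayscale PNG or TIFF; intensities are normalized to
#' `[0, 1]` preserving order (both bit depths of the same scene decode to
#' the same grid up to quantization). The JSON sidecar must supply
#' `mm_per_pixel`, `plexus`, and `signal_strength`; `participant_id` and
#' `eye` are optional.
#'
#' @param image_path Path to a PNG or TIFF image.
#' @param sidecar_path Path to the JSON sidecar.
#' @return An [en_face_angiogram()].
#' @export
read_angiogram <- function(image_path, sidecar_path) {
  if (!file.exists(image_path)) stop("image file not found: ", image_path, call. = FALSE)
  if (!file.exists(sidecar_path)) stop("sidecar file not found: ", sidecar_path, call. = FALSE)
  m <- read_gray_image(image_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("mm_per_pixel", "plexus", "signal_strength")) {
    if (is.null(meta[[field]])) {
      stop("sidecar is missing required field '", field, "'", call. = FALSE)
    }
  }
  if (length(meta$mm_per_pixel) > 1L) {
    if (diff(range(meta$mm_per_pixel)) > 1e-12) {
      stop("non-square pixels are not supported (mm_per_pixel differs by axis)",
           call. = FALSE)
    }
    meta$mm_per_pixel <- meta$mm_per_pixel[[1L]]
  }
  en_face_angiogram(m,
                    mm_per_pixel = as.numeric(meta$mm_per_pixel),
                    plexus = as.character(meta$plexus),
                    signal_strength = as.numeric(meta$signal_strength),
                    participant_id = meta$participant_id %||% NA_character_,
                    eye = meta$eye %||% NA_character_)
}

#' Write an angiogram image and sidecar
#'
#' PNG images are written at 8 bits, TIFF at 16 bits per sample; choose by
#' file extension.
#'
#' @param angiogram An [en_face_angiogram()].
#' @param image_path Output image path (`.png`, `.tif`, or `.tiff`).
#' @param sidecar_path Output JSON sidecar path; default replaces the image
#'   extension with `.json`.
#' @return Invisibly, `image_path`.
#' @export
write_angiogram <- function(angiogram, image_path,
                            sidecar_path = sub("\\.[^.]+$", ".json", image_path)) {
  stopifnot(inherits(angiogram, "en_face_angiogram"))
  m <- angiogram$intensities
  if (max(m) > 1) m <- m / max(m)
  ext <- tolower(tools::file_ext(image_path))
  if (ext == "png") {
    png::writePNG(m, image_path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, image_path, bits.per.sample = 16L)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  meta <- list(mm_per_pixel = angiogram$mm_per_pixel,
               plexus = angiogram$plexus,
               signal_strength = angiogram$signal_strength,
               participant_id = angiogram$participant_id,
               eye = angiogram$eye)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  if (length(dim(a)) == 3L) a <- rowMeans(a[, , 1:min(3L, dim(a)[3L]), drop = FALSE], dims = 2L)
  if (max(a) > 1) a <- a / max(a)
  pmin(pmax(a, 0), 1)
}

#' Read a FAZ boundary polygon from CSV
#'
#' Expects two numeric columns `(x_mm, y_mm)`, one vertex per row, in order
#' around the boundary. Validation (>= 3 vertices, simple, positive area)
#' is performed by [faz_polygon()].
#'
#' @param path CSV path.
#' @return A [faz_polygon()].
#' @export
read_faz_polygon <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("FAZ polygon CSV needs two numeric columns", call. = FALSE)
  faz_polygon(as.matrix(df[, 1:2]))
}

#' Write a FAZ polygon to CSV
#'
#' @param polygon A [faz_polygon()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_faz_polygon <- function(polygon, path) {
  utils::write.csv(as.data.frame(unclass(polygon)), path, row.names = FALSE)
  invisible(path)
}

metric_record_columns <- c(
  "participant_id", "eye", "vd_scp", "vd_dcp", "fd_scp", "fd_dcp",
  "pd_large_scp", "faz_area_scp", "faz_area_dcp",
  "signal_strength_scp", "signal_strength_dcp"
)

#' Write per-eye metric records
#'
#' One row per eye with a stable column order; CSV or JSON chosen by the
#' file extension, with identical content either way. An empty record list
#' produces a header-only CSV (or empty JSON array).
#'
#' @param records A data frame of [compute_metric_record()] rows (they
#'   rbind cleanly), or an empty data frame.
#' @param path Output path ending in `.csv` or `.json`.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- as.data.frame(
      setNames(rep(list(logical(0)), length(metric_record_columns)),
               metric_record_columns))
  }
  missing_cols <- setdiff(metric_record_columns, names(records))
  if (length(missing_cols)) {
    stop("metric records are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[, metric_record_columns, drop = FALSE]
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null")
  } else {
    stop("unsupported metrics extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a metric table written by [write_metrics()]
#'
#' @param path CSV or JSON path.
#' @return A data frame with the standard metric-record columns.
#' @export
read_metrics <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") {
    utils::read.csv(path, colClasses = c(participant_id = "character",
                                         eye = "character"))
  } else if (ext == "json") {
    out <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(out) == 0L) return(read_metrics_empty())
    as.data.frame(out)
  } else {
    stop("unsupported metrics extension: ", ext, call. = FALSE)
  }
  if (nrow(df)) df[, metric_record_columns, drop = FALSE] else read_metrics_empty()
}

read_metrics_empty <- function() {
  as.data.frame(setNames(rep(list(logical(0)), length(metric_record_columns)),
                         metric_record_columns))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
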