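#' Correct smooth multiplicative illumination defects
#'
#' Fluorescence fields acquired across a plate carry slowly varying shading
#' (vignetting, uneven excitation) that is well modelled as a multiplicative
#' low-order surface. The surface is estimated by fitting a second-degree
#' polynomial in the pixel coordinates to background pixels (those at or
#' below the Otsu threshold; if fewer than 5% of pixels qualify, all pixels
#' are used), normalised to mean one, and divided out. A flat field is
#' returned unchanged up to floating-point tolerance, and the operation is
#' idempotent up to the same tolerance.
#'
#' @param image Numeric matrix of nonnegative intensities.
#' @return A numeric matrix of the same dimensions, nonnegative, with the
#'   shading divided out.
#' @export
correct_illumination <- function(image) {
  stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0)
  img <- image * 1.0
  if (all(img == 0)) {
    warn("All-zero image: returned unchanged.")
    return(img)
  }
  rng <- range(img)
  if (diff(rng) < .Machine$double.eps * max(1, rng[2])) {
    return(img)                      # constant image: nothing to correct
  }

  # robust background band: bright objects are excluded, and the M-estimator
  # below downweights any remaining object skirts
  bg <- img <= stats::median(img) + 4 * stats::mad(img)
  if (mean(bg) < 0.05) bg[] <- TRUE

  d <- dim(img)
  xs <- (row(img) - 1) / max(1, d[1] - 1)
  ys <- (col(img) - 1) / max(1, d[2] - 1)
  dat <- data.frame(z = as.vector(img), x = as.vector(xs), y = as.vector(ys))
  sub <- dat[as.vector(bg), , drop = FALSE]
  if (nrow(sub) > 4000L) {    # deterministic thinning keeps the fit cheap
    sub <- sub[seq(1L, nrow(sub), length.out = 4000L), , drop = FALSE]
  }
  fit <- tryCatch(
    suppressWarnings(MASS::rlm(z ~ x + y + I(x^2) + I(y^2) + I(x * y),
                               data = sub, maxit = 50)),
    error = function(e) lm(z ~ x + y + I(x^2) + I(y^2) + I(x * y), data = sub)
  )
  field <- matrix(predict(fit, newdata = dat), d[1], d[2])
  field <- pmax(field, 1e-6 * max(field, 1e-12))
  field <- field / mean(field)
  pmax(img / field, 0)
}

#' Segment and count nuclei in a feature image
#'
#' Foreground is taken by a global Otsu threshold on the (illumination-
#' corrected) image, labelled by connected components, and optionally
#' declumped by a watershed on the distance transform so that touching
#' nuclei split into separate objects. Components smaller than
#' `min_area_px` are discarded as debris.
#'
#' @param image Numeric matrix, ideally the output of
#'   [correct_illumination()].
#' @param nucleus_radius_px Expected nucleus radius in pixels; sets the
#'   default minimum area and the watershed tolerance (default 5).
#' @param min_area_px Minimum object area in pixels; default 25% of the
#'   expected nucleus area `pi * r^2`.
#' @param declump Split touching nuclei with a distance-transform watershed
#'   (default `TRUE`).
#' @return An object of class `segmentation`: a list with `nucleus_count`,
#'   `label_image` (integer matrix, 0 = background), `centroids` (tibble
#'   `x`, `y`, `area_px`), and `mean_area_px`.
#' @export
segment_nuclei <- function(image, nucleus_radius_px = 5, min_area_px = NULL,
                           declump = TRUE) {
  stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0)
  if (is.null(min_area_px)) {
    min_area_px <- 0.25 * pi * nucleus_radius_px^2
  }
  img <- image * 1.0
  rng <- range(img)
  empty <- function(msg = NULL) {
    if (!is.null(msg)) warn(msg)
    structure(
      list(nucleus_count = 0L,
           label_image = matrix(0L, nrow(img), ncol(img)),
           centroids = tibble(x = numeric(), y = numeric(),
                              area_px = numeric()),
           mean_area_px = NA_real_),
      class = "segmentation"
    )
  }
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))) {
    return(empty("Uniform image: no objects segmented."))
  }

  norm <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > th
  if (!any(mask)) return(empty())

  # foreground must clear the background by a robust margin, otherwise Otsu
  # merely bisects the noise distribution of an empty field
  th_abs <- rng[1] + th * diff(rng)
  if (th_abs <= stats::median(img) + 5 * stats::mad(img)) {
    return(empty())
  }

  if (declump) {
    dm <- EBImage::distmap(EBImage::Image(mask))
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  } else {
    lab <- EBImage::bwlabel(EBImage::Image(mask))
  }
  lab <- EBImage::imageData(lab)

  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]

  if (length(keep) == 0L) return(empty())
  cents <- dplyr::bind_rows(lapply(seq_along(keep), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    tibble(x = mean(idx[, 1]), y = mean(idx[, 2]),
           area_px = nrow(idx))
  }))
  structure(
    list(nucleus_count = length(keep),
         label_image = matrix(as.integer(lab), nrow(img), ncol(img)),
         centroids = cents,
         mean_area_px = mean(cents$area_px)),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d nuclei, mean area %.1f px\n",
              x$nucleus_count, x$mean_area_px))
  invisible(x)
}

#' Parse a feature-image filename into its coordinates
#'
#' @param filename Basename(s) following the
#'   `well{W}_pos{RRR}x{CCC}_day{D}` pattern.
#' @return A tibble with `well`, `grid_row`, `grid_col`, `day`; rows that do
#'   not parse are `NA`.
#' @export
parse_image_filename <- function(filename) {
  base <- tools::file_path_sans_ext(basename(filename))
  m <- stringr::str_match(base, "^well(\\d+)_pos(\\d+)x(\\d+)_day(\\d+)$")
  tibble(
    filename = filename,
    well = as.integer(m[, 2]),
    grid_row = as.integer(m[, 3]),
    grid_col = as.integer(m[, 4]),
    day = as.integer(m[, 5])
  )
}

#' Count nuclei across a plate of feature images
#'
#' Maps every image to its (well, grid position, day), corrects illumination,
#' segments nuclei, and returns one count record per image. Records can be
#' persisted to a keyed CSV store with upsert semantics: re-processing an
#' image replaces its record.
#'
#' @param images Either a directory (or vector of file paths) of
#'   TIFF/PNG images named per [feature_image_filename()], or the `images`
#'   tibble returned by [generate_plate_timelapse()].
#' @param layout Optional [plate_layout()] used to validate grid coordinates.
#' @param store Optional path to a CSV count store updated with the new
#'   records (see [update_count_store()]).
#' @param ... Passed to [segment_nuclei()].
#' @return A tibble of count records: `well`, `grid_row`, `grid_col`, `day`,
#'   `nucleus_count`.
#' @export
process_plate <- function(images, layout = NULL, store = NULL, ...) {
  if (is.character(images)) {
    paths <- if (length(images) == 1L && dir.exists(images)) {
      list.files(images, pattern = "\\.(tif|tiff|png)$", full.names = TRUE,
                 ignore.case = TRUE)
    } else {
      images
    }
    meta <- parse_image_filename(paths)
    bad <- is.na(meta$well)
    if (any(bad)) {
      warn(sprintf("Skipping %d file(s) with unparseable names.", sum(bad)))
      meta <- meta[!bad, , drop = FALSE]
    }
    meta$image <- lapply(meta$filename, read_feature_image)
    meta$filename <- NULL
  } else {
    stopifnot(is.data.frame(images))
    meta <- images
    if (!"image" %in% names(meta) && "path" %in% names(meta)) {
      meta$image <- lapply(meta$path, read_feature_image)
    }
  }
  if (nrow(meta) == 0L) {
    return(tibble(well = integer(), grid_row = integer(),
                  grid_col = integer(), day = integer(),
                  nucleus_count = integer()))
  }
  if (!is.null(layout)) {
    off <- meta$grid_row > layout$grid_rows | meta$grid_col > layout$grid_cols
    if (any(off)) {
      warn(sprintf("Skipping %d image(s) outside the layout grid.", sum(off)))
      meta <- meta[!off, , drop = FALSE]
    }
  }

  counts <- vapply(meta$image, function(img) {
    corrected <- correct_illumination(img)
    seg <- segment_nuclei(corrected, ...)
    seg$nucleus_count
  }, integer(1))

  records <- tibble(
    well = as.integer(meta$well), grid_row = as.integer(meta$grid_row),
    grid_col = as.integer(meta$grid_col), day = as.integer(meta$day),
    nucleus_count = counts
  ) |>
    dplyr::arrange(.data$well, .data$grid_row, .data$grid_col, .data$day)

  dup <- duplicated(records[c("well", "grid_row", "grid_col", "day")],
                    fromLast = TRUE)
  if (any(dup)) {
    warn(sprintf("Replacing %d duplicate record(s) (last wins).", sum(dup)))
    records <- records[!dup, , drop = FALSE]
  }
  if (!is.null(store)) update_count_store(store, records)
  records
}

#' Keyed CSV store of per-feature nucleus counts
#'
#' A single CSV file with header `well,grid_row,grid_col,day,nucleus_count`
#' acts as the tabular results store. `update_count_store()` upserts: an
#' incoming record replaces any stored record with the same
#' (well, grid_row, grid_col, day) key, with a warning.
#'
#' @param path Store CSV path.
#' @param records Count-record tibble as from [process_plate()].
#' @return The full store contents as a tibble (invisibly for the updater).
#' @export
update_count_store <- function(path, records) {
  key <- c("well", "grid_row", "grid_col", "day")
  stopifnot(all(c(key, "nucleus_count") %in% names(records)))
  if (file.exists(path)) {
    old <- read_count_store(path)
    clash <- dplyr::semi_join(old, records, by = key)
    if (nrow(clash) > 0) {
      warn(sprintf("Replacing %d existing record(s) in the store.",
                   nrow(clash)))
    }
    records <- dplyr::bind_rows(dplyr::anti_join(old, records, by = key),
                                records)
  }
  records <- dplyr::arrange(records, .data$well, .data$grid_row,
                            .data$grid_col, .data$day)
  readr::write_csv(records, path)
  invisible(records)
}

#' @rdname update_count_store
#' @export
read_count_store <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    well = readr::col_integer(), grid_row = readr::col_integer(),
    grid_col = readr::col_integer(), day = readr::col_integer(),
    nucleus_count = readr::col_integer()
  ))
}
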