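#' Plate layout for micropatterned culture plates
#'
#' Describes the geometry of an arrayed editing plate: each well carries a
#' rectangular grid of circular cell-adhesive features (one clonal colony per
#' feature), imaged one field per feature. The defaults give the standard
#' 20 x 20 grid of 300 um features, i.e. 400 features per well and 2,400 per
#' 6-well plate.
#'
#' @param n_wells Number of wells on the plate (default 6).
#' @param grid_rows,grid_cols Acquisition grid dimensions per well
#'   (default 20 x 20).
#' @param feature_diameter_um Diameter of each circular feature in
#'   micrometres (default 300).
#' @param feature_pitch_um Centre-to-centre feature spacing in micrometres;
#'   must exceed the diameter (default 750).
#' @param pixels_per_um Image scale in pixels per micrometre (default 0.5,
#'   i.e. 2 um per pixel).
#'
#' @return An object of class `plate_layout`.
#' @examples
#' layout <- plate_layout()
#' n_features(layout)          # per well
#' n_features(layout, total = TRUE)  # whole plate
#' @export
plate_layout <- function(n_wells = 6L, grid_rows = 20L, grid_cols = 20L,
                         feature_diameter_um = 300, feature_pitch_um = 750,
                         pixels_per_um = 0.5) {
  assert_scalar_number(n_wells, "n_wells", min = 1)
  assert_scalar_number(grid_rows, "grid_rows", min = 1)
  assert_scalar_number(grid_cols, "grid_cols", min = 1)
  assert_scalar_number(feature_diameter_um, "feature_diameter_um", min = 1e-9)
  assert_scalar_number(feature_pitch_um, "feature_pitch_um", min = 1e-9)
  assert_scalar_number(pixels_per_um, "pixels_per_um", min = 1e-9)
  if (feature_pitch_um <= feature_diameter_um) {
    abort("`feature_pitch_um` must be greater than `feature_diameter_um`.")
  }
  structure(
    list(
      n_wells = as.integer(n_wells),
      grid_rows = as.integer(grid_rows),
      grid_cols = as.integer(grid_cols),
      feature_diameter_um = feature_diameter_um,
      feature_pitch_um = feature_pitch_um,
      pixels_per_um = pixels_per_um
    ),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf(
    "<plate_layout> %d wells, %d x %d grid (%d features/well, %d total)\n",
    x$n_wells, x$grid_rows, x$grid_cols, n_features(x),
    n_features(x, total = TRUE)
  ))
  cat(sprintf("  feature diameter %g um, pitch %g um, %g px/um\n",
              x$feature_diameter_um, x$feature_pitch_um, x$pixels_per_um))
  invisible(x)
}

#' Number of features on a layout
#'
#' @param layout A [plate_layout()].
#' @param total If `TRUE`, count features over all wells; otherwise per well.
#' @return An integer count.
#' @export
n_features <- function(layout, total = FALSE) {
  stopifnot(inherits(layout, "plate_layout"))
  per_well <- layout$grid_rows * layout$grid_cols
  if (total) per_well * layout$n_wells else per_well
}

#' Side length in pixels of a single feature image
#'
#' One image is acquired per feature; the field of view covers the feature
#' disk with a 15% margin.
#'
#' @param layout A [plate_layout()].
#' @return Integer image side length in pixels.
#' @export
feature_image_px <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  as.integer(ceiling(layout$feature_diameter_um * 1.15 * layout$pixels_per_um))
}
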