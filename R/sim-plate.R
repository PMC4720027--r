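#' Parameters for the clonal growth / imaging simulator
#'
#' Controls seeding, the daily birth-death process, and image rendering for
#' [generate_plate_timelapse()]. Seeding is clonal: the number of cells
#' deposited on each feature is Poisson with mean `seeding_density_lambda`,
#' chosen so that most features receive 0 or 1 cell. Each subsequent day every
#' cell first dies with probability `death_prob_per_day`, then each survivor
#' divides with probability `exp(growth_rate_per_day) - 1`, so the expected
#' per-day multiplier is `(1 - death_prob) * exp(rate)` and a noise-free rate
#' of `log(2)` doubles the colony exactly once per day. In stochastic mode,
#' rates above `log(2)` per day are rejected (a cell divides at most once
#' between daily images).
#'
#' Nuclei are rendered as 2-D Gaussian spots confined to the circular feature
#' disk, on a flat background with additive Gaussian read-out noise, quantised
#' to 16-bit counts.
#'
#' @param seeding_density_lambda Poisson mean cells seeded per feature
#'   (default 1).
#' @param growth_rate_per_day Exponential growth rate per day, at most
#'   `log(2)` (default `log(2)`).
#' @param death_prob_per_day Per-cell daily death probability (default 0).
#' @param nucleus_radius_px Nucleus radius in pixels (default 5, i.e. a
#'   20 um nucleus at the default 0.5 px/um scale).
#' @param intensity_mean,intensity_sd Peak nuclear intensity distribution in
#'   16-bit counts (defaults 20000 and 2000).
#' @param background_level Flat background level in counts (default 1000).
#' @param noise_sd Additive Gaussian read-out noise, counts (default 200).
#' @param stochastic If `FALSE`, division noise is disabled: colonies follow
#'   the exponential `size * exp(rate * days)` exactly (counts are the
#'   rounded sizes), leaving imaging as the only noise source. Default
#'   `TRUE` (binomial division and death).
#' @return An object of class `clone_sim_params`.
#' @export
clone_sim_params <- function(seeding_density_lambda = 1,
                             growth_rate_per_day = log(2),
                             death_prob_per_day = 0,
                             nucleus_radius_px = 5,
                             intensity_mean = 20000,
                             intensity_sd = 2000,
                             background_level = 1000,
                             noise_sd = 200,
                             stochastic = TRUE) {
  assert_scalar_number(seeding_density_lambda, "seeding_density_lambda", min = 0)
  assert_scalar_number(growth_rate_per_day, "growth_rate_per_day")
  if (isTRUE(stochastic) && growth_rate_per_day > log(2) + 1e-12) {
    abort(paste("`growth_rate_per_day` above log(2) needs `stochastic = FALSE`:",
                "a cell divides at most once between daily images."))
  }
  assert_scalar_number(death_prob_per_day, "death_prob_per_day", min = 0, max = 1)
  assert_scalar_number(nucleus_radius_px, "nucleus_radius_px", min = 1e-9)
  assert_scalar_number(intensity_mean, "intensity_mean", min = 0)
  assert_scalar_number(intensity_sd, "intensity_sd", min = 0)
  assert_scalar_number(background_level, "background_level", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  structure(
    list(
      seeding_density_lambda = seeding_density_lambda,
      growth_rate_per_day = growth_rate_per_day,
      death_prob_per_day = death_prob_per_day,
      nucleus_radius_px = nucleus_radius_px,
      intensity_mean = intensity_mean,
      intensity_sd = intensity_sd,
      background_level = background_level,
      noise_sd = noise_sd,
      stochastic = isTRUE(stochastic)
    ),
    class = "clone_sim_params"
  )
}

# one day of the branching process for a vector of per-feature colony sizes;
# sizes are integer counts in stochastic mode and real-valued otherwise
step_sizes <- function(sizes, params) {
  if (params$stochastic) {
    survivors <- sizes -
      rbinom(length(sizes), sizes, params$death_prob_per_day)
    p_div <- min(max(exp(params$growth_rate_per_day) - 1, 0), 1)
    survivors + rbinom(length(survivors), survivors, p_div)
  } else {
    sizes * (1 - params$death_prob_per_day) * exp(params$growth_rate_per_day)
  }
}

#' Simulate per-feature colony counts over days
#'
#' Runs only the seeding and daily birth-death process (no images). Day 1 is
#' the first imaging day, 24 h after seeding, and carries the seeded count.
#'
#' @param n_f Number of features.
#' @param params A [clone_sim_params()].
#' @param n_days Number of daily time points (>= 1).
#' @return A tibble with columns `feature`, `day`, `true_count`.
#' @export
simulate_clone_counts <- function(n_f, params, n_days) {
  stopifnot(inherits(params, "clone_sim_params"))
  assert_scalar_number(n_days, "n_days", min = 1)
  sizes <- rpois(n_f, params$seeding_density_lambda)
  out <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    if (d > 1L) sizes <- step_sizes(sizes, params)
    out[[d]] <- tibble(feature = seq_len(n_f), day = d,
                       true_count = as.integer(round(sizes)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$feature, .data$day)
}

# place n centres inside a disk (radius r_disk, centred at c0) with pairwise
# separation >= sep; separation is relaxed if the disk gets crowded
place_nuclei <- function(n, c0, r_disk, sep) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  sep_cur <- sep
  tries <- 0L
  while (placed < n) {
    a <- runif(1, 0, 2 * pi)
    r <- r_disk * sqrt(runif(1))
    p <- c0 + r * c(cos(a), sin(a))
    ok <- placed == 0L ||
      min(sqrt(rowSums((pts[seq_len(placed), , drop = FALSE] -
                          matrix(p, placed, 2, byrow = TRUE))^2))) >= sep_cur
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- p
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > 200L) {       # crowded disk: relax the exclusion radius
        sep_cur <- sep_cur * 0.8
        tries <- 0L
      }
    }
  }
  pts
}

# render one 16-bit feature image given nucleus centres
render_feature_image <- function(centres, side, params) {
  img <- matrix(params$background_level, side, side)
  if (nrow(centres) > 0) {
    sigma <- params$nucleus_radius_px / 2
    xs <- seq_len(side)
    for (i in seq_len(nrow(centres))) {
      amp <- max(0, rnorm(1, params$intensity_mean, params$intensity_sd))
      dx2 <- (xs - centres[i, 1])^2
      dy2 <- (xs - centres[i, 2])^2
      img <- img + amp * exp(-outer(dx2, dy2, "+") / (2 * sigma^2))
    }
  }
  if (params$noise_sd > 0) {
    img <- img + matrix(rnorm(side^2, 0, params$noise_sd), side, side)
  }
  matrix(as.integer(pmin(pmax(round(img), 0), 65535)), side, side)
}

#' Simulate a daily-imaged micropatterned plate
#'
#' Generates one 16-bit grayscale image per (well, grid position, day)
#' together with the ground-truth cell counts. Colonies are seeded clonally
#' (Poisson) and evolved with the daily birth-death process of
#' [clone_sim_params()]; nuclei are rendered as Gaussian spots confined to
#' the feature disk. Ground truth is for scoring downstream counting and
#' growth analysis only — the analysis operations never read it.
#'
#' @param layout A [plate_layout()].
#' @param params A [clone_sim_params()].
#' @param n_days Number of daily imaging rounds (>= 1).
#' @param wells Integer vector of well ids to simulate (default `1`).
#' @param dir If non-`NULL`, write images as TIFF files named
#'   `well{W}_pos{RRR}x{CCC}_day{D}.tif` into `dir` and return file paths;
#'   otherwise images are returned in-memory as a list column.
#' @return A list with elements `images` (tibble: `well`, `grid_row`,
#'   `grid_col`, `day`, and either `image` (list of integer matrices) or
#'   `path`) and `truth` (tibble: `well`, `grid_row`, `grid_col`, `day`,
#'   `true_count`).
#' @examples
#' layout <- plate_layout(grid_rows = 2, grid_cols = 2)
#' sim <- generate_plate_timelapse(layout, clone_sim_params(), n_days = 3)
#' sim$truth
#' @export
generate_plate_timelapse <- function(layout, params, n_days,
                                     wells = 1L, dir = NULL) {
  stopifnot(inherits(layout, "plate_layout"), inherits(params, "clone_sim_params"))
  assert_scalar_number(n_days, "n_days", min = 1)
  side <- feature_image_px(layout)
  if (side < 1) abort("Layout implies non-positive image dimensions.")
  r_disk <- layout$feature_diameter_um / 2 * layout$pixels_per_um
  c0 <- c((side + 1) / 2, (side + 1) / 2)
  grid <- tidyr::expand_grid(
    well = as.integer(wells),
    grid_row = seq_len(layout$grid_rows),
    grid_col = seq_len(layout$grid_cols)
  )
  n_f <- nrow(grid)

  sizes <- rpois(n_f, params$seeding_density_lambda)
  truth <- vector("list", n_days)
  imgs <- vector("list", n_days)
  to_disk <- !is.null(dir)
  if (to_disk && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  for (d in seq_len(n_days)) {
    if (d > 1L) sizes <- step_sizes(sizes, params)
    counts <- as.integer(round(sizes))
    truth[[d]] <- dplyr::mutate(grid, day = d, true_count = counts)
    day_imgs <- vector("list", n_f)
    for (i in seq_len(n_f)) {
      centres <- place_nuclei(counts[i], c0,
                              r_disk - params$nucleus_radius_px,
                              2.4 * params$nucleus_radius_px)
      img <- render_feature_image(centres, side, params)
      if (to_disk) {
        path <- file.path(dir, feature_image_filename(
          grid$well[i], grid$grid_row[i], grid$grid_col[i], d))
        write_feature_tiff(img, path)
        day_imgs[[i]] <- path
      } else {
        day_imgs[[i]] <- img
      }
    }
    imgs[[d]] <- dplyr::mutate(grid, day = d)
    if (to_disk) {
      imgs[[d]]$path <- unlist(day_imgs)
    } else {
      imgs[[d]]$image <- day_imgs
    }
  }

  list(
    images = dplyr::arrange(dplyr::bind_rows(imgs),
                            .data$well, .data$grid_row, .data$grid_col, .data$day),
    truth = dplyr::arrange(dplyr::bind_rows(truth),
                           .data$well, .data$grid_row, .data$grid_col, .data$day)
  )
}

#' Standard feature-image filename
#'
#' @param well,grid_row,grid_col,day Image coordinates.
#' @param ext File extension (default `"tif"`).
#' @return `well{W}_pos{RRR}x{CCC}_day{D}.{ext}` with zero-padded grid
#'   coordinates.
#' @export
feature_image_filename <- function(well, grid_row, grid_col, day, ext = "tif") {
  sprintf("well%d_pos%03dx%03d_day%d.%s", well, grid_row, grid_col, day, ext)
}

#' Write / read a 16-bit feature image
#'
#' Images are stored as single-channel 16-bit grayscale TIFF; PNG is accepted
#' on read. In-memory images are integer matrices of raw counts (0..65535).
#'
#' @param image Integer matrix of counts.
#' @param path File path (`.tif`/`.tiff` or `.png`).
#' @return `write_feature_tiff()` returns `path` invisibly;
#'   `read_feature_image()` returns an integer matrix.
#' @export
write_feature_tiff <- function(image, path) {
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_feature_tiff
#' @export
read_feature_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "png") {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}
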