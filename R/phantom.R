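#' Acoustic/optical medium presets
#'
#' Bundled optical and acoustic constants for the specimen classes the
#' instrument is used on. `"gel"` is a gelatin standard (negligible optical
#' attenuation, water-like acoustics); `"brain"` carries the near-infrared
#' excitation attenuation length calibrated so that the three-photon
#' photoacoustic signal decays with a 250 um 1/e length, together with the
#' 50 um near-ultraviolet emission extinction length; `"organoid"` is
#' brain-like but with a 1.5x longer excitation attenuation length, since
#' engineered neural tissue scatters and absorbs less than brain.
#'
#' @param name one of `"gel"`, `"brain"`, `"organoid"`, `"water"`.
#' @return a list with elements `L_I_um` (excitation intensity 1/e attenuation
#'   length, um), `L_em_um` (emission 1/e extinction length, um), `c_m_s`
#'   (sound speed, m/s), `alpha_db_mm_mhz` (acoustic attenuation coefficient,
#'   dB/(mm*MHz^b)) and `alpha_exponent` (b).
#' @export
medium_preset <- function(name = c("gel", "brain", "organoid", "water")) {
  name <- match.arg(name)
  base <- list(
    gel      = list(L_I_um = 1e6,        L_em_um = 1e6, c_m_s = 1500,
                    alpha_db_mm_mhz = 4 / 270, alpha_exponent = 1),
    brain    = list(L_I_um = 750,        L_em_um = 50,  c_m_s = 1540,
                    alpha_db_mm_mhz = 4 / 270, alpha_exponent = 1),
    organoid = list(L_I_um = 750 * 1.5,  L_em_um = 50,  c_m_s = 1540,
                    alpha_db_mm_mhz = 4 / 270, alpha_exponent = 1),
    water    = list(L_I_um = 1e6,        L_em_um = 1e6, c_m_s = 1500,
                    alpha_db_mm_mhz = 0,      alpha_exponent = 1)
  )
  out <- base[[name]]
  out$name <- name
  out
}

#' Construct a specimen phantom
#'
#' A phantom is a 3D voxel grid of chromophore concentration together with the
#' optical and acoustic constants of the embedding medium. Coordinates: z = 0
#' at the specimen top surface (the objective side), z increasing toward the
#' transducer below the specimen; voxel centers sit at `(i - 0.5) * pitch`.
#'
#' @param concentration 3D numeric array of concentration in mM, indexed
#'   `[x, y, z]`. Must be finite and non-negative.
#' @param pitch_um voxel pitch in um (> 0, isotropic).
#' @param medium a medium list as returned by [medium_preset()], or a preset
#'   name.
#' @return an object of class `"phantom"`.
#' @export
phantom <- function(concentration, pitch_um, medium = "gel") {
  if (is.character(medium)) medium <- medium_preset(medium)
  if (!is.array(concentration) || length(dim(concentration)) != 3L)
    stop("`concentration` must be a 3D array [x, y, z]")
  if (!all(is.finite(concentration)))
    stop("`concentration` must be finite everywhere")
  if (any(concentration < 0))
    stop("`concentration` must be non-negative")
  if (!is.numeric(pitch_um) || length(pitch_um) != 1L || pitch_um <= 0)
    stop("`pitch_um` must be a single positive number")
  stopifnot(medium$L_I_um > 0, medium$L_em_um > 0, medium$c_m_s > 0,
            medium$alpha_db_mm_mhz >= 0)
  structure(
    list(concentration = concentration, pitch_um = pitch_um, medium = medium),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$concentration)
  cat(sprintf("phantom: %d x %d x %d voxels at %.3g um pitch (%s medium)\n",
              d[1], d[2], d[3], x$pitch_um, x$medium$name))
  cat(sprintf("  extent: %.3g x %.3g x %.3g um, concentration %.3g-%.3g mM\n",
              d[1] * x$pitch_um, d[2] * x$pitch_um, d[3] * x$pitch_um,
              min(x$concentration), max(x$concentration)))
  invisible(x)
}

# voxel-center coordinate vectors (um) for each axis
phantom_axes <- function(ph) {
  d <- dim(ph$concentration)
  lapply(1:3, function(i) (seq_len(d[i]) - 0.5) * ph$pitch_um)
}

#' Gel cylinder standard phantom
#'
#' A uniform-concentration cylinder in a bounding box, emulating the gelatin
#' NADH standards cast in a cylindrical mold (the bench standard is 3 mm in
#' diameter and 1.58 mm in height). The cylinder axis is vertical (z).
#'
#' @param concentration_mM uniform concentration inside the cylinder (>= 0).
#' @param diameter_mm,height_mm cylinder geometry in mm (> 0).
#' @param pitch_um voxel pitch in um (> 0).
#' @param medium medium preset name or list; default `"gel"`.
#' @return a [phantom()].
#' @export
make_gel_cylinder <- function(concentration_mM, diameter_mm = 3,
                              height_mm = 1.58, pitch_um = 10,
                              medium = "gel") {
  if (concentration_mM < 0) stop("`concentration_mM` must be >= 0")
  if (diameter_mm <= 0 || height_mm <= 0 || pitch_um <= 0)
    stop("cylinder geometry and pitch must be positive")
  d_um <- diameter_mm * 1e3
  h_um <- height_mm * 1e3
  nx <- max(1L, ceiling(d_um / pitch_um))
  nz <- max(1L, ceiling(h_um / pitch_um))
  xs <- (seq_len(nx) - 0.5) * pitch_um - d_um / 2
  r2 <- outer(xs^2, xs^2, `+`)                 # squared lateral radius, nx x nx
  inside <- r2 <= (d_um / 2)^2
  C <- array(0, dim = c(nx, nx, nz))
  C[] <- rep(as.numeric(inside) * concentration_mM, times = nz)
  phantom(C, pitch_um, medium)
}

#' Spherical organoid phantom
#'
#' A sphere of tissue with a radial concentration profile, emulating a
#' cerebral organoid (default diameter 1.2 mm). The sphere top touches z = 0.
#'
#' @param diameter_mm sphere diameter in mm (> 0).
#' @param concentration_profile either a single non-negative number (uniform
#'   concentration, mM) or a function of radius in um returning mM.
#' @param pitch_um voxel pitch in um.
#' @param medium medium preset; default `"organoid"`.
#' @return a [phantom()].
#' @export
make_organoid <- function(diameter_mm = 1.2, concentration_profile = 1,
                          pitch_um = 10, medium = "organoid") {
  if (diameter_mm <= 0 || pitch_um <= 0)
    stop("`diameter_mm` and `pitch_um` must be positive")
  d_um <- diameter_mm * 1e3
  n <- max(1L, ceiling(d_um / pitch_um))
  ax <- (seq_len(n) - 0.5) * pitch_um - d_um / 2
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))  # radius from center, um
  if (is.function(concentration_profile)) {
    C <- array(concentration_profile(as.vector(r)), dim = dim(r))
  } else {
    if (length(concentration_profile) != 1L || concentration_profile < 0)
      stop("uniform `concentration_profile` must be a single non-negative value")
    C <- array(concentration_profile, dim = dim(r))
  }
  if (any(!is.finite(C)) || any(C < 0))
    stop("concentration profile must be finite and non-negative")
  C[r > d_um / 2] <- 0
  phantom(C, pitch_um, medium)
}

#' Random field of cells
#'
#' `n_cells` non-overlapping spheres of elevated concentration at seeded
#' uniform-random positions in a cubic field over a uniform background,
#' a stand-in for cultured-cell and tissue-slice specimens (typical neurons
#' are 5-15 um across).
#'
#' @param n_cells number of cells (>= 0).
#' @param cell_diameter_um cell diameter in um.
#' @param intra_mM,background_mM intracellular and background concentration,
#'   `intra_mM >= background_mM >= 0`.
#' @param field_um edge length of the cubic field, um.
#' @param pitch_um voxel pitch, um.
#' @param seed integer seed; the grid is reproducible for a fixed seed.
#' @param medium medium preset; default `"brain"`.
#' @param max_tries placement retries per cell before giving up.
#' @return a [phantom()] with attribute `"cell_centers_um"` (n x 3 matrix).
#' @export
make_cell_field <- function(n_cells, cell_diameter_um = 10, intra_mM = 10,
                            background_mM = 0.5, field_um = 150,
                            pitch_um = 2, seed = 1, medium = "brain",
                            max_tries = 1000L) {
  if (n_cells < 0) stop("`n_cells` must be >= 0")
  if (!(intra_mM >= background_mM && background_mM >= 0))
    stop("need intra_mM >= background_mM >= 0")
  n <- max(1L, ceiling(field_um / pitch_um))
  C <- array(background_mM, dim = c(n, n, n))
  centers <- matrix(numeric(0), ncol = 3)
  if (n_cells > 0) {
    rad <- cell_diameter_um / 2
    centers <- with_seed(seed, {
      acc <- matrix(NA_real_, nrow = n_cells, ncol = 3)
      placed <- 0L
      tries <- 0L
      while (placed < n_cells) {
        if (tries >= max_tries * n_cells)
          stop("field too small to place ", n_cells,
               " non-overlapping cells (placement error)")
        cand <- stats::runif(3, min = rad, max = field_um - rad)
        ok <- placed == 0L ||
          all(sqrt(rowSums((acc[seq_len(placed), , drop = FALSE] -
                              matrix(cand, placed, 3, byrow = TRUE))^2)) >=
                cell_diameter_um)
        if (ok) {
          placed <- placed + 1L
          acc[placed, ] <- cand
        }
        tries <- tries + 1L
      }
      acc
    })
    ax <- (seq_len(n) - 0.5) * pitch_um
    for (k in seq_len(n_cells)) {
      dx2 <- (ax - centers[k, 1])^2
      dy2 <- (ax - centers[k, 2])^2
      dz2 <- (ax - centers[k, 3])^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= rad^2
      C[inside] <- intra_mM
    }
  }
  ph <- phantom(C, pitch_um, medium)
  attr(ph, "cell_centers_um") <- centers
  ph
}

#' Add a fiducial fiber to a phantom
#'
#' Overwrites a cylinder of contrast concentration along a straight line,
#' emulating the hair fibers added to standard samples to provide spatial
#' features for image registration.
#'
#' @param ph a [phantom()].
#' @param from_um,to_um line endpoints, length-3 um coordinates.
#' @param diameter_um fiber diameter, um.
#' @param contrast_mM concentration written into the fiber voxels.
#' @return the modified [phantom()].
#' @export
add_fiducial_fiber <- function(ph, from_um, to_um, diameter_um = 80,
                               contrast_mM = 20) {
  stopifnot(inherits(ph, "phantom"), length(from_um) == 3, length(to_um) == 3)
  v <- to_um - from_um
  len <- sqrt(sum(v^2))
  if (len == 0) stop("zero-length fiber line (invalid argument)")
  axes <- phantom_axes(ph)
  d <- dim(ph$concentration)
  # distance of each voxel center to the segment
  grid <- expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]])
  p <- as.matrix(grid) - matrix(from_um, nrow(grid), 3, byrow = TRUE)
  tpar <- pmin(pmax((p %*% v) / len^2, 0), 1)
  closest <- tpar %*% t(v)
  dist <- sqrt(rowSums((p - closest)^2))
  inside <- array(dist <= diameter_um / 2, dim = d)
  if (!any(inside)) stop("fiber does not intersect the phantom grid")
  C <- ph$concentration
  C[inside] <- contrast_mM
  phantom(C, ph$pitch_um, ph$medium)
}

#' Concentration sampled at arbitrary points
#'
#' Nearest-voxel lookup of the concentration field; points outside the grid
#' return 0 (no chromophore outside the specimen).
#'
#' @param ph a [phantom()].
#' @param xyz_um n x 3 matrix of um coordinates.
#' @return numeric vector of concentrations in mM.
#' @export
phantom_concentration_at <- function(ph, xyz_um) {
  d <- dim(ph$concentration)
  idx <- ceiling(xyz_um / ph$pitch_um)
  idx[xyz_um == 0] <- 1L
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- numeric(nrow(idx))
  if (any(ok)) {
    lin <- (idx[ok, 3] - 1) * d[1] * d[2] + (idx[ok, 2] - 1) * d[1] + idx[ok, 1]
    out[ok] <- ph$concentration[lin]
  }
  out
}
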