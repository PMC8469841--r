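#' Phantom generator configuration
#'
#' Synthetic CT-like volumes with a geometrically consistent landmark: a
#' bright spheroid (the "aortic root") with an attached bright tube (the
#' "coronary artery") whose junction on the sphere surface is the target --
#' the ostium analogy. The junction, rather than the free tube tip, is the
#' landmark, because its surroundings (sphere wall plus emerging tube) look
#' the same in every generated volume, which is what makes it learnable.
#'
#' @param dims Volume dimensions in voxels (default `c(64, 64, 64)`).
#' @param spacing_mm Isotropic voxel size in mm (default 0.33, so 3 voxels
#'   are about 1 mm).
#' @param sphere_radius_range Sphere radius range in voxels (default 10 to
#'   14, drawn uniformly).
#' @param tube_radius,tube_length Tube geometry in voxels (defaults 2 and
#'   18).
#' @param fg,bg Foreground / background intensity means (defaults 0.8 and
#'   0.15).
#' @param noise_sd Gaussian noise standard deviation (default 0.03).
#' @param margin Minimum distance (voxels) of the landmark and tube from
#'   every volume face (default 8, half the desk-scale patch size, so
#'   observations at the target are padding-free).
#' @param seed Seed; the same seed reproduces the volume bit for bit.
#' @return An object of class `"phantom_config"`.
#' @export
phantom_config <- function(dims = c(64L, 64L, 64L), spacing_mm = 0.33,
                           sphere_radius_range = c(10, 14), tube_radius = 2,
                           tube_length = 18, fg = 0.8, bg = 0.15,
                           noise_sd = 0.03, margin = 8L, seed = 1L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 8), spacing_mm > 0,
            length(sphere_radius_range) == 2,
            sphere_radius_range[1] <= sphere_radius_range[2],
            sphere_radius_range[1] > 0, tube_radius > 0, tube_length > 0,
            noise_sd >= 0, margin >= 0, fg >= 0, fg <= 1, bg >= 0, bg <= 1)
  if (min(dims) / 2 < sphere_radius_range[2] + margin)
    stop("geometry cannot fit: sphere radius plus margin exceeds half the volume",
         call. = FALSE)
  structure(list(dims = dims, spacing_mm = spacing_mm,
                 sphere_radius_range = as.numeric(sphere_radius_range),
                 tube_radius = as.numeric(tube_radius),
                 tube_length = as.numeric(tube_length), fg = fg, bg = bg,
                 noise_sd = noise_sd, margin = as.numeric(margin),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# uniform direction on the unit sphere
random_direction <- function() {
  repeat {
    u <- rnorm(3)
    n <- sqrt(sum(u^2))
    if (n > 1e-8) return(u / n)
  }
}

#' Generate one phantom volume with its landmark
#'
#' Draws a sphere center uniformly within the central third of the volume,
#' a radius from `sphere_radius_range`, and a tube direction uniformly on
#' the sphere (re-drawn until the landmark and the whole tube respect the
#' configured face margin; a geometry that cannot fit raises an error).
#' The volume is `bg` plus the sphere and tube at `fg`, plus Gaussian
#' noise, clipped to `[0, 1]`. The landmark is the sphere-surface /
#' tube-axis junction voxel. Deterministic per `cfg$seed`.
#'
#' @param cfg A [phantom_config].
#' @return A list with `volume` (a [volume]), `landmark` (a [landmark]
#'   named `"ostium"`), and `geometry` (the drawn sphere center, radius,
#'   tube direction and exact junction point, useful for geometric checks).
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(derive_seed(cfg$seed, "phantom"))
  d <- cfg$dims
  ok <- FALSE
  for (try in seq_len(200)) {
    center <- vapply(d, function(n) runif(1, n / 3, 2 * n / 3), numeric(1))
    radius <- runif(1, cfg$sphere_radius_range[1], cfg$sphere_radius_range[2])
    dir <- random_direction()
    junction <- center + radius * dir
    tube_end <- junction + cfg$tube_length * dir
    lm_vox <- round_half_away(junction)
    fits <- all(lm_vox >= cfg$margin) && all(lm_vox <= d - 1 - cfg$margin) &&
      all(tube_end >= cfg$tube_radius + 1) &&
      all(tube_end <= d - 1 - cfg$tube_radius - 1) &&
      all(center - radius >= 1) && all(center + radius <= d - 2)
    if (fits) { ok <- TRUE; break }
  }
  if (!ok)
    stop("phantom geometry cannot fit inside the configured dimensions",
         call. = FALSE)
  # voxel coordinate grids (0-based)
  px <- array(rep(0:(d[1] - 1), times = d[2] * d[3]), dim = d)
  py <- array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), dim = d)
  pz <- array(rep(0:(d[3] - 1), each = d[1] * d[2]), dim = d)
  dx <- px - center[1]; dy <- py - center[2]; dz <- pz - center[3]
  in_sphere <- dx^2 + dy^2 + dz^2 <= radius^2
  # distance to the tube axis segment [junction, tube_end]
  ax <- px - junction[1]; ay <- py - junction[2]; az <- pz - junction[3]
  t_par <- ax * dir[1] + ay * dir[2] + az * dir[3]
  t_par <- pmin(pmax(t_par, 0), cfg$tube_length)
  in_tube <- (ax - t_par * dir[1])^2 + (ay - t_par * dir[2])^2 +
    (az - t_par * dir[3])^2 <= cfg$tube_radius^2
  img <- array(cfg$bg, dim = d)
  img[in_sphere | in_tube] <- cfg$fg
  if (cfg$noise_sd > 0)
    img <- img + array(rnorm(prod(d), 0, cfg$noise_sd), dim = d)
  img <- pmin(pmax(img, 0), 1)
  v <- volume(img, spacing = rep(cfg$spacing_mm, 3))
  list(volume = v,
       landmark = landmark("ostium", as.integer(lm_vox), volume = v),
       geometry = list(center = center, radius = radius, direction = dir,
                       junction = junction))
}

#' Generate a phantom suite with a train/test split
#'
#' Creates `n` phantoms with seeds `base_seed, ..., base_seed + n - 1` and
#' a manifest assigning the first 75% to the training split and the rest
#' to the test split (so `n = 32` gives the 24 train / 8 test layout).
#' When `out_dir` is given, volumes are written as NIfTI, landmarks as
#' JSON, and the manifest as CSV.
#'
#' @param n Number of phantoms.
#' @param base_seed First seed.
#' @param cfg A [phantom_config] (its `seed` field is overridden per
#'   phantom).
#' @param out_dir Optional output directory.
#' @return A list with `volumes`, `landmarks` (parallel lists), and
#'   `manifest` (data.frame with id, seed, split, landmark voxel, file).
#' @export
generate_suite <- function(n, base_seed = 1L, cfg = phantom_config(),
                           out_dir = NULL) {
  stopifnot(n >= 1)
  n_train <- round(0.75 * n)
  vols <- vector("list", n)
  lms <- vector("list", n)
  rows <- vector("list", n)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(n)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(base_seed + i - 1L)
    ph <- generate_phantom(cfg_i)
    vols[[i]] <- ph$volume
    lms[[i]] <- ph$landmark
    fname <- sprintf("phantom_%03d.nii.gz", i)
    if (!is.null(out_dir)) {
      write_volume(ph$volume, file.path(out_dir, fname))
      attr(lms[[i]], "volume_file") <- fname
    }
    rows[[i]] <- data.frame(
      id = i, seed = cfg_i$seed,
      split = if (i <= n_train) "train" else "test",
      vx = ph$landmark$voxel[1], vy = ph$landmark$voxel[2],
      vz = ph$landmark$voxel[3], file = fname)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write_landmarks(lms, file.path(out_dir, "landmarks.json"))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(volumes = vols, landmarks = lms, manifest = manifest)
}
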