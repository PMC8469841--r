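#' Observation specification
#'
#' Controls how the agent sees the volume: patch side length `N`, the number
#' of past frames `H` kept alongside the current one, the linear intensity
#' window mapped to `[0, 1]`, and the raw-scale value used for samples
#' outside the volume.
#'
#' A patch centered at voxel `c` covers in-plane indices
#' `c - floor(N/2) ... c - floor(N/2) + N - 1`, so for even `N` the center is
#' slightly left/low-biased; this convention is fixed. The default window
#' `[0, 1]` suits the synthetic phantoms; for CT intensities in Hounsfield
#' units a window such as `c(-200, 800)` is appropriate. The padding default
#' is the window minimum, i.e. an air-equivalent neutral background that
#' normalizes to 0.
#'
#' @param N Patch side length in voxels (>= 3).
#' @param H Number of past frames kept (>= 0); the observation stack holds
#'   `H + 1` frames.
#' @param window Length-2 `c(lo, hi)` intensity window, `lo < hi`.
#' @param pad_value Raw-scale intensity used outside the volume bounds.
#' @return An object of class `"obs_spec"`.
#' @export
obs_spec <- function(N = 32L, H = 3L, window = c(0, 1), pad_value = window[1]) {
  N <- as.integer(N); H <- as.integer(H)
  if (is.na(N) || N < 3) stop("'N' must be an integer >= 3", call. = FALSE)
  if (is.na(H) || H < 0) stop("'H' must be an integer >= 0", call. = FALSE)
  window <- as.numeric(window)
  if (length(window) != 2 || !all(is.finite(window)) || window[1] >= window[2])
    stop("'window' must be c(lo, hi) with lo < hi", call. = FALSE)
  structure(list(N = N, H = H, window = window, pad_value = as.numeric(pad_value)),
            class = "obs_spec")
}

#' @export
print.obs_spec <- function(x, ...) {
  cat(sprintf("<obs_spec> N = %d, H = %d (%d frames), window [%g, %g], pad %g\n",
              x$N, x$H, x$H + 1L, x$window[1], x$window[2], x$pad_value))
  invisible(x)
}

axis_index <- function(axis) {
  if (is.character(axis)) match(axis, c("x", "y", "z"))
  else as.integer(axis)
}

#' Extract one axis-normal patch
#'
#' Returns the `N x N` slice through `center` whose normal is the given
#' axis. The two in-plane axes keep their natural (x, y, z) order: an
#' x-normal patch spans (y, z), a y-normal patch (x, z), a z-normal patch
#' (x, y), with the first in-plane axis along patch rows. Samples outside
#' the grid take `spec$pad_value`; intensities are windowed to `[0, 1]`.
#' `center` may lie anywhere, including outside the grid (the patch is then
#' fully padded).
#'
#' @param v A [volume].
#' @param center Integer length-3, 0-based voxel index.
#' @param axis `"x"`, `"y"`, `"z"` or 1:3 (the patch normal).
#' @param spec An [obs_spec].
#' @return An `N x N` numeric matrix with values in `[0, 1]`.
#' @export
extract_plane_patch <- function(v, center, axis, spec) {
  stopifnot(inherits(v, "volume"), inherits(spec, "obs_spec"))
  ax <- axis_index(axis)
  if (is.na(ax) || ax < 1 || ax > 3)
    stop("'axis' must be one of \"x\", \"y\", \"z\" (or 1:3)", call. = FALSE)
  if (!is_int3(center)) stop("'center' must be three integer coordinates", call. = FALSE)
  m <- cpp_extract_patches(v$data, matrix(as.integer(center), 1, 3), ax,
                           spec$N, spec$window[1], spec$window[2], spec$pad_value)
  matrix(m[, 1], spec$N, spec$N)
}

# batched extraction: centers is an M x 3 matrix of 0-based voxel indices;
# returns an N^2 x M matrix, one windowed patch per column (first in-plane
# axis fastest)
extract_patches <- function(v, centers, axis, spec) {
  storage.mode(centers) <- "integer"
  cpp_extract_patches(v$data, centers, axis_index(axis), spec$N,
                      spec$window[1], spec$window[2], spec$pad_value)
}

# positions at times t, t-1, ..., t-H as an (H+1) x 3 matrix; when fewer
# than H past positions exist the oldest available is replicated
position_frames <- function(env, H) {
  frames <- H + 1L
  hist <- env$history
  out <- matrix(0L, frames, 3)
  out[1, ] <- env$position
  if (frames > 1) {
    n_hist <- nrow(hist)
    for (h in seq_len(frames - 1)) {
      out[h + 1, ] <- if (n_hist == 0) env$position
      else hist[min(h, n_hist), ]
    }
  }
  out
}

# build the per-axis plane batches fed to the network. pos_list is a list of
# B (H+1) x 3 position-frame matrices (possibly from different volumes,
# selected by vol_idx into vols). Columns are ordered frame-major: column
# b + (h-1) * B holds item b's frame h.
build_planes <- function(vols, vol_idx, pos_list, spec) {
  B <- length(pos_list)
  frames <- spec$H + 1L
  centers <- matrix(0L, B * frames, 3)
  for (h in seq_len(frames))
    for (b in seq_len(B))
      centers[(h - 1L) * B + b, ] <- pos_list[[b]][h, ]
  row_vol <- rep(vol_idx, frames)
  lapply(1:3, function(ax) {
    out <- matrix(0, spec$N^2, B * frames)
    for (vi in unique(row_vol)) {
      sel <- which(row_vol == vi)
      out[, sel] <- extract_patches(vols[[vi]], centers[sel, , drop = FALSE],
                                    ax, spec)
    }
    out
  })
}

planes_to_stack <- function(planes, spec, item = 1L, B = 1L) {
  frames <- spec$H + 1L
  N <- spec$N
  stack <- array(0, c(frames, 3, N, N))
  for (h in seq_len(frames))
    for (ax in 1:3)
      stack[h, ax, , ] <- matrix(planes[[ax]][, (h - 1L) * B + item], N, N)
  stack
}

stack_to_planes <- function(stacks, spec) {
  if (is.array(stacks) && length(dim(stacks)) == 4) stacks <- list(stacks)
  frames <- spec$H + 1L
  N <- spec$N
  B <- length(stacks)
  lapply(1:3, function(ax) {
    out <- matrix(0, N * N, B * frames)
    for (b in seq_len(B)) {
      st <- stacks[[b]]
      if (!identical(dim(st), as.integer(c(frames, 3, N, N))))
        stop(sprintf("observation stack %d has shape (%s); expected (%d, 3, %d, %d)",
                     b, paste(dim(st), collapse = ", "), frames, N, N),
             call. = FALSE)
      for (h in seq_len(frames))
        out[, (h - 1L) * B + b] <- as.vector(st[h, ax, , ])
    }
    out
  })
}

#' Observe the environment
#'
#' Builds the Markovian state: an `(H+1) x 3 x N x N` array where frame
#' `h` (1-based index `h + 1`) is the three-plane 2.5D patch at the agent's
#' position `h` steps in the past, and frame index 1 is the current
#' position. At episode start (or whenever fewer than `H` past positions
#' exist) missing frames replicate the oldest available observation, so a
#' freshly reset environment yields `H + 1` identical frames.
#'
#' @param v A [volume].
#' @param env An environment state from [env_reset()] / [env_step()].
#' @param spec An [obs_spec].
#' @return Numeric array of dimension `(H+1, 3, N, N)`, values in `[0, 1]`.
#' @export
observe <- function(v, env, spec) {
  stopifnot(inherits(v, "volume"), inherits(env, "env_state"),
            inherits(spec, "obs_spec"))
  pf <- position_frames(env, spec$H)
  planes <- build_planes(list(v), rep(1L, 1), list(pf), spec)
  planes_to_stack(planes, spec)
}
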