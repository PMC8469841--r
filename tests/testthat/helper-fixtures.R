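# shared fixtures: all built in code at test time

make_test_volume <- function(dims = c(16, 16, 16), seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  volume(array(runif(prod(dims)), dim = dims), spacing = spacing)
}

# independent brute-force patch sampler: per-pixel loops, no shared code
# with the compiled extractor
brute_force_patch <- function(v, center, axis, spec) {
  N <- spec$N
  half <- N %/% 2
  lo <- spec$window[1]; hi <- spec$window[2]
  d <- dim(v$data)
  ax <- if (is.character(axis)) match(axis, c("x", "y", "z")) else axis
  inplane <- switch(ax, c(2, 3), c(1, 3), c(1, 2))
  out <- matrix(0, N, N)
  for (j in seq_len(N)) {
    for (i in seq_len(N)) {
      p <- as.integer(center)
      p[inplane[1]] <- center[inplane[1]] - half + (i - 1)
      p[inplane[2]] <- center[inplane[2]] - half + (j - 1)
      val <- if (all(p >= 0) && all(p <= d - 1))
        v$data[p[1] + 1, p[2] + 1, p[3] + 1]
      else spec$pad_value
      out[i, j] <- (min(max(val, lo), hi) - lo) / (hi - lo)
    }
  }
  out
}

# stub policy descending the distance-to-target geometry: prefers the axis
# with the largest remaining displacement, stays once on the target
make_descent_policy <- function(gt_vox) {
  gt_vox <- as.numeric(gt_vox)
  function(v, pf) {
    p <- as.numeric(pf[1, ])
    disp <- gt_vox - p
    q <- rep(0, 7)
    if (all(disp == 0)) {
      q[7] <- 1
    } else {
      k <- which.max(abs(disp))
      q[2 * (k - 1) + if (disp[k] > 0) 1 else 2] <- 1
    }
    q
  }
}

# a small, quick-to-generate phantom configuration for plumbing tests
small_phantom_config <- function(seed = 1) {
  phantom_config(dims = c(32, 32, 32), sphere_radius_range = c(6, 8),
                 tube_radius = 1.5, tube_length = 8, margin = 4, seed = seed)
}

tiny_arch <- function(head_mode = "dueling") {
  arch_spec(N = 8, frames = 3, channels = c(4, 8), enc_dim = 16,
            local_dim = 12, global_dim = 20, head_mode = head_mode)
}

random_stack <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif((spec$H + 1) * 3 * spec$N^2), c(spec$H + 1, 3, spec$N, spec$N))
}

# zero out every learnable tensor of a parameter set
zero_params <- function(params) {
  parts <- qlandmark:::model_parts(params)
  for (p in parts)
    params[[p]] <- rapply(params[[p]], function(x) x * 0, how = "replace")
  params
}
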