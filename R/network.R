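#' Q-network architecture specification
#'
#' Describes the spatio-sequential encoding Q-network: a per-axis
#' convolutional encoder (weights shared across time frames, separate per
#' image axis), a per-frame local-inference layer fusing the three planes,
#' a global-inference layer over the concatenated frames, and either a
#' dueling head pair (state value V plus action advantage A) or a single
#' plain linear head.
#'
#' The reference encoder at `N = 32` is three 3x3 stride-2 convolutions
#' (1 -> 8 -> 16 -> 32 channels, zero padding 1), flatten, and a fully
#' connected layer to `enc_dim = 64`; local inference maps the 3 x 64
#' concatenation to 64 per frame; global inference maps the 4 x 64
#' concatenation to 128; heads are 128 -> 1 (V) and 128 -> 7 (A), or
#' 128 -> 7 (plain). All activations are ReLU. The FLOPs budget of the
#' architecture can be checked with [count_flops()].
#'
#' @param N Input patch side length (voxels).
#' @param frames Number of observation frames (`H + 1`).
#' @param channels Integer vector of convolution output channels.
#' @param kernel,stride Convolution kernel size and stride (zero padding is
#'   `kernel %/% 2`).
#' @param enc_dim Per-plane encoding width.
#' @param local_dim Per-frame local-inference width.
#' @param global_dim Global-inference width.
#' @param n_actions Number of actions (7).
#' @param head_mode `"dueling"` or `"plain"`.
#' @return An object of class `"arch_spec"`.
#' @export
arch_spec <- function(N = 32L, frames = 4L, channels = c(8L, 16L, 32L),
                      kernel = 3L, stride = 2L, enc_dim = 64L,
                      local_dim = 64L, global_dim = 128L, n_actions = 7L,
                      head_mode = c("dueling", "plain")) {
  head_mode <- match.arg(head_mode)
  N <- as.integer(N); frames <- as.integer(frames)
  channels <- as.integer(channels)
  kernel <- as.integer(kernel); stride <- as.integer(stride)
  stopifnot(N >= 3, frames >= 1, length(channels) >= 1, all(channels >= 1),
            kernel >= 1, stride >= 1, enc_dim >= 1, local_dim >= 1,
            global_dim >= 1, n_actions >= 2)
  pad <- kernel %/% 2L
  conv <- list()
  n <- N; c_in <- 1L
  for (i in seq_along(channels)) {
    m <- (n + 2L * pad - kernel) %/% stride + 1L
    if (m < 1) stop(sprintf("conv layer %d collapses the %d-voxel plane", i, n),
                    call. = FALSE)
    conv[[i]] <- list(n_in = n, c_in = c_in, c_out = channels[i],
                      kernel = kernel, stride = stride, pad = pad, n_out = m)
    n <- m; c_in <- channels[i]
  }
  structure(list(N = N, frames = frames, conv = conv,
                 flat_dim = n * n * c_in,
                 enc_dim = as.integer(enc_dim), local_dim = as.integer(local_dim),
                 global_dim = as.integer(global_dim),
                 n_actions = as.integer(n_actions), head_mode = head_mode),
            class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec> N = %d, frames = %d, head = %s\n", x$N, x$frames,
              x$head_mode))
  for (l in x$conv)
    cat(sprintf("  conv %dx%d/%d: %d -> %d ch, %d -> %d px\n", l$kernel,
                l$kernel, l$stride, l$c_in, l$c_out, l$n_in, l$n_out))
  cat(sprintf("  encoder FC %d -> %d; local FC %d -> %d (x%d frames); global FC %d -> %d\n",
              x$flat_dim, x$enc_dim, 3 * x$enc_dim, x$local_dim, x$frames,
              x$frames * x$local_dim, x$global_dim))
  if (x$head_mode == "dueling")
    cat(sprintf("  heads: V %d -> 1, A %d -> %d\n", x$global_dim, x$global_dim,
                x$n_actions))
  else
    cat(sprintf("  head: %d -> %d\n", x$global_dim, x$n_actions))
  invisible(x)
}

# im2col gather tables for one conv layer: a (k^2 * c_in) x (m^2) 0-based
# index matrix into the flattened (spatial-major, channel blocks) input,
# with out-of-plane taps mapped to the pad slot (row n^2 * c_in of the
# zero-extended input). Row order within a column is (du fastest, dv, then
# channel); column order is (u_out fastest, v_out), matching the patch
# layout used everywhere else.
conv_layer_indices <- function(l) {
  n <- l$n_in; k <- l$kernel; s <- l$stride; pad <- l$pad
  m <- l$n_out; c_in <- l$c_in
  npix <- n * n
  du <- rep(0:(k - 1), times = k)
  dv <- rep(0:(k - 1), each = k)
  start <- (seq_len(m) - 1L) * s - pad             # 0-based window starts
  u0 <- rep(start, times = m)
  v0 <- rep(start, each = m)
  U <- outer(du, u0, "+")                          # k^2 x m^2
  V <- outer(dv, v0, "+")
  inb <- U >= 0 & U < n & V >= 0 & V < n
  base <- V * n + U
  base[!inb] <- NA
  idx <- matrix(0L, k * k * c_in, m * m)
  pad_row <- npix * c_in
  for (ch in seq_len(c_in) - 1L) {
    blk <- base + ch * npix
    blk[is.na(blk)] <- pad_row
    idx[ch * k * k + seq_len(k * k), ] <- blk
  }
  list(idx0 = as.integer(idx), in_rows = npix * c_in, c_out = l$c_out,
       mm = m * m, kkcin = k * k * c_in)
}

conv_indices <- function(arch) lapply(arch$conv, conv_layer_indices)

param_geometry <- function(params) {
  g <- attr(params, "geometry")
  if (is.null(g)) g <- conv_indices(params$arch)
  g
}

he_uniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize network parameters
#'
#' Parameters are partitioned as: `theta` -- the per-axis convolutional
#' encoders (one set per image axis x, y, z; each reused for every time
#' frame of that axis); `omega` -- one local-inference layer per frame (not
#' shared across frames); `global` -- the global-inference layer; and the
#' heads (`value` + `adv` for dueling, `out` for plain). Weights are
#' He-uniform, biases zero.
#'
#' @param arch An [arch_spec].
#' @param seed Integer seed for the initialization draw.
#' @return An object of class `"essenet_params"`; the architecture is
#'   carried in `$arch`.
#' @export
essenet_init <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "arch_spec"))
  set.seed(derive_seed(seed, "net-init"))
  init_encoder <- function() {
    convs <- lapply(arch$conv, function(l) {
      kk <- l$kernel^2 * l$c_in
      list(W = he_uniform(l$c_out, kk, kk), b = numeric(l$c_out))
    })
    list(conv = convs,
         fc = list(W = he_uniform(arch$enc_dim, arch$flat_dim, arch$flat_dim),
                   b = numeric(arch$enc_dim)))
  }
  params <- list(
    arch = arch,
    theta = list(x = init_encoder(), y = init_encoder(), z = init_encoder()),
    omega = lapply(seq_len(arch$frames), function(h)
      list(W = he_uniform(arch$local_dim, 3L * arch$enc_dim, 3L * arch$enc_dim),
           b = numeric(arch$local_dim))),
    global = list(W = he_uniform(arch$global_dim, arch$frames * arch$local_dim,
                                 arch$frames * arch$local_dim),
                  b = numeric(arch$global_dim)))
  if (arch$head_mode == "dueling") {
    params$value <- list(W = he_uniform(1L, arch$global_dim, arch$global_dim),
                         b = numeric(1))
    params$adv <- list(W = he_uniform(arch$n_actions, arch$global_dim,
                                      arch$global_dim),
                       b = numeric(arch$n_actions))
  } else {
    params$out <- list(W = he_uniform(arch$n_actions, arch$global_dim,
                                      arch$global_dim),
                       b = numeric(arch$n_actions))
  }
  attr(params, "geometry") <- conv_indices(arch)
  class(params) <- "essenet_params"
  params
}

#' @export
print.essenet_params <- function(x, ...) {
  n_par <- sum(vapply(param_leaves(x), length, numeric(1)))
  cat(sprintf("<essenet_params> %s head, %d learnable parameters\n",
              x$arch$head_mode, n_par))
  print(x$arch)
  invisible(x)
}

# leaf tensors of a parameter (or gradient) list in a fixed canonical order
param_leaves <- function(params) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      nm <- names(x)
      for (i in seq_along(x)) {
        tag <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
        walk(x[[i]], paste0(prefix, ".", tag))
      }
    } else if (is.numeric(x)) {
      out[[prefix]] <<- x
    }
  }
  for (part in intersect(c("theta", "omega", "global", "value", "adv", "out"),
                         names(params)))
    walk(params[[part]], part)
  out
}

# strip the plane batches out of stacks and run the compiled forward pass
net_forward_planes <- function(params, planes) {
  par <- unclass(params)
  cpp_esse_forward(planes, par, param_geometry(params))
}

net_grad_planes <- function(params, planes, a_taken, y) {
  par <- unclass(params)
  cpp_esse_grad(planes, par, param_geometry(params), as.integer(a_taken),
                as.numeric(y))
}

#' Forward pass of the Q-network
#'
#' Computes action values for one observation stack or a list of stacks.
#' In dueling mode `Q = V + (A - mean(A))` (see [dueling_aggregate()]); in
#' plain mode Q is a direct linear head and `V`/`A` are absent. With
#' `trace = TRUE` (single stack only) a full [forward trace][essenet_trace]
#' with all intermediate encodings is returned instead.
#'
#' @param params An `"essenet_params"` object.
#' @param stacks An `(H+1) x 3 x N x N` observation stack, or a list of
#'   them.
#' @param trace Return the full forward trace (computed in double
#'   precision)?
#' @return A list with `Q` (`n_actions x B` matrix) and, in dueling mode,
#'   `V` (`1 x B`) and `A` (`n_actions x B`); or an `"essenet_trace"`.
#' @export
essenet_forward <- function(params, stacks, trace = FALSE) {
  stopifnot(inherits(params, "essenet_params"))
  spec_like <- list(N = params$arch$N, H = params$arch$frames - 1L)
  if (trace) {
    if (is.list(stacks) && !is.array(stacks)) {
      if (length(stacks) != 1) stop("trace = TRUE requires a single stack",
                                    call. = FALSE)
      stacks <- stacks[[1]]
    }
    return(essenet_trace(params, stacks))
  }
  planes <- stack_to_planes(stacks, structure(spec_like, class = "obs_spec"))
  net_forward_planes(params, planes)
}

#' Reference forward trace
#'
#' A straightforward double-precision implementation of the forward pass
#' that exposes every intermediate quantity: the per-plane encodings
#' `t[[h]][[j]]`, per-frame concatenations `T[[h]]`, local inferences
#' `Tbar[[h]]`, the global input `sbar`, the global encoding `g`, and the
#' head outputs. Used for inspection and as a cross-check of the compiled
#' single-precision path.
#'
#' @param params An `"essenet_params"` object.
#' @param stack One `(H+1) x 3 x N x N` observation stack.
#' @return An object of class `"essenet_trace"`.
#' @export
essenet_trace <- function(params, stack) {
  arch <- params$arch
  geom <- param_geometry(params)
  frames <- arch$frames
  relu <- function(x) pmax(x, 0)
  axes <- c("x", "y", "z")
  t_hj <- vector("list", frames)
  for (h in seq_len(frames)) {
    t_hj[[h]] <- vector("list", 3)
    for (j in 1:3) {
      x <- as.vector(stack[h, j, , ])
      enc <- params$theta[[axes[j]]]
      for (l in seq_along(enc$conv)) {
        gm <- geom[[l]]
        xp <- c(x, 0)
        xcol <- matrix(xp[gm$idx0 + 1L], gm$kkcin, gm$mm)
        y <- enc$conv[[l]]$W %*% xcol + enc$conv[[l]]$b   # c_out x mm
        x <- as.vector(t(y))                              # mm-major per channel
        x <- relu(x)
      }
      t_hj[[h]][[j]] <- relu(as.vector(enc$fc$W %*% x + enc$fc$b))
    }
  }
  T_h <- lapply(t_hj, function(tl) c(tl[[1]], tl[[2]], tl[[3]]))
  Tbar <- lapply(seq_len(frames), function(h)
    relu(as.vector(params$omega[[h]]$W %*% T_h[[h]] + params$omega[[h]]$b)))
  sbar <- unlist(Tbar)
  g <- relu(as.vector(params$global$W %*% sbar + params$global$b))
  out <- list(t = t_hj, T = T_h, Tbar = Tbar, sbar = sbar, g = g)
  if (arch$head_mode == "dueling") {
    out$V <- as.numeric(params$value$W %*% g + params$value$b)
    out$A <- as.vector(params$adv$W %*% g + params$adv$b)
    out$Q <- dueling_aggregate(out$V, out$A)
  } else {
    out$Q <- as.vector(params$out$W %*% g + params$out$b)
  }
  class(out) <- "essenet_trace"
  out
}

#' Dueling aggregation of state value and action advantages
#'
#' `Q_a = V + A_a - mean(A)`. Subtracting the advantage mean makes the
#' decomposition identifiable: adding a constant to every advantage leaves
#' Q unchanged, and `mean(Q) = V` holds exactly.
#'
#' @param V Scalar state value (or length-B vector for a batch).
#' @param A Advantage vector (or `n_actions x B` matrix).
#' @return Q with the same shape as `A`.
#' @export
dueling_aggregate <- function(V, A) {
  if (is.matrix(A)) {
    sweep(A, 2, colMeans(A) - as.vector(V))
  } else {
    stopifnot(length(V) == 1)
    V + A - mean(A)
  }
}
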