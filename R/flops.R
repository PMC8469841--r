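#' Per-layer FLOPs table for an architecture
#'
#' Counts one multiply-accumulate per convolution / fully-connected output
#' element as one FLOP (`output_elements x kernel_volume x in_channels`);
#' biases, activations, pooling and the dueling mean-subtraction are
#' excluded. The per-axis encoder cost is multiplied by the number of plane
#' passes per forward, `frames x 3` (every frame of every axis passes
#' through an encoder of identical shape); each per-frame local-inference
#' layer runs once, as do the global layer and the heads.
#'
#' @param arch An [arch_spec].
#' @return A data.frame with columns `layer`, `out_elements`,
#'   `macs_per_element`, `passes`, `flops`.
#' @export
flops_table <- function(arch) {
  stopifnot(inherits(arch, "arch_spec"))
  passes <- arch$frames * 3L
  rows <- list()
  add <- function(layer, out_el, macs, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      layer = layer, out_elements = out_el, macs_per_element = macs,
      passes = p, flops = as.numeric(out_el) * macs * p)
  }
  for (i in seq_along(arch$conv)) {
    l <- arch$conv[[i]]
    add(sprintf("encoder conv%d %dx%d/%d %d->%d", i, l$kernel, l$kernel,
                l$stride, l$c_in, l$c_out),
        l$n_out^2 * l$c_out, l$kernel^2 * l$c_in, passes)
  }
  add(sprintf("encoder fc %d->%d", arch$flat_dim, arch$enc_dim),
      arch$enc_dim, arch$flat_dim, passes)
  add(sprintf("local fc %d->%d (per frame)", 3L * arch$enc_dim, arch$local_dim),
      arch$local_dim, 3L * arch$enc_dim, arch$frames)
  add(sprintf("global fc %d->%d", arch$frames * arch$local_dim, arch$global_dim),
      arch$global_dim, arch$frames * arch$local_dim, 1L)
  if (arch$head_mode == "dueling") {
    add(sprintf("value head %d->1", arch$global_dim), 1L, arch$global_dim, 1L)
    add(sprintf("advantage head %d->%d", arch$global_dim, arch$n_actions),
        arch$n_actions, arch$global_dim, 1L)
  } else {
    add(sprintf("output head %d->%d", arch$global_dim, arch$n_actions),
        arch$n_actions, arch$global_dim, 1L)
  }
  do.call(rbind, rows)
}

#' Total FLOPs of one forward pass
#'
#' @inheritParams flops_table
#' @return Total FLOPs (numeric scalar) under the 1 MAC = 1 FLOP
#'   convention.
#' @seealso [flops_table()] for the per-layer breakdown.
#' @export
count_flops <- function(arch) {
  sum(flops_table(arch)$flops)
}
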