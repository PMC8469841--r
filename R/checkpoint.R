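#' Save / load network parameters
#'
#' Checkpoints are self-describing: the architecture specification travels
#' with the parameter tensors, and loading verifies it against an expected
#' architecture when one is supplied (patch size, frame count, layer widths
#' and head mode must all match).
#'
#' @param params An `"essenet_params"` object.
#' @param path Checkpoint file path.
#' @return `save_params`: `path`, invisibly. `load_params`: the restored
#'   `"essenet_params"`.
#' @export
save_params <- function(params, path) {
  stopifnot(inherits(params, "essenet_params"))
  obj <- list(format = "qlandmark-checkpoint", version = 1L,
              arch = params$arch, params = unclass(params))
  obj$params$arch <- NULL
  attr(obj$params, "geometry") <- NULL
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_params
#' @param expected_arch Optional [arch_spec] the checkpoint must match.
#' @export
load_params <- function(path, expected_arch = NULL) {
  if (!file.exists(path))
    stop(sprintf("checkpoint not found: '%s'", path), call. = FALSE)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "qlandmark-checkpoint"))
    stop(sprintf("'%s' is not a qlandmark checkpoint", path), call. = FALSE)
  arch <- obj$arch
  if (!is.null(expected_arch)) {
    stopifnot(inherits(expected_arch, "arch_spec"))
    if (!identical(unclass(arch), unclass(expected_arch))) {
      diffs <- c()
      for (f in c("N", "frames", "head_mode", "enc_dim", "local_dim",
                  "global_dim", "n_actions"))
        if (!identical(arch[[f]], expected_arch[[f]]))
          diffs <- c(diffs, sprintf("%s: checkpoint %s vs expected %s", f,
                                    format(arch[[f]]), format(expected_arch[[f]])))
      if (length(diffs) == 0) diffs <- "convolutional layer structure differs"
      stop(sprintf("checkpoint architecture mismatch (%s)",
                   paste(diffs, collapse = "; ")), call. = FALSE)
    }
  }
  params <- obj$params
  params$arch <- arch
  attr(params, "geometry") <- conv_indices(arch)
  class(params) <- "essenet_params"
  params
}
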