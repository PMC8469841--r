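#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one root seed. Named sub-streams
#' (network initialization, environment resets, replay sampling, agent
#' spawning, ...) get their own derived seed so that changing one consumer
#' does not perturb the draws of another.
#'
#' @param seed Root integer seed.
#' @param stream Character name of the sub-stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  # exact in double arithmetic: all intermediates < 2^53
  as.integer((((seed %% m) * 1000003) %% m + h) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_int3 <- function(x) is.numeric(x) && length(x) == 3 && all(is.finite(x)) &&
  all(x == round(x))

check_named_list <- function(x, allowed, where) {
  if (is.null(x)) return(invisible(NULL))
  if (!is.list(x)) stop(sprintf("'%s' must be a mapping", where), call. = FALSE)
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0)
    stop(sprintf("unknown key%s in '%s': %s", if (length(bad) > 1) "s" else "",
                 where, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(NULL)
}

# round half away from zero, used when collapsing fractional voxel
# coordinates back onto the grid
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
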