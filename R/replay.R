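#' Experience replay buffer
#'
#' A FIFO ring of transitions with fixed capacity: once full, pushing a new
#' transition evicts the oldest. Sampling draws uniformly without
#' replacement within a batch. The buffer is a mutable handle (an R
#' environment), matching how it is threaded through the training loop.
#'
#' @param capacity Maximum number of stored transitions (default
#'   `1.5e5`).
#' @return An object of class `"replay_buffer"`.
#' @export
replay_buffer <- function(capacity = 1.5e5) {
  capacity <- as.integer(capacity)
  stopifnot(capacity >= 1)
  buf <- new.env(parent = emptyenv())
  buf$items <- vector("list", capacity)
  buf$capacity <- capacity
  buf$head <- 0L     # slot of the most recent push
  buf$size <- 0L
  class(buf) <- "replay_buffer"
  buf
}

#' @rdname replay_buffer
#' @param buf A replay buffer.
#' @param transition Any R object (typically a transition record with
#'   fields `s`, `a`, `r`, `s_next`, `terminal`).
#' @export
replay_push <- function(buf, transition) {
  stopifnot(inherits(buf, "replay_buffer"))
  buf$head <- buf$head %% buf$capacity + 1L
  buf$items[[buf$head]] <- transition
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

#' @rdname replay_buffer
#' @param k Batch size.
#' @export
replay_sample <- function(buf, k) {
  stopifnot(inherits(buf, "replay_buffer"))
  if (k > buf$size)
    stop(sprintf("cannot sample %d transitions from a buffer holding %d",
                 k, buf$size), call. = FALSE)
  buf$items[sample.int(buf$size, k)]
}

#' @rdname replay_buffer
#' @export
replay_size <- function(buf) buf$size

#' @rdname replay_buffer
#' @return `replay_contents`: the stored transitions, oldest first.
#' @export
replay_contents <- function(buf) {
  stopifnot(inherits(buf, "replay_buffer"))
  if (buf$size < buf$capacity) return(buf$items[seq_len(buf$size)])
  buf$items[c(seq_len(buf$capacity)[-seq_len(buf$head)], seq_len(buf$head))]
}

#' @export
print.replay_buffer <- function(x, ...) {
  cat(sprintf("<replay_buffer> %d / %d transitions\n", x$size, x$capacity))
  invisible(x)
}
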