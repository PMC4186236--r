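#' Named substream RNG registry
#'
#' A master seed fans out to named, independent random streams (e.g.
#' \code{"world"} for motor noise, \code{"protocol"} for trial-level draws,
#' \code{"fixtures"} for arena generation). Every stream keeps its own saved
#' generator state, so an ablated run (say, with the contextual layer
#' disabled) consumes exactly the same world-noise draws as the intact run
#' until the two behaviours actually diverge.
#'
#' @param master_seed single integer master seed.
#' @return an object of class \code{rng_registry}.
#' @export
rng_registry <- function(master_seed) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, is.finite(master_seed))
  reg <- new.env(parent = emptyenv())
  reg$master_seed <- as.integer(master_seed)
  reg$streams <- new.env(parent = emptyenv())
  class(reg) <- "rng_registry"
  reg
}

# Deterministic 31-bit hash of a stream name, mixed with the master seed.
stream_seed <- function(master_seed, name) {
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer((h + as.double(master_seed) * 2654435761) %% 2147483647)
}

#' Fetch (creating on demand) a named stream from a registry
#'
#' @param reg an \code{rng_registry}.
#' @param name stream name; the same name always yields the same stream.
#' @return an environment holding the stream's saved generator state.
#' @export
rng_stream <- function(reg, name) {
  stopifnot(inherits(reg, "rng_registry"))
  if (!exists(name, envir = reg$streams, inherits = FALSE)) {
    s <- new.env(parent = emptyenv())
    s$seed <- stream_seed(reg$master_seed, name)
    s$state <- NULL
    class(s) <- "rng_stream"
    assign(name, s, envir = reg$streams)
  }
  get(name, envir = reg$streams, inherits = FALSE)
}

# Run `expr` under the stream's generator state, then save the state back.
# The global .Random.seed is restored afterwards so package code never
# perturbs the caller's RNG.
with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  if (is.null(stream$state)) {
    set.seed(stream$seed)
  } else {
    assign(".Random.seed", stream$state, envir = globalenv())
  }
  out <- expr
  stream$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  out
}

#' Draw standard-normal deviates from a named stream
#' @param stream an \code{rng_stream}.
#' @param n number of deviates.
#' @param sd standard deviation.
#' @return numeric vector of length \code{n}.
#' @export
stream_rnorm <- function(stream, n, sd = 1) {
  if (sd == 0) return(rep(0, n))
  with_stream(stream, stats::rnorm(n, 0, sd))
}

#' Draw uniform deviates from a named stream
#' @inheritParams stream_rnorm
#' @param min,max range.
#' @return numeric vector of length \code{n}.
#' @export
stream_runif <- function(stream, n, min = 0, max = 1) {
  with_stream(stream, stats::runif(n, min, max))
}

#' Sample indices from a named stream
#' @inheritParams stream_rnorm
#' @param x vector (or single integer upper bound) to sample from.
#' @param size number of draws.
#' @param replace sample with replacement?
#' @return sampled values.
#' @export
stream_sample <- function(stream, x, size = 1, replace = FALSE) {
  with_stream(stream, sample(x, size, replace = replace))
}
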