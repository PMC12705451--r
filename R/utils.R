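# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package internals never
#' disturb the caller's random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a base seed and a stream index; stays below 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483629)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

logit <- function(p, eps = 1e-7) {
  p <- clamp_prob(p, eps)
  log(p / (1 - p))
}

inv_logit <- function(x) 1 / (1 + exp(-x))

# Coerce an image_fov or bare numeric array/matrix to a numeric array.
as_pixels <- function(x) {
  if (inherits(x, "image_fov")) x <- x$pixels
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

stop_if_shape_mismatch <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape-mismatch: images have dimensions ",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}
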