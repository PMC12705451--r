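# Iterative cycle inference: alternate the fixed best forward/backward
# transforms from a starting image so that transform errors accumulate into a
# detectable temporal signature. The transforms used for the cycle are the
# predetermined best checkpoints, configured independently of the model that
# produced the image under test.

new_cycle_sequence <- function(mode, frames, provenance) {
  structure(list(mode = mode, T = length(frames) %/% 2L, frames = frames,
                 provenance = provenance),
            class = "cycle_sequence")
}

#' @export
print.cycle_sequence <- function(x, ...) {
  cat(sprintf("<cycle_sequence %s, T=%d, %d frames (%s)>\n", x$mode, x$T,
              length(x$frames),
              paste(vapply(x$frames[seq_len(min(4, length(x$frames)))],
                           function(f) f$domain, character(1)),
                    collapse = ",")))
  invisible(x)
}

check_cycle_models <- function(g_vs, g_vaf) {
  if (g_vs$direction != "AF_TO_STAIN")
    stop("direction-mismatch: g_vs must map AF to STAIN", call. = FALSE)
  if (g_vaf$direction != "STAIN_TO_AF")
    stop("direction-mismatch: g_vaf must map STAIN to AF", call. = FALSE)
}

provenance_of <- function(g_vs, g_vaf) {
  list(g_vs = g_vs$id %||% paste0("epoch", g_vs$epoch %||% NA),
       g_vaf = g_vaf$id %||% paste0("epoch", g_vaf$epoch %||% NA))
}

#' Cycle inference starting from a measured autofluorescence image
#'
#' Builds the alternating sequence `(x0, y0, x1, y1, ..., x_{T-1}, y_{T-1})`
#' with `x_{t+1}` the backward transform of `y_t` and `y_t` the forward
#' transform of `x_t`. `x0` is the measured autofluorescence image and `y0`
#' the stained image under scrutiny (possibly produced by a different,
#' suspect model); the cycle itself always runs through the fixed transform
#' pair given here. Frames are clipped to `[0, 1]` after each transform.
#'
#' @param x0 AF-domain [image_fov] (the measurement).
#' @param y0 STAIN-domain [image_fov] (the image under test).
#' @param g_vs forward transform (`AF_TO_STAIN`).
#' @param g_vaf backward transform (`STAIN_TO_AF`).
#' @param T number of cycles (>= 1); the sequence has `2T` frames.
#' @return a `cycle_sequence`.
#' @export
run_cycle_vs_start <- function(x0, y0, g_vs, g_vaf, T = 5L) {
  stopifnot(T >= 1)
  check_cycle_models(g_vs, g_vaf)
  if (x0$domain != "AF" || y0$domain != "STAIN")
    stop("direction-mismatch: x0 must be AF, y0 must be STAIN", call. = FALSE)
  if (!identical(dim(x0$pixels)[1:2], dim(y0$pixels)[1:2]))
    stop("shape-mismatch: x0 and y0 differ in height/width", call. = FALSE)
  frames <- vector("list", 2L * T)
  frames[[1L]] <- x0
  frames[[2L]] <- y0
  x <- x0; y <- y0
  if (T >= 2) for (t in seq_len(T - 1L)) {
    x <- predict(g_vaf, y)
    y <- predict(g_vs, x)
    frames[[2L * t + 1L]] <- x
    frames[[2L * t + 2L]] <- y
  }
  new_cycle_sequence("VS_START", frames, provenance_of(g_vs, g_vaf))
}

#' Cycle inference starting from a stained image only
#'
#' When no autofluorescence measurement exists, the backward sequence is
#' shifted one step: `x_t` is the backward transform of `y_t` for
#' `t = 0..T-1` and `y_{t+1}` the forward transform of `x_t`, giving the
#' frame order `(y0, x0, ..., y_{T-1}, x_{T-1})` with `2T - 1` transform
#' calls in total.
#'
#' @param y0 STAIN-domain [image_fov].
#' @inheritParams run_cycle_vs_start
#' @return a `cycle_sequence`.
#' @export
run_cycle_hs_start <- function(y0, g_vs, g_vaf, T = 5L) {
  stopifnot(T >= 1)
  check_cycle_models(g_vs, g_vaf)
  if (y0$domain != "STAIN")
    stop("direction-mismatch: y0 must be STAIN", call. = FALSE)
  frames <- vector("list", 2L * T)
  y <- y0
  for (t in seq_len(T)) {
    x <- predict(g_vaf, y)
    frames[[2L * t - 1L]] <- y
    frames[[2L * t]] <- x
    if (t < T) y <- predict(g_vs, x)
  }
  new_cycle_sequence("HS_START", frames, provenance_of(g_vs, g_vaf))
}

stain_frames <- function(seq) Filter(function(f) f$domain == "STAIN",
                                     seq$frames)

#' Divergence profile of a cycle sequence
#'
#' Distance (or similarity) between each stain-domain frame `y_t` and the
#' starting stain frame `y_0`, as a diagnostic of how inference uncertainty
#' accumulates over the cycles. The first entry is the metric's identity
#' value (0 for mse, 1 for pcc/ssim, `Inf` for psnr).
#'
#' @param seq a `cycle_sequence`.
#' @param metric one of `"mse"`, `"pcc"`, `"psnr"`, `"ssim"`.
#' @return numeric vector of length `T`.
#' @export
cycle_divergence_profile <- function(seq, metric = c("mse", "pcc", "psnr",
                                                     "ssim")) {
  metric <- match.arg(metric)
  ys <- stain_frames(seq)
  fn <- switch(metric, mse = mse, pcc = pcc, psnr = psnr, ssim = ssim)
  vapply(ys, function(y) fn(y, ys[[1L]]), numeric(1))
}

#' Dump the frames of a cycle sequence as numbered images
#'
#' @param seq a `cycle_sequence`.
#' @param dir output directory.
#' @return character vector of file paths, invisibly.
#' @export
write_cycle_frames <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(seq$frames))
  for (i in seq_along(seq$frames)) {
    f <- seq$frames[[i]]
    paths[i] <- file.path(dir, sprintf("frame_%02d_%s.png", i - 1L,
                                       tolower(f$domain)))
    write_image(f, paths[i])
  }
  invisible(paths)
}
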