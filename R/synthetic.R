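# Synthetic paired-histology generator: seeded scenes with planted nuclei and
# a smooth cytoplasm texture, rendered into paired autofluorescence-like and
# stain-like (H&E-like) images, plus degradation operators that emulate the
# failure modes of a poorly generalising staining model (missing nuclei,
# blur, aberrant colour, noise).

#' Scene parameters for the synthetic generator
#'
#' @param size image side in pixels (square scenes), at least 16.
#' @param n_nuclei nucleus count: a single integer or an inclusive range
#'   `c(lo, hi)` sampled uniformly.
#' @param radius_range inclusive nucleus radius range in pixels, positive.
#' @param min_gap extra clearance in px required between disk boundaries
#'   (centre distance must exceed the radius sum plus this gap).
#' @return a list of validated parameters.
#' @export
scene_params <- function(size = 64, n_nuclei = c(6, 12), radius_range = c(2, 4),
                         min_gap = 1) {
  if (size < 16) stop("invalid-parameter: size must be >= 16 px", call. = FALSE)
  if (any(radius_range <= 0)) stop("invalid-parameter: radii must be > 0", call. = FALSE)
  if (max(radius_range) > size / 2)
    stop("invalid-parameter: radius range exceeds half the image size", call. = FALSE)
  if (length(n_nuclei) == 1L) n_nuclei <- c(n_nuclei, n_nuclei)
  stopifnot(n_nuclei[1] >= 0, n_nuclei[2] >= n_nuclei[1], min_gap >= 0)
  list(size = as.integer(size), n_nuclei = as.integer(n_nuclei),
       radius_range = as.numeric(radius_range), min_gap = as.numeric(min_gap))
}

# Smooth scalar field in [0, 1]: low-resolution seeded noise, bilinearly
# upsampled, then rescaled into [lo, hi].
smooth_field <- function(size, lo = 0.15, hi = 0.65) {
  g <- max(4L, size %/% 8L)
  base <- matrix(stats::runif(g * g), g, g)
  # bilinear interpolation onto the full grid
  src <- seq(1, g, length.out = size)
  i0 <- pmin(floor(src), g - 1L); fi <- src - i0
  f <- base[i0, , drop = FALSE] * (1 - fi) + base[i0 + 1L, , drop = FALSE] * fi
  f <- f[, i0, drop = FALSE] * rep(1 - fi, each = size) +
       f[, i0 + 1L, drop = FALSE] * rep(fi, each = size)
  rng <- range(f)
  if (diff(rng) < 1e-12) return(matrix((lo + hi) / 2, size, size))
  lo + (hi - lo) * (f - rng[1]) / diff(rng)
}

#' Sample a seeded ground-truth scene
#'
#' Places non-overlapping nucleus disks by rejection sampling (up to 1000
#' attempts per nucleus; a shortfall is recorded rather than looping forever)
#' and generates a smooth cytoplasm field. Regeneration with the same seed and
#' parameters is bit-identical.
#'
#' @param params a [scene_params] list.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap per nucleus.
#' @return an object of class `gt_scene` with fields `width`, `height`,
#'   `nuclei` (data frame `row`, `col`, `radius`), `cytoplasm` (matrix in
#'   `[0, 1]`), `seed`, `n_requested`, `n_placed`.
#' @export
sample_scene <- function(params = scene_params(), seed = 1, max_attempts = 1000) {
  s <- params$size
  with_seed(seed, {
    n_req <- if (params$n_nuclei[1] == params$n_nuclei[2]) params$n_nuclei[1]
             else sample(params$n_nuclei[1]:params$n_nuclei[2], 1L)
    rows <- cols <- radii <- numeric(0)
    if (n_req > 0) for (k in seq_len(n_req)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        r <- stats::runif(1, params$radius_range[1], params$radius_range[2])
        if (s - 2 * r - 2 <= 0) break
        rc <- stats::runif(2, r + 1, s - r)
        ok <- all(sqrt((rows - rc[1])^2 + (cols - rc[2])^2) >
                    radii + r + params$min_gap)
        if (ok) {
          rows <- c(rows, rc[1]); cols <- c(cols, rc[2]); radii <- c(radii, r)
          placed <- TRUE
          break
        }
      }
      if (!placed) break
    }
    cyto <- smooth_field(s)
    structure(list(width = s, height = s,
                   nuclei = data.frame(row = rows, col = cols, radius = radii),
                   cytoplasm = cyto, seed = as.integer(seed),
                   n_requested = n_req, n_placed = length(rows),
                   params = params),
              class = "gt_scene")
  })
}

#' @export
print.gt_scene <- function(x, ...) {
  cat(sprintf("<gt_scene %dx%d, %d/%d nuclei placed, seed %d>\n",
              x$height, x$width, x$n_placed, x$n_requested, x$seed))
  invisible(x)
}

# Binary nucleus mask rasterised from the scene's disks.
nuclei_mask <- function(scene, keep = seq_len(nrow(scene$nuclei))) {
  m <- matrix(0, scene$height, scene$width)
  nuc <- scene$nuclei[keep, , drop = FALSE]
  if (nrow(nuc) == 0) return(m)
  rr <- row(m); cc <- col(m)
  for (k in seq_len(nrow(nuc)))
    m[(rr - nuc$row[k])^2 + (cc - nuc$col[k])^2 <= nuc$radius[k]^2] <- 1
  m
}

#' Default rendering parameters
#'
#' Stain vectors are the standard haematoxylin and eosin optical-density
#' directions (unit-normalised `(0.65, 0.70, 0.29)` and `(0.07, 0.99, 0.11)`),
#' the widely used colour-deconvolution reference. Optical-density amplitudes
#' and autofluorescence gains are desk-scale defaults chosen so nuclei are
#' clearly darker than cytoplasm in both modalities.
#'
#' @param d_h,d_e optical-density amplitudes of the nuclei (haematoxylin) and
#'   cytoplasm (eosin) channels.
#' @param af_gain_nuclei,af_gain_cyto affine weights of the nucleus mask and
#'   cytoplasm field in the autofluorescence render.
#' @param af_noise_sd standard deviation of the seeded Gaussian noise added to
#'   the autofluorescence image.
#' @return a list of render parameters including unit stain vectors
#'   `v_h`, `v_e`.
#' @export
default_render_params <- function(d_h = 1.8, d_e = 0.9,
                                  af_gain_nuclei = 0.65, af_gain_cyto = 0.3,
                                  af_noise_sd = 0.02) {
  vh <- c(0.65, 0.70, 0.29); ve <- c(0.07, 0.99, 0.11)
  list(v_h = vh / sqrt(sum(vh^2)), v_e = ve / sqrt(sum(ve^2)),
       d_h = d_h, d_e = d_e,
       af_gain_nuclei = af_gain_nuclei, af_gain_cyto = af_gain_cyto,
       af_noise_sd = af_noise_sd)
}

render_stain <- function(scene, rp, keep = seq_len(nrow(scene$nuclei))) {
  mask <- nuclei_mask(scene, keep)
  px <- array(0, c(scene$height, scene$width, 3L))
  for (c in 1:3)
    px[, , c] <- exp(-(mask * rp$d_h * rp$v_h[c] +
                       scene$cytoplasm * rp$d_e * rp$v_e[c]))
  image_fov(clamp01(px), "STAIN")
}

render_af <- function(scene, rp) {
  mask <- nuclei_mask(scene)
  base <- rp$af_gain_nuclei * mask + rp$af_gain_cyto * scene$cytoplasm
  noise <- with_seed(derive_seed(scene$seed, 7L),
                     matrix(stats::rnorm(length(base), 0, rp$af_noise_sd),
                            nrow(base), ncol(base)))
  image_fov(clamp01(base + noise), "AF")
}

#' Render a paired autofluorescence/stain sample from a scene
#'
#' The stain image follows a Beer-Lambert-style optical-density model: per RGB
#' channel, `exp(-(mask * d_h * v_h + cytoplasm * d_e * v_e))`, clipped to
#' `[0, 1]`; deconvolving it with the same stain vectors recovers the nucleus
#' mask. The autofluorescence image is an affine combination of the nucleus
#' mask and cytoplasm field plus seeded Gaussian noise.
#'
#' @param scene a [sample_scene] result.
#' @param render_params see [default_render_params].
#' @return an object of class `paired_sample`: list with `af` (1-channel
#'   [image_fov]), `stain` (3-channel [image_fov]) and `scene`.
#' @export
render_pair <- function(scene, render_params = default_render_params()) {
  stopifnot(inherits(scene, "gt_scene"))
  rp <- render_params
  cross <- sum(rp$v_h * rp$v_e) / sqrt(sum(rp$v_h^2) * sum(rp$v_e^2))
  if (abs(cross) > 1 - 1e-8)
    stop("degenerate-stain-vectors: the two stain vectors are parallel",
         call. = FALSE)
  structure(list(af = render_af(scene, rp),
                 stain = render_stain(scene, rp),
                 scene = scene),
            class = "paired_sample")
}

#' Specify a degradation operator
#'
#' Degradations emulate the output of a hallucinating or technically failing
#' staining model: `nuclei_dropout` removes each planted nucleus independently
#' with probability `severity` (a realistic hallucination - structures missing
#' from the rendered tissue); `gaussian_blur` (sigma in px), `colour_shift`
#' (hue offset in fractions of a full turn) and `additive_noise` (Gaussian sd)
#' reproduce technical artefact modes; `compose` chains a list of specs.
#'
#' @param kind one of `"nuclei_dropout"`, `"gaussian_blur"`, `"colour_shift"`,
#'   `"additive_noise"`, `"compose"`.
#' @param severity non-negative severity; for `nuclei_dropout` a probability
#'   in `[0, 1]`.
#' @param seed integer seed for the stochastic kinds.
#' @param parts for `kind = "compose"`, a list of degradation specs.
#' @return an object of class `degradation_spec`.
#' @export
degradation_spec <- function(kind = c("nuclei_dropout", "gaussian_blur",
                                      "colour_shift", "additive_noise",
                                      "compose"),
                             severity = 0, seed = 1, parts = NULL) {
  kind <- match.arg(kind)
  if (severity < 0) stop("invalid-parameter: severity must be >= 0", call. = FALSE)
  if (kind == "nuclei_dropout" && severity > 1)
    stop("invalid-parameter: dropout severity must lie in [0, 1]", call. = FALSE)
  if (kind == "compose" && !length(parts))
    stop("invalid-parameter: compose requires a list of parts", call. = FALSE)
  structure(list(kind = kind, severity = severity, seed = as.integer(seed),
                 parts = parts),
            class = "degradation_spec")
}

#' Apply a degradation operator to a stain image
#'
#' `severity = 0` is the identity for every kind. `nuclei_dropout` requires
#' the generating scene: it re-renders the scene with each nucleus removed
#' independently with probability `severity` under the spec's seed. All
#' outputs stay in `[0, 1]`.
#'
#' @param img a STAIN-domain [image_fov].
#' @param spec a [degradation_spec].
#' @param scene the generating `gt_scene` (required for `nuclei_dropout`).
#' @param render_params render parameters used for dropout re-rendering.
#' @return a degraded STAIN [image_fov].
#' @export
apply_degradation <- function(img, spec, scene = NULL,
                              render_params = default_render_params()) {
  stopifnot(is_image_fov(img), inherits(spec, "degradation_spec"))
  if (spec$kind == "compose") {
    for (p in spec$parts)
      img <- apply_degradation(img, p, scene = scene,
                               render_params = render_params)
    return(img)
  }
  if (spec$severity == 0) return(img)
  px <- img$pixels
  out <- switch(spec$kind,
    nuclei_dropout = {
      if (is.null(scene))
        stop("missing-scene: nuclei_dropout needs the generating scene",
             call. = FALSE)
      keep <- with_seed(spec$seed,
                        which(stats::runif(nrow(scene$nuclei)) >= spec$severity))
      render_stain(scene, render_params, keep = keep)$pixels
    },
    gaussian_blur = {
      b <- px
      for (c in seq_len(dim(px)[3]))
        b[, , c] <- EBImage::gblur(px[, , c], sigma = spec$severity)
      clamp01(b)
    },
    colour_shift = {
      if (dim(px)[3] != 3L)
        stop("colour_shift requires a 3-channel image", call. = FALSE)
      m <- matrix(aperm(px, c(3, 1, 2)), nrow = 3)
      hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
      hsv[1, ] <- (hsv[1, ] + spec$severity) %% 1
      rgb <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])) / 255
      aperm(array(rgb, c(3, dim(px)[1], dim(px)[2])), c(2, 3, 1))
    },
    additive_noise = {
      noise <- with_seed(spec$seed,
                         array(stats::rnorm(length(px), 0, spec$severity),
                               dim(px)))
      clamp01(px + noise)
    })
  image_fov(out, "STAIN")
}

#' Write a seeded fixture dataset to disk
#'
#' Renders paired samples, optionally degrades the stain image of a seeded
#' subset, writes 8-bit PNGs and a CSV manifest. The train/validation split is
#' a seeded shuffle at the configured counts; re-running with the same
#' configuration produces byte-identical files.
#'
#' @param config list with `n_train`, `n_val`, `n_test` (all >= 1), `size`,
#'   `seed`, optional `scene_params`, `render_params`, `degradations` (list of
#'   [degradation_spec]) and `degraded_fraction` (default 0.5 when
#'   degradations are supplied).
#' @param out_dir output directory (created if needed).
#' @return the manifest data frame (columns `path_af`, `path_stain`, `split`,
#'   `seed`, `label`), invisibly; also written to `manifest.csv`.
#' @export
build_fixture <- function(config, out_dir) {
  cfg <- config
  stopifnot(cfg$n_train >= 1, cfg$n_val >= 1, cfg$n_test >= 1)
  if (is.null(cfg$size)) cfg$size <- 64
  if (is.null(cfg$seed)) cfg$seed <- 1
  sp <- cfg$scene_params %||% scene_params(size = cfg$size)
  rp <- cfg$render_params %||% default_render_params()
  dfrac <- cfg$degraded_fraction %||% 0.5
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("io-error: cannot write to ", out_dir, call. = FALSE)

  n <- cfg$n_train + cfg$n_val + cfg$n_test
  split <- c(with_seed(derive_seed(cfg$seed, 1L),
                       sample(rep(c("train", "val"),
                                  c(cfg$n_train, cfg$n_val)))),
             rep("test", cfg$n_test))
  labels <- rep("clean", n)
  if (length(cfg$degradations)) {
    pick <- with_seed(derive_seed(cfg$seed, 2L), {
      deg <- stats::runif(n) < dfrac
      idx <- sample(length(cfg$degradations), n, replace = TRUE)
      ifelse(deg, idx, 0L)
    })
  } else pick <- rep(0L, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- sample_scene(sp, seed = derive_seed(cfg$seed, 100L + i))
    pair <- render_pair(sc, rp)
    stain <- pair$stain
    lab <- "clean"
    if (pick[i] > 0L) {
      spec <- cfg$degradations[[pick[i]]]
      spec$seed <- derive_seed(cfg$seed, 500L + i)
      stain <- apply_degradation(stain, spec, scene = sc, render_params = rp)
      lab <- spec$kind
    }
    pa <- file.path(out_dir, sprintf("%04d_af.png", i))
    ps <- file.path(out_dir, sprintf("%04d_stain.png", i))
    write_image(pair$af, pa)
    write_image(stain, ps)
    rows[[i]] <- data.frame(path_af = basename(pa), path_stain = basename(ps),
                            split = split[i], seed = sc$seed, label = lab,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
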