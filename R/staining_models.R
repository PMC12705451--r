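# Forward (AF -> STAIN) and backward (STAIN -> AF) staining transforms:
# small encoder-decoder generators trained with the composite losses, an
# adversarial discriminator for the forward direction, per-epoch checkpoints
# with validation losses, and the grey-zone good/poor labelling rule.

#' Training configuration for the staining transforms
#'
#' Loss weights follow the published settings: forward transform
#' `alpha = 1, beta = 0.05, gamma = 0.01, delta = 0.01`; backward transform
#' `alpha = 1, beta = 0.05, gamma = 0.01, delta = 0.05, epsilon = 0.01`;
#' SSIM constants `c1 = 0.01`, `c2 = 0.03`; generator:discriminator update
#' ratio 3:1; Adam optimiser. The `"desk"` preset uses a learning rate of
#' 1e-3 and small networks so that training converges in seconds on 64 px
#' fixtures; the `"full"` preset uses the published learning rate of 1e-5.
#'
#' @param preset `"desk"` or `"full"`.
#' @param lr learning rate (overrides the preset).
#' @param max_epochs number of training epochs (one checkpoint each).
#' @param base_channels generator/discriminator base channel count.
#' @param update_ratio integer pair: generator steps per discriminator step.
#' @param seed training seed.
#' @return an object of class `training_config`.
#' @export
training_config <- function(preset = c("desk", "full"), lr = NULL,
                            max_epochs = 20L, base_channels = 8L,
                            update_ratio = c(3L, 1L), seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(lr)) lr <- if (preset == "desk") 1e-3 else 1e-5
  stopifnot(all(update_ratio >= 1), max_epochs >= 1)
  structure(list(
    vs_weights = c(alpha = 1, beta = 0.05, gamma = 0.01, delta = 0.01),
    vaf_weights = c(alpha = 1, beta = 0.05, gamma = 0.01, delta = 0.05,
                    epsilon = 0.01),
    c1 = 0.01, c2 = 0.03,
    lr = lr, max_epochs = as.integer(max_epochs),
    base_channels = as.integer(base_channels),
    update_ratio = as.integer(update_ratio),
    preset = preset, seed = as.integer(seed)),
    class = "training_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

new_transform_model <- function(direction, params, epoch, val_loss, cfg,
                                seed) {
  structure(list(direction = direction, params = params,
                 epoch = as.integer(epoch), val_loss = val_loss,
                 quality_label = "unlabeled", seed = as.integer(seed),
                 base_channels = cfg$base_channels,
                 config_hash = config_hash(cfg)),
            class = "transform_model")
}

#' @export
print.transform_model <- function(x, ...) {
  cat(sprintf("<transform_model %s epoch %d, val_loss %.4f, label %s>\n",
              x$direction, x$epoch, x$val_loss, x$quality_label))
  invisible(x)
}

transform_io_domains <- function(direction) {
  if (direction == "AF_TO_STAIN") c("AF", "STAIN") else c("STAIN", "AF")
}

#' Apply a staining transform to an image
#'
#' @param object a `transform_model`.
#' @param fov an [image_fov] in the transform's input domain.
#' @param ... unused.
#' @return an [image_fov] in the output domain, clipped to `[0, 1]`.
#' @export
predict.transform_model <- function(object, fov, ...) {
  io <- transform_io_domains(object$direction)
  if (is_image_fov(fov) && fov$domain != io[1])
    stop("direction-mismatch: model expects ", io[1], " input, got ",
         fov$domain, call. = FALSE)
  y <- gen_forward(object$params, as_pixels(fov))$y
  image_fov(clamp01(y), io[2])
}

# Wrap a plain function as a transform (used by tests and identity cycles).
#' Wrap a function as a staining transform
#'
#' Mainly for diagnostics and tests: wraps `fun` (pixels in, pixels out) so it
#' can stand in for a trained transform in cycle inference.
#' @param fun function taking and returning a pixel array.
#' @param direction `"AF_TO_STAIN"` or `"STAIN_TO_AF"`.
#' @param id optional identifier.
#' @return an object usable wherever a `transform_model` is.
#' @export
as_transform <- function(fun, direction = c("AF_TO_STAIN", "STAIN_TO_AF"),
                         id = "fn") {
  direction <- match.arg(direction)
  structure(list(fun = fun, direction = direction, id = id,
                 quality_label = "unlabeled"),
            class = c("transform_fn", "transform_model"))
}

#' @export
predict.transform_fn <- function(object, fov, ...) {
  io <- transform_io_domains(object$direction)
  if (is_image_fov(fov) && fov$domain != io[1])
    stop("direction-mismatch: transform expects ", io[1], " input, got ",
         fov$domain, call. = FALSE)
  image_fov(clamp01(object$fun(as_pixels(fov))), io[2])
}

# ---- training -------------------------------------------------------------

# In the training objective (and the recorded validation loss) the
# total-variation term is weighted per pixel: the raw-sum convention of
# tv_loss at mean-scale L1 would otherwise dominate every gradient and
# smooth all structure away.
tv_weight <- function(gamma, y) gamma / prod(dim(y)[1:2])

vs_val_loss <- function(gparams, dparams, pairs, cfg) {
  w <- cfg$vs_weights
  mean(vapply(pairs, function(pr) {
    y <- gen_forward(gparams, as_pixels(pr$af))$y
    p <- disc_forward(dparams, y)$p
    t <- as_pixels(pr$stain)
    w[["alpha"]] * l1_loss(y, t) +
      ssim_term(y, t, w[["beta"]], cfg$c1, cfg$c2) +
      tv_weight(w[["gamma"]], y) * tv_loss(y) +
      w[["delta"]] * bce_loss(p, 1)
  }, numeric(1)))
}

vaf_val_loss <- function(gparams, vs_model, pairs, cfg) {
  w <- cfg$vaf_weights
  mean(vapply(pairs, function(pr) {
    hs <- as_pixels(pr$stain)
    af <- as_pixels(pr$af)
    y <- gen_forward(gparams, hs)$y
    base <- w[["alpha"]] * l1_loss(y, af) +
      ssim_term(y, af, w[["beta"]], cfg$c1, cfg$c2) +
      tv_weight(w[["gamma"]], y) * tv_loss(y)
    if (is.null(vs_model)) return(base)
    z <- gen_forward(vs_model$params, y)$y
    base + w[["delta"]] * l1_loss(z, hs) +
      ssim_term(z, hs, w[["epsilon"]], cfg$c1, cfg$c2)
  }, numeric(1)))
}

#' Train a staining transform
#'
#' Adversarial training of the forward (AF to STAIN) transform at the
#' configured generator:discriminator update ratio, or composite training of
#' the backward (STAIN to AF) transform including the physical-consistency
#' terms through a fixed forward model. Inputs are standardised to zero mean
#' and unit variance per image before entering the network; outputs are
#' produced in `[0, 1]` by a sigmoid head. Inside the training objective (and
#' the recorded validation loss) the total-variation term is weighted per
#' pixel so that it stays commensurate with the mean-scale fidelity terms at
#' any image size. One checkpoint is recorded per epoch with its validation
#' loss; the whole loop is seeded and deterministic.
#'
#' @param train_pairs,val_pairs lists of `paired_sample` objects
#'   (at least 2 training and 1 validation pair).
#' @param direction `"AF_TO_STAIN"` or `"STAIN_TO_AF"`.
#' @param cfg a [training_config].
#' @param vs_model for `STAIN_TO_AF`: the fixed forward transform used by the
#'   physical-consistency terms. If `NULL`, those terms are dropped
#'   (equivalent to zeroing their weights).
#' @return list of `transform_model` checkpoints (one per epoch), with the
#'   training history attached as attribute `"history"`.
#' @export
train_transform <- function(train_pairs, val_pairs,
                            direction = c("AF_TO_STAIN", "STAIN_TO_AF"),
                            cfg = training_config(), vs_model = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(train_pairs) >= 2, length(val_pairs) >= 1)
  cin <- if (direction == "AF_TO_STAIN") 1L else 3L
  cout <- if (direction == "AF_TO_STAIN") 3L else 1L
  gparams <- gen_init_params(cin, cout, cfg$base_channels,
                             derive_seed(cfg$seed, 1L))
  gstate <- adam_init(gparams)
  use_disc <- direction == "AF_TO_STAIN"
  if (use_disc) {
    dparams <- disc_init_params(cout, cfg$base_channels,
                                derive_seed(cfg$seed, 2L))
    dstate <- adam_init(dparams)
  }
  w <- if (use_disc) cfg$vs_weights else cfg$vaf_weights
  checkpoints <- vector("list", cfg$max_epochs)
  history <- data.frame(epoch = integer(0), val_loss = numeric(0))
  gen_steps <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 100L + epoch),
                     sample(length(train_pairs)))
    for (i in ord) {
      pr <- train_pairs[[i]]
      x <- as_pixels(if (use_disc) pr$af else pr$stain)
      t <- as_pixels(if (use_disc) pr$stain else pr$af)
      fw <- gen_forward(gparams, x, keep_cache = TRUE)
      y <- fw$y
      dy <- w[["alpha"]] * l1_grad(y, t) +
        ssim_term_grad(y, t, w[["beta"]], cfg$c1, cfg$c2) +
        tv_weight(w[["gamma"]], y) * tv_grad(y)
      if (use_disc) {
        dfw <- disc_forward(dparams, y, keep_cache = TRUE)
        dp <- w[["delta"]] * bce_grad_p(dfw$p, 1)
        dy <- dy + disc_backward(dparams, dfw$cache, dp)$dx
      } else if (!is.null(vs_model)) {
        zfw <- gen_forward(vs_model$params, y, keep_cache = TRUE)
        dz <- w[["delta"]] * l1_grad(zfw$y, x) +
          ssim_term_grad(zfw$y, x, w[["epsilon"]], cfg$c1, cfg$c2)
        dy <- dy + gen_backward(vs_model$params, zfw$cache, dz)$dx
      }
      gb <- gen_backward(gparams, fw$cache, dy)
      up <- adam_step(gparams, gb$grads, gstate, cfg$lr)
      gparams <- up$params; gstate <- up$state
      gen_steps <- gen_steps + 1L

      if (use_disc && gen_steps %% cfg$update_ratio[1] == 0L) {
        for (rep in seq_len(cfg$update_ratio[2])) {
          ffake <- disc_forward(dparams, y, keep_cache = TRUE)
          gfake <- disc_backward(dparams, ffake$cache,
                                 bce_grad_p(ffake$p, 0) / 2)$grads
          freal <- disc_forward(dparams, t, keep_cache = TRUE)
          greal <- disc_backward(dparams, freal$cache,
                                 bce_grad_p(freal$p, 1) / 2)$grads
          gsum <- Map(function(a, b) Map(`+`, a, b), gfake, greal)
          dup <- adam_step(dparams, gsum, dstate, cfg$lr)
          dparams <- dup$params; dstate <- dup$state
        }
      }
    }
    vl <- if (use_disc) vs_val_loss(gparams, dparams, val_pairs, cfg)
          else vaf_val_loss(gparams, vs_model, val_pairs, cfg)
    if (!is.finite(vl))
      stop("non-finite-loss: validation loss diverged at epoch ", epoch,
           call. = FALSE)
    checkpoints[[epoch]] <- new_transform_model(direction, gparams, epoch, vl,
                                                cfg, cfg$seed)
    history <- rbind(history, data.frame(epoch = epoch, val_loss = vl))
  }
  attr(checkpoints, "history") <- history
  checkpoints
}

# ---- checkpoint labelling -------------------------------------------------

#' Grey-zone labelling rule for checkpoints
#'
#' A checkpoint with epoch `e` and validation loss `l` is labelled poor when
#' `e < e0` and `l > l0`, good when `e > e0` and `l < l0`, in both cases only
#' if it lies outside the grey zone `e in [e0 - epoch_margin, e0 +
#' epoch_margin]` and `l in [(1 - loss_margin) l0, (1 + loss_margin) l0]`;
#' everything else (including the quadrants where neither rule matches) is
#' grey. Published margins: epoch margin 50 (kidney) or 100 (lung), loss
#' margin 0.03.
#'
#' @param e0,l0 epoch and loss thresholds at the onset of convergence.
#' @param epoch_margin half-width of the epoch grey band.
#' @param loss_margin fractional half-width of the loss grey band.
#' @return an object of class `grey_zone_rule`.
#' @export
grey_zone_rule <- function(e0, l0, epoch_margin = 50, loss_margin = 0.03) {
  stopifnot(epoch_margin >= 0, loss_margin >= 0, loss_margin < 1)
  structure(list(e0 = e0, l0 = l0, epoch_margin = epoch_margin,
                 loss_margin = loss_margin),
            class = "grey_zone_rule")
}

#' Label checkpoints as good, poor or grey
#'
#' @param checkpoints list of `transform_model` checkpoints.
#' @param rule a [grey_zone_rule].
#' @return the checkpoints with `quality_label` set to one of
#'   `"good"`, `"poor"`, `"grey"`.
#' @export
label_checkpoints <- function(checkpoints, rule) {
  stopifnot(inherits(rule, "grey_zone_rule"))
  lapply(checkpoints, function(ck) {
    e <- ck$epoch; l <- ck$val_loss
    in_zone <- e >= rule$e0 - rule$epoch_margin &&
      e <= rule$e0 + rule$epoch_margin &&
      l >= (1 - rule$loss_margin) * rule$l0 &&
      l <= (1 + rule$loss_margin) * rule$l0
    ck$quality_label <-
      if (!in_zone && e < rule$e0 && l > rule$l0) "poor"
      else if (!in_zone && e > rule$e0 && l < rule$l0) "good"
      else "grey"
    ck
  })
}

# ---- serialization --------------------------------------------------------

#' Save a transform checkpoint
#'
#' Writes the serialised model state next to a JSON sidecar carrying
#' direction, epoch, validation loss, label, seed and configuration hash.
#' @param model a `transform_model`.
#' @param path output path for the state file (`.rds`); the sidecar gets the
#'   same path with extension `.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path, version = 2)
  sidecar <- list(direction = model$direction, epoch = model$epoch,
                  val_loss = model$val_loss, label = model$quality_label,
                  seed = model$seed, config_hash = model$config_hash)
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path),
                                       ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a transform checkpoint saved by [save_checkpoint]
#' @param path path to the `.rds` state file.
#' @return a `transform_model`.
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "transform_model"))
  m
}
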