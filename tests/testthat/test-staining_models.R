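test_that("scalar losses match brute-force oracles on random inputs", {
  set.seed(10)
  for (i in 1:100) {
    a <- random_image(8, 8, 1)
    b <- random_image(8, 8, 1)
    expect_equal(l1_loss(a, b), oracle_l1(a, b), tolerance = 1e-12)
    expect_equal(ssim(a, b), oracle_ssim(a[, , 1], b[, , 1]),
                 tolerance = 1e-12)
    expect_equal(tv_loss(a), oracle_tv(a), tolerance = 1e-12)
  }
  # multi-channel: SSIM averages channels, TV sums them
  a <- random_image(6, 6, 3); b <- random_image(6, 6, 3)
  expect_equal(ssim(a, b),
               mean(sapply(1:3, function(c) oracle_ssim(a[, , c], b[, , c]))),
               tolerance = 1e-12)
  expect_equal(tv_loss(a), oracle_tv(a), tolerance = 1e-12)
})

test_that("loss closed-form spot values hold", {
  a <- array(0, c(4, 4, 1)); b <- array(1, c(4, 4, 1))
  expect_equal(l1_loss(a, a), 0)
  expect_equal(l1_loss(a, b), 1)
  x <- random_image(5, 5, 1, seed = 1)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(a, b), 0.01 / 1.01, tolerance = 1e-12)
  expect_equal(tv_loss(array(0.3, c(4, 4, 1))), 0)
  expect_equal(tv_loss(array(c(0, 0, 1, 1), c(2, 2, 1))), 2)
  expect_equal(bce_loss(1, 1), 0, tolerance = 1e-6)
  expect_equal(bce_loss(0.5, 1), log10(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.9, 0), 1, tolerance = 1e-9)
  expect_error(tv_loss(array(0, c(1, 3, 1))), "too-small")
  expect_error(l1_loss(random_image(4, 4), random_image(5, 5)),
               "shape-mismatch")
})

test_that("composite generator losses equal their weighted term sums", {
  set.seed(3)
  cfg <- training_config()
  for (i in 1:20) {
    y <- random_image(8, 8, 3); t <- random_image(8, 8, 3); p <- runif(1)
    w <- cfg$vs_weights
    expected <- w[["alpha"]] * oracle_l1(y, t) -
      w[["beta"]] * log10((1 + mean(sapply(1:3, function(c)
        oracle_ssim(y[, , c], t[, , c])))) / 2) +
      w[["gamma"]] * oracle_tv(y) +
      w[["delta"]] * oracle_bce(p, 1)
    expect_equal(vs_generator_loss(y, t, p, cfg), expected,
                 tolerance = 1e-12)
    # backward transform, five terms
    v <- random_image(8, 8, 1); af <- random_image(8, 8, 1)
    z <- random_image(8, 8, 3)
    wv <- cfg$vaf_weights
    expected_vaf <- wv[["alpha"]] * oracle_l1(v, af) -
      wv[["beta"]] * log10((1 + oracle_ssim(v[, , 1], af[, , 1])) / 2) +
      wv[["gamma"]] * oracle_tv(v) +
      wv[["delta"]] * oracle_l1(z, t) -
      wv[["epsilon"]] * log10((1 + mean(sapply(1:3, function(c)
        oracle_ssim(z[, , c], t[, , c])))) / 2)
    expect_equal(vaf_generator_loss(v, af, z, t, cfg), expected_vaf,
                 tolerance = 1e-12)
  }
  # perfect-generator limit and coefficient zeroing
  y <- random_image(8, 8, 3)
  expect_equal(vs_generator_loss(y, y, 1, cfg),
               cfg$vs_weights[["gamma"]] * tv_loss(y), tolerance = 1e-6)
  v <- random_image(8, 8, 1)
  expect_equal(vaf_generator_loss(v, v, y, y, cfg),
               cfg$vaf_weights[["gamma"]] * tv_loss(v), tolerance = 1e-6)
  cfg0 <- cfg
  cfg0$vaf_weights[c("delta", "epsilon")] <- 0
  z <- random_image(8, 8, 3); t <- random_image(8, 8, 3); af <- random_image(8, 8, 1)
  expect_equal(vaf_generator_loss(v, af, z, t, cfg0),
               cfg$vaf_weights[["alpha"]] * l1_loss(v, af) -
                 cfg$vaf_weights[["beta"]] * log10((1 + ssim(v, af)) / 2) +
                 cfg$vaf_weights[["gamma"]] * tv_loss(v),
               tolerance = 1e-12)
})

test_that("discriminator loss is symmetric and zero for a perfect judge", {
  expect_equal(vs_discriminator_loss(0, 1), 0, tolerance = 1e-6)
  expect_equal(vs_discriminator_loss(0.5, 0.5), log10(2), tolerance = 1e-9)
  set.seed(4)
  for (i in 1:20) {
    dv <- runif(1); dh <- runif(1)
    expect_equal(vs_discriminator_loss(dv, dh),
                 vs_discriminator_loss(1 - dh, 1 - dv), tolerance = 1e-12)
  }
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(5)
  y <- random_image(8, 8, 3); t <- random_image(8, 8, 3)
  cfg <- training_config()
  w <- cfg$vs_weights
  L <- function(yy) w[["alpha"]] * l1_loss(yy, t) +
    aquaqc:::ssim_term(yy, t, w[["beta"]], cfg$c1, cfg$c2) +
    w[["gamma"]] * tv_loss(yy)
  g <- w[["alpha"]] * aquaqc:::l1_grad(y, t) +
    aquaqc:::ssim_term_grad(y, t, w[["beta"]], cfg$c1, cfg$c2) +
    w[["gamma"]] * aquaqc:::tv_grad(y)
  eps <- 1e-6
  for (idx in list(c(2, 3, 1), c(8, 8, 3), c(5, 1, 2))) {
    ya <- y; ya[idx[1], idx[2], idx[3]] <- ya[idx[1], idx[2], idx[3]] + eps
    yb <- y; yb[idx[1], idx[2], idx[3]] <- yb[idx[1], idx[2], idx[3]] - eps
    expect_equal(g[idx[1], idx[2], idx[3]], (L(ya) - L(yb)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("network backpropagation matches finite differences", {
  set.seed(6)
  x <- random_image(16, 16, 1)
  t <- random_image(16, 16, 3)
  gp <- aquaqc:::gen_init_params(1, 3, 4, seed = 2)
  loss <- function(p) mean((aquaqc:::gen_forward(p, x)$y - t)^2)
  fw <- aquaqc:::gen_forward(gp, x, keep_cache = TRUE)
  gb <- aquaqc:::gen_backward(gp, fw$cache, 2 * (fw$y - t) / length(t))
  eps <- 1e-6
  num <- function(set) (loss(set(eps)) - loss(set(-eps))) / (2 * eps)
  expect_equal(gb$grads$c3$W[1, 2, 1, 2],
               num(function(e) { p <- gp; p$c3$W[1, 2, 1, 2] <- p$c3$W[1, 2, 1, 2] + e; p }),
               tolerance = 1e-5)
  expect_equal(gb$grads$c6$b[2],
               num(function(e) { p <- gp; p$c6$b[2] <- p$c6$b[2] + e; p }),
               tolerance = 1e-5)
  # input gradient (used by the physical-consistency terms)
  xa <- x; xa[5, 5, 1] <- xa[5, 5, 1] + eps
  xb <- x; xb[5, 5, 1] <- xb[5, 5, 1] - eps
  expect_equal(gb$dx[5, 5, 1],
               (mean((aquaqc:::gen_forward(gp, xa)$y - t)^2) -
                mean((aquaqc:::gen_forward(gp, xb)$y - t)^2)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("training runs, improves the validation loss, and is deterministic", {
  pairs <- tiny_pairs(8)
  cfg <- training_config("desk", max_epochs = 4, seed = 9)
  cks <- train_transform(pairs[1:6], pairs[7:8], "AF_TO_STAIN", cfg)
  h <- attr(cks, "history")
  expect_equal(nrow(h), 4)
  expect_lt(h$val_loss[4], h$val_loss[1])
  expect_true(all(is.finite(h$val_loss)))
  cks2 <- train_transform(pairs[1:6], pairs[7:8], "AF_TO_STAIN", cfg)
  expect_identical(serialize(cks[[4]]$params, NULL),
                   serialize(cks2[[4]]$params, NULL))
  # backward transform with physical consistency through the forward model
  vaf <- train_transform(pairs[1:6], pairs[7:8], "STAIN_TO_AF",
                         training_config("desk", max_epochs = 2, seed = 9),
                         vs_model = cks[[4]])
  expect_length(vaf, 2)
  expect_true(all(is.finite(attr(vaf, "history")$val_loss)))
  out <- predict(vaf[[2]], pairs[[1]]$stain)
  expect_equal(out$domain, "AF")
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
})

test_that("overfitting to a tiny subset shows a train/test gap", {
  pairs <- tiny_pairs(10)
  cfg <- training_config("desk", max_epochs = 12, seed = 13)
  cks <- train_transform(pairs[1:3], pairs[4:5], "AF_TO_STAIN", cfg)
  best <- cks[[length(cks)]]
  in_l1 <- mean(vapply(pairs[1:3], function(pr)
    l1_loss(predict(best, pr$af), pr$stain), numeric(1)))
  out_l1 <- mean(vapply(pairs[6:10], function(pr)
    l1_loss(predict(best, pr$af), pr$stain), numeric(1)))
  expect_gt(out_l1, in_l1)
})

test_that("checkpoint labelling implements the grey-zone rule exactly", {
  rule <- grey_zone_rule(e0 = 100, l0 = 1.0, epoch_margin = 50,
                         loss_margin = 0.03)
  mk <- function(e, l) structure(list(epoch = e, val_loss = l,
                                      quality_label = "unlabeled"),
                                 class = "transform_model")
  lab <- function(e, l) label_checkpoints(list(mk(e, l)), rule)[[1]]$quality_label
  expect_equal(lab(30, 1.5), "poor")
  expect_equal(lab(200, 0.5), "good")
  expect_equal(lab(100, 1.0), "grey")     # inside both bands
  expect_equal(lab(30, 0.5), "grey")      # quadrant where no rule matches
  expect_equal(lab(200, 1.5), "grey")
  expect_equal(lab(60, 1.5), "poor")      # inside epoch band, outside loss band
  expect_equal(lab(60, 1.01), "grey")     # inside both bands
  # partition property: every checkpoint gets exactly one label
  set.seed(20)
  cks <- lapply(1:50, function(i) mk(sample(1:300, 1), runif(1, 0.3, 2)))
  labs <- vapply(label_checkpoints(cks, rule), `[[`, character(1),
                 "quality_label")
  expect_true(all(labs %in% c("good", "poor", "grey")))
})

test_that("checkpoints serialise with a JSON sidecar and round-trip", {
  pairs <- tiny_pairs(4)
  cks <- train_transform(pairs[1:2], pairs[3:4], "AF_TO_STAIN",
                         training_config("desk", max_epochs = 1, seed = 2))
  path <- file.path(withr::local_tempdir(), "ck.rds")
  save_checkpoint(cks[[1]], path)
  side <- jsonlite::read_json(sub("rds$", "json", path))
  expect_equal(side$direction, "AF_TO_STAIN")
  expect_equal(side$epoch, 1L)
  m <- load_checkpoint(path)
  expect_identical(serialize(m$params, NULL),
                   serialize(cks[[1]]$params, NULL))
})
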