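test_that("stain deconvolution inverts the optical-density model", {
  # pure white: zero optical density everywhere
  white <- image_fov(array(1, c(8, 8, 3)), "STAIN")
  conc <- stain_deconvolve(white)
  expect_true(all(abs(conc$h) < 1e-12) && all(abs(conc$e) < 1e-12))
  # a pixel rendered from the haematoxylin vector alone has ~zero eosin
  sv <- hed_stain_vectors()
  px <- array(rep(10^(-0.8 * sv["h", ]), each = 16), c(4, 4, 3))
  conc <- stain_deconvolve(image_fov(px, "STAIN"))
  expect_true(all(abs(conc$e) < 1e-6))
  expect_true(all(conc$h > 0.7))
  # parallel vectors are rejected
  expect_error(stain_deconvolve(white, rbind(sv[1, ], sv[1, ])),
               "singular-stain-matrix")
  # synthetic round trip: nuclei channel correlates with the planted mask
  sc <- sample_scene(scene_params(64, n_nuclei = 10, radius_range = c(2, 3)),
                     seed = 8)
  pr <- render_pair(sc)
  conc <- stain_deconvolve(pr$stain)
  expect_gt(cor(as.numeric(conc$h), as.numeric(aquaqc:::nuclei_mask(sc))),
            0.99)
})

test_that("Otsu threshold maximises between-class variance", {
  # two-delta histogram: threshold strictly between the modes
  ch <- matrix(rep(c(0.2, 0.8), each = 32), 8, 8)
  thr <- otsu_threshold(ch)
  expect_gt(thr, 0.2); expect_lt(thr, 0.8)
  # brute-force oracle: exhaustive search over the same 256 candidate edges
  set.seed(40)
  ch <- matrix(runif(256)^2, 16, 16)
  edges <- seq(min(ch), max(ch), length.out = 257)
  between_var <- vapply(2:256, function(k) {
    thr <- edges[k]
    lo <- ch[ch <= thr]; hi <- ch[ch > thr]
    if (!length(lo) || !length(hi)) return(-Inf)
    # histogram-domain oracle: class stats over binned midpoints
    idx <- pmin(pmax(findInterval(ch, edges, rightmost.closed = TRUE), 1), 256)
    mids <- (edges[-1] + edges[-257]) / 2
    w0 <- mean(idx <= k - 1); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) return(-Inf)
    m0 <- mean(mids[idx[idx <= k - 1]]); m1 <- mean(mids[idx[idx > k - 1]])
    w0 * w1 * (m0 - m1)^2
  }, numeric(1))
  expect_equal(otsu_threshold(ch), edges[which.max(between_var) + 1],
               tolerance = 1e-12)
  # shift equivariance with a fixed range supplied
  thr0 <- otsu_threshold(ch, range = c(0, 1))
  thr1 <- otsu_threshold(ch + 0.1, range = c(0.1, 1.1))
  expect_equal(thr1, thr0 + 0.1, tolerance = 1e-9)
  expect_error(otsu_threshold(matrix(0.5, 4, 4)), "constant-image")
})

test_that("nuclei segmentation recovers planted well-separated disks", {
  sp <- scene_params(64, n_nuclei = 12, radius_range = c(3, 4), min_gap = 4)
  sc <- sample_scene(sp, seed = 21)
  pr <- render_pair(sc)
  conc <- stain_deconvolve(pr$stain)
  seg <- segment_nuclei(conc$h)
  expect_equal(seg$n_components, sc$n_placed)
  # blank channel: zero components, no error
  blank <- segment_nuclei(matrix(0, 32, 32))
  expect_equal(blank$n_components, 0)
})

test_that("component labelling is 8-connected", {
  m <- matrix(0, 5, 5)
  m[1, 1] <- 1; m[2, 2] <- 1; m[4, 4] <- 1; m[5, 5] <- 1
  lab <- aquaqc:::label_components_8(m)
  expect_equal(max(lab), 2)  # two diagonal chains
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(lab[4, 4], lab[5, 5])
  expect_false(lab[1, 1] == lab[4, 4])
})

test_that("adjacent disks merging is flagged in the merge diagnostic", {
  ch <- matrix(0, 32, 32)
  rr <- row(ch); cc <- col(ch)
  ch[(rr - 16)^2 + (cc - 12)^2 <= 9] <- 1   # radius-3 disk
  ch[(rr - 16)^2 + (cc - 17)^2 <= 9] <- 1   # 5 px away: overlapping waist
  seg <- segment_nuclei(ch, opening_radius = 1, expected_count = 2)
  expect_equal(seg$n_components, 1)         # the two disks fuse
  expect_equal(seg$merged_count, 1)
  # well-separated disks are not flagged
  ch2 <- matrix(0, 32, 32)
  ch2[(rr - 10)^2 + (cc - 10)^2 <= 9] <- 1
  ch2[(rr - 22)^2 + (cc - 22)^2 <= 9] <- 1
  seg2 <- segment_nuclei(ch2, opening_radius = 1, expected_count = 2)
  expect_equal(seg2$n_components, 2)
  expect_equal(seg2$merged_count, 0)
})

test_that("nuclei metrics satisfy the exact counting identities", {
  m <- matrix(0, 100, 100)
  m[10:14, 10:14] <- 1  # one 5x5 square
  q <- nuclei_metrics(m)
  expect_equal(q$normalized_nuclei_count, 1e-4)
  expect_equal(q$average_nuclei_area, 25)
  expect_equal(q$n_components, 1)
  empty <- nuclei_metrics(matrix(0, 10, 10))
  expect_equal(empty$n_components, 0)
  expect_true(is.na(empty$average_nuclei_area))
  # exact integer identity over random masks
  set.seed(41)
  for (i in 1:10) {
    mask <- matrix(rbinom(400, 1, 0.2), 20, 20)
    q <- nuclei_metrics(mask)
    expect_equal(q$normalized_nuclei_count * 400, q$n_components)
  }
})

test_that("feature-distribution comparison is calibrated and sensitive", {
  mk <- function(seed, shift = 0) {
    set.seed(seed)
    data.frame(nuclei_count = rpois(200, 8 + shift),
               average_area = rnorm(200, 28 + 3 * shift, 4))
  }
  same <- compare_feature_distributions(mk(1), mk(2))
  expect_equal(nrow(same), 2)
  expect_true(all(same$hellinger < 0.2))
  ident <- compare_feature_distributions(mk(3), mk(3))
  expect_equal(ident$hellinger, c(0, 0))
  expect_equal(ident$G, c(0, 0), tolerance = 1e-9)
  # null calibration: same distribution, mostly non-significant at 0.05
  set.seed(55)
  nonsig <- vapply(1:20, function(r) {
    a <- data.frame(nuclei_count = rpois(200, 8),
                    average_area = rnorm(200, 28, 4))
    b <- data.frame(nuclei_count = rpois(200, 8),
                    average_area = rnorm(200, 28, 4))
    !compare_feature_distributions(a, b)$significant
  }, logical(2))
  expect_gte(mean(nonsig), 0.9)  # per-test rate over 2 features x 20 draws
  # a strong dropout-like shift is detected and exceeds the null distance
  shifted <- compare_feature_distributions(mk(5), mk(6, shift = -4))
  expect_gt(shifted$hellinger[1], same$hellinger[1])
  expect_true(shifted$significant[1])
  expect_error(compare_feature_distributions(mk(1)[0, ], mk(2)), "empty-set")
})

test_that("image-set QC is order-invariant in distribution comparisons", {
  sp <- scene_params(48, n_nuclei = c(4, 9), radius_range = c(2, 3),
                     min_gap = 2)
  qcs <- lapply(1:12, function(i)
    qc_stain_image(render_pair(sample_scene(sp, seed = 60 + i))$stain))
  tab <- data.frame(
    nuclei_count = vapply(qcs, `[[`, numeric(1), "n_components"),
    average_area = vapply(qcs, `[[`, numeric(1), "average_nuclei_area"))
  a <- tab[1:6, ]; b <- tab[7:12, ]
  cmp1 <- compare_feature_distributions(a, b)
  cmp2 <- compare_feature_distributions(a[sample(6), ], b[sample(6), ])
  expect_equal(cmp1$hellinger, cmp2$hellinger, tolerance = 1e-12)
  expect_equal(cmp1$G, cmp2$G, tolerance = 1e-9)
})
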