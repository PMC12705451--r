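# Hand-crafted histochemical-stain QC: stain-vector colour deconvolution,
# Otsu thresholding, morphological clean-up, 8-connected component
# labelling, normalized nuclei count / average nuclei area, and
# feature-distribution comparison between two image sets.

#' Standard haematoxylin/eosin stain vectors
#'
#' Unit-normalised optical-density directions for haematoxylin (nuclei,
#' purple) and eosin (cytoplasm/extracellular matrix, pink).
#' @return 2 x 3 matrix with rows `h` and `e`.
#' @export
hed_stain_vectors <- function() {
  m <- rbind(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11))
  m / sqrt(rowSums(m^2))
}

#' Stain-vector colour deconvolution
#'
#' Converts an RGB stain image to optical density
#' `OD = -log10(max(rgb, floor))` and projects each pixel's OD vector onto
#' the stain vectors by least squares; negative concentrations are clipped
#' to 0. The OD floor (default 1/255) guards the logarithm at black pixels.
#'
#' @param rgb a 3-channel STAIN [image_fov] (or array).
#' @param stain_vectors matrix with 2-3 rows of unit OD vectors (default
#'   [hed_stain_vectors]).
#' @param od_floor minimum intensity entering the log.
#' @return list of per-stain concentration matrices, named by the rows of
#'   `stain_vectors`.
#' @export
stain_deconvolve <- function(rgb, stain_vectors = hed_stain_vectors(),
                             od_floor = 1 / 255) {
  px <- as_pixels(rgb)
  stopifnot(dim(px)[3] == 3L)
  S <- as.matrix(stain_vectors)
  if (abs(det(S %*% t(S))) < 1e-10)
    stop("singular-stain-matrix: stain vectors are linearly dependent",
         call. = FALSE)
  od <- -log10(pmax(px, od_floor))
  odm <- matrix(od, ncol = 3L)            # pixels x 3
  conc <- odm %*% t(S) %*% solve(S %*% t(S))  # least-squares projection
  conc[conc < 0] <- 0
  out <- lapply(seq_len(nrow(S)), function(k)
    matrix(conc[, k], dim(px)[1], dim(px)[2]))
  names(out) <- rownames(S) %||% paste0("stain", seq_len(nrow(S)))
  out
}

#' Otsu threshold of a scalar image
#'
#' Exhaustively maximises the between-class variance over a 256-level
#' histogram spanning `range` (the image's own range by default). The
#' returned threshold is in the image's units.
#'
#' @param channel numeric matrix with at least two distinct values.
#' @param levels histogram resolution.
#' @param range optional fixed `c(lo, hi)` range; disabling the default
#'   range normalisation makes the threshold shift-equivariant.
#' @return scalar threshold strictly inside the value range.
#' @export
otsu_threshold <- function(channel, levels = 256L, range = NULL) {
  v <- as.numeric(channel)
  if (is.null(range)) range <- base::range(v)
  if (diff(range) <= 0 || length(unique(v)) < 2)
    stop("constant-image: Otsu threshold undefined", call. = FALSE)
  edges <- seq(range[1], range[2], length.out = levels + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE),
                               1L), levels), nbins = levels)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- counts / sum(counts)
  best_t <- NA_real_; best_var <- -Inf
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mT <- cm[levels]
  for (k in seq_len(levels - 1L)) {
    w0 <- cw[k]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    m0 <- cm[k] / w0
    m1 <- (mT - cm[k]) / w1
    bv <- w0 * w1 * (m0 - m1)^2
    if (bv > best_var) { best_var <- bv; best_t <- edges[k + 1L] }
  }
  best_t
}

# 8-connected labelling: 4-connected labelling (EBImage) plus union of
# labels that touch diagonally.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl < 2) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- dim(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-d[1], -d[2]]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -d[2]]), as.vector(lab[-d[1], -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Segment nuclei from a deconvolved stain channel
#'
#' Thresholds the nuclei-stain concentration channel at its Otsu value,
#' applies a morphological opening (erosion then dilation with a disc
#' structuring element) and labels 8-connected components. When the true
#' nucleus count is supplied, components lost to merging are flagged in a
#' merge-count diagnostic.
#'
#' @param nuclei_channel scalar concentration image in arbitrary units.
#' @param opening_radius structuring-element radius in px (0 skips
#'   morphology).
#' @param expected_count optional ground-truth nucleus count for the merge
#'   diagnostic.
#' @return list with `mask` (binary matrix), `labels` (integer matrix),
#'   `n_components`, `n_components_raw` (before morphology) and
#'   `merged_count` (`NA` when `expected_count` is missing).
#' @export
segment_nuclei <- function(nuclei_channel, opening_radius = 1L,
                           expected_count = NULL) {
  ch <- if (is.matrix(nuclei_channel)) nuclei_channel
        else as_pixels(nuclei_channel)[, , 1]
  if (length(unique(as.numeric(ch))) < 2) {
    mask <- matrix(0L, nrow(ch), ncol(ch))
    return(list(mask = mask, labels = mask, n_components = 0L,
                n_components_raw = 0L,
                merged_count = if (is.null(expected_count)) NA_integer_
                               else as.integer(expected_count)))
  }
  thr <- otsu_threshold(ch)
  mask <- (ch > thr) * 1
  raw_labels <- label_components_8(mask)
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
    mask <- EBImage::dilate(EBImage::erode(mask, brush), brush)
    mask <- (mask > 0) * 1
  }
  labels <- label_components_8(mask)
  n <- max(labels)
  merged <- if (is.null(expected_count)) NA_integer_
            else max(0L, as.integer(expected_count) - n)
  list(mask = mask, labels = labels, n_components = n,
       n_components_raw = max(raw_labels), merged_count = merged)
}

#' Nuclei metrics from a segmentation
#'
#' Normalized nuclei count (components per pixel, px^-2; exactly
#' `n_components / total_pixels`) and the mean component area in px^2
#' (`NA` when the mask is empty).
#'
#' @param seg a [segment_nuclei] result, or a binary mask matrix.
#' @return an object of class `qc_metrics` with fields
#'   `normalized_nuclei_count`, `average_nuclei_area`, `n_components`,
#'   `nuclei_mask`.
#' @export
nuclei_metrics <- function(seg) {
  if (is.matrix(seg)) {
    labels <- label_components_8((seg > 0) * 1)
    seg <- list(mask = (seg > 0) * 1, labels = labels,
                n_components = max(labels))
  }
  areas <- tabulate(seg$labels[seg$labels > 0], nbins = max(1L, seg$n_components))
  total <- length(seg$labels)
  structure(list(
    normalized_nuclei_count = seg$n_components / total,
    average_nuclei_area = if (seg$n_components > 0)
      mean(areas[seq_len(seg$n_components)]) else NA_real_,
    n_components = seg$n_components,
    nuclei_mask = seg$mask),
    class = "qc_metrics")
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat(sprintf("<qc_metrics %d components, %.3g px^-2, mean area %s px^2>\n",
              x$n_components, x$normalized_nuclei_count,
              if (is.na(x$average_nuclei_area)) "NA"
              else sprintf("%.1f", x$average_nuclei_area)))
  invisible(x)
}

# Full QC of one stain image: deconvolve, segment, measure.
#' Run the full hand-crafted QC on one stain image
#'
#' Deconvolves the image with the supplied stain vectors, segments nuclei
#' from the haematoxylin channel and reports [nuclei_metrics].
#' @inheritParams stain_deconvolve
#' @param opening_radius passed to [segment_nuclei].
#' @return a `qc_metrics` object.
#' @export
qc_stain_image <- function(rgb, stain_vectors = hed_stain_vectors(),
                           opening_radius = 1L) {
  conc <- stain_deconvolve(rgb, stain_vectors)
  nuclei_metrics(segment_nuclei(conc[[1]], opening_radius))
}

#' Compare QC feature distributions between two image sets
#'
#' For each feature (per-image nuclei count and average nuclei area, by
#' default binned into 7 and 6 bins respectively) the two sets are histogrammed
#' on shared edges spanning the pooled range, the Hellinger distance is
#' computed on the normalised masses, and the distributions are compared with
#' a G-test of independence on the 2 x k binned counts (expected counts from
#' the pooled proportions, `k - 1` degrees of freedom) at significance 0.05.
#'
#' @param set_a,set_b data frames with columns `nuclei_count` and
#'   `average_area` (one row per image), e.g. built from [qc_stain_image]
#'   results; both non-empty.
#' @param k named bin counts per feature.
#' @param alpha significance level.
#' @return data frame with one row per feature: `hellinger`, `G`, `dof`,
#'   `p_value`, `significant`.
#' @export
compare_feature_distributions <- function(set_a, set_b,
                                          k = c(nuclei_count = 7L,
                                                average_area = 6L),
                                          alpha = 0.05) {
  if (!nrow(set_a) || !nrow(set_b))
    stop("empty-set: both sets must contain at least one image", call. = FALSE)
  out <- lapply(names(k), function(feat) {
    a <- set_a[[feat]]; b <- set_b[[feat]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    rng <- range(c(a, b))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = k[[feat]] + 1L)
    ca <- tabulate(pmin(pmax(findInterval(a, edges, rightmost.closed = TRUE),
                             1L), k[[feat]]), nbins = k[[feat]])
    cb <- tabulate(pmin(pmax(findInterval(b, edges, rightmost.closed = TRUE),
                             1L), k[[feat]]), nbins = k[[feat]])
    h <- hellinger(ca / sum(ca), cb / sum(cb))
    pooled <- (ca + cb) / sum(ca + cb)
    keep <- pooled > 0
    ga <- g_test(ca[keep], pooled[keep] * sum(ca))
    gb <- g_test(cb[keep], pooled[keep] * sum(cb))
    G <- ga$G + gb$G
    dof <- sum(keep) - 1L
    pv <- stats::pchisq(G, df = dof, lower.tail = FALSE)
    data.frame(feature = feat, hellinger = h, G = G, dof = dof, p_value = pv,
               significant = pv < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
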