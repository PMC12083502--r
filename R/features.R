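#' Names of the 12 blood-flow image features, in fixed order
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  c("maximum", "minimum", "variance", "coefficient_of_variation", "range",
    "skewness", "interquartile_range", "textural_contrast",
    "textural_energy", "entropy", "fwhm_threshold", "mean_above_fwhm")
}

# Min-max quantization to `levels` gray levels (constant image -> level 1).
quantize_levels <- function(img, levels = 16L) {
  rng <- range(img)
  if (rng[2] <= rng[1]) return(matrix(1L, nrow(img), ncol(img)))
  q <- floor((img - rng[1]) / (rng[2] - rng[1]) * levels) + 1L
  q[q > levels] <- levels
  q
}

# Symmetric GLCM features averaged over the 0/45/90/135 degree unit
# offsets (standard Haralick choices): contrast = sum (i-j)^2 p(i,j),
# energy = sum p^2.
glcm_features <- function(img, levels = 16L) {
  q <- quantize_levels(img, levels)
  nr <- nrow(q); nc <- ncol(q)
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  contrast <- energy <- numeric(length(offsets))
  for (o in seq_along(offsets)) {
    dr <- offsets[[o]][1]; dc <- offsets[[o]][2]
    rr <- seq_len(nr); cc <- seq_len(nc)
    r1 <- rr[rr + dr >= 1 & rr + dr <= nr]
    c1 <- cc[cc + dc >= 1 & cc + dc <= nc]
    a <- q[r1, c1, drop = FALSE]
    bm <- q[r1 + dr, c1 + dc, drop = FALSE]
    counts <- matrix(0, levels, levels)
    for (k in seq_along(a)) {
      counts[a[k], bm[k]] <- counts[a[k], bm[k]] + 1
      counts[bm[k], a[k]] <- counts[bm[k], a[k]] + 1   # symmetric
    }
    p <- counts / sum(counts)
    dmat <- outer(seq_len(levels), seq_len(levels), "-")
    contrast[o] <- sum(dmat^2 * p)
    energy[o] <- sum(p^2)
  }
  c(contrast = mean(contrast), energy = mean(energy))
}

#' Compute the 12 blood-flow image features
#'
#' Feature definitions (on the pixel values of a 2-D relative-BFI slice):
#' maximum, minimum and range over pixels; population variance;
#' coefficient of variation = population sd / mean; Fisher-Pearson moment
#' skewness (0 for a constant image); interquartile range with
#' linear-interpolation quantiles; textural contrast and energy from a
#' 16-level min-max-quantized, symmetric gray-level co-occurrence matrix
#' averaged over the four unit offsets; Shannon entropy (base 2) of the
#' 16-bin min-max histogram; FWHM threshold = minimum + range/2; and the
#' mean of pixels strictly above the FWHM threshold (the threshold itself
#' when no pixel exceeds it).
#'
#' @param img Numeric matrix (>= 4 finite, nonnegative pixels).
#' @param glcm_levels Gray levels for quantization (default 16).
#' @return Named numeric vector of length 12 in the order of
#'   [feature_names()].
#' @export
compute_features <- function(img, glcm_levels = 16L) {
  stopifnot(is.matrix(img), length(img) >= 4)
  if (!all(is.finite(img)))
    stop("image contains non-finite values", call. = FALSE)
  v <- as.numeric(img)
  n <- length(v)
  mx <- max(v); mn <- min(v)
  mu <- mean(v)
  varp <- mean((v - mu)^2)
  sdp <- sqrt(varp)
  cv <- if (mu != 0) sdp / mu else 0
  skew <- if (sdp > 0) mean((v - mu)^3) / sdp^3 else 0
  iqr <- unname(diff(stats::quantile(v, c(0.25, 0.75), type = 7)))
  g <- glcm_features(img, glcm_levels)
  # first-order histogram entropy over 16 min-max bins
  if (mx > mn) {
    bins <- quantize_levels(img, 16L)
    p <- tabulate(bins, 16L) / n
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
  } else ent <- 0
  fwhm <- mn + (mx - mn) / 2
  above <- v[v > fwhm]
  mabove <- if (length(above)) mean(above) else fwhm
  stats::setNames(c(mx, mn, varp, cv, mx - mn, skew, iqr,
                    g[["contrast"]], g[["energy"]], ent, fwhm, mabove),
                  feature_names())
}

#' Feature table for a cohort of images
#'
#' @param images Named list of numeric matrices (slices).
#' @param labels Optional factor/character of class labels.
#' @return A data.frame with `id`, the 12 feature columns, and `label`
#'   when given.
#' @export
feature_table <- function(images, labels = NULL) {
  feats <- t(vapply(images, compute_features, numeric(12)))
  df <- data.frame(id = if (!is.null(names(images))) names(images)
                        else sprintf("s%03d", seq_along(images)),
                   feats, row.names = NULL, check.names = FALSE)
  if (!is.null(labels)) df$label <- labels
  df
}

#' PCA reduction of feature tables
#'
#' Standardizes the training features (center/scale by training statistics;
#' constant columns get unit scale), fits principal components on the
#' training table only, and projects both tables onto the first `k`
#' components.
#'
#' @param train_features,test_features Numeric matrices / data frames of
#'   features (rows = subjects).
#' @param k Number of components (default 2).
#' @return List with `train`, `test` (n x k score matrices), `rotation`,
#'   `center`, `scale`, and `k` (possibly reduced, with a warning, for
#'   rank-deficient training data).
#' @export
pca_reduce <- function(train_features, test_features = NULL, k = 2L) {
  X <- as.matrix(train_features)
  stopifnot(k <= ncol(X), nrow(X) >= k)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (rank < k) {
    warning("training table is rank ", rank, "; returning ", rank,
            " component(s) instead of ", k, call. = FALSE)
    k <- rank
  }
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  project <- function(M) scale(as.matrix(M), ctr, scl) %*% rot
  list(train = Xs %*% rot,
       test = if (!is.null(test_features)) project(test_features),
       rotation = rot, center = ctr, scale = scl, k = k)
}
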