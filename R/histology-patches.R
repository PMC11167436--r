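## Patch bookkeeping, the tissue filter, stain normalization, and
## augmentation.

#' Fraction of pixels classified as tissue
#'
#' A pixel is tissue if its HSV saturation exceeds `sat_min` (stained
#' material is colorful) or its brightness (HSV value) falls below
#' `bright_max` (dark nuclei). Blank glass is bright and unsaturated.
#'
#' @param pixels H x W x 3 array in \[0, 1\].
#' @param sat_min saturation threshold (default 0.08).
#' @param bright_max brightness threshold (default 0.85).
#' @return fraction in \[0, 1\].
#' @export
tissue_fraction <- function(pixels, sat_min = 0.08, bright_max = 0.85) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  v <- pmax(pixels[, , 1], pixels[, , 2], pixels[, , 3])
  mn <- pmin(pixels[, , 1], pixels[, , 2], pixels[, , 3])
  s <- ifelse(v > 0, (v - mn) / v, 0)
  mean(s > sat_min | v < bright_max)
}

#' Extract non-overlapping patches from a slide
#'
#' Tiles the slide on a regular grid anchored at the top-left corner
#' (0-based origins `{0, P, 2P, ...}`, half-open tiles `[r, r+P)`),
#' drops incomplete border tiles, and keeps a patch only if its tissue
#' fraction reaches `tissue_threshold`.
#'
#' @param slide a `slide_image` (or a bare H x W x 3 array).
#' @param patch_size tile side P in pixels (default 512).
#' @param tissue_threshold minimum tissue fraction (default 0.5).
#' @return list of patches; each is a list with `pixels`, `origin`
#'   (0-based c(row, col)), `tissue_fraction`, `parent`, `label`, and
#'   `mask` (the matching tile of the slide's ground-truth mask, when the
#'   slide carries one).
#' @export
extract_patches <- function(slide, patch_size = 512, tissue_threshold = 0.5) {
  if (is.array(slide))
    slide <- list(pixels = slide, subject_id = NA_character_,
                  label = NA_character_, mask = NULL)
  px <- slide$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  P <- check_count(patch_size, "patch_size")
  if (H < P || W < P) {
    warning(sprintf("slide %s (%dx%d) smaller than patch size %d: no patches",
                    slide$subject_id, H, W, P))
    return(list())
  }
  out <- list()
  for (r0 in seq(0L, H - P, by = P)) for (c0 in seq(0L, W - P, by = P)) {
    tile <- px[(r0 + 1):(r0 + P), (c0 + 1):(c0 + P), , drop = FALSE]
    tf <- tissue_fraction(tile)
    if (tf >= tissue_threshold) {
      out[[length(out) + 1L]] <- list(
        pixels = tile, origin = c(row = r0, col = c0), tissue_fraction = tf,
        parent = slide$subject_id, label = slide$label,
        mask = if (!is.null(slide$mask))
          slide$mask[(r0 + 1):(r0 + P), (c0 + 1):(c0 + P)] else NULL)
    }
  }
  out
}

#' Patch manifest table for a cohort
#'
#' @param patches list of patches from [extract_patches()].
#' @return data.frame (subject_id, origin_row, origin_col,
#'   tissue_fraction, label).
#' @export
patch_manifest <- function(patches) {
  data.frame(
    subject_id = vapply(patches, function(p) p$parent, ""),
    origin_row = vapply(patches, function(p) p$origin[["row"]], 0),
    origin_col = vapply(patches, function(p) p$origin[["col"]], 0),
    tissue_fraction = vapply(patches, function(p) p$tissue_fraction, 0),
    label = vapply(patches, function(p) p$label, ""),
    stringsAsFactors = FALSE)
}

## --- stain normalization ----------------------------------------------------

## Estimate a 2-stain matrix (3 x 2, unit columns) from optical densities
## by the plane-and-extreme-angles construction: project OD pixels onto
## the top-2 principal directions and take the 1st/99th percentile angles.
estimate_stain_matrix <- function(pixels, beta = 0.15, alpha = 1) {
  od <- -log10(pmax(matrix(pixels, ncol = 3L), 1e-6))
  keep <- rowMeans(od) > beta
  if (sum(keep) < 10L) return(NULL)
  od <- od[keep, , drop = FALSE]
  e <- eigen(stats::cov(od), symmetric = TRUE)
  V <- e$vectors[, 1:2, drop = FALSE]
  ## orient the plane consistently
  for (j in 1:2) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  proj <- od %*% V
  ang <- atan2(proj[, 2], proj[, 1])
  lo <- stats::quantile(ang, alpha / 100)
  hi <- stats::quantile(ang, 1 - alpha / 100)
  M <- cbind(V %*% c(cos(lo), sin(lo)), V %*% c(cos(hi), sin(hi)))
  M <- pmax(M, 0)
  sc <- sqrt(colSums(M^2))
  if (any(sc == 0)) return(NULL)
  M <- sweep(M, 2, sc, "/")
  ## order: hematoxylin (more blue) first
  if (M[3, 1] < M[3, 2]) M <- M[, 2:1]
  M
}

#' Structure-preserving stain normalization
#'
#' Stain-matrix factorization in optical-density space: the two stain
#' vectors of the source and target are estimated from the extreme angles
#' in the top-2 principal plane of their OD pixel clouds, source
#' concentrations are solved by least squares, robustly rescaled so their
#' 99th percentiles match the target's, and recombined with the target's
#' stain vectors.
#'
#' @param patch H x W x 3 array in \[0, 1\] to normalize.
#' @param target_patch reference patch whose palette is imposed.
#' @return normalized H x W x 3 array. A patch without measurable stain
#'   is returned unchanged with a warning; a degenerate (constant) target
#'   is an error.
#' @export
normalize_stain <- function(patch, target_patch) {
  Mt <- estimate_stain_matrix(target_patch)
  if (is.null(Mt))
    stop_invalid("degenerate target patch: no measurable stain content")
  Ms <- estimate_stain_matrix(patch)
  if (is.null(Ms)) {
    warning("patch has no measurable stain content; returned unchanged")
    return(patch)
  }
  d <- dim(patch)
  od_s <- -log10(pmax(matrix(patch, ncol = 3L), 1e-6))
  od_t <- -log10(pmax(matrix(target_patch, ncol = 3L), 1e-6))
  pinv <- function(M) {
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-8
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  }
  Cs <- od_s %*% t(pinv(Ms))              # n x 2 concentrations
  Ct <- od_t %*% t(pinv(Mt))
  q_s <- apply(Cs, 2, stats::quantile, 0.99)
  q_t <- apply(Ct, 2, stats::quantile, 0.99)
  q_s[q_s <= 0] <- 1
  Cn <- sweep(Cs, 2, q_t / q_s, "*")
  ## recombine with the target's stain vectors, keeping each pixel's
  ## off-plane OD residual so structure outside the 2-stain plane is
  ## preserved (and self-normalization is exact)
  od_n <- Cn %*% t(Mt) + (od_s - Cs %*% t(Ms))
  out <- array(10^(-od_n), dim = d)
  pmin(pmax(out, 0), 1)
}

## --- augmentation -----------------------------------------------------------

#' Augment a patch
#'
#' Applies the listed operations in order: `rotate90` (counter-clockwise
#' quarter turn), `hflip`, `vflip`, `gamma` (power-law intensity with the
#' given exponent; identity at 1), and `crop_resize` (random
#' crop-and-resize within the patch, the "segmentation"-style spatial
#' augmentation; requires `seed`).
#'
#' @param pixels H x W x 3 array in \[0, 1\].
#' @param ops character vector drawn from
#'   `c("rotate90", "hflip", "vflip", "gamma", "crop_resize")`.
#' @param gamma exponent for the `gamma` op (> 0).
#' @param seed seed for `crop_resize`.
#' @return augmented array of the same dimensions.
#' @export
augment <- function(pixels, ops = character(0), gamma = 1, seed = NULL) {
  if (gamma <= 0) stop_invalid("gamma must be > 0")
  bad <- setdiff(ops, c("rotate90", "hflip", "vflip", "gamma", "crop_resize"))
  if (length(bad)) stop_invalid("unknown augmentation op: %s", paste(bad, collapse = ", "))
  for (op in ops) {
    pixels <- switch(op,
      rotate90 = aperm(pixels, c(2, 1, 3))[dim(pixels)[2]:1, , , drop = FALSE],
      hflip = pixels[, dim(pixels)[2]:1, , drop = FALSE],
      vflip = pixels[dim(pixels)[1]:1, , , drop = FALSE],
      gamma = pixels^gamma,
      crop_resize = {
        H <- dim(pixels)[1]; W <- dim(pixels)[2]
        sc <- with_seed(seed %||% 0L, stats::runif(3, c(0.6, 0, 0), c(0.95, 1, 1)))
        h <- round(sc[1] * H); w <- round(sc[1] * W)
        r0 <- 1L + floor(sc[2] * (H - h)); c0 <- 1L + floor(sc[3] * (W - w))
        resize_bilinear(pixels[r0:(r0 + h - 1L), c0:(c0 + w - 1L), , drop = FALSE],
                        H, W)
      })
  }
  pixels
}

## bilinear resize of an H x W x C array (also used by GradCAM upsampling)
resize_bilinear <- function(x, H2, W2) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  ry <- if (H2 > 1) (seq_len(H2) - 1) * (H - 1) / (H2 - 1) + 1 else rep(1, H2)
  rx <- if (W2 > 1) (seq_len(W2) - 1) * (W - 1) / (W2 - 1) + 1 else rep(1, W2)
  y0 <- pmin(floor(ry), H - 1); x0 <- pmin(floor(rx), W - 1)
  wy <- ry - y0; wx <- rx - x0
  if (H == 1) { y0 <- rep(1, H2); wy <- rep(0, H2) }
  if (W == 1) { x0 <- rep(1, W2); wx <- rep(0, W2) }
  out <- array(0, dim = c(H2, W2, C))
  for (ch in seq_len(C)) {
    pl <- x[, , ch]
    a <- pl[y0, x0, drop = FALSE]; b <- pl[y0, pmin(x0 + 1, W), drop = FALSE]
    cc <- pl[pmin(y0 + 1, H), x0, drop = FALSE]
    dd <- pl[pmin(y0 + 1, H), pmin(x0 + 1, W), drop = FALSE]
    WX <- matrix(wx, H2, W2, byrow = TRUE); WY <- matrix(wy, H2, W2)
    out[, , ch] <- a * (1 - WY) * (1 - WX) + b * (1 - WY) * WX +
      cc * WY * (1 - WX) + dd * WY * WX
  }
  out
}
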