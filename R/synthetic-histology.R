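## Synthetic two-class duodenal histology.
##
## Slides are stylized, not photorealistic: an eosin-pink textured tissue
## field with hematoxylin-dark epithelium bands, scattered lymphocyte-like
## purple blobs, goblet-like white vacuoles, and a blank-glass margin so
## the tissue filter is exercised. Disease slides concentrate extra
## lymphocyte blobs into one infiltration focus per lesion-grid cell; the
## union of those focus disks is the per-slide ground-truth lesion mask.

#' Morphology parameters for the synthetic slide generator
#'
#' Densities are expected object counts per lesion-grid cell
#' (`lesion_grid` x `lesion_grid` pixels of tissue). The defaults give a
#' clearly separable disease/control contrast (a 5x lymphocyte-blob ratio
#' and 3x vacuole ratio) chosen for comfortable signal recovery;
#' `epithelium_crowding` scales the spatial frequency of the epithelium
#' bands.
#'
#' @param blob_density named c(disease=, control=) lymphocyte blobs per cell.
#' @param vacuole_density named c(disease=, control=) vacuoles per cell.
#' @param epithelium_crowding named c(disease=, control=) band-frequency scalars.
#' @param stain_palette list with `hematoxylin` and `eosin` RGB triples in \[0,1\].
#' @param background_fraction fraction of the slide left as blank glass in \[0,1).
#' @param lesion_grid lesion-cell side in pixels (default 64).
#' @param focus_radius infiltration-focus radius in pixels (default 12).
#' @return a list of class `morphology_params`.
#' @export
morphology_params <- function(blob_density = c(disease = 30, control = 6),
                              vacuole_density = c(disease = 6, control = 2),
                              epithelium_crowding = c(disease = 1.6, control = 1.0),
                              stain_palette = list(
                                hematoxylin = c(0.36, 0.25, 0.60),
                                eosin = c(0.92, 0.75, 0.82)),
                              background_fraction = 0.2,
                              lesion_grid = 64, focus_radius = 12) {
  if (any(blob_density < 0) || any(vacuole_density < 0))
    stop_invalid("densities must be >= 0")
  check_fraction(background_fraction, "background_fraction", 0, 0.999)
  structure(list(blob_density = blob_density,
                 vacuole_density = vacuole_density,
                 epithelium_crowding = epithelium_crowding,
                 stain_palette = stain_palette,
                 background_fraction = background_fraction,
                 lesion_grid = lesion_grid,
                 focus_radius = focus_radius),
            class = "morphology_params")
}

## paint a filled disk into img (H x W x 3), in place via returned array
paint_disk <- function(img, cy, cx, r, col, rim = NULL) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(img)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  inside <- d2 <= r^2
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    plane[inside] <- col[ch]
    if (!is.null(rim)) {
      ring <- d2 <= r^2 & d2 >= (max(r - 1.5, 0))^2
      plane[ring] <- rim[ch]
    }
    img[ys, xs, ch] <- plane
  }
  img
}

disk_mask <- function(mask, cy, cx, r) {
  H <- nrow(mask); W <- ncol(mask)
  ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  mask[ys, xs][d2 <= r^2] <- 1L
  mask
}

generate_slide <- function(image_size, label, params, seed) {
  with_seed(seed, {
    L <- image_size
    pal <- params$stain_palette
    img <- array(stats::runif(L * L * 3, 0.955, 0.995), dim = c(L, L, 3))
    mask <- matrix(0L, L, L)
    ## blank-glass margin on one side
    mwidth <- round(params$background_fraction * L)
    side <- sample(c("left", "right", "top", "bottom"), 1)
    tis <- list(r0 = 1L, r1 = L, c0 = 1L, c1 = L)
    if (mwidth > 0) switch(side,
      left = { tis$c0 <- mwidth + 1L },
      right = { tis$c1 <- L - mwidth },
      top = { tis$r0 <- mwidth + 1L },
      bottom = { tis$r1 <- L - mwidth })
    rows <- tis$r0:tis$r1; cols <- tis$c0:tis$c1
    ## eosin field with texture
    for (ch in 1:3)
      img[rows, cols, ch] <- pmin(1, pmax(0, pal$eosin[ch] +
        matrix(stats::rnorm(length(rows) * length(cols), 0, 0.035),
               length(rows))))
    ## epithelium bands: hematoxylin-dark sinusoidal stripes
    crowd <- params$epithelium_crowding[[label]]
    phase <- stats::runif(1, 0, 2 * pi)
    band <- 0.5 + 0.5 * sin(2 * pi * crowd * rows / 48 + phase)
    depth <- 0.35
    for (ch in 1:3) {
      tgt <- pal$hematoxylin[ch]
      img[rows, cols, ch] <- img[rows, cols, ch] * (1 - depth * band) +
        tgt * depth * band
    }
    ## per lesion-cell content
    g <- params$lesion_grid
    fr <- params$focus_radius
    blobs <- params$blob_density[[label]]
    vacs <- params$vacuole_density[[label]]
    cell_r <- seq(tis$r0, tis$r1 - g + 1, by = g)
    cell_c <- seq(tis$c0, tis$c1 - g + 1, by = g)
    for (cr in cell_r) for (cc in cell_c) {
      ## infiltration focus: most blobs cluster here
      fy <- stats::runif(1, cr + fr + 2, cr + g - fr - 2)
      fx <- stats::runif(1, cc + fr + 2, cc + g - fr - 2)
      n_focus <- stats::rpois(1, 0.8 * blobs)
      n_scatter <- stats::rpois(1, 0.2 * blobs)
      if (n_focus > 0) {
        ang <- stats::runif(n_focus, 0, 2 * pi)
        rad <- fr * sqrt(stats::runif(n_focus)) * 0.9
        for (b in seq_len(n_focus))
          img <- paint_disk(img, fy + rad[b] * sin(ang[b]),
                            fx + rad[b] * cos(ang[b]),
                            stats::runif(1, 1.6, 3.2), pal$hematoxylin)
        if (label == "disease") mask <- disk_mask(mask, fy, fx, fr)
      }
      if (n_scatter > 0) for (b in seq_len(n_scatter))
        img <- paint_disk(img, stats::runif(1, cr, cr + g - 1),
                          stats::runif(1, cc, cc + g - 1),
                          stats::runif(1, 1.6, 3.2), pal$hematoxylin)
      n_vac <- stats::rpois(1, vacs)
      if (n_vac > 0) for (b in seq_len(n_vac))
        img <- paint_disk(img, stats::runif(1, cr + 4, cr + g - 4),
                          stats::runif(1, cc + 4, cc + g - 4),
                          stats::runif(1, 3, 6), c(0.97, 0.97, 0.97),
                          rim = pal$hematoxylin)
    }
    list(pixels = img, mask = mask)
  })
}

#' Generate a labeled synthetic whole-slide cohort
#'
#' @param n_disease,n_control slides per class (>= 1 each; one slide per
#'   synthetic subject).
#' @param image_size slide side in pixels (square; must be at least twice
#'   the intended downstream patch size).
#' @param params a [morphology_params()] object.
#' @param seed integer seed; output is bit-identical for identical calls.
#' @return list of `slide_image` objects: each has `pixels`
#'   (H x W x 3 array in \[0,1\]), `mask` (H x W 0/1 ground-truth lesion
#'   mask), `subject_id`, `label`, `site_tag`.
#' @export
generate_wsi_cohort <- function(n_disease, n_control, image_size = 256,
                                params = morphology_params(), seed = 1) {
  n_disease <- check_count(n_disease, "n_disease")
  n_control <- check_count(n_control, "n_control")
  image_size <- check_count(image_size, "image_size", min = 2L * params$lesion_grid)
  labels <- c(rep("disease", n_disease), rep("control", n_control))
  ids <- c(sprintf("D%02d", seq_len(n_disease)),
           sprintf("C%02d", seq_len(n_control)))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- generate_slide(image_size, labels[i], params,
                        substream_seed(seed, 10L + i))
    out[[i]] <- structure(list(pixels = s$pixels, mask = s$mask,
                               subject_id = ids[i], label = labels[i],
                               site_tag = "synthetic"),
                          class = "slide_image")
  }
  names(out) <- ids
  out
}

#' Write a slide cohort to PNG files with ground-truth sidecars
#'
#' Images become 8-bit RGB PNGs, masks single-channel PNGs, and the
#' cohort's labels a JSON sidecar.
#'
#' @param cohort result of [generate_wsi_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_wsi_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- lapply(cohort, function(s)
    list(subject_id = s$subject_id, label = s$label, site_tag = s$site_tag))
  for (s in cohort) {
    png::writePNG(s$pixels, file.path(dir, sprintf("%s.png", s$subject_id)))
    png::writePNG(s$mask + 0.0, file.path(dir, sprintf("%s_mask.png", s$subject_id)))
  }
  jsonlite::write_json(meta, file.path(dir, "cohort.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a slide cohort written by [write_wsi_cohort()]
#' @param dir cohort directory.
#' @return list of `slide_image` objects.
#' @export
read_wsi_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"))
  out <- lapply(meta, function(m) {
    px <- png::readPNG(file.path(dir, sprintf("%s.png", m$subject_id)))
    mk <- png::readPNG(file.path(dir, sprintf("%s_mask.png", m$subject_id)))
    structure(list(pixels = px, mask = matrix(as.integer(mk > 0.5), nrow(mk)),
                   subject_id = m$subject_id, label = m$label,
                   site_tag = m$site_tag), class = "slide_image")
  })
  names(out) <- vapply(out, function(s) s$subject_id, "")
  out
}
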