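# Vessel lumen detection from the vascular-marker channel.
# Pipeline: Gaussian smoothing (physical-units sigma) -> Otsu (or absolute)
# threshold -> morphological closing (1 px) -> hole filling -> minimum-size
# filter -> connected-component labeling (8-connectivity in 2D, 26 in 3D).

otsu_threshold <- function(x, nbins = 512L) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = nbins + 1L),
                      plot = FALSE)
  counts <- as.numeric(h$counts)
  mids <- h$mids
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  tot <- w[nbins]
  mu_t <- mu[nbins]
  w1 <- w[-nbins]
  w2 <- tot - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (mu_t * w1[valid] - tot * mu[-nbins][valid])^2 /
    (w1[valid] * w2[valid])
  h$breaks[which.max(between) + 1L]
}

# box dilation/erosion with Chebyshev radius 1 (shift-based, any ndim)
morph_box <- function(mask, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(mask)
  nd <- length(d)
  if (op == "erode") mask <- !mask
  acc <- mask
  offsets <- expand.grid(rep(list(-1:1), nd))
  for (i in seq_len(nrow(offsets))) {
    off <- as.integer(offsets[i, ])
    if (all(off == 0L)) next
    shifted <- array(FALSE, d)
    src <- dst <- vector("list", nd)
    ok <- TRUE
    for (ax in seq_len(nd)) {
      o <- off[ax]
      if (abs(o) >= d[ax]) { ok <- FALSE; break }
      if (o >= 0) { src[[ax]] <- seq_len(d[ax] - o); dst[[ax]] <- src[[ax]] + o }
      else { src[[ax]] <- seq(1 - o, d[ax]); dst[[ax]] <- src[[ax]] + o }
    }
    if (!ok) next
    shifted <- do.call(`[<-`, c(list(shifted), dst,
                                list(do.call(`[`, c(list(mask), src)))))
    acc <- acc | shifted
  }
  if (op == "erode") !acc else acc
}

fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  # background uses the complementary (minimal) connectivity
  lab <- array(cpp_label(as.logical(bg), as.integer(d), FALSE), d)
  on_border <- unique(lab[border_mask(d) & bg])
  mask | (bg & !(lab %in% on_border))
}

label_components <- function(mask, min_size_px = 0L) {
  d <- dim(mask)
  lab <- array(cpp_label(as.logical(mask), as.integer(d), TRUE), d)
  if (min_size_px > 0L && max(lab) > 0L) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_size_px)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Segment vessel lumina from the vascular-marker channel
#'
#' Detects the stained vessel lumen and labels individual vessels. The
#' channel is smoothed with a Gaussian whose sigma is given in micrometres
#' (converted per axis, so z smoothing respects voxel anisotropy),
#' thresholded (Otsu by default; scale-invariant, or a fixed absolute
#' value), morphologically closed with a 1-pixel box, hole-filled, and
#' objects below the minimum physical size are removed before
#' connected-component labeling.
#'
#' @param field an [image_field()].
#' @param channel channel name holding the vessel marker (default
#'   `"vessel"`).
#' @param smooth_sigma_um Gaussian smoothing sigma in µm (default 0.5).
#' @param threshold `"otsu"` (default) or `"absolute"`.
#' @param threshold_value intensity cutoff, required when
#'   `threshold = "absolute"`.
#' @param min_size_um minimum object size in µm² (2D) or µm³ (3D); defaults
#'   to 10 µm² / 30 µm³.
#' @param fill logical, fill enclosed holes (default TRUE).
#' @return An object of class `vessel_segmentation`: binary `lumen_mask`,
#'   integer `labels` (0 = background), `n_vessels`, and a `per_vessel`
#'   tibble with physical size, centroid, equivalent radius and a border
#'   flag per vessel.
#' @export
segment_vessels <- function(field, channel = "vessel",
                            smooth_sigma_um = 0.5,
                            threshold = c("otsu", "absolute"),
                            threshold_value = NULL,
                            min_size_um = NULL,
                            fill = TRUE) {
  threshold <- tryCatch(match.arg(threshold), error = function(e) {
    abort(sprintf("unknown threshold method '%s' (use 'otsu' or 'absolute')",
                  threshold[1L]))
  })
  x <- get_channel(field, channel)
  d <- dim(x)
  nd <- length(d)
  px <- field$pixel_size
  if (is.null(min_size_um)) min_size_um <- if (nd == 2L) 10 else 30
  if (min_size_um < 0) abort("`min_size_um` must be >= 0")

  empty <- function() {
    structure(list(
      lumen_mask = array(FALSE, d), labels = array(0L, d), n_vessels = 0L,
      per_vessel = per_vessel_table(array(0L, d), px),
      pixel_size = px, field_id = field$field_id, threshold = NA_real_
    ), class = "vessel_segmentation")
  }
  if (diff(range(x)) == 0) {
    warn("vessel channel is flat; returning zero vessels")
    return(empty())
  }

  sigma_px <- smooth_sigma_um / px
  sm <- array(cpp_gauss_blur(as.numeric(x), as.integer(d),
                             as.numeric(sigma_px)), d)
  thr <- if (threshold == "otsu") {
    otsu_threshold(sm)
  } else {
    if (is.null(threshold_value)) {
      abort("`threshold_value` is required for absolute thresholding")
    }
    as.numeric(threshold_value)
  }
  mask <- sm > thr
  if (!any(mask)) {
    warn("no pixels above threshold; returning zero vessels")
    return(empty())
  }
  mask <- morph_box(morph_box(mask, "dilate"), "erode")
  if (fill) mask <- fill_holes(mask)
  min_px <- ceiling(min_size_um / voxel_volume(px))
  labels <- label_components(mask, min_size_px = min_px)
  mask <- labels > 0L
  n <- max(labels)
  structure(list(
    lumen_mask = mask, labels = labels, n_vessels = as.integer(n),
    per_vessel = per_vessel_table(labels, px),
    pixel_size = px, field_id = field$field_id, threshold = thr
  ), class = "vessel_segmentation")
}

per_vessel_table <- function(labels, px) {
  d <- dim(labels)
  nd <- length(d)
  n <- max(labels)
  size_col <- if (nd == 2L) "area_um2" else "volume_um3"
  if (n == 0L) {
    out <- tibble(label = integer(), size_px = integer())
    out[[size_col]] <- numeric()
    for (ax in seq_len(nd)) out[[paste0("centroid_", ax, "_um")]] <- numeric()
    out$eq_radius_um <- numeric()
    out$on_border <- logical()
    return(out)
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  sizes <- tabulate(lab, nbins = n)
  coords <- arrayInd(idx, d)
  vol <- voxel_volume(px)
  border <- border_mask(d)
  on_border <- vapply(seq_len(n), function(k) FALSE, logical(1))
  bl <- unique(labels[border & labels > 0L])
  on_border[bl] <- TRUE
  out <- tibble(label = seq_len(n), size_px = as.integer(sizes))
  out[[size_col]] <- sizes * vol
  for (ax in seq_len(nd)) {
    cm <- vapply(seq_len(n), function(k) mean(coords[lab == k, ax]),
                 numeric(1))
    out[[paste0("centroid_", ax, "_um")]] <- (cm - 0.5) * px[ax]
  }
  out$eq_radius_um <- if (nd == 2L) {
    sqrt(out[[size_col]] / pi)
  } else {
    (3 * out[[size_col]] / (4 * pi))^(1 / 3)
  }
  out$on_border <- on_border
  out
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf("<vessel_segmentation '%s'> %d vessels, %.2f%% lumen\n",
              x$field_id, x$n_vessels,
              100 * mean(x$lumen_mask)))
  invisible(x)
}

#' Vessel count and lumen area/volume fraction of a field
#'
#' @param seg a [segment_vessels()] result.
#' @param field the [image_field()] the segmentation came from (used for
#'   consistency checks only).
#' @return A one-row tibble with `n_vessels` (vessels per field-of-view)
#'   and `lumen_fraction_pct` (100 × lumen pixels / total pixels).
#' @export
vessel_density <- function(seg, field = NULL) {
  if (!is.null(field) &&
      !identical(dim(seg$lumen_mask), field_dim(field))) {
    abort("segmentation and field dimensions differ")
  }
  tibble(
    n_vessels = seg$n_vessels,
    lumen_fraction_pct = 100 * mean(seg$lumen_mask)
  )
}

# internal: wrap a known mask + labels as a segmentation (phantom ground truth)
segmentation_from_mask <- function(mask, labels, px, field_id = "truth") {
  structure(list(
    lumen_mask = mask, labels = labels,
    n_vessels = as.integer(max(labels)),
    per_vessel = per_vessel_table(labels, px),
    pixel_size = px, field_id = field_id, threshold = NA_real_
  ), class = "vessel_segmentation")
}
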