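#' Construct a multichannel image field
#'
#' An `image_field` is the unit of analysis: one microscopy field-of-view
#' (2D cryosection image) or one confocal stack (3D), holding named intensity
#' channels plus the physical sampling metadata every downstream computation
#' relies on.
#'
#' @param channels named list of numeric arrays, all with identical
#'   dimensions (2D matrices or 3D arrays). Typical names are `"vessel"`
#'   (vascular marker, e.g. rhodamine-lectin), `"carrier"` (nanocarrier
#'   fluorescence) and `"igg"` (extravasated IgG stain).
#' @param pixel_size numeric vector of micrometres per pixel along each array
#'   axis (length 2 for 2D, length 3 for 3D; the z spacing may differ from
#'   the in-plane spacing).
#' @param field_id identifier string.
#' @return An object of class `image_field`.
#' @export
image_field <- function(channels, pixel_size, field_id = "field") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    abort("`channels` must be a named list of arrays")
  }
  dims <- lapply(channels, function(ch) dim(ch) %||% length(ch))
  if (length(unique(dims)) != 1L) {
    abort("all channels must share the same dimensions")
  }
  d <- dims[[1L]]
  if (!length(d) %in% c(2L, 3L)) abort("channels must be 2D or 3D arrays")
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, length(d))
  if (length(pixel_size) != length(d) || any(!is.finite(pixel_size)) ||
      any(pixel_size <= 0)) {
    abort("`pixel_size` must be positive, one value per array axis")
  }
  channels <- lapply(channels, function(ch) {
    if (any(ch < 0, na.rm = TRUE)) abort("channel intensities must be >= 0")
    array(as.numeric(ch), d)
  })
  structure(
    list(channels = channels, pixel_size = pixel_size,
         field_id = as.character(field_id)),
    class = "image_field"
  )
}

field_dim <- function(field) dim(field$channels[[1L]])
field_ndim <- function(field) length(field_dim(field))

get_channel <- function(field, channel) {
  if (!channel %in% names(field$channels)) {
    abort(sprintf("channel '%s' not found (available: %s)", channel,
                  paste(names(field$channels), collapse = ", ")))
  }
  field$channels[[channel]]
}

#' @export
print.image_field <- function(x, ...) {
  d <- field_dim(x)
  cat(sprintf("<image_field '%s'> %s px, %s µm/px, channels: %s\n",
              x$field_id, paste(d, collapse = "×"),
              paste(signif(x$pixel_size, 3), collapse = "×"),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Physical extent of a field in micrometres
#' @param field an [image_field()].
#' @return numeric vector, extent per axis in µm.
#' @export
field_extent_um <- function(field) field_dim(field) * field$pixel_size
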