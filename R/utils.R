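# Small shared helpers. Coordinate convention (used everywhere): arrays are
# indexed [y, x] in 2D and [y, x, z] in 3D; `pixel_size` is a per-axis vector
# of micrometres aligned with dim(); distances are measured between pixel
# centres and expressed in micrometres.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# logical array of border pixels for a given dim()
border_mask <- function(dims) {
  m <- array(FALSE, dims)
  nd <- length(dims)
  for (ax in seq_len(nd)) {
    idx <- rep(list(quote(expr = )), nd)
    for (i in c(1L, dims[ax])) {
      idx[[ax]] <- i
      m <- do.call(`[<-`, c(list(m), idx, list(value = TRUE)))
      idx[[ax]] <- quote(expr = )
    }
  }
  m
}

# pixel/voxel volume in µm^ndim
voxel_volume <- function(pixel_size) prod(pixel_size)

# round-half-up to integer (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Dice overlap coefficient between two binary masks
#'
#' The standard overlap score \eqn{2|A \cap B| / (|A| + |B|)}, used throughout
#' the package to validate segmentations against phantom ground truth.
#'
#' @param a,b logical arrays of identical dimensions.
#' @return A number in \[0, 1\]; defined as 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b), identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
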