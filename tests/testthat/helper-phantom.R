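# Shared fixtures: small phantom specs and the brute-force distance oracle.

# exhaustive nearest-lumen-pixel distance (O(N * n_lumen)); the independent
# oracle for the separable distance transform
brute_distance <- function(mask, px) {
  d <- dim(mask)
  nd <- length(d)
  co <- arrayInd(seq_along(mask), d)
  for (ax in seq_len(nd)) co[, ax] <- co[, ax] * px[ax]
  out <- rep(Inf, length(mask))
  for (s in which(mask)) {
    diff2 <- (co - rep(co[s, ], each = nrow(co)))^2
    out <- pmin(out, rowSums(diff2))
  }
  array(sqrt(out), d)
}

# classify brute-force distances into compartments with the same convention
# as build_shells (lumen 0, shell k = (edge[k-1], edge[k]], beyond = -1)
brute_shells <- function(dvals, edges) {
  comp <- array(-1L, dim(dvals))
  comp[dvals == 0] <- 0L
  pos <- dvals > 0 & dvals <= edges[length(edges)]
  comp[pos] <- findInterval(dvals[pos], c(0, edges), left.open = TRUE)
  comp
}

two_shell_profile <- function(fr = c(80, 20, 0)) {
  penetration_profile_new(fr, edges = c(5, 10))
}

# small, fast 2D spec: 38.4 µm field, 2-3 small vessels, two 5 µm shells
small_spec_2d <- function(seed = 1, n_vessels = c(2L, 3L),
                          vessel_radius_range = c(3, 4),
                          profile = two_shell_profile(), ...) {
  phantom_spec(shape = c(128, 128), pixel_size = 0.3,
               profile = profile, n_vessels = n_vessels,
               vessel_radius_range = vessel_radius_range,
               seed = seed, ...)
}

# small 3D slab: 32x32x24 µm, anisotropic voxels
small_spec_3d <- function(seed = 1, n_vessels = 2L,
                          vessel_radius_range = c(3, 4),
                          profile = two_shell_profile(), ...) {
  suppressMessages(phantom_spec(
    shape = c(64, 64, 24), pixel_size = c(0.5, 0.5, 1),
    profile = profile, n_vessels = n_vessels,
    vessel_radius_range = vessel_radius_range,
    seed = seed, ...))
}

# ground-truth segmentation wrapper (bypasses image segmentation)
truth_segmentation <- function(truth, px) {
  perivasc:::segmentation_from_mask(truth$lumen_mask, truth$labels, px)
}
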