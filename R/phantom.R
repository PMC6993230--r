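# Synthetic phantom fields with exactly known ground truth. Vessels are
# bright tubular objects (discs in 2D cryosection-like fields, randomly
# oriented cylinders in 3D slab stacks); the carrier channel's intensity
# mass is apportioned over the lumen and the concentric 5 µm shells of the
# *realized* ground-truth geometry so the true penetration profile matches
# the requested one exactly before noise; IgG halos decay over 0-10 µm
# around exactly the vessels flagged leaky. A camera-like noise model
# (baseline offset + Poisson shot noise + Gaussian read noise, quantized
# to integer counts) is applied to every channel.

#' Specify a synthetic phantom field
#'
#' @param shape pixel grid dimensions (length 2 or 3).
#' @param pixel_size µm per pixel along each axis (z may differ).
#' @param profile a [penetration_profile_new()] giving the target
#'   per-compartment percentages of carrier signal; shell edges are taken
#'   from it (5 µm spacing).
#' @param n_vessels vessel count: a single number or a `c(min, max)` range
#'   sampled per field. Defaults to 8-12 (2D) or 3-5 (3D).
#' @param vessel_radius_range radius range in µm; defaults to 3-10 µm (2D)
#'   or 3-6 µm (3D slabs, where large vessels would fill the slab).
#' @param leaky_vessel_fraction fraction of vessels given a perivascular
#'   IgG halo (BBB-opened vessels), in \[0, 1\].
#' @param target_area_fraction optional % of field pixels carrying carrier
#'   signal; when set, the carrier is placed as sparse puncta-like support
#'   occupying exactly this fraction instead of filling the compartments
#'   diffusely.
#' @param noise list with `gaussian_sd` (read noise, counts; default 2% of
#'   the vessel peak), `poisson_scale` (shot-noise scaling; 0 disables) and
#'   `baseline` (camera offset, counts).
#' @param seed integer; fixing it makes the generated field bit-identical.
#' @param tuning internal appearance knobs (documented in the methods
#'   vignette): vessel peak intensity, carrier intensity floor, shell decay
#'   length, IgG halo amplitude/decay/range, placement margins.
#' @return A validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(512, 512),
                         pixel_size = if (length(shape) == 2L) 0.3 else c(0.3, 0.3, 0.5),
                         profile = make_profile_preset("polymer_US_2D"),
                         n_vessels = NULL,
                         vessel_radius_range = NULL,
                         leaky_vessel_fraction = 0,
                         target_area_fraction = NULL,
                         noise = list(),
                         seed = 1L,
                         tuning = list()) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!nd %in% c(2L, 3L) || any(shape < 8L)) {
    abort("`shape` must be 2 or 3 dimensions of at least 8 pixels")
  }
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, nd)
  if (length(pixel_size) != nd || any(pixel_size <= 0)) {
    abort("`pixel_size` must be positive, one value per axis")
  }
  if (!inherits(profile, "penetration_profile")) {
    abort("`profile` must be a penetration_profile")
  }
  if (is.null(n_vessels)) n_vessels <- if (nd == 2L) c(8L, 12L) else c(3L, 5L)
  n_vessels <- as.integer(n_vessels)
  if (any(n_vessels < 1L)) abort("`n_vessels` must be >= 1")
  if (is.null(vessel_radius_range)) {
    vessel_radius_range <- if (nd == 2L) c(3, 10) else c(3, 6)
  }
  if (any(vessel_radius_range <= 0)) abort("vessel radii must be > 0")
  if (leaky_vessel_fraction < 0 || leaky_vessel_fraction > 1) {
    abort("`leaky_vessel_fraction` must be in [0, 1]")
  }
  if (!is.null(target_area_fraction) &&
      (target_area_fraction <= 0 || target_area_fraction > 100)) {
    abort("`target_area_fraction` must be in (0, 100]")
  }
  tuning <- modifyList(list(
    vessel_peak = 1000, vessel_edge_sigma_um = 0.4,
    carrier_floor = 200, carrier_ceiling = 50000, shell_tau_um = 5,
    igg_amp = 500, igg_tau_um = 3, igg_range_um = 10,
    margin_um = 5, separation_um = 2, max_retries = 20L
  ), tuning)
  noise <- modifyList(list(
    gaussian_sd = 0.02 * tuning$vessel_peak, poisson_scale = 1,
    baseline = 100
  ), noise)

  edges <- profile_edges(profile)
  extent <- shape * pixel_size
  fit_extent <- if (nd == 2L) min(extent) else min(extent[1:2])
  need <- 2 * (max(vessel_radius_range) + max(edges))
  if (need > fit_extent) {
    abort(sprintf(
      "shells cannot fit: 2*(max radius + outermost edge) = %.1f µm exceeds the %s field extent (%.1f µm)",
      need, if (nd == 2L) "minimum" else "minimum in-plane", fit_extent))
  }
  if (nd == 3L && need > min(extent)) {
    # thin-slab acquisition: shells are z-truncated exactly as in real
    # 25-40 µm sections; profiles stay exact because mass is apportioned
    # against the realized shell map
    inform("3D slab thinner than the nominal shell diameter; shells will be z-truncated")
  }
  structure(list(
    shape = shape, pixel_size = pixel_size, profile = profile,
    n_vessels = n_vessels, vessel_radius_range = vessel_radius_range,
    leaky_vessel_fraction = leaky_vessel_fraction,
    target_area_fraction = target_area_fraction,
    noise = noise, seed = as.integer(seed), tuning = tuning
  ), class = "phantom_spec")
}

#' Named phantom presets for the study conditions
#'
#' Builds a ready-to-run [phantom_spec()] for a study condition: the eight
#' penetration-profile presets of [make_profile_preset()] (2D fields or 3D
#' slab stacks), the IgG BBB-opening conditions (`igg_US`: 23.7% leaky
#' vessels, `igg_ctrl`: 6.0%), the carrier area-fraction conditions
#' (`area_polymer_US`: 2.1%, `area_polymer_ctrl`: 1.5%), and the
#' extravasation-positive vessel-count conditions (`extrav_US` /
#' `extrav_ctrl`: 10 vessels per field with 68% / 6% of them haloed,
#' i.e. 6.8 vs 0.6 positive vessels per field-of-view).
#'
#' @param name preset name (see Details).
#' @param seed integer seed stored in the spec.
#' @param ... overrides forwarded to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name, seed = 1L, ...) {
  profile_names <- profile_preset_names()
  extra <- c("igg_US", "igg_ctrl", "area_polymer_US", "area_polymer_ctrl",
             "extrav_US", "extrav_ctrl")
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c(profile_names, extra)) {
    abort(sprintf("unknown phantom preset '%s'; valid presets: %s",
                  as.character(name)[1L],
                  paste(c(profile_names, extra), collapse = ", ")))
  }
  args <- list(seed = seed)
  if (name %in% profile_names) {
    args$profile <- make_profile_preset(name)
    if (endsWith(name, "_3D")) {
      args$shape <- c(256L, 256L, 60L)
      args$pixel_size <- c(0.3, 0.3, 0.5)
    }
  } else {
    lumen_only <- penetration_profile_new(c(100, 0, 0, 0, 0),
                                          edges = c(5, 10, 15, 20))
    args$profile <- switch(name,
      igg_US = , igg_ctrl = , extrav_US = , extrav_ctrl = lumen_only,
      area_polymer_US = make_profile_preset("polymer_US_2D"),
      area_polymer_ctrl = make_profile_preset("polymer_ctrl_2D"))
    args <- c(args, switch(name,
      igg_US = list(leaky_vessel_fraction = 0.237),
      igg_ctrl = list(leaky_vessel_fraction = 0.060),
      area_polymer_US = list(target_area_fraction = 2.1),
      area_polymer_ctrl = list(target_area_fraction = 1.5),
      extrav_US = list(leaky_vessel_fraction = 0.68, n_vessels = 10L),
      extrav_ctrl = list(leaky_vessel_fraction = 0.06, n_vessels = 10L)))
  }
  do.call(phantom_spec, modifyList(args, list(...)))
}

# ---- geometry ------------------------------------------------------------

# physical coordinates of pixel centres along one axis
axis_coords <- function(n, px) (seq_len(n) - 0.5) * px

sample_vessels_2d <- function(spec) {
  d <- spec$shape
  px <- spec$pixel_size
  extent <- d * px
  t <- spec$tuning
  n <- if (length(spec$n_vessels) == 2L) {
    sample(spec$n_vessels[1L]:spec$n_vessels[2L], 1L)
  } else spec$n_vessels[1L]
  radii <- runif(n, spec$vessel_radius_range[1L], spec$vessel_radius_range[2L])
  centers <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(300L)) {
      margin <- radii[i] + t$margin_um
      if (any(extent - 2 * margin <= 0)) break
      p <- runif(2L, margin, extent - margin)
      ok <- TRUE
      if (i > 1L) {
        dd <- sqrt(colSums((t(centers[seq_len(i - 1L), , drop = FALSE]) - p)^2))
        ok <- all(dd >= radii[seq_len(i - 1L)] + radii[i] + t$separation_um)
      }
      if (ok) { centers[i, ] <- p; placed <- TRUE; break }
    }
    if (!placed) return(NULL)
  }
  list(n = n, radii = radii, centers = centers)
}

rasterize_discs <- function(geom, d, px) {
  labels <- array(0L, d)
  a1 <- axis_coords(d[1L], px[1L])
  a2 <- axis_coords(d[2L], px[2L])
  for (i in seq_len(geom$n)) {
    c1 <- geom$centers[i, 1L]; c2 <- geom$centers[i, 2L]; r <- geom$radii[i]
    i1 <- which(abs(a1 - c1) <= r)
    i2 <- which(abs(a2 - c2) <= r)
    if (!length(i1) || !length(i2)) next
    sub <- outer((a1[i1] - c1)^2, (a2[i2] - c2)^2, `+`) <= r^2
    block <- labels[i1, i2]
    block[sub] <- i
    labels[i1, i2] <- block
  }
  labels
}

# minimum distance between two infinite lines (p, unit u)
line_line_dist <- function(p1, u1, p2, u2) {
  n <- c(u1[2L] * u2[3L] - u1[3L] * u2[2L],
         u1[3L] * u2[1L] - u1[1L] * u2[3L],
         u1[1L] * u2[2L] - u1[2L] * u2[1L])
  nn <- sqrt(sum(n^2))
  w <- p2 - p1
  if (nn < 1e-9) { # parallel: point-to-line distance
    proj <- sum(w * u1)
    return(sqrt(max(sum(w^2) - proj^2, 0)))
  }
  abs(sum(w * n)) / nn
}

sample_vessels_3d <- function(spec) {
  d <- spec$shape
  px <- spec$pixel_size
  extent <- d * px
  t <- spec$tuning
  n <- if (length(spec$n_vessels) == 2L) {
    sample(spec$n_vessels[1L]:spec$n_vessels[2L], 1L)
  } else spec$n_vessels[1L]
  radii <- runif(n, spec$vessel_radius_range[1L], spec$vessel_radius_range[2L])
  points <- matrix(NA_real_, n, 3L)
  dirs <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(300L)) {
      phi <- runif(1L, 0, 2 * pi)
      tilt <- runif(1L, -pi / 9, pi / 9) # within 20° of the slab plane
      u <- c(cos(tilt) * cos(phi), cos(tilt) * sin(phi), sin(tilt))
      margin <- radii[i] + t$margin_um
      p <- c(runif(2L, margin, extent[1:2] - margin),
             runif(1L, radii[i], extent[3L] - radii[i]))
      ok <- TRUE
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          if (line_line_dist(points[j, ], dirs[j, ], p, u) <
              radii[i] + radii[j] + t$separation_um) { ok <- FALSE; break }
        }
      }
      if (ok) { points[i, ] <- p; dirs[i, ] <- u; placed <- TRUE; break }
    }
    if (!placed) return(NULL)
  }
  list(n = n, radii = radii, points = points, dirs = dirs)
}

rasterize_cylinders <- function(geom, d, px) {
  labels <- array(0L, d)
  a1 <- axis_coords(d[1L], px[1L])
  a2 <- axis_coords(d[2L], px[2L])
  a3 <- axis_coords(d[3L], px[3L])
  X1 <- array(a1, d)
  X2 <- array(rep(a2, each = d[1L]), d)
  X3 <- array(rep(a3, each = d[1L] * d[2L]), d)
  for (i in seq_len(geom$n)) {
    p <- geom$points[i, ]; u <- geom$dirs[i, ]; r <- geom$radii[i]
    w1 <- X1 - p[1L]; w2 <- X2 - p[2L]; w3 <- X3 - p[3L]
    proj <- w1 * u[1L] + w2 * u[2L] + w3 * u[3L]
    d2 <- w1 * w1 + w2 * w2 + w3 * w3 - proj * proj
    labels[d2 <= r * r] <- i
  }
  labels
}

# ---- carrier placement ---------------------------------------------------

# apportion carrier mass over compartments so realized fractions are exact
place_carrier <- function(spec, comp, dvals, depth) {
  t <- spec$tuning
  frac <- profile_fractions(spec$profile) / 100
  edges <- profile_edges(spec$profile)
  k <- length(edges)
  lower <- c(0, edges[-k])
  w <- array(0, dim(comp))
  sel <- comp == 0L
  if (any(sel)) {
    dmax <- max(depth[sel])
    w[sel] <- 0.5 + if (dmax > 0) depth[sel] / dmax else 0
  }
  for (s in seq_len(k)) {
    sel <- comp == s
    if (any(sel)) {
      w[sel] <- exp(-(dvals[sel] - lower[s]) / t$shell_tau_um)
    }
  }

  active <- which(frac > 0) - 1L # compartment ids with mass
  if (!is.null(spec$target_area_fraction)) {
    npix <- length(comp)
    n_sup <- max(round(spec$target_area_fraction / 100 * npix),
                 length(active))
    # allocate support pixels per active compartment proportional to mass
    fa <- frac[active + 1L]
    alloc <- diff(round(c(0, cumsum(fa / sum(fa))) * n_sup))
    alloc <- pmax(alloc, 1L)
    keep <- array(FALSE, dim(comp))
    for (j in seq_along(active)) {
      idx <- which(comp == active[j])
      nj <- min(alloc[j], length(idx))
      if (nj < 1L) return(NULL)
      # puncta-like: prefer high-weight pixels with random jitter
      ord <- order(w[idx] * runif(length(idx), 0.85, 1), decreasing = TRUE)
      keep[idx[ord[seq_len(nj)]]] <- TRUE
    }
    w[!keep] <- 0
  }

  inten <- array(0, dim(comp))
  for (cid in active) {
    sel <- comp == cid & w > 0
    sw <- sum(w[sel])
    if (sw <= 0) return(NULL) # compartment unrealizable -> retry layout
    inten[sel] <- w[sel] / sw * frac[cid + 1L]
  }
  lit <- inten > 0
  scale <- t$carrier_floor / min(inten[lit])
  # keep the total mass large enough that clipped read noise on dark
  # compartment pixels (~0.4 sd per pixel after max(x - bg, 0)) stays below
  # ~1% of the analyzed carrier signal
  if (spec$noise$gaussian_sd > 0) {
    n_analysis <- sum(comp >= 0L)
    scale <- max(scale, 300 * 0.4 * spec$noise$gaussian_sd * n_analysis)
  }
  scale <- min(scale, t$carrier_ceiling / max(inten[lit]))
  inten * scale
}

add_camera_noise <- function(x, noise) {
  y <- x + noise$baseline
  if (noise$poisson_scale > 0) {
    s <- noise$poisson_scale
    y <- rpois(length(y), lambda = s * y) / s
  }
  if (noise$gaussian_sd > 0) {
    y <- y + rnorm(length(y), 0, noise$gaussian_sd)
  }
  array(pmin(pmax(round(y), 0), 65535), dim(x))
}

# ---- generation ----------------------------------------------------------

#' Generate one synthetic field with known ground truth
#'
#' Draws the vessel geometry, builds exact ground-truth distance shells,
#' apportions carrier intensity so that the realized penetration profile
#' (measured against the ground-truth shell map) equals the requested one
#' before noise, adds IgG halos around exactly the leaky vessels, then
#' applies the camera noise model to every channel.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `field` (an [image_field()] with channels `vessel`,
#'   `carrier`, `igg`) and `truth` (class `phantom_truth`: ground-truth
#'   `lumen_mask`, `labels`, per-vessel table with leaky flags,
#'   `true_profile` as realized pre-noise, `true_area_fraction`,
#'   `true_leaky_count`, and the ground-truth `shells`).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_field_impl(spec))
}

generate_field_impl <- function(spec) {
  d <- spec$shape
  nd <- length(d)
  px <- spec$pixel_size
  t <- spec$tuning
  frac <- profile_fractions(spec$profile)
  edges <- profile_edges(spec$profile)

  for (attempt in seq_len(t$max_retries)) {
    geom <- if (nd == 2L) sample_vessels_2d(spec) else sample_vessels_3d(spec)
    if (is.null(geom)) next
    labels <- if (nd == 2L) rasterize_discs(geom, d, px)
              else rasterize_cylinders(geom, d, px)
    mask <- labels > 0L
    if (!any(mask)) next
    seg <- segmentation_from_mask(mask, labels, px)
    dmap <- distance_map(seg)
    shells <- build_shells(dmap, edges = edges)
    comp <- shells$compartments
    # every compartment that must carry mass needs enough pixels
    sizes <- vapply(0:length(edges), function(i) sum(comp == i), numeric(1))
    if (any(sizes[frac > 0] < 20)) next
    depth <- array(cpp_edt(as.logical(!mask), as.integer(d),
                           as.numeric(px))$dist, d)
    carrier_pre <- place_carrier(spec, comp, dmap$values, depth)
    if (is.null(carrier_pre)) next

    # IgG halos around exactly the leaky vessels (randomized rounding keeps
    # the expected leaky count at fraction * n)
    f <- spec$leaky_vessel_fraction
    n_leaky <- floor(f * geom$n) +
      (runif(1L) < (f * geom$n - floor(f * geom$n)))
    leaky_labels <- if (n_leaky > 0) sort(sample(seq_len(geom$n), n_leaky))
                    else integer()
    igg_pre <- array(0, d)
    if (length(leaky_labels)) {
      sel <- dmap$values > 0 & dmap$values <= t$igg_range_um &
        (dmap$nearest_label %in% leaky_labels)
      igg_pre[sel] <- t$igg_amp * exp(-dmap$values[sel] / t$igg_tau_um)
    }

    vessel_pre <- t$vessel_peak *
      array(cpp_gauss_blur(as.numeric(mask), as.integer(d),
                           as.numeric(t$vessel_edge_sigma_um / px)), d)

    field <- image_field(
      channels = list(
        vessel = add_camera_noise(vessel_pre, spec$noise),
        carrier = add_camera_noise(carrier_pre, spec$noise),
        igg = add_camera_noise(igg_pre, spec$noise)
      ),
      pixel_size = px,
      field_id = sprintf("phantom_seed%d", spec$seed)
    )

    k <- length(edges)
    true_sums <- vapply(0:k, function(i) sum(carrier_pre[comp == i]),
                        numeric(1))
    true_profile <- penetration_profile_new(
      100 * true_sums / sum(true_sums), edges, raw_sums = true_sums)
    per_vessel <- tibble(
      label = seq_len(geom$n),
      radius_um = geom$radii,
      leaky = seq_len(geom$n) %in% leaky_labels
    )
    truth <- structure(list(
      lumen_mask = mask, labels = labels, per_vessel = per_vessel,
      leaky_labels = leaky_labels,
      true_profile = true_profile,
      requested_profile = spec$profile,
      true_area_fraction = 100 * mean(carrier_pre > 0),
      true_leaky_count = length(leaky_labels),
      carrier_total = sum(carrier_pre),
      shells = shells, spec = spec
    ), class = "phantom_truth")
    return(list(field = field, truth = truth))
  }
  abort(sprintf(
    "could not place %s vessels with their shells inside the field after %d attempts",
    paste(spec$n_vessels, collapse = "-"), t$max_retries))
}

#' Generate a reproducible cohort of phantom fields
#'
#' Field i uses seed `base_seed + i - 1`, so cohorts are fully reproducible
#' and the first field is identical to `generate_field()` with
#' `seed = base_seed`.
#'
#' @param spec a [phantom_spec()] (its own seed is ignored).
#' @param n_fields number of fields (>= 1).
#' @param base_seed integer base seed (default: the spec's seed).
#' @return A list with `fields` (list of [image_field()]), `truths` (list
#'   of `phantom_truth`) and `cohort`, a tibble with one ground-truth row
#'   per field (realized profile percentages, leaky counts, area
#'   fractions).
#' @export
generate_cohort <- function(spec, n_fields, base_seed = spec$seed) {
  if (n_fields < 1L) abort("`n_fields` must be >= 1")
  res <- purrr::map(seq_len(n_fields), function(i) {
    si <- spec
    si$seed <- as.integer(base_seed + i - 1L)
    out <- tryCatch(generate_field(si), error = function(e) {
      abort(sprintf("field %d (seed %d): %s", i, si$seed,
                    conditionMessage(e)))
    })
    out$field$field_id <- sprintf("field_%03d", i)
    out
  })
  fields <- purrr::map(res, "field")
  truths <- purrr::map(res, "truth")
  cohort <- purrr::imap(truths, function(tr, i) {
    prof <- flatten_profile(tr$true_profile, prefix = "true_pct_")
    dplyr::bind_cols(
      tibble(field_id = fields[[i]]$field_id,
             seed = as.integer(base_seed + i - 1L),
             n_vessels = nrow(tr$per_vessel),
             true_leaky_count = tr$true_leaky_count,
             true_leaky_pct = 100 * tr$true_leaky_count /
               nrow(tr$per_vessel),
             true_area_fraction_pct = tr$true_area_fraction),
      prof)
  }) |> dplyr::bind_rows()
  list(fields = fields, truths = truths, cohort = cohort)
}

# one-row tibble of profile fractions with stable names (units: %)
flatten_profile <- function(profile, prefix = "pct_") {
  nm <- c("lumen", sprintf("%g_%g", profile$lower_um[-1L],
                           profile$upper_um[-1L]))
  out <- as.list(profile$fraction_pct)
  names(out) <- paste0(prefix, nm)
  as_tibble(out)
}
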