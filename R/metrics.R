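# Field- and vessel-level summary metrics: carrier-positive area fraction,
# extravasation-positive vessel classification (carrier or IgG channel),
# and the macroscale percent-injected-dose conversion.

#' Carrier-positive area fraction of a field
#'
#' Percentage of pixels whose carrier intensity exceeds a robust noise
#' threshold. The default rule is `median + 3 * MAD` of the whole channel
#' (the field is overwhelmingly parenchyma, so median and MAD estimate the
#' background level and noise scale); an absolute threshold can be given
#' instead.
#'
#' @param field an [image_field()].
#' @param carrier_channel channel to threshold (default `"carrier"`).
#' @param threshold optional absolute intensity cutoff overriding the
#'   default rule.
#' @param k_mad MAD multiplier of the default rule (default 3).
#' @return Percentage in \[0, 100\] with attribute `threshold`.
#' @export
area_fraction <- function(field, carrier_channel = "carrier",
                          threshold = NULL, k_mad = 3) {
  x <- get_channel(field, carrier_channel)
  if (is.null(threshold)) {
    threshold <- median(x) + k_mad * mad(x)
  }
  out <- 100 * mean(x > threshold)
  attr(out, "threshold") <- threshold
  out
}

# shared positivity rule: a vessel is positive when the mean
# background-subtracted intensity in its perivascular ring exceeds
# k times the MAD noise scale of far parenchyma. Invariant to a uniform
# gain applied to the whole channel (both sides scale).
vessel_positivity <- function(seg, shells, field, channel,
                              ring_um = 5, k = 2) {
  if (max(shells$edges) < ring_um) {
    abort("`ring_um` must not exceed the outermost shell edge")
  }
  x <- get_channel(field, channel)
  comp <- shells$compartments
  if (!identical(dim(x), dim(comp))) {
    abort("shell map and field dimensions differ")
  }
  far <- x[comp == -1L]
  if (length(far) < 10L) far <- as.vector(x)
  background <- median(far)
  noise_scale <- mad(far)
  ring_comps <- which(shells$edges <= ring_um) # shells fully inside ring
  in_ring <- comp %in% ring_comps
  labs <- seq_len(seg$n_vessels)
  ring_lab <- shells$nearest_label[in_ring]
  ring_val <- x[in_ring] - background
  means <- vapply(labs, function(l) {
    v <- ring_val[ring_lab == l]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  evaluable <- !is.na(means)
  if (any(!evaluable)) {
    inform(sprintf("%d vessel(s) with empty perivascular ring excluded",
                   sum(!evaluable)))
  }
  tibble(
    label = labs, ring_mean = means, evaluable = evaluable,
    positive = evaluable & means > k * noise_scale
  )
}

#' Count vessels positive for extravasated carrier signal
#'
#' Classifies each segmented vessel by the signal in its perivascular ring
#' (shell pixels within `ring_um` of the lumen whose nearest vessel it is):
#' positive when the mean background-subtracted intensity exceeds
#' `k` times the MAD-based noise scale of far parenchyma. Vessels with a
#' fully truncated (empty) ring are excluded from evaluation.
#'
#' @param seg a [segment_vessels()] result.
#' @param shells the matching [build_shells()] result.
#' @param field the [image_field()].
#' @param channel channel to evaluate (default `"carrier"`).
#' @param ring_um ring width in µm (default 5, the first shell).
#' @param k positivity criterion multiplier (default 2).
#' @return Integer count of positive vessels per field-of-view, with the
#'   per-vessel decision table in attribute `per_vessel`.
#' @export
count_extravasation_positive_vessels <- function(seg, shells, field,
                                                 channel = "carrier",
                                                 ring_um = 5, k = 2) {
  if (seg$n_vessels == 0L) {
    warn("no vessels segmented; returning 0 positive vessels")
    out <- 0L
    attr(out, "per_vessel") <- tibble(label = integer(),
                                      ring_mean = numeric(),
                                      evaluable = logical(),
                                      positive = logical())
    return(out)
  }
  tab <- vessel_positivity(seg, shells, field, channel, ring_um, k)
  out <- sum(tab$positive)
  attr(out, "per_vessel") <- tab
  out
}

#' Percentage of vessels with extravasated IgG
#'
#' Applies the same ring-positivity rule as
#' [count_extravasation_positive_vessels()] to the IgG channel and returns
#' 100 × positives / evaluable vessels — the per-field BBB-opening readout.
#'
#' @inheritParams count_extravasation_positive_vessels
#' @param channel channel to evaluate (default `"igg"`).
#' @return Percentage in \[0, 100\] (NA with a warning when no vessel is
#'   evaluable), with the decision table in attribute `per_vessel`.
#' @export
igg_positive_vessel_pct <- function(seg, shells, field, channel = "igg",
                                    ring_um = 5, k = 2) {
  if (seg$n_vessels == 0L) {
    warn("no vessels segmented; IgG-positive percentage undefined")
    return(NA_real_)
  }
  tab <- vessel_positivity(seg, shells, field, channel, ring_um, k)
  n_eval <- sum(tab$evaluable)
  if (n_eval == 0L) {
    warn("no evaluable vessels; IgG-positive percentage undefined")
    return(NA_real_)
  }
  out <- 100 * sum(tab$positive) / n_eval
  attr(out, "per_vessel") <- tab
  out
}

#' Linear fluorescence-to-dose calibration
#'
#' @param injected_dose injected dye amount (nmol).
#' @param fluorescence_per_amount detected signal units per nmol (strictly
#'   linear calibration; depth-dependent attenuation is not modeled).
#' @param roi_volume_mm3 volume of the analyzed region of interest in mm³.
#' @return An object of class `dose_calibration`.
#' @export
dose_calibration <- function(injected_dose, fluorescence_per_amount,
                             roi_volume_mm3) {
  vals <- c(injected_dose, fluorescence_per_amount, roi_volume_mm3)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all calibration values must be positive")
  }
  structure(list(injected_dose = injected_dose,
                 fluorescence_per_amount = fluorescence_per_amount,
                 roi_volume_mm3 = roi_volume_mm3),
            class = "dose_calibration")
}

#' Percent injected dose per 500 mm³
#'
#' Converts total detected fluorescence in a region of interest into the
#' macroscale accumulation readout %ID/500 mm³: the detected amount as a
#' percentage of the injected dose, normalized to a 500 mm³ reference
#' volume.
#'
#' @param total_signal summed fluorescence in the ROI.
#' @param cal a [dose_calibration()].
#' @return %ID per 500 mm³ (numeric).
#' @export
percent_id <- function(total_signal, cal) {
  stopifnot(inherits(cal, "dose_calibration"))
  amount <- total_signal / cal$fluorescence_per_amount
  100 * (amount / cal$injected_dose) * (500 / cal$roi_volume_mm3)
}

#' Relative enhancement of a treated mean over a control mean
#'
#' `100 * (treated - control) / control`, reported unrounded and rounded to
#' the nearest integer (round-half-up, the convention used for printed
#' enhancement percentages).
#'
#' @param treated_mean,control_mean group means; `control_mean` must be
#'   positive.
#' @return A one-row tibble with `enhancement_pct` and
#'   `enhancement_pct_rounded`.
#' @export
enhancement_pct <- function(treated_mean, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0) {
    abort("`control_mean` must be positive")
  }
  val <- 100 * (treated_mean - control_mean) / control_mean
  tibble(enhancement_pct = val,
         enhancement_pct_rounded = round_half_up(val))
}
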