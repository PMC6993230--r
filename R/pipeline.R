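# Pipeline orchestration: one configuration object drives segmentation,
# shell construction, profiling and the vessel-level metrics for every
# field of a cohort, and a cohort comparison runs the statistics layer.

#' Pipeline configuration
#'
#' Central, validated set of analysis parameters. Every run writes the
#' resolved configuration next to its outputs so results are reproducible
#' from the config + seed alone.
#'
#' @param vessel_channel,carrier_channel,igg_channel channel names (set
#'   `igg_channel = NULL` when no IgG stain was acquired).
#' @param smooth_sigma_um segmentation smoothing sigma, µm.
#' @param threshold `"otsu"` or `"absolute"` (with `threshold_value`).
#' @param threshold_value absolute intensity cutoff when
#'   `threshold = "absolute"`.
#' @param min_size_um minimum vessel size (µm² in 2D, µm³ in 3D; NULL for
#'   the dimension-dependent default).
#' @param edges shell edges in µm.
#' @param background carrier background override (NULL = median of
#'   far parenchyma).
#' @param positivity_k ring-positivity criterion multiplier.
#' @param ring_um positivity ring width, µm.
#' @param seed integer seed for any stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vessel_channel = "vessel",
                            carrier_channel = "carrier",
                            igg_channel = "igg",
                            smooth_sigma_um = 0.5,
                            threshold = "otsu",
                            threshold_value = NULL,
                            min_size_um = NULL,
                            edges = c(5, 10, 15, 20),
                            background = NULL,
                            positivity_k = 2,
                            ring_um = 5,
                            seed = 1L) {
  if (!threshold %in% c("otsu", "absolute")) {
    abort("`threshold` must be 'otsu' or 'absolute'")
  }
  if (any(diff(c(0, edges)) <= 0)) {
    abort("`edges` must be positive and strictly increasing")
  }
  if (positivity_k <= 0) abort("`positivity_k` must be > 0")
  structure(list(
    vessel_channel = vessel_channel, carrier_channel = carrier_channel,
    igg_channel = igg_channel, smooth_sigma_um = smooth_sigma_um,
    threshold = threshold, threshold_value = threshold_value,
    min_size_um = min_size_um, edges = edges, background = background,
    positivity_k = positivity_k, ring_um = ring_um, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of [pipeline_config()] fields.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Write the resolved configuration as YAML
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Analyze one field end-to-end
#'
#' Runs segmentation, distance shells, penetration profiling and the
#' field-level metrics, returning one tidy row per field.
#'
#' @param field an [image_field()].
#' @param config a [pipeline_config()].
#' @return A one-row tibble: vessel counts, lumen fraction, carrier area
#'   fraction (% of pixels), extravasation-positive vessels per FOV,
#'   IgG-positive vessel % (when an IgG channel is configured), the
#'   flattened penetration profile (% per compartment) and the excluded
#'   signal %.
#' @export
analyze_field <- function(field, config = pipeline_config()) {
  seg <- segment_vessels(
    field, channel = config$vessel_channel,
    smooth_sigma_um = config$smooth_sigma_um,
    threshold = config$threshold,
    threshold_value = config$threshold_value,
    min_size_um = config$min_size_um
  )
  base <- tibble(field_id = field$field_id,
                 n_vessels = seg$n_vessels,
                 lumen_fraction_pct = 100 * mean(seg$lumen_mask),
                 area_fraction_pct = as.numeric(
                   area_fraction(field, config$carrier_channel)))
  if (seg$n_vessels == 0L) {
    base$positive_vessels_per_fov <- 0L
    base$igg_positive_pct <- NA_real_
    base$excluded_signal_pct <- NA_real_
    return(base)
  }
  shells <- build_shells(distance_map(seg, field), edges = config$edges)
  prof <- penetration_profile(shells, field,
                              carrier_channel = config$carrier_channel,
                              background = config$background)
  base$positive_vessels_per_fov <- as.integer(
    count_extravasation_positive_vessels(
      seg, shells, field, channel = config$carrier_channel,
      ring_um = config$ring_um, k = config$positivity_k))
  base$igg_positive_pct <- if (!is.null(config$igg_channel) &&
                               config$igg_channel %in% names(field$channels)) {
    as.numeric(igg_positive_vessel_pct(
      seg, shells, field, channel = config$igg_channel,
      ring_um = config$ring_um, k = config$positivity_k))
  } else NA_real_
  base$excluded_signal_pct <- attr(prof, "excluded_signal_pct")
  dplyr::bind_cols(base, flatten_profile(prof))
}

#' Analyze a cohort of fields
#'
#' @param fields list of [image_field()] objects.
#' @param config a [pipeline_config()].
#' @param condition optional condition label recorded per row.
#' @return A tibble with one [analyze_field()] row per field.
#' @export
run_cohort <- function(fields, config = pipeline_config(),
                       condition = NULL) {
  out <- purrr::imap(fields, function(f, i) {
    tryCatch(analyze_field(f, config), error = function(e) {
      abort(sprintf("field %s: %s", f$field_id %||% i, conditionMessage(e)))
    })
  }) |> dplyr::bind_rows()
  if (!is.null(condition)) {
    out <- dplyr::mutate(out, condition = condition, .before = 1L)
  }
  out
}

#' Compare two analyzed cohorts
#'
#' Statistics layer over [run_cohort()] tables from two conditions:
#' two-way ANOVA (treatment × compartment) with Bonferroni-corrected
#' per-compartment comparisons on the penetration profiles, and Student's
#' t-tests on the scalar per-field readouts (area fraction, positive
#' vessels per FOV, IgG-positive %).
#'
#' @param cohort_a,cohort_b [run_cohort()] tibbles (their `condition`
#'   column, or `label_a`/`label_b`, names the groups).
#' @param label_a,label_b condition labels.
#' @return A list of class `cohort_comparison` with `anova`
#'   (a [two_way_anova_bonferroni()] object) and `ttests` (tibble).
#' @export
compare_cohorts <- function(cohort_a, cohort_b,
                            label_a = NULL, label_b = NULL) {
  label_a <- label_a %||% cohort_a$condition[1L] %||% "treated"
  label_b <- label_b %||% cohort_b$condition[1L] %||% "control"
  pct_cols <- grep("^pct_", names(cohort_a), value = TRUE)
  if (!length(pct_cols)) abort("cohort tables carry no profile columns")
  long <- dplyr::bind_rows(
    dplyr::mutate(cohort_a[, c("field_id", pct_cols)], treatment = label_a),
    dplyr::mutate(cohort_b[, c("field_id", pct_cols)], treatment = label_b)
  ) |>
    tidyr::pivot_longer(dplyr::all_of(pct_cols),
                        names_to = "compartment", values_to = "value") |>
    dplyr::mutate(compartment = factor(.data$compartment,
                                       levels = pct_cols))
  an <- two_way_anova_bonferroni(long, value, treatment, compartment)

  scalar_cols <- intersect(
    c("area_fraction_pct", "positive_vessels_per_fov", "igg_positive_pct"),
    names(cohort_a))
  ttests <- purrr::map_dfr(scalar_cols, function(cl) {
    va <- cohort_a[[cl]]
    vb <- cohort_b[[cl]]
    if (sum(is.finite(va)) < 2L || sum(is.finite(vb)) < 2L) return(NULL)
    if (sd(va, na.rm = TRUE) == 0 && sd(vb, na.rm = TRUE) == 0) {
      return(NULL) # constant readout in both arms: no test possible
    }
    res <- tryCatch(two_group_ttest(va[is.finite(va)], vb[is.finite(vb)]),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$p_value)) return(NULL)
    dplyr::mutate(tidy(res), readout = cl,
                  mean_a = mean(va, na.rm = TRUE),
                  mean_b = mean(vb, na.rm = TRUE), .before = 1L)
  })
  structure(list(anova = an, ttests = ttests,
                 labels = c(label_a, label_b)),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Cohort comparison: %s vs %s\n", x$labels[1L], x$labels[2L]))
  print(x$anova)
  if (nrow(x$ttests)) {
    cat("\nScalar readouts (Student's t):\n")
    print(x$ttests)
  }
  invisible(x)
}

#' @export
tidy.cohort_comparison <- function(x, ...) tidy(x$anova)

#' Run the full pipeline on simulated or on-disk cohorts
#'
#' Orchestrates one or two conditions end-to-end: simulate phantom cohorts
#' (or read OME-TIFF fields from directories), analyze every field, and —
#' when two conditions are given — run the comparison statistics. With
#' `out` set, writes the cohort CSV, a per-condition field CSV, the
#' comparison report JSON and the resolved config YAML; outputs are
#' byte-deterministic given config + seed.
#'
#' @param config a [pipeline_config()].
#' @param simulate named list mapping condition labels to
#'   [phantom_preset()] names (or `phantom_spec` objects) to simulate, e.g.
#'   `list(treated = "polymer_US_2D", control = "polymer_ctrl_2D")`.
#' @param paths named list mapping condition labels to directories or
#'   vectors of TIFF paths (alternative to `simulate`).
#' @param n_fields fields per simulated condition.
#' @param out optional output directory.
#' @param pixel_size forwarded to [read_field()] for files without
#'   metadata.
#' @return A list with `cohort` (combined tibble) and `comparison` (a
#'   [compare_cohorts()] result, or NULL for a single condition).
#' @export
run_pipeline <- function(config = pipeline_config(), simulate = NULL,
                         paths = NULL, n_fields = 20L, out = NULL,
                         pixel_size = NULL) {
  if (is.null(simulate) == is.null(paths)) {
    abort("supply exactly one of `simulate` or `paths`")
  }
  conds <- if (!is.null(simulate)) names(simulate) else names(paths)
  if (is.null(conds) || any(!nzchar(conds))) {
    abort("conditions must be a named list")
  }
  cohorts <- list()
  for (i in seq_along(conds)) {
    cond <- conds[i]
    if (!is.null(simulate)) {
      sp <- simulate[[i]]
      if (is.character(sp)) {
        sp <- phantom_preset(sp, seed = config$seed + 1000L * (i - 1L))
      }
      gen <- generate_cohort(sp, n_fields = n_fields, base_seed = sp$seed)
      fields <- gen$fields
    } else {
      fp <- paths[[i]]
      if (length(fp) == 1L && dir.exists(fp)) {
        fp <- list.files(fp, pattern = "\\.tiff?$", full.names = TRUE)
      }
      if (!length(fp)) abort(sprintf("no TIFF files for condition '%s'", cond))
      fields <- lapply(fp, read_field, pixel_size = pixel_size)
    }
    cohorts[[cond]] <- run_cohort(fields, config, condition = cond)
  }
  cohort <- dplyr::bind_rows(cohorts)
  comparison <- if (length(conds) == 2L) {
    compare_cohorts(cohorts[[1L]], cohorts[[2L]])
  } else NULL

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(cohort, file.path(out, "cohort.csv"))
    write_config(config, file.path(out, "config.yaml"))
    if (!is.null(comparison)) {
      report <- list(
        conditions = conds,
        anova = comparison$anova$anova,
        per_compartment = comparison$anova$comparisons,
        ttests = comparison$ttests
      )
      jsonlite::write_json(report, file.path(out, "comparison.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
    }
    writeLines(c(
      sprintf("perivasc run: %d condition(s), %d field(s)",
              length(conds), nrow(cohort)),
      sprintf("seed: %d", config$seed)
    ), file.path(out, "run.log"))
  }
  list(cohort = cohort, comparison = comparison)
}
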