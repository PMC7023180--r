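default_analytes <- function() {
  c("E1", "E2", "E3", "EE2", "AMX", "TET", "PEN", "CIP")
}

default_classes <- function() {
  c(rep("estrogen", 4), rep("antibiotic", 4))
}

# Half-saturation exposures (arbitrary exposure units) per (phage, analyte).
# Smaller affinity = stronger swelling response. Estrogens bind the
# EEEE-displaying phage strongly, antibiotics the RGD-displaying phage;
# the wild-type film responds moderately to everything. Small within-class
# gradients keep same-class analytes distinct but mutually closer than
# analytes across classes.
default_affinity <- function(phage_types = c("wild", "RGD", "EEEE"),
                             analyte_ids = default_analytes()) {
  aff <- rbind(
    wild = c(1.6, 1.8, 2.0, 2.2, 2.8, 3.0, 3.2, 3.4),
    RGD  = c(4.0, 4.5, 5.0, 5.5, 0.25, 0.30, 0.35, 0.40),
    EEEE = c(0.25, 0.30, 0.35, 0.40, 4.0, 4.5, 5.0, 5.5))
  colnames(aff) <- default_analytes()
  aff[phage_types, analyte_ids, drop = FALSE]
}

# Multiplicative reaction-strength factor per (analyte, temperature):
# higher temperature raises analyte vapor pressure, strengthening the
# film reaction.
default_temp_gain <- function(analyte_ids = default_analytes(),
                              temperatures_c = c(30, 60, 90, 120)) {
  gain <- matrix(rep(c(0.4, 0.7, 1.0, 1.3)[seq_along(temperatures_c)],
                     each = length(analyte_ids)),
                 nrow = length(analyte_ids),
                 dimnames = list(analyte_ids, as.character(temperatures_c)))
  gain
}

#' Define a synthetic sensing scenario with known ground truth
#'
#' Bundles everything needed to simulate a sensor-array study: the analyte
#' panel and its class labels, the temperature levels, the chip design
#' (phage type per row, film color per column), the optical/swelling model,
#' the camera noise level, and a root seed. The default reproduces the
#' 8-analyte design: four estrogen drugs (estrone-, estradiol-, estriol-
#' and ethinylestradiol-like, labelled E1/E2/E3/EE2) and four antibiotics
#' (AMX/TET/PEN/CIP), each sensed at 30, 60, 90 and 120 degrees C on a
#' 3 x 3 chip (wild/RGD/EEEE phage rows; red/green/blue film columns whose
#' unswollen Bragg peaks sit at roughly 650/550/450 nm).
#'
#' Swelling of cell (phage p, film f) exposed to analyte a at temperature t
#' is `s = min(s_max, s_max * e / (e + affinity[p, a]) * temp_gain[a, t])`,
#' a saturating uptake curve scaled by a temperature gain; the film color
#' then shifts from the unswollen Bragg peak `2 * n_eff * d0[f]` to the
#' swollen one `2 * n_eff * d0[f] * (1 + s)`.
#'
#' @param analyte_ids Analyte labels.
#' @param class_labels Class per analyte (same length as `analyte_ids`).
#' @param temperatures_c Temperature levels in degrees C.
#' @param phage_types Phage type per chip row.
#' @param film_colors Film color per chip column.
#' @param d0_nm Named unswollen structure periods (nm) per film color.
#' @param n_eff Effective refractive index of the films.
#' @param s_max Maximum fractional swelling.
#' @param exposure Analyte exposure in the same arbitrary units as
#'   `affinity`.
#' @param affinity Half-saturation exposure matrix, phage x analyte.
#' @param temp_gain Gain matrix, analyte x temperature.
#' @param peak_width_nm,peak_amplitude,peak_baseline Spectral peak shape
#'   defaults (see [spectral_peak()]).
#' @param noise_sd Per-channel pixel noise standard deviation in 8-bit
#'   counts.
#' @param seed Root seed; all randomness in dataset generation flows from
#'   it.
#' @param layout A `"chip_layout"`; defaults to [chip_layout()].
#' @return An object of class `"synthetic_scenario"`.
#' @examples
#' sc <- synthetic_scenario()
#' sc$analyte_ids
#' @export
synthetic_scenario <- function(analyte_ids = default_analytes(),
                               class_labels = default_classes(),
                               temperatures_c = c(30, 60, 90, 120),
                               phage_types = c("wild", "RGD", "EEEE"),
                               film_colors = c("red", "green", "blue"),
                               d0_nm = c(red = 650 / 3, green = 550 / 3,
                                         blue = 450 / 3),
                               n_eff = 1.5,
                               s_max = 0.12,
                               exposure = 1,
                               affinity = NULL,
                               temp_gain = NULL,
                               peak_width_nm = 30,
                               peak_amplitude = 0.9,
                               peak_baseline = 0.05,
                               noise_sd = 2,
                               seed = 20200109,
                               layout = NULL) {
  if (length(class_labels) != length(analyte_ids))
    stop_csa("class_labels must match analyte_ids",
             class = "invalid_parameter")
  if (anyDuplicated(analyte_ids))
    stop_csa("duplicate analyte ids", class = "labeling_error")
  if (noise_sd < 0 || s_max < 0 || n_eff < 1 || any(d0_nm <= 0) ||
      exposure < 0)
    stop_csa("invalid scenario parameter", class = "invalid_parameter")
  if (is.null(affinity))
    affinity <- default_affinity(phage_types, analyte_ids)
  if (is.null(temp_gain))
    temp_gain <- default_temp_gain(analyte_ids, temperatures_c)
  if (!all(phage_types %in% rownames(affinity)) ||
      !all(analyte_ids %in% colnames(affinity)))
    stop_csa("affinity matrix must cover all phage types and analytes",
             class = "invalid_parameter")
  if (any(affinity <= 0) || any(temp_gain < 0))
    stop_csa("affinity must be > 0 and temp_gain >= 0",
             class = "invalid_parameter")
  if (is.null(layout))
    layout <- chip_layout(n_rows = length(phage_types),
                          n_cols = length(film_colors),
                          phage_types = phage_types,
                          film_colors = film_colors)
  names(class_labels) <- analyte_ids
  structure(
    list(analyte_ids = analyte_ids, class_labels = class_labels,
         temperatures_c = temperatures_c, phage_types = phage_types,
         film_colors = film_colors, d0_nm = d0_nm, n_eff = n_eff,
         s_max = s_max, exposure = exposure, affinity = affinity,
         temp_gain = temp_gain, peak_width_nm = peak_width_nm,
         peak_amplitude = peak_amplitude, peak_baseline = peak_baseline,
         noise_sd = noise_sd, seed = as.integer(seed), layout = layout),
    class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "synthetic_scenario: %d analytes (%s), %d temperatures, %d x %d cells\n",
    length(x$analyte_ids),
    paste(unique(x$class_labels), collapse = " / "),
    length(x$temperatures_c), length(x$phage_types),
    length(x$film_colors)))
  cat(sprintf("noise_sd %.2f counts, s_max %.3f, seed %d\n",
              x$noise_sd, x$s_max, x$seed))
  invisible(x)
}

# Ground-truth swelling fraction of every cell for one exposure.
swelling_fractions <- function(scenario, analyte, temperature_c) {
  e <- scenario$exposure
  gain <- scenario$temp_gain[analyte, as.character(temperature_c)]
  s <- outer(scenario$phage_types, scenario$film_colors,
             function(p, f) {
               raw <- scenario$s_max * e / (e + scenario$affinity[p, analyte]) *
                 gain
               pmin(pmax(raw, 0), scenario$s_max)
             })
  dimnames(s) <- list(scenario$phage_types, scenario$film_colors)
  s
}

#' Simulate the pre/post-exposure colors of one chip
#'
#' Computes, for every cell of the chip, the 8-bit RGB color before
#' exposure (zero swelling) and after exposure of the given analyte at the
#' given temperature, using the Bragg/swelling model of the scenario. The
#' result is deterministic: pixel noise is added later, at image-rendering
#' time.
#'
#' @param scenario A `"synthetic_scenario"`.
#' @param analyte Analyte label present in the scenario.
#' @param temperature_c Temperature level present in the scenario.
#' @return A list with integer matrices `pre` and `post` (cells x RGB, in
#'   row-major cell order) and the numeric vector `swelling` of ground-truth
#'   swelling fractions.
#' @examples
#' r <- simulate_response(synthetic_scenario(), "E1", 120)
#' r$post - r$pre
#' @export
simulate_response <- function(scenario, analyte, temperature_c) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!analyte %in% scenario$analyte_ids)
    stop_csa("unknown analyte: ", analyte, class = "lookup_error")
  if (!temperature_c %in% scenario$temperatures_c)
    stop_csa("unknown temperature: ", temperature_c, class = "lookup_error")
  s <- swelling_fractions(scenario, analyte, temperature_c)
  nms <- cell_names(scenario$layout)
  cells <- scenario$layout$cells
  pre <- post <- matrix(0L, nrow(cells), 3,
                        dimnames = list(nms, c("R", "G", "B")))
  sw <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    f <- scenario$film_colors[cells$col[i]]
    p <- scenario$phage_types[cells$row[i]]
    peak_args <- list(width_nm = scenario$peak_width_nm,
                      amplitude = scenario$peak_amplitude,
                      baseline = scenario$peak_baseline)
    pre[i, ] <- do.call(spectrum_to_rgb8, list(
      do.call(bragg_peak, c(list(scenario$d0_nm[[f]], scenario$n_eff, 0),
                            peak_args))))
    sw[i] <- s[p, f]
    post[i, ] <- do.call(spectrum_to_rgb8, list(
      do.call(bragg_peak, c(list(scenario$d0_nm[[f]], scenario$n_eff, sw[i]),
                            peak_args))))
  }
  names(sw) <- nms
  list(pre = pre, post = post, swelling = sw)
}
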