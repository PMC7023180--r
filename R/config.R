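#' Save / load a synthetic scenario as YAML
#'
#' The snapshot round-trips every generative parameter (including the
#' affinity and temperature-gain matrices and the chip layout), so a saved
#' config fully reproduces a dataset.
#'
#' @param scenario A `"synthetic_scenario"`.
#' @param path YAML file path.
#' @return `read_scenario_config()` returns a `"synthetic_scenario"`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  lay <- scenario$layout
  cfg <- list(
    analyte_ids = as.list(scenario$analyte_ids),
    class_labels = as.list(unname(scenario$class_labels)),
    temperatures_c = as.list(scenario$temperatures_c),
    phage_types = as.list(scenario$phage_types),
    film_colors = as.list(scenario$film_colors),
    d0_nm = as.list(scenario$d0_nm),
    n_eff = scenario$n_eff, s_max = scenario$s_max,
    exposure = scenario$exposure,
    affinity = apply(scenario$affinity, 1, as.list, simplify = FALSE),
    temp_gain = apply(scenario$temp_gain, 1, as.list, simplify = FALSE),
    peak_width_nm = scenario$peak_width_nm,
    peak_amplitude = scenario$peak_amplitude,
    peak_baseline = scenario$peak_baseline,
    noise_sd = scenario$noise_sd, seed = scenario$seed,
    layout = list(image_width = lay$image_width,
                  image_height = lay$image_height,
                  roi_side = lay$roi_side,
                  cells = lapply(seq_len(nrow(lay$cells)), function(i)
                    as.list(lay$cells[i, ]))))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  listmat <- function(x, cols) {
    m <- do.call(rbind, lapply(x, function(r) unlist(r[cols])))
    rownames(m) <- names(x); colnames(m) <- cols
    m
  }
  affinity <- listmat(cfg$affinity, unlist(cfg$analyte_ids))
  temp_gain <- listmat(cfg$temp_gain, as.character(unlist(cfg$temperatures_c)))
  cells <- do.call(rbind, lapply(cfg$layout$cells, as.data.frame))
  layout <- chip_layout(cells = cells,
                        roi_side = cfg$layout$roi_side,
                        image_width = cfg$layout$image_width,
                        image_height = cfg$layout$image_height,
                        phage_types = unlist(cfg$phage_types),
                        film_colors = unlist(cfg$film_colors))
  synthetic_scenario(
    analyte_ids = unlist(cfg$analyte_ids),
    class_labels = unlist(cfg$class_labels),
    temperatures_c = unlist(cfg$temperatures_c),
    phage_types = unlist(cfg$phage_types),
    film_colors = unlist(cfg$film_colors),
    d0_nm = unlist(cfg$d0_nm),
    n_eff = cfg$n_eff, s_max = cfg$s_max, exposure = cfg$exposure,
    affinity = affinity, temp_gain = temp_gain,
    peak_width_nm = cfg$peak_width_nm,
    peak_amplitude = cfg$peak_amplitude,
    peak_baseline = cfg$peak_baseline,
    noise_sd = cfg$noise_sd, seed = cfg$seed, layout = layout)
}
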