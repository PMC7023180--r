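#' Simulate a dataset from a config file or scenario
#'
#' Pipeline front-end wrapping [generate_dataset()]: resolves the scenario
#' (YAML config path, `"synthetic_scenario"` object, or the package
#' default), writes the image dataset, and appends a run manifest with
#' file checksums.
#'
#' @param config Path to a scenario YAML, a `"synthetic_scenario"`, or
#'   `NULL` for the default scenario.
#' @param out_dir Output directory.
#' @param seed Optional override of the scenario seed.
#' @return The dataset manifest data frame, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir, seed = NULL) {
  scenario <- resolve_scenario(config, seed)
  manifest <- generate_dataset(scenario, out_dir)
  write_run_manifest(out_dir, list(
    command = "simulate", seed = scenario$seed,
    noise_sd = scenario$noise_sd,
    n_analytes = length(scenario$analyte_ids),
    n_temperatures = length(scenario$temperatures_c)))
  invisible(manifest)
}

resolve_scenario <- function(config, seed = NULL) {
  scenario <-
    if (is.null(config)) synthetic_scenario()
    else if (inherits(config, "synthetic_scenario")) config
    else if (is.character(config)) read_scenario_config(config)
    else stop_csa("config must be a path or synthetic_scenario",
                  class = "invalid_parameter")
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  scenario
}

#' Extract feature tables from a simulated or measured dataset
#'
#' Reads `manifest.csv` and the pre/post chip-image pairs in `input_dir`,
#' extracts per-cell means, forms delta-RGB patterns, and assembles the
#' feature table for the requested mode.
#'
#' @param input_dir Dataset directory containing `manifest.csv` and PNGs.
#' @param layout A `"chip_layout"` (default: the standard 3 x 3 layout).
#' @param mode Feature assembly mode, see [assemble_feature_table()].
#' @return List with `features` (table or list of tables), `patterns`,
#'   and the `manifest`.
#' @export
extract_dataset <- function(input_dir, layout = chip_layout(),
                            mode = c("concatenated", "per_temperature")) {
  mode <- match.arg(mode)
  manifest_path <- file.path(input_dir, "manifest.csv")
  if (!file.exists(manifest_path))
    stop_csa("no manifest.csv in ", input_dir, class = "completeness_error")
  manifest <- utils::read.csv(manifest_path)
  patterns <- lapply(seq_len(nrow(manifest)), function(i) {
    pre <- read_chip_image(file.path(input_dir, manifest$pre_image[i]))
    post <- read_chip_image(file.path(input_dir, manifest$post_image[i]))
    compute_delta_pattern(extract_cell_means(pre, layout),
                          extract_cell_means(post, layout),
                          manifest$analyte_id[i],
                          manifest$temperature_c[i])
  })
  list(features = assemble_feature_table(patterns, mode),
       patterns = patterns, manifest = manifest)
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: reads a dataset directory (images + manifest) or a
#' pre-extracted feature CSV, computes the color-distance matrix, performs
#' hierarchical clustering, cuts the tree at `k`, and writes all outputs
#' to `out_dir`: `features.csv`, `distance.csv` and
#' `distance.phylip.txt`, `merges.csv`, `tree.newick`, `cut_labels.csv`,
#' per-exposure difference-map PNGs (`diffmap_*.png`, cells painted by
#' `|delta RGB|`), a dendrogram plot (`dendrogram.png`, when a graphics
#' device is available), and `run_manifest.yaml` with the configuration,
#' checksums and any tie-break events. When ground-truth class labels are
#' present in the manifest, the adjusted Rand index of the k-cut against
#' them is computed and reported.
#'
#' @param input Dataset directory or feature CSV path.
#' @param out_dir Output directory.
#' @param layout A `"chip_layout"` for image inputs.
#' @param dialect Distance dialect, see [color_distance()].
#' @param linkage Linkage rule, see [hierarchical_cluster()].
#' @param mode Feature mode, see [assemble_feature_table()]; clustering
#'   runs on the concatenated table or, in per-temperature mode, on each
#'   temperature's table separately (outputs suffixed by temperature).
#' @param k Number of clusters for the cut.
#' @param quiet Suppress console summary.
#' @return List with `features`, `distance`, `tree`, `cut`, `ari` (or
#'   `NA` when no ground truth is available), invisibly.
#' @export
run_analyze <- function(input, out_dir, layout = chip_layout(),
                        dialect = c("squared", "euclidean"),
                        linkage = "ward_d",
                        mode = c("concatenated", "per_temperature"),
                        k = 2, quiet = FALSE) {
  dialect <- match.arg(dialect)
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  classes <- NULL; patterns <- NULL; manifest <- NULL
  if (dir.exists(input)) {
    ex <- extract_dataset(input, layout, mode = "concatenated")
    patterns <- ex$patterns; manifest <- ex$manifest
    features <- if (mode == "concatenated") ex$features
                else assemble_feature_table(patterns, "per_temperature")
    cl <- unique(ex$manifest[, c("analyte_id", "class_label")])
    classes <- setNames(cl$class_label, cl$analyte_id)
  } else if (file.exists(input)) {
    features <- read_feature_csv(input)
  } else stop_csa("input not found: ", input, class = "completeness_error")

  analyze_one <- function(feat, tag = "") {
    sfx <- if (nzchar(tag)) paste0("_", tag) else ""
    d <- distance_matrix(feat, dialect)
    tree <- hierarchical_cluster(d, linkage)
    cut <- cut_tree(tree, k)
    write_feature_csv(feat, file.path(out_dir,
                                      paste0("features", sfx, ".csv")))
    write_distance_csv(d, file.path(out_dir,
                                    paste0("distance", sfx, ".csv")))
    write_distance_phylip(d, file.path(out_dir,
                                       paste0("distance", sfx,
                                              ".phylip.txt")))
    write_merges_csv(tree, file.path(out_dir, paste0("merges", sfx,
                                                     ".csv")))
    writeLines(dendrogram_to_newick(tree),
               file.path(out_dir, paste0("tree", sfx, ".newick")))
    utils::write.csv(data.frame(analyte_id = names(cut), cluster = cut),
                     file.path(out_dir, paste0("cut_labels", sfx, ".csv")),
                     row.names = FALSE)
    ari <- NA_real_
    if (!is.null(classes))
      ari <- ari_score(cut[names(classes)], classes)
    plot_dendrogram_png(tree, file.path(out_dir,
                                        paste0("dendrogram", sfx, ".png")))
    list(features = feat, distance = d, tree = tree, cut = cut, ari = ari)
  }

  if (mode == "per_temperature") {
    res <- lapply(names(features), function(t)
      analyze_one(features[[t]], paste0("t", t)))
    names(res) <- names(features)
    main <- res[[length(res)]]
  } else {
    main <- analyze_one(features)
    res <- main
  }

  if (!is.null(patterns))
    write_difference_maps(patterns, layout, out_dir)

  ties <- if (inherits(main$tree, "color_dendrogram")) main$tree$ties
          else list()
  write_run_manifest(out_dir, list(
    command = "analyze", input = normalizePath(input),
    dialect = dialect, linkage = linkage, mode = mode, k = k,
    ari = if (is.na(main$ari)) NULL else main$ari,
    tie_events = length(ties)))
  if (!quiet) {
    cat(sprintf("analyzed %d patterns (%s dialect, %s linkage, %s mode)\n",
                length(main$cut), dialect, linkage, mode))
    cat(sprintf("k = %d cut: %s\n", k,
                paste(names(main$cut), main$cut, sep = "=",
                      collapse = " ")))
    if (!is.na(main$ari))
      cat(sprintf("adjusted Rand index vs ground truth: %.3f\n",
                  main$ari))
  }
  invisible(res)
}

# Paint each cell with |delta RGB| as an 8-bit patch; display-only, the
# analysis path keeps signed deltas.
write_difference_maps <- function(patterns, layout, out_dir) {
  for (p in patterns) {
    rgbs <- pmin(pmax(round(abs(p$bins)), 0), 255)
    img <- render_chip_image(layout, rgbs, noise_sd = 0, background = 0L)
    write_chip_image(img, file.path(out_dir,
                                    sprintf("diffmap_%s_%03d.png",
                                            p$analyte_id,
                                            p$temperature_c)))
  }
}

plot_dendrogram_png <- function(tree, path) {
  tryCatch({
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices::dev.off())
    graphics::plot(stats::as.dendrogram(as.hclust(tree)),
                   main = sprintf("Hierarchical cluster analysis (%s)",
                                  tree$linkage),
                   ylab = "merge height")
  }, error = function(e) {
    warning("dendrogram plot skipped: ", conditionMessage(e))
  })
  invisible(path)
}

write_run_manifest <- function(out_dir, extra) {
  files <- setdiff(list.files(out_dir), "run_manifest.yaml")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- c(
    list(tool = "csaclust",
         version = as.character(utils::packageVersion("csaclust")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra,
    list(files = as.list(setNames(unname(sums), files))))
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  invisible(manifest)
}
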