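# End-to-end orchestration: image -> masks -> features -> statistics, or
# synthetic cohort -> statistics, with one shared statistics code path.

#' Pipeline configuration
#'
#' All knobs of the pipeline in one (nestable, YAML-serializable) list.
#' Exactly one of the two modes is active: `"synthetic"` draws a cohort
#' feature table from a named preset; `"images"` reads a manifest CSV
#' (columns `subject`, `group`, `image_path`) and runs the full image
#' pipeline per subject. The statistics stage is identical in both modes.
#'
#' @param mode `"synthetic"` or `"images"`.
#' @param preset cohort preset for synthetic mode, see
#'   [default_group_params()].
#' @param manifest path to the manifest CSV (images mode).
#' @param seed RNG seed recorded in every report.
#' @param pixel_size micrometers per pixel.
#' @param median_window median filter window.
#' @param equalize_first histogram equalization before (TRUE) or after the
#'   median filter.
#' @param polarity villous binarization polarity ([binarize_villi()]).
#' @param threshold_on `"denoised"` (default) thresholds the median-filtered
#'   grayscale; `"equalized"` thresholds the contrast-enhanced image. When a
#'   narrow-band background dominates the frame, equalization spreads the
#'   background mode across the dynamic range and valley-seeking
#'   thresholding degrades; the denoised image keeps the tissue/background
#'   bimodality intact.
#' @param villous_min_area,villous_hole_cap island/hole cleanup for villi, px.
#' @param cap_iterations,cap_resid_threshold,cap_min_area morphological
#'   capillary detection knobs ([morph_capillaries()]).
#' @param b_threshold,density_threshold blood detection knobs
#'   ([blood_capillary_mask()]).
#' @param connectivity component connectivity (4 or 8).
#' @param linkage HCA linkage ([hca()]).
#' @param accuracy_scheme `"loo"` or `"resubstitution"`.
#' @param n_top_features how many top-ranked features feed HCA/PCA.
#' @param debug_images write intermediate grayscale/mask PNGs (images mode).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "images"),
                            preset = "full-cohort", manifest = NULL,
                            seed = 1L, pixel_size = 0.63,
                            median_window = 3L, equalize_first = FALSE,
                            polarity = "auto",
                            threshold_on = c("denoised", "equalized"),
                            villous_min_area = 64L, villous_hole_cap = 400L,
                            cap_iterations = 8L, cap_resid_threshold = 40L,
                            cap_min_area = 4L,
                            b_threshold = 10, density_threshold = 0.15,
                            connectivity = 8L,
                            linkage = "ward", accuracy_scheme = "loo",
                            n_top_features = 5L, debug_images = FALSE) {
  mode <- match.arg(mode)
  if (mode == "images" && is.null(manifest))
    stop("images mode needs a manifest path")
  threshold_on <- match.arg(threshold_on)
  cfg <- list(mode = mode, preset = preset, manifest = manifest,
              threshold_on = threshold_on,
              seed = as.integer(seed), pixel_size = pixel_size,
              median_window = as.integer(median_window),
              equalize_first = isTRUE(equalize_first), polarity = polarity,
              villous_min_area = as.integer(villous_min_area),
              villous_hole_cap = as.integer(villous_hole_cap),
              cap_iterations = as.integer(cap_iterations),
              cap_resid_threshold = cap_resid_threshold,
              cap_min_area = as.integer(cap_min_area),
              b_threshold = b_threshold,
              density_threshold = density_threshold,
              connectivity = as.integer(connectivity), linkage = linkage,
              accuracy_scheme = accuracy_scheme,
              n_top_features = as.integer(n_top_features),
              debug_images = isTRUE(debug_images))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return a `pipeline_config` (for the reader).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- config
  class(x) <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

# stable md5 over the canonical JSON serialization of the config
config_hash <- function(config) {
  x <- config
  class(x) <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Segment one micrograph into villous and capillary labelings
#'
#' The full single-image path: preprocessing, Otsu villous segmentation with
#' cleanup, morphological + blood capillary detection, union and labeling.
#'
#' @param img RGB array (0..255).
#' @param config a [pipeline_config()].
#' @return list: `gray` (preprocessed), `villi_mask`, `capillary_mask`,
#'   `villi` and `capillaries` (labelings), `threshold` (Otsu level).
#' @export
segment_image <- function(img, config = pipeline_config()) {
  denoised <- median_filter(rgb_to_gray(img), config$median_window)
  equalized <- equalize_histogram(denoised)
  gray <- if (config$threshold_on == "denoised") denoised else equalized
  t <- otsu_threshold(gray)
  villi <- binarize_villi(gray, t, config$polarity)
  villi <- remove_islands(villi, config$villous_min_area,
                          config$villous_hole_cap, config$connectivity)
  morph <- morph_capillaries(gray, villi, config$cap_iterations,
                             config$cap_resid_threshold, config$cap_min_area)
  blood <- blood_capillary_mask(img, villi,
                                b_threshold = config$b_threshold,
                                density_threshold = config$density_threshold,
                                min_area = config$cap_min_area)
  clab <- combine_capillaries(morph, blood, villi, config$connectivity,
                              config$cap_min_area)
  cap_mask <- matrix(as.integer(clab$labels > 0L), nrow(villi), ncol(villi))
  list(gray = gray, equalized = equalized, villi_mask = villi,
       capillary_mask = cap_mask,
       villi = label_regions(villi, config$connectivity),
       capillaries = clab, threshold = t)
}

#' Run the full analysis pipeline
#'
#' Produces the per-subject feature table (synthetic draw or image
#' segmentation according to the config), then the shared statistics
#' battery: group-comparison t-test table, single-feature accuracy ranking,
#' hierarchical clustering and PCA on the top-ranked features. All outputs
#' are written under `output_dir` as CSV/JSON/Newick, with the seed and a
#' hash of the config embedded in the JSON report.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for the report bundle (created).
#' @return invisibly, a list with `cohort`, `comparison`, `ranking`,
#'   `top_features`, `hca`, `pca`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = tempfile("vmrun")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (config$mode == "synthetic") {
    gp <- default_group_params(config$preset)
    generate_cohort_features(gp$pe, gp$ctrl, config$seed)
  } else {
    cohort_from_manifest(config, output_dir)
  }
  if (any(table(cohort$group) < 3L))
    stop("statistics stage needs >= 3 subjects per group; got ",
         paste(table(cohort$group), collapse = " vs "))

  comparison <- group_comparison(cohort)
  ranking <- rank_features(cohort, scheme = config$accuracy_scheme)
  top <- ranking$feature[seq_len(min(config$n_top_features, nrow(ranking)))]
  cl <- hca(cohort, top, linkage = config$linkage)
  pc <- pca_features(cohort, top)
  truth <- as.integer(factor(cohort$group, levels = unique(cohort$group)))

  report <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    mode = config$mode,
    n_subjects = nrow(cohort),
    group_sizes = as.list(table(cohort$group)),
    top_features = top,
    ranking = ranking,
    pca_explained = pc$explained,
    pca_cumulative = pc$cumulative,
    hca_rand_index = rand_index(cl$clusters, truth))

  utils::write.csv(cohort, file.path(output_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(comparison, file.path(output_dir, "group_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(ranking, file.path(output_dir, "ranking.csv"),
                   row.names = FALSE)
  utils::write.csv(cl$merges, file.path(output_dir, "hca_merges.csv"),
                   row.names = FALSE)
  writeLines(cl$newick, file.path(output_dir, "dendrogram.nwk"))
  utils::write.csv(data.frame(component = seq_along(pc$explained),
                              explained_pct = pc$explained,
                              cumulative_pct = pc$cumulative),
                   file.path(output_dir, "pca_variance.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(pc$loadings, row.names = top),
                   file.path(output_dir, "pca_loadings.csv"))
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, comparison = comparison, ranking = ranking,
                 top_features = top, hca = cl, pca = pc, report = report))
}

#' Run the gestational-age-matched subgroup analysis
#'
#' The same battery as [run_pipeline()] on the matched-subgroup preset
#' (n = 10 vs 8), checking whether group differences persist when
#' gestational age is held at 35-36 weeks.
#'
#' @param config base [pipeline_config()] (mode is forced to synthetic with
#'   the gestation-matched preset).
#' @param output_dir report directory.
#' @return as [run_pipeline()].
#' @export
run_subgroup <- function(config = pipeline_config(), output_dir = tempfile("vmsub")) {
  config$mode <- "synthetic"
  config$preset <- "gestation-matched"
  run_pipeline(config, output_dir)
}

# images mode: segment every manifest image, aggregate per subject
cohort_from_manifest <- function(config, output_dir) {
  man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
  need <- c("subject", "group", "image_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  missing <- man$image_path[!file.exists(man$image_path)]
  if (length(missing))
    stop("unreadable image path(s): ", paste(missing, collapse = ", "))
  subjects <- unique(man$subject)
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    sub <- man[man$subject == subjects[i], ]
    vlabs <- list(); clabs <- list()
    for (j in seq_len(nrow(sub))) {
      img <- read_image_rgb(sub$image_path[j])
      seg <- segment_image(img, config)
      vlabs[[j]] <- seg$villi; clabs[[j]] <- seg$capillaries
      if (config$debug_images) {
        qcdir <- file.path(output_dir, "qc")
        dir.create(qcdir, showWarnings = FALSE, recursive = TRUE)
        base <- sprintf("%s_%02d", subjects[i], j)
        png::writePNG(seg$gray / 255, file.path(qcdir, paste0(base, "_gray.png")))
        write_mask_png(seg$villi_mask,
                       file.path(qcdir, paste0(base, "_villi.png")))
        write_image_png(overlay_qc(img, seg$villi_mask, seg$capillary_mask),
                        file.path(qcdir, paste0(base, "_overlay.png")))
      }
    }
    fv <- subject_features(vlabs, clabs, config$pixel_size)
    rows[[i]] <- cbind(data.frame(subject = subjects[i],
                                  group = sub$group[1]), fv)
  }
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = unique(out$group))
  out
}
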