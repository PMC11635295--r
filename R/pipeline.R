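#' Pipeline configuration
#'
#' Collects every decision knob of the end-to-end analysis with the
#' package defaults: 0.01-0.1 Hz third-order zero-phase band-pass, one PCA
#' component removed, the three-rule QC thresholds, 5-min stable segment,
#' the 0.05-0.80 sparsity grid, the predefined feature sets and
#' KNN(k=3)/LDA with 20 averaged repetitions.
#'
#' @param optics An [optical_model()].
#' @param band Band-pass edges in Hz.
#' @param filter_order Butterworth order.
#' @param pca_components Leading components removed by
#'   [pca_motion_correct()].
#' @param qc List of QC thresholds (`snr_min`, `cardiac_ratio_min`,
#'   `peak_factor`).
#' @param segment_length Stable-segment length in seconds.
#' @param grid Sparsity grid.
#' @param feature_sets Named feature-set list for classification.
#' @param k,n_repeats,positive Classifier settings.
#' @param fc_threshold Suprathreshold-edge cutoff for graph export.
#' @param seed Seed recorded with the run.
#' @return A `pipeline_config` list, fully JSON-serializable.
#' @export
pipeline_config <- function(optics = optical_model(),
                            band = c(0.01, 0.1), filter_order = 3,
                            pca_components = 1L,
                            qc = list(snr_min = 2, cardiac_ratio_min = 0.05,
                                      peak_factor = 5),
                            segment_length = 300,
                            grid = sparsity_grid(),
                            feature_sets = default_feature_sets(),
                            k = 3L, n_repeats = 20L, positive = "MCS",
                            fc_threshold = 0.35, seed = 1L) {
  structure(list(optics = optics, band = band, filter_order = filter_order,
                 pca_components = pca_components, qc = qc,
                 segment_length = segment_length, grid = grid,
                 feature_sets = feature_sets, k = k, n_repeats = n_repeats,
                 positive = positive, fc_threshold = fc_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$optics <- list(wavelengths = config$optics$wavelengths,
                     extinction = config$optics$extinction,
                     dpf = config$optics$dpf,
                     separation = config$optics$separation)
  cfg
}

#' Write a synthetic cohort to disk
#'
#' One CSV per subject (rows = channel x wavelength series named
#' `ch<i>_wl<nm>`, columns = samples), a YAML montage, a JSON ground-truth
#' sidecar and the generating configuration.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- cohort$recordings
  truth <- cohort$truth
  for (si in seq_along(recs)) {
    raw <- recs[[si]]
    nch <- dim(raw$intensity)[1]
    rows <- do.call(rbind, lapply(seq_len(nch), function(ch)
      rbind(raw$intensity[ch, 1, ], raw$intensity[ch, 2, ])))
    series <- as.vector(t(outer(seq_len(nch), raw$wavelengths,
                                function(ch, wl) sprintf("ch%d_wl%g", ch, wl))))
    dt <- data.table::data.table(series = series)
    dt <- cbind(dt, data.table::as.data.table(rows))
    data.table::fwrite(dt, file.path(dir, sprintf("sub%02d.csv", si)))
  }
  write_montage(recs[[1]]$montage, file.path(dir, "montage.yaml"))
  jsonlite::write_json(
    list(labels = truth$labels,
         density = truth$density,
         coupling_eff = truth$coupling_eff,
         latent_adjacency = lapply(truth$latent_adjacency, unname),
         planted_bad_channels = truth$planted_bad_channels,
         injected_spikes = truth$injected_spikes,
         fs = recs[[1]]$fs,
         wavelengths = recs[[1]]$wavelengths,
         config = unclass(truth$config)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `recordings` (list of `raw_recording`) and `labels`.
#' @export
read_cohort <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  montage <- read_montage(file.path(dir, "montage.yaml"))
  files <- sort(list.files(dir, pattern = "^sub[0-9]+\\.csv$",
                           full.names = TRUE))
  recordings <- lapply(seq_along(files), function(si) {
    dt <- data.table::fread(files[si])
    mat <- as.matrix(dt[, -1])
    nch <- nrow(mat) / 2L
    intensity <- array(NA_real_, c(nch, 2L, ncol(mat)))
    intensity[, 1, ] <- mat[seq(1L, nrow(mat), by = 2L), ]
    intensity[, 2, ] <- mat[seq(2L, nrow(mat), by = 2L), ]
    raw_recording(intensity, fs = gt$fs, montage = montage,
                  wavelengths = gt$wavelengths,
                  subject = sub("\\.csv$", "", basename(files[si])))
  })
  list(recordings = recordings, labels = gt$labels)
}

#' Simulate a cohort and write it to disk
#'
#' Thin wrapper over [generate_cohort()] + [write_cohort()].
#'
#' @param config A [synth_config()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
simulate_cohort_files <- function(config = synth_config(), dir) {
  write_cohort(generate_cohort(config), dir)
}

#' Per-subject feature extraction
#'
#' Runs the preprocessing chain (MBLL conversion, QC on the unfiltered
#' series, band-pass, PCA correction, stable-segment selection), then
#' computes the masked connectivity matrix, region means and network
#' metric AUCs for one subject.
#'
#' @param raw A `raw_recording`.
#' @param config A [pipeline_config()].
#' @param metrics Network metrics to compute.
#' @return List with `qc`, `fc`, `roi`, `metrics`.
#' @export
process_subject <- function(raw, config = pipeline_config(),
                            metrics = c("Lp", "Cp", "Eg", "Eloc")) {
  hemo0 <- mbll_convert(raw, config$optics)
  qc <- prune_channels(raw, hemo0, snr_min = config$qc$snr_min,
                       cardiac_ratio_min = config$qc$cardiac_ratio_min,
                       peak_factor = config$qc$peak_factor)
  if (all(qc$bad))
    stop("all channels failed quality control for subject ", raw$subject)
  hemo <- bandpass(hemo0, config$band[1], config$band[2],
                   order = config$filter_order)
  if (config$pca_components > 0L)
    hemo <- pca_motion_correct(hemo, config$pca_components)
  seg <- select_stable_segment(hemo, config$segment_length)
  fc <- fc_matrix(seg, qc)
  list(qc = qc, fc = fc,
       roi = roi_mean(fc, raw$montage),
       metrics = network_metrics(fc, config$grid, metrics = metrics))
}

#' Run the full group analysis pipeline
#'
#' Executes the resting-state analysis end to end on a cohort: per-subject
#' preprocessing, quality control, connectivity and network metrics; then
#' group-mean connectivity, the ten groupwise feature comparisons (six
#' region means + four network AUCs) and the feature-set x classifier
#' LOOCV table.  Subjects whose channels all fail QC are excluded with a
#' warning.
#'
#' @param recordings List of `raw_recording`s, or a cohort directory
#'   written by [write_cohort()].
#' @param labels Group label per subject (taken from the cohort ground
#'   truth when a directory is given).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, all tables are written
#'   as CSV/JSON alongside the effective configuration.
#' @return A `pipeline_result` list: `subjects` (per-subject results),
#'   `labels`, `roi_table`, `auc_table`, `mean_fc` (per subject),
#'   `group_fc` (per group), `edges` (suprathreshold edge lists),
#'   `comparisons`, `classification`, `config`.
#' @export
run_pipeline <- function(recordings, labels = NULL,
                         config = pipeline_config(), output_dir = NULL) {
  if (is.character(recordings)) {
    cohort <- read_cohort(recordings)
    if (is.null(labels)) labels <- cohort$labels
    recordings <- cohort$recordings
  }
  stopifnot(length(labels) == length(recordings))
  subjects <- vector("list", length(recordings))
  kept <- logical(length(recordings))
  for (si in seq_along(recordings)) {
    res <- tryCatch(process_subject(recordings[[si]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("subject ", si, " excluded: ", conditionMessage(res))
      next
    }
    subjects[[si]] <- res
    kept[si] <- TRUE
  }
  if (!any(kept)) stop("no subject survived preprocessing")
  labels <- labels[kept]
  subjects <- subjects[kept]

  roi_table <- as.data.frame(do.call(rbind, lapply(subjects, function(s)
    stats::setNames(s$roi$mean_r, s$roi$region))))
  auc_table <- as.data.frame(do.call(rbind, lapply(subjects, function(s)
    s$metrics$auc)))
  features <- cbind(roi_table, auc_table)

  lv <- unique(c(config$positive, sort(unique(labels))))
  lv <- lv[lv %in% labels]
  comparisons <- compare_all(features, factor(labels, levels = lv))

  classification <- classification_table(auc_table, roi_table, labels,
                                         feature_sets = config$feature_sets,
                                         k = config$k,
                                         n_repeats = config$n_repeats,
                                         positive = config$positive,
                                         skip_incomplete = TRUE)

  fcs <- lapply(subjects, `[[`, "fc")
  group_fc <- lapply(split(fcs, labels), group_mean_fc)
  edges <- lapply(group_fc, suprathreshold_edges,
                  threshold = config$fc_threshold)
  result <- structure(list(
    subjects = subjects, labels = labels,
    montage = recordings[which(kept)[1]][[1]]$montage,
    roi_table = roi_table, auc_table = auc_table,
    mean_fc = vapply(fcs, mean_fc_strength, numeric(1)),
    group_fc = group_fc, edges = edges,
    distribution = fc_distribution(fcs, groups = labels),
    comparisons = comparisons, classification = classification,
    config = config), class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_result(result, output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("rs-fNIRS pipeline result:", length(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
            collapse = ", "), ")\n")
  cat("\nGroup comparisons:\n")
  print(x$comparisons)
  cat("\nClassification (LOOCV):\n")
  print(x$classification, digits = 3)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' One sub-directory per stage with tidy CSV tables plus a JSON metadata
#' file recording the effective value of every decision knob.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("qc", "fc", "network"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  for (si in seq_along(result$subjects)) {
    s <- result$subjects[[si]]
    tag <- sprintf("sub%02d", si)
    write_qc_report(s$qc, file.path(dir, "qc", paste0(tag, ".csv")))
    utils::write.csv(unclass(s$fc), file.path(dir, "fc", paste0(tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(s$metrics$curves,
                     file.path(dir, "network", paste0(tag, "_curves.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(cbind(subject = seq_len(nrow(result$roi_table)),
                         label = result$labels, result$roi_table,
                         result$auc_table),
                   file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$comparisons),
                   file.path(dir, "group_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(result$classification,
                   file.path(dir, "classification.csv"), row.names = FALSE)
  for (g in names(result$group_fc)) {
    utils::write.csv(unclass(result$group_fc[[g]]),
                     file.path(dir, paste0("group_fc_", g, ".csv")),
                     row.names = FALSE)
    write_node_edge(result$group_fc[[g]], result$montage,
                    file.path(dir, paste0("network_", g)),
                    threshold = result$config$fc_threshold)
  }
  jsonlite::write_json(list(config = serialize_config(result$config),
                            n_subjects = length(result$subjects),
                            labels = result$labels,
                            auc_rule = "trapezoid"),
                       file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
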