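#' Default run configuration
#'
#' The resolved configuration of a pipeline run: input source (synthetic
#' generator by default, or matrix + manifest CSVs), preprocessing
#' parameters, band definitions, PCA/LDA settings, output directory and
#' seed. A run writes its resolved configuration verbatim into the
#' output directory so every numeric table is regenerable from
#' config + seed.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1234L,
    output_dir = "pelletspec_run",
    input = list(source = "generate",
                 matrix_csv = NULL, manifest_csv = NULL),
    instrument = "lab",
    design = list(n_producers = 8L, pellets_per_producer = 5L,
                  spots_per_pellet = 10L,
                  producer_licel_weights = c(1.5, 1.5, 1.5, 1, 1, 1, 1, 1),
                  sigma_pellet = 0.05, sigma_spot = 0.08,
                  sigma_scale = 0.20, sigma_res = 0.10,
                  sigma_partition = c(0.06, 0.04),
                  baseline_amplitude_range = c(0.5, 1.5),
                  noise_sd = 0.02, axis_step = 1),
    preprocess = list(sg_order = 2L, sg_frame = 7L,
                      rc_radius_cm1 = 800, rc_passes = 10L,
                      crop = c(800, 1800)),
    bands = list(lignin_area = c(1250, 1700),
                 cellulose_area = c(980, 1150),
                 lignin_peak = 1600, cellulose_peak = 1096,
                 peak_halfwindow = 10),
    pca = list(range_cm1 = c(800, 1800), n_components_kept = 10L),
    lda = list(n_display = 2L),
    write_figures = TRUE), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Keys absent from the file keep their [default_run_config()] values;
#' the merged configuration is validated before any computation.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
    class(cfg) <- "run_config"
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A run configuration list.
#' @export
validate_run_config <- function(cfg) {
  need_bands <- c("lignin_area", "cellulose_area", "lignin_peak",
                  "cellulose_peak", "peak_halfwindow")
  miss <- setdiff(need_bands, names(cfg$bands))
  if (length(miss))
    stop("config error: missing band key(s): ",
         paste(miss, collapse = ", "))
  if (!cfg$input$source %in% c("generate", "files"))
    stop("config error: input.source must be 'generate' or 'files'")
  if (cfg$input$source == "files" &&
      (is.null(cfg$input$matrix_csv) || is.null(cfg$input$manifest_csv)))
    stop("config error: input.source 'files' needs matrix_csv and ",
         "manifest_csv")
  if (!cfg$instrument %in% c("lab", "handheld"))
    stop("config error: instrument must be 'lab' or 'handheld'")
  # constructors validate the numeric parameter blocks
  do.call(preprocess_params,
          list(sg_order = cfg$preprocess$sg_order,
               sg_frame = cfg$preprocess$sg_frame,
               rc_radius = cfg$preprocess$rc_radius_cm1,
               rc_passes = cfg$preprocess$rc_passes,
               crop = cfg$preprocess$crop))
  do.call(default_bands, cfg$bands)
  invisible(cfg)
}

config_design <- function(cfg) {
  d <- cfg$design
  ensemble_design(n_producers = d$n_producers,
                  pellets_per_producer = d$pellets_per_producer,
                  spots_per_pellet = d$spots_per_pellet,
                  producer_licel_weights = d$producer_licel_weights,
                  sigma_pellet = d$sigma_pellet,
                  sigma_spot = d$sigma_spot,
                  sigma_scale = d$sigma_scale, sigma_res = d$sigma_res,
                  sigma_partition = d$sigma_partition,
                  baseline_amplitude_range = d$baseline_amplitude_range,
                  noise_sd = d$noise_sd,
                  axis = default_axis(d$axis_step),
                  seed = cfg$seed)
}

stage_log <- function(stage, ...) {
  message(sprintf("[pelletspec] %-12s %s", stage,
                  paste0(..., collapse = "")))
}

#' Run the full analysis pipeline
#'
#' Executes ingest/generate -> resample -> smooth -> baseline -> crop ->
#' quantify -> PCA -> LDA -> report. Every stage's output is written to
#' the output directory as CSV (plus vector-graphic figures emulating
#' the producer band-area / Li/Ce-ratio panels and the PCA/LDA score
#' plots), and the resolved configuration is stored alongside, so a run
#' is reproducible from config + seed alone.
#'
#' @param config A `run_config` from [default_run_config()] /
#'   [read_run_config()].
#' @return Invisibly, a list of class `run_report`: `set` (preprocessed
#'   ensemble), `spots` (per-spot ratio table), `pellet_summary`,
#'   `producer_summary`, `pca`, `ellipses`, `lda`, `truth` (when
#'   generated), `output_dir`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  cfg <- validate_run_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(out, "run_config.yaml"))

  truth <- NULL
  if (cfg$input$source == "generate") {
    design <- config_design(cfg)
    ens <- generate_ensemble(design, instrument_profile(cfg$instrument))
    raw <- ens$set; truth <- ens$truth
    stage_log("generate", nrow(raw$intensity), " spectra, seed ",
              cfg$seed, ", ", cfg$instrument, " profile")
    utils::write.csv(truth, file.path(out, "truth.csv"),
                     row.names = FALSE)
  } else {
    raw <- read_spectrum_set(cfg$input$matrix_csv,
                             cfg$input$manifest_csv)
    stage_log("ingest", nrow(raw$intensity), " spectra from ",
              cfg$input$matrix_csv)
  }
  write_spectrum_set(raw, file.path(out, "spectra_raw.csv"),
                     file.path(out, "manifest.csv"))

  pp <- preprocess_params(sg_order = cfg$preprocess$sg_order,
                          sg_frame = cfg$preprocess$sg_frame,
                          rc_radius = cfg$preprocess$rc_radius_cm1,
                          rc_passes = cfg$preprocess$rc_passes,
                          crop = cfg$preprocess$crop)
  proc <- preprocess_spectra(raw, pp)
  stage_log("preprocess", "SG(", pp$sg_order, ",", pp$sg_frame,
            ") + rolling-circle(r=", pp$rc_radius, ", passes=",
            pp$rc_passes, ") + crop[", pp$crop[1], ",", pp$crop[2], "]")
  write_spectrum_set(proc, file.path(out, "spectra_preprocessed.csv"),
                     file.path(out, "manifest.csv"))

  bands <- do.call(default_bands, cfg$bands)
  spots <- quantify_spots(proc, bands)
  pellet_summary <- summarize_groups(spots, "pellet")
  producer_summary <- summarize_groups(spots, "producer")
  stage_log("quantify", nrow(spots), " spots, ",
            length(unique(spots$producer_id)), " producers")
  utils::write.csv(spots, file.path(out, "ratios_per_spot.csv"),
                   row.names = FALSE)
  utils::write.csv(pellet_summary, file.path(out, "summary_pellet.csv"),
                   row.names = FALSE)
  utils::write.csv(producer_summary,
                   file.path(out, "summary_producer.csv"),
                   row.names = FALSE)

  pca <- fit_uncentered_pca(proc, range = cfg$pca$range_cm1,
                            n_components = cfg$pca$n_components_kept)
  stage_log("pca", "PC1+PC2 capture ",
            sprintf("%.2f%%", 100 * sum(pca$variance_fraction[1:2])),
            " of total uncentered variance")
  utils::write.csv(summary(pca), file.path(out, "pca_variance.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(pca$manifest, pca$scores, check.names = FALSE),
    file.path(out, "pca_scores.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(wavenumber = pca$wavenumber, t(pca$loadings),
               check.names = FALSE),
    file.path(out, "pca_loadings.csv"), row.names = FALSE)

  ellipses <- lapply(split(seq_len(nrow(pca$scores)),
                           pca$manifest$producer_id),
                     function(i)
                       mahalanobis_ellipse(pca$scores[i, 1:2,
                                                      drop = FALSE]))
  etab <- do.call(rbind, lapply(names(ellipses), function(g) {
    e <- ellipses[[g]]
    data.frame(group_id = g, center_1 = e$center[1],
               center_2 = e$center[2], semi_axis_1 = e$semi_axes[1],
               semi_axis_2 = e$semi_axes[2], angle_rad = e$angle)
  }))
  utils::write.csv(etab, file.path(out, "pca_ellipses.csv"),
                   row.names = FALSE)

  n_lda <- min(10L, ncol(pca$scores))
  lda <- fit_lda(pca$scores[, seq_len(n_lda), drop = FALSE],
                 pca$manifest$producer_id)
  stage_log("lda", length(lda$class_labels), " classes on first ",
            n_lda, " PC scores")
  utils::write.csv(
    data.frame(pca$manifest,
               lda$scores[, seq_len(min(cfg$lda$n_display,
                                        ncol(lda$scores))),
                          drop = FALSE], check.names = FALSE),
    file.path(out, "lda_scores.csv"), row.names = FALSE)

  if (isTRUE(cfg$write_figures)) {
    report_figures(out, spots, producer_summary, pca, lda)
    stage_log("report", "figures written to ", out)
  }

  invisible(structure(list(set = proc, spots = spots,
                           pellet_summary = pellet_summary,
                           producer_summary = producer_summary,
                           pca = pca, ellipses = ellipses, lda = lda,
                           truth = truth, config = cfg,
                           output_dir = out),
                      class = "run_report"))
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (", x$output_dir, ")\n", sep = "")
  cat("  spectra:", nrow(x$set$intensity),
      "| producers:", length(unique(x$spots$producer_id)), "\n")
  pr <- x$producer_summary
  r <- pr[pr$statistic == "licel_area_ratio", ]
  cat("  producer Li/Ce (area):",
      paste(sprintf("%s %.2f", r$group_id, r$mean), collapse = ", "),
      "\n")
  cat("  PC1+PC2 variance:",
      sprintf("%.2f%%", 100 * sum(x$pca$variance_fraction[1:2])), "\n")
  invisible(x)
}

report_figures <- function(out, spots, producer_summary, pca, lda) {
  prod <- sort(unique(spots$producer_id))
  grDevices::pdf(file.path(out, "figures.pdf"), width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)

  # producer band areas (mean +/- 1 sd error bars)
  for (stat in c("lignin_area", "cellulose_area")) {
    s <- producer_summary[producer_summary$statistic == stat, ]
    m <- match(prod, s$group_id)
    graphics::plot(seq_along(prod), s$mean[m], pch = 19,
                   ylim = range(c(s$mean[m] - s$sd[m],
                                  s$mean[m] + s$sd[m])),
                   xaxt = "n", xlab = "Producer",
                   ylab = expression(paste("Band area (counts %.% ",
                                           cm^-1, ")")),
                   main = gsub("_", " ", stat))
    graphics::axis(1, seq_along(prod), prod)
    graphics::arrows(seq_along(prod), s$mean[m] - s$sd[m],
                     seq_along(prod), s$mean[m] + s$sd[m],
                     angle = 90, code = 3, length = 0.04)
  }
  # area-ratio vs height-ratio comparison
  a <- producer_summary[producer_summary$statistic ==
                          "licel_area_ratio", ]
  h <- producer_summary[producer_summary$statistic ==
                          "licel_height_ratio", ]
  ma <- match(prod, a$group_id); mh <- match(prod, h$group_id)
  ylim <- range(c(a$mean[ma] - a$sd[ma], a$mean[ma] + a$sd[ma],
                  h$mean[mh] - h$sd[mh], h$mean[mh] + h$sd[mh]))
  graphics::plot(seq_along(prod), a$mean[ma], pch = 19, col = "darkgreen",
                 ylim = ylim, xaxt = "n", xlab = "Producer",
                 ylab = "Li/Ce ratio",
                 main = "Li/Ce: integrated areas vs peak heights")
  graphics::axis(1, seq_along(prod), prod)
  graphics::arrows(seq_along(prod), a$mean[ma] - a$sd[ma],
                   seq_along(prod), a$mean[ma] + a$sd[ma],
                   angle = 90, code = 3, length = 0.04,
                   col = "darkgreen")
  graphics::points(seq_along(prod) + 0.15, h$mean[mh], pch = 17)
  graphics::arrows(seq_along(prod) + 0.15, h$mean[mh] - h$sd[mh],
                   seq_along(prod) + 0.15, h$mean[mh] + h$sd[mh],
                   angle = 90, code = 3, length = 0.04)
  graphics::legend("topright", c("area ratio", "height ratio"),
                   pch = c(19, 17), col = c("darkgreen", "black"),
                   bty = "n")
  # PCA loadings and scores, LDA projection
  plot(pca, which = "loadings", components = 1:min(3, nrow(pca$loadings)),
       main = "Uncentered PCA loadings")
  plot(pca, which = "scores", main = "Uncentered PCA scores")
  cols <- grDevices::hcl.colors(length(lda$class_labels), "Dark 2")
  g <- factor(lda$labels, levels = lda$class_labels)
  graphics::plot(lda$scores[, 1], lda$scores[, 2], col = cols[g],
                 pch = as.integer(g) %% 25, xlab = "LD1", ylab = "LD2",
                 main = "LDA of first PC scores")
  invisible(NULL)
}

#' Compare lab and handheld instrument profiles
#'
#' Runs the generator + pipeline twice on the same design and seed,
#' once per instrument profile, and pairs the producer-mean Li/Ce area
#' ratios. Because the seed is shared, the two runs differ only through
#' the profile (resolution broadening and noise level).
#'
#' @param config A `run_config` (generator input required).
#' @return A data.frame with one row per producer: `producer_id`,
#'   `lab_mean`, `handheld_mean`, `rel_diff` (handheld/lab - 1).
#' @export
compare_instruments <- function(config = default_run_config()) {
  cfg <- validate_run_config(config)
  if (cfg$input$source != "generate")
    stop("instrument comparison needs generator-based input")
  res <- lapply(c("lab", "handheld"), function(kind) {
    c2 <- cfg
    c2$instrument <- kind
    c2$write_figures <- FALSE
    c2$output_dir <- file.path(cfg$output_dir,
                               paste0("instrument_", kind))
    rep <- run_pipeline(c2)
    s <- rep$producer_summary
    s <- s[s$statistic == "licel_area_ratio", ]
    stats::setNames(s$mean, s$group_id)
  })
  prod <- names(res[[1]])
  out <- data.frame(producer_id = prod, lab_mean = as.numeric(res[[1]]),
                    handheld_mean = as.numeric(res[[2]][prod]))
  out$rel_diff <- out$handheld_mean / out$lab_mean - 1
  utils::write.csv(out, file.path(cfg$output_dir,
                                  "instrument_comparison.csv"),
                   row.names = FALSE)
  out
}
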