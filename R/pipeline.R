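#' Pipeline run configuration
#'
#' Assembles the per-stage parameter blocks of an end-to-end run with the
#' package defaults. Every random choice in the run (phantom synthesis, pixel
#' sampling, train/test split, undersampling, cross-validation folds) flows
#' from the single `seed`, so a completed run is reproducible bit-identically
#' from its stored config.
#'
#' @param seed Run seed.
#' @param n_tumors Number of phantom specimens generated and pooled
#'   (mirrors a multi-specimen study design).
#' @param phantom List of [phantom_config()] overrides applied to every
#'   tumor (each tumor gets its own derived seed).
#' @param preprocess List: `denoise_method`, `denoise_strength`,
#'   `bias_correction`, `target_spacing`.
#' @param texture List: `levels`, `radius`, `mode`, `distance`.
#' @param stroma List: `radius`.
#' @param classify List: `sample_frac`, `train_frac`, `folds`, `threshold`,
#'   `with_si`, `kernel`, `C`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_tumors = 4L, phantom = list(),
                       preprocess = list(), texture = list(),
                       stroma = list(), classify = list()) {
  cfg <- list(
    seed = as.integer(seed),
    n_tumors = as.integer(n_tumors),
    phantom = phantom,
    preprocess = utils::modifyList(
      list(denoise_method = "gaussian", denoise_strength = 0.5,
           bias_correction = TRUE, target_spacing = NULL), preprocess),
    texture = utils::modifyList(
      list(levels = 64L, radius = 3L, mode = "2d-4dir", distance = 1L),
      texture),
    stroma = utils::modifyList(list(radius = 3), stroma),
    classify = utils::modifyList(
      list(sample_frac = 0.30, train_frac = 0.50, folds = 20L,
           threshold = 50, with_si = FALSE, kernel = "rbf", C = 1), classify))
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(config) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  for (block in c("seed", "n_tumors", "phantom", "preprocess", "texture",
                  "stroma", "classify"))
    if (is.null(config[[block]]))
      stop("config is missing required block: ", block)
  invisible(TRUE)
}

# grayscale / color PNG renderings (visual artifacts only, never re-read)
write_map_png <- function(map, path, colors = NULL) {
  m <- if (length(dim(map)) == 3L) map[, , 1L] else map
  if (is.null(colors)) {
    rng <- range(m, na.rm = TRUE)
    g <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    g[is.na(g)] <- 0
    png::writePNG(t(g), path)
  } else {
    img <- array(0, dim = c(dim(m), 3L))
    for (code in names(colors)) {
      sel <- !is.na(m) & m == as.integer(code)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[sel] <- colors[[code]][ch]
        img[, , ch] <- pl
      }
    }
    png::writePNG(aperm(img, c(2, 1, 3)), path)
  }
  invisible(path)
}

#' Run the full phantom-to-classification pipeline
#'
#' Executes every stage in order — phantom synthesis, preprocessing, texture
#' mapping, stromal-proportion mapping, binned association, and stroma
#' classification — writing all intermediate artifacts under `out_dir` and
#' returning (and saving) a manifest of stage outputs, seeds and headline
#' numbers. Rerunning with the same config reproduces the numeric outputs
#' bit-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_pixel_table Also write the pooled pixel feature table CSV
#'   (can be large).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run_"),
                         write_pixel_table = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  outputs <- character()
  emit <- function(stage, files) {
    manifest$stages[[stage]] <<- c(manifest$stages[[stage]], files)
    outputs <<- c(outputs, files)
  }

  tumors <- vector("list", config$n_tumors)
  for (t in seq_len(config$n_tumors)) {
    pcfg <- do.call(phantom_config,
                    utils::modifyList(config$phantom,
                                      list(seed = (config$seed %% 1000000L) * 1000L + t)))
    ph <- generate_phantom(pcfg)
    ip <- file.path(out_dir, sprintf("tumor%02d_image.nii", t))
    lp <- file.path(out_dir, sprintf("tumor%02d_labels.nii", t))
    write_image(ph$image, ip)
    write_labels(ph$labels, lp)
    emit("phantom", c(ip, mask_path(ip), lp, sub("\\.nii$", ".labels.json", lp)))

    pp <- preprocess(ph$image,
                     denoise_method = config$preprocess$denoise_method,
                     denoise_strength = config$preprocess$denoise_strength,
                     bias_correction = config$preprocess$bias_correction,
                     target_spacing = config$preprocess$target_spacing)
    cp <- file.path(out_dir, sprintf("tumor%02d_preprocessed.nii", t))
    write_image(pp$volume, cp)
    sp <- file.path(out_dir, sprintf("tumor%02d_preprocess_stages.csv", t))
    utils::write.csv(pp$stages, sp, row.names = FALSE)
    emit("preprocess", c(cp, mask_path(cp), sp))

    q <- quantize(pp$volume, G = config$texture$levels)
    stack <- texture_map(q, radius = config$texture$radius,
                         mode = config$texture$mode,
                         distance = config$texture$distance,
                         si = pp$volume)
    tfiles <- character()
    for (fn in names(stack$maps)) {
      fp <- file.path(out_dir, sprintf("tumor%02d_%s.nii", t, fn))
      m <- stack$maps[[fn]]
      m[is.na(m)] <- 0
      write_nifti(m, stack$spacing, fp, "float32")
      tfiles <- c(tfiles, fp)
    }
    emit("texture", tfiles)

    rl <- resample_labels(ph$labels, dim(pp$volume$data), pp$volume$spacing)
    prop <- stromal_proportion(rl, radius = config$stroma$radius)
    prp <- file.path(out_dir, sprintf("tumor%02d_stromal_proportion.nii", t))
    pm <- prop$proportion; pm[is.na(pm)] <- -1
    write_nifti(pm, prop$spacing, prp, "float32")
    write_map_png(prop$proportion,
                  file.path(out_dir, sprintf("tumor%02d_stromal_proportion.png", t)))
    emit("stromamap", c(prp, file.path(out_dir, sprintf("tumor%02d_stromal_proportion.png", t))))

    tumors[[t]] <- list(stack = stack, prop = prop,
                        table = pixel_feature_table(stack, prop, tumor_id = t,
                                                    threshold = config$classify$threshold))
  }

  pooled <- do.call(rbind, lapply(tumors, `[[`, "table"))
  if (write_pixel_table) {
    ptp <- file.path(out_dir, "pixel_table.csv")
    utils::write.csv(pooled, ptp, row.names = FALSE)
    emit("associate", ptp)
  }
  assoc <- association_report(table = pooled)
  ap <- file.path(out_dir, "association_report.csv")
  utils::write.csv(assoc$report, ap, row.names = FALSE)
  bp <- file.path(out_dir, "association_bins.csv")
  utils::write.csv(data.frame(center = assoc$bins$centers,
                              count = assoc$bins$counts, assoc$bins$means,
                              check.names = FALSE),
                   bp, row.names = FALSE)
  emit("associate", c(ap, bp))

  split <- sample_and_split(pooled, sample_frac = config$classify$sample_frac,
                            train_frac = config$classify$train_frac,
                            seed = config$seed)
  model <- train_svm(split$train, folds = config$classify$folds,
                     seed = config$seed, with_si = config$classify$with_si,
                     kernel = config$classify$kernel, C = config$classify$C)
  held <- evaluate(model, split$test)
  metrics <- data.frame(subject = "test set", n = held$n_test,
                        t(held$rates), check.names = FALSE)
  cfiles <- character()
  for (t in seq_len(config$n_tumors)) {
    pmres <- predict_map(model, tumors[[t]]$stack, tumors[[t]]$prop,
                         threshold = config$classify$threshold)
    pnii <- file.path(out_dir, sprintf("tumor%02d_predicted.nii", t))
    enii <- file.path(out_dir, sprintf("tumor%02d_evaluation.nii", t))
    pv <- pmres$predicted; pv[is.na(pv)] <- 255L
    ev <- pmres$evaluation; ev[is.na(ev)] <- 255L
    write_nifti(pv, tumors[[t]]$stack$spacing, pnii, "uint8")
    write_nifti(ev, tumors[[t]]$stack$spacing, enii, "uint8")
    # Fig-style renderings: rich green / poor red; correct yellow / wrong blue
    ppng <- sub("\\.nii$", ".png", pnii)
    epng <- sub("\\.nii$", ".png", enii)
    write_map_png(pmres$predicted, ppng,
                  colors = list(`1` = c(0, 0.8, 0), `0` = c(0.9, 0, 0)))
    write_map_png(pmres$evaluation, epng,
                  colors = list(`1` = c(1, 1, 0), `0` = c(0, 0, 1)))
    cfiles <- c(cfiles, pnii, enii, ppng, epng)
    metrics <- rbind(metrics,
                     data.frame(subject = sprintf("tumor %d", t),
                                n = sum(!is.na(pmres$evaluation)),
                                t(pmres$rates), check.names = FALSE))
  }
  mp <- file.path(out_dir, "classification_metrics.csv")
  utils::write.csv(metrics, mp, row.names = FALSE)
  emit("classify", c(cfiles, mp))

  manifest$n_pixels <- nrow(pooled)
  manifest$cv_accuracy <- model$cv_accuracy
  manifest$test_accuracy <- unname(held$rates["accuracy"])
  manifest$association <- stats::setNames(assoc$report$r, assoc$report$feature)
  manifest$checksums <- as.list(tools::md5sum(outputs))
  names(manifest$checksums) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
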