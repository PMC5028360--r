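#' Pipeline configuration
#'
#' All knobs of the segmentation pipeline in one serializable object.
#' Defaults reproduce the reference method: blue channel, hair removal on,
#' corner removal on, bior6.8 wavelet at level 2, Otsu segmentation
#' threshold, standard morphology.
#'
#' @param channel channel selector, see [extract_channel()].
#' @param hair_removal logical: run the hair removal stage.
#' @param hair_params [dog_params()] for the directional filter bank.
#' @param hair_strategy threshold strategy for [segment_hairs()].
#' @param inpaint_iterations,inpaint_dilate inpainting settings.
#' @param median_window median smoothing window after inpainting.
#' @param corner_removal logical: detect and mask dark lens corners.
#' @param wavelet mother wavelet (default `"bior6.8"`).
#' @param level approximation level used for segmentation (default 2).
#' @param seg_threshold `"otsu"` or `"fixed:<value>"` threshold on the
#'   approximation band.
#' @param morphology [morphology_config()].
#' @param seed integer seed recorded in the config (the pipeline itself is
#'   deterministic; the seed is used by phantom/fixture helpers).
#' @param verbose log one line per stage with timing and mask areas.
#' @return object of class `"dermseg_config"`.
#' @export
dermseg_config <- function(channel = "blue",
                           hair_removal = TRUE,
                           hair_params = dog_params(),
                           hair_strategy = "contrast",
                           inpaint_iterations = 50L,
                           inpaint_dilate = 2L,
                           median_window = 3L,
                           corner_removal = TRUE,
                           wavelet = "bior6.8",
                           level = 2L,
                           seg_threshold = "otsu",
                           morphology = morphology_config(),
                           seed = 1L,
                           verbose = FALSE) {
  if (!inherits(hair_params, "dog_params")) hair_params <- do.call(dog_params, hair_params)
  if (!inherits(morphology, "morphology_config"))
    morphology <- do.call(morphology_config, morphology)
  wavelet_bank(wavelet)  # validate name
  structure(list(channel = channel, hair_removal = isTRUE(hair_removal),
                 hair_params = hair_params, hair_strategy = hair_strategy,
                 inpaint_iterations = as.integer(inpaint_iterations),
                 inpaint_dilate = as.integer(inpaint_dilate),
                 median_window = as.integer(median_window),
                 corner_removal = isTRUE(corner_removal),
                 wavelet = wavelet, level = as.integer(level),
                 seg_threshold = seg_threshold,
                 morphology = morphology, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "dermseg_config")
}

#' Write / read a pipeline configuration as flat YAML
#'
#' Round-trips bit-identically through [dermseg_config()].
#'
#' @param cfg [dermseg_config()].
#' @param path file path.
#' @return `path` invisibly (write) / a `dermseg_config` (read).
#' @export
write_config <- function(cfg, path) {
  flat <- unclass(cfg)
  flat$hair_params <- unclass(flat$hair_params)
  flat$morphology <- unclass(flat$morphology)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  flat$hair_params <- do.call(dog_params, flat$hair_params)
  flat$morphology <- do.call(morphology_config, flat$morphology)
  do.call(dermseg_config, flat)
}

stage_log <- function(cfg, name, t0, note = "") {
  if (cfg$verbose)
    message(sprintf("[dermseg] %-14s %6.2fs  %s", name,
                    as.numeric(Sys.time()) - t0, note))
}

#' Run the full segmentation pipeline on one image
#'
#' Stages, in order: optional hair removal (on the RGB image), dark-corner
#' detection (on the luminance of the cleaned image — after hair removal so
#' dark hairs cannot bridge the lesion to a corner), channel extraction,
#' wavelet segmentation of the approximation band, morphological
#' post-processing. Deterministic: identical image and config give
#' identical results.
#'
#' @param img RGB image (see [rgb_image()], [read_image()]).
#' @param cfg [dermseg_config()].
#' @return object of class `"dermseg_result"`: list with `lesion_mask`
#'   (final), `wavelet_mask` (raw, pre-post-processing), `channel_img`,
#'   `cleaned_img` (RGB after hair removal), `hair_mask`, `corner_mask`,
#'   `no_lesion` flag, and `config` (snapshot).
#' @export
dermseg_run <- function(img, cfg = dermseg_config()) {
  img <- rgb_image(img)
  t0 <- as.numeric(Sys.time())
  if (cfg$hair_removal) {
    hr <- remove_hairs(img, p = cfg$hair_params, strategy = cfg$hair_strategy,
                       iterations = cfg$inpaint_iterations,
                       window = cfg$median_window,
                       dilate_radius = cfg$inpaint_dilate)
    cleaned <- hr$image; hmask <- hr$hair_mask
  } else {
    cleaned <- img
    hmask <- binary_mask(matrix(FALSE, dim(img)[1], dim(img)[2]))
  }
  stage_log(cfg, "hair_removal", t0, sprintf("area=%d", sum(hmask)))

  t0 <- as.numeric(Sys.time())
  cmask <- if (cfg$corner_removal) corner_mask(luminance(cleaned))
           else binary_mask(matrix(FALSE, dim(img)[1], dim(img)[2]))
  stage_log(cfg, "corners", t0, sprintf("area=%d", sum(cmask)))

  t0 <- as.numeric(Sys.time())
  chan <- extract_channel(cleaned, cfg$channel)
  stage_log(cfg, "channel", t0, cfg$channel)

  t0 <- as.numeric(Sys.time())
  raw <- tryCatch(
    segment_wavelet_cfg(chan, cmask, cfg),
    error = function(e) {
      if (grepl("no contrast", conditionMessage(e))) {
        # contrast-free field: report "no lesion" instead of crashing
        warning("dermseg_run: ", conditionMessage(e), "; no lesion found")
        binary_mask(matrix(FALSE, nrow(chan), ncol(chan)))
      } else stop("wavelet_seg stage: ", conditionMessage(e))
    })
  stage_log(cfg, "wavelet_seg", t0, sprintf("area=%d", sum(raw)))

  t0 <- as.numeric(Sys.time())
  final <- withCallingHandlers(
    postprocess_mask(raw, cmask, cfg$morphology),
    warning = function(w) {
      if (cfg$verbose) message("[dermseg] postprocess: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  stage_log(cfg, "postprocess", t0, sprintf("area=%d", sum(final)))

  structure(list(lesion_mask = final, wavelet_mask = raw,
                 channel_img = chan, cleaned_img = cleaned,
                 hair_mask = hmask, corner_mask = cmask,
                 no_lesion = !any(final), config = cfg),
            class = "dermseg_result")
}

# wavelet segmentation honoring the configured threshold strategy
segment_wavelet_cfg <- function(chan, cmask, cfg) {
  if (identical(cfg$seg_threshold, "otsu"))
    return(segment_lesion(chan, cmask, cfg$wavelet, cfg$level))
  if (grepl("^fixed:", cfg$seg_threshold)) {
    val <- as.numeric(sub("^fixed:", "", cfg$seg_threshold))
    x <- bare(chan); rng <- gray_range(chan)
    if (any(cmask)) x[cmask] <- stats::median(x[!cmask])
    pyr <- dwt2(gray_image(x, rng), cfg$wavelet, cfg$level)
    a <- approximation(pyr, cfg$level)
    # map the threshold through the low-pass DC gain, on the fixed band range
    g <- lowpass_gain(cfg$wavelet, cfg$level)
    arng <- sort(rng * g)
    a <- gray_image(pmin(pmax(bare(a), arng[1]), arng[2]), arng)
    t_a <- min(max(val * g, arng[1]), arng[2])
    small <- binarize(a, t_a, dark_foreground = TRUE)
    f <- 2^cfg$level; d <- filter_delay(cfg$wavelet)
    map <- function(pos, n) pmin(pmax(as.integer(floor((pos + d * (f - 1)) / f + 0.5)), 1L), n)
    m <- small[map(seq_len(nrow(x)), nrow(small)), map(seq_len(ncol(x)), ncol(small))]
    binary_mask(m & !cmask)
  } else stop("unknown seg_threshold: ", cfg$seg_threshold)
}

#' @export
print.dermseg_result <- function(x, ...) {
  d <- dim(x$lesion_mask)
  cat(sprintf("dermseg result (%d x %d, %s level %d, channel %s)\n",
              d[1], d[2], x$config$wavelet, x$config$level, x$config$channel))
  cat(sprintf("  lesion %d px (raw %d), hair %d px, corners %d px%s\n",
              sum(x$lesion_mask), sum(x$wavelet_mask), sum(x$hair_mask),
              sum(x$corner_mask), if (x$no_lesion) "  [no lesion found]" else ""))
  invisible(x)
}

#' Segment every image in a directory
#'
#' Writes one `<stem>_mask.png` per readable image into `out_dir`; when a
#' ground-truth directory is given (masks matched by filename stem, with an
#' optional `_lesion` suffix), also returns an evaluation report.
#' Unreadable images are skipped with a warning.
#'
#' @param in_dir directory of input images.
#' @param cfg [dermseg_config()].
#' @param gt_dir optional directory of ground-truth masks.
#' @param out_dir output directory (default `in_dir`); created if needed.
#' @param overlay also write `<stem>_overlay.png` contour images.
#' @return list with `masks` (named list of final masks), `report`
#'   ([evaluate_batch()] result or `NULL`), `failed` (character vector).
#' @export
dermseg_batch <- function(in_dir, cfg = dermseg_config(), gt_dir = NULL,
                          out_dir = in_dir, overlay = FALSE) {
  exts <- "\\.(png|jpg|jpeg|tif|tiff|bmp)$"
  files <- list.files(in_dir, pattern = exts, ignore.case = TRUE, full.names = TRUE)
  files <- files[!grepl("_(mask|overlay|lesion|hair|corner)\\.png$", files)]
  if (length(files) == 0L) stop("dermseg_batch: no readable images in ", in_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  masks <- list(); pairs <- list(); failed <- character()
  for (f in files) {
    stem <- sub("\\.[^.]+$", "", basename(f))
    res <- tryCatch(dermseg_run(read_image(f), cfg), error = function(e) e)
    if (inherits(res, "error")) {
      warning("dermseg_batch: skipping ", basename(f), ": ", conditionMessage(res))
      failed <- c(failed, stem)
      next
    }
    masks[[stem]] <- res$lesion_mask
    write_mask_png(res$lesion_mask, file.path(out_dir, paste0(stem, "_mask.png")))
    gt <- NULL
    if (!is.null(gt_dir)) {
      cand <- c(file.path(gt_dir, paste0(stem, "_lesion.png")),
                file.path(gt_dir, paste0(stem, ".png")))
      hit <- cand[file.exists(cand)]
      if (length(hit)) gt <- read_mask(hit[1])
    }
    if (overlay)
      write_image_png(overlay_contours(read_image(f), res$lesion_mask, gt),
                      file.path(out_dir, paste0(stem, "_overlay.png")))
    if (!is.null(gt))
      pairs[[length(pairs) + 1L]] <- list(pred = res$lesion_mask, gt = gt,
                                          image_id = stem)
  }
  report <- if (length(pairs)) evaluate_batch(pairs) else NULL
  list(masks = masks, report = report, failed = failed)
}

#' Wavelet-family comparison grid
#'
#' Runs the full pipeline on a phantom suite (or a user-supplied list of
#' `(image, gt)` pairs) once per wavelet family and tabulates ATDR, AFPR,
#' AEP and mean Dice per family — the format of the wavelet-selection
#' experiment.
#'
#' @param cases list of `phantom_case` objects (see [generate_suite()]) or
#'   of lists with elements `image` and `lesion_mask`.
#' @param families wavelet names (default all of [wavelet_families()]).
#' @param cfg base [dermseg_config()]; its `wavelet` field is overridden.
#' @param csv optional path: write the grid as CSV.
#' @return data.frame with columns `wavelet`, `atdr`, `afpr`, `aep`, `dice`
#'   (percent scale).
#' @export
compare_wavelets <- function(cases, families = wavelet_families(),
                             cfg = dermseg_config(), csv = NULL) {
  stopifnot(length(cases) >= 1)
  rows <- lapply(families, function(wv) {
    cfg$wavelet <- wv
    pairs <- lapply(seq_along(cases), function(i) {
      res <- dermseg_run(cases[[i]]$image, cfg)
      list(pred = res$lesion_mask, gt = cases[[i]]$lesion_mask,
           image_id = sprintf("case_%03d", i))
    })
    rep <- evaluate_batch(pairs)
    data.frame(wavelet = wv, atdr = rep$atdr, afpr = rep$afpr,
               aep = rep$aep, dice = rep$mean_dice, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(grid, csv, row.names = FALSE)
  grid
}
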