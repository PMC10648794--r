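## End-to-end orchestration: synthesize or load slides, tile and QC them,
## train (or load) the classifier, predict every kept tile, aggregate to
## slide calls and write a run report. One global seed determines every
## stage seed through a fixed derivation (derive_seed(seed, stage offset)),
## so a full run is reproducible byte for byte in its summary CSV and
## metrics JSON. The run log carries per-stage tile counts and timings and
## is outside the byte-identity contract.

#' Default run configuration
#'
#' Returns the full nested configuration with the published defaults: tile
#' size 2048 (64 for the synthetic cohort), 64 x 64 model input, learning
#' rate 0.001, 200 PCA components / ReliefF-selected features, slide
#' threshold 0.20. Any subset can be overridden from YAML or by argument.
#'
#' @param seed Global seed; every stage seed derives from it.
#' @return A nested list of configuration sections.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    paths = list(slides_dir = NULL, out_dir = NULL),
    synthetic = list(
      n_okc_slides = 2L, n_nonkc_slides = 2L,
      grid_rows = 4L, grid_cols = 4L, tile_size = 64L,
      background_share = 0.25, okc_share = 0.5, nonkc_okc_share = 0.05
    ),
    tiling = list(
      tile_size = 64L, min_tissue_fraction = 0.05, edge_policy = "PAD_WHITE"
    ),
    model = list(
      preset = "default", input_size = 64L,
      n_components = 200L, n_selected = 200L, hidden_units = 64L,
      relieff_on = "pca"
    ),
    relieff = list(k_neighbors = 10L, n_iterations = NULL),
    pretrain = list(epochs = 3L, batch_size = 32L, n_per_class = 80L),
    training = list(
      learning_rate = 0.001, epochs = 10L, batch_size = 32L,
      split_fraction = 0.8, split_unit = "TILE", n_per_class = 150L
    ),
    augmentation = list(
      enabled = TRUE, rotation_range = 20, width_shift = 0.1,
      height_shift = 0.1, shear_range = 0.2, zoom_range = 0.2,
      horizontal_flip = TRUE
    ),
    aggregation = list(threshold = 0.20, denominator = "KEPT_TILES")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration from YAML
#'
#' Values present in the file override [default_run_config()]; everything
#' else keeps its default.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Optional named list applied after the file.
#' @return The merged configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Generate a synthetic slide cohort on disk
#'
#' Writes one PNG and one ground-truth manifest CSV per slide plus a
#' `cohort.csv` index with each slide's planted label.
#'
#' @param config Run configuration (its `synthetic` section is used).
#' @param slides_dir Output directory, created if needed.
#' @param seed Cohort seed.
#' @return The cohort index tibble: `slide_id, planted_label, image, manifest`.
#' @export
synth_cohort <- function(config = default_run_config(), slides_dir, seed = config$seed) {
  sc <- config$synthetic
  dir.create(slides_dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- c(rep("OKC", sc$n_okc_slides), rep("NONKC", sc$n_nonkc_slides))
  index <- purrr::imap_dfr(kinds, function(kind, i) {
    sid <- sprintf("%s_slide_%02d", tolower(kind), i)
    spec <- random_slide_spec(
      slide_id = sid, kind = kind,
      grid_rows = sc$grid_rows, grid_cols = sc$grid_cols,
      tile_size = sc$tile_size,
      okc_share = if (kind == "OKC") sc$okc_share else sc$nonkc_okc_share,
      background_share = sc$background_share,
      seed = derive_seed(seed, 500L + i)
    )
    slide <- make_slide(spec)
    img_path <- file.path(slides_dir, paste0(sid, ".png"))
    man_path <- file.path(slides_dir, paste0(sid, "_manifest.csv"))
    write_image(slide$image, img_path)
    write_manifest(slide$manifest, man_path)
    tibble::tibble(
      slide_id = sid, planted_label = kind,
      image = img_path, manifest = man_path
    )
  })
  readr::write_csv(index, file.path(slides_dir, "cohort.csv"))
  index
}

## tile one slide image and return kept tiles with pixels + any truth labels
tile_one_slide <- function(img_path, manifest_path, tcfg, input_size, slide_id) {
  raster <- read_image(img_path)
  records <- tile_slide(raster, tcfg, slide_id = slide_id)
  truth <- NULL
  if (!is.null(manifest_path) && file.exists(manifest_path)) {
    truth <- read_manifest(manifest_path)[, c("row", "col", "true_class")]
    records <- dplyr::left_join(records, truth, by = c("row", "col"))
  }
  kept <- dplyr::filter(records, .data$qc_status == "KEPT")
  tiles <- purrr::map(seq_len(nrow(kept)), function(i) {
    px <- tile_pixels(raster, kept[i, ])
    if (dim(px)[1] != input_size) px <- resize_image(px, input_size) else px
  })
  list(records = records, kept = kept, tiles = tiles)
}

#' Run the full pipeline
#'
#' `TRAIN` mode synthesizes (or reuses) the slide cohort, tiles and QCs all
#' slides, pretrains the extractor on labeled kept tiles, fits PCA and
#' ReliefF, trains the head, predicts every kept tile, aggregates slide
#' decisions and writes the report plus reusable model artifacts.
#' `PREDICT` mode loads previously saved artifacts and repeats only the
#' tile/predict/aggregate stages, rejecting the run with a list of missing
#' files when artifacts are absent.
#'
#' @param config Run configuration (see [default_run_config()] /
#'   [load_run_config()]); `config$paths$out_dir` is required,
#'   `config$paths$slides_dir` defaults to `<out_dir>/slides`.
#' @param mode `"TRAIN"` or `"PREDICT"`.
#' @return A `kc_run` list: `decisions` (slide summary tibble), `metrics`
#'   (validation-tile metric report, TRAIN mode), `model`, `cohort`,
#'   `tile_counts` and the output `paths`.
#' @export
run_pipeline <- function(config = default_run_config(), mode = c("TRAIN", "PREDICT")) {
  mode <- match.arg(mode)
  out_dir <- config$paths$out_dir
  if (is.null(out_dir)) stop("config$paths$out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slides_dir <- config$paths$slides_dir %||% file.path(out_dir, "slides")
  seed <- config$seed
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  cohort_path <- file.path(slides_dir, "cohort.csv")
  if (!file.exists(cohort_path)) {
    if (mode == "PREDICT") stop("no cohort found at ", cohort_path, call. = FALSE)
    say("synthesizing cohort into %s", slides_dir)
    cohort <- synth_cohort(config, slides_dir, seed = seed)
  } else {
    cohort <- readr::read_csv(cohort_path, show_col_types = FALSE, progress = FALSE)
  }

  if (nrow(cohort) == 0L) {
    warning("cohort is empty; writing an empty report", call. = FALSE)
    decisions <- tibble::tibble(
      slide_id = character(0), n_tiles = integer(0), n_okc = integer(0),
      n_nonkc = integer(0), okc_fraction = double(0),
      threshold = double(0), label = character(0)
    )
    run <- structure(
      list(
        decisions = decisions, metrics = NULL, model = NULL,
        cohort = cohort, tile_counts = tibble::tibble(),
        config = config, log = log_lines,
        paths = list(out_dir = out_dir, slides_dir = slides_dir, model = NULL)
      ),
      class = "kc_run"
    )
    write_report(run, out_dir)
    return(run)
  }

  tcfg <- tiling_config(
    tile_size = config$tiling$tile_size,
    min_tissue_fraction = config$tiling$min_tissue_fraction,
    edge_policy = config$tiling$edge_policy
  )
  input_size <- config$model$input_size

  say("tiling %d slides", nrow(cohort))
  tiled <- purrr::map(seq_len(nrow(cohort)), function(i) {
    tile_one_slide(
      cohort$image[i],
      if ("manifest" %in% names(cohort)) cohort$manifest[i] else NULL,
      tcfg, input_size, cohort$slide_id[i]
    )
  })
  names(tiled) <- cohort$slide_id
  tile_counts <- purrr::map_dfr(tiled, function(t) {
    tibble::tibble(
      n_tiles = nrow(t$records),
      n_kept = nrow(t$kept),
      n_discarded = nrow(t$records) - nrow(t$kept)
    )
  }, .id = "slide_id")
  purrr::pwalk(tile_counts, function(slide_id, n_tiles, n_kept, n_discarded) {
    say("%s: %d tiles, %d kept, %d discarded", slide_id, n_tiles, n_kept, n_discarded)
  })

  model_path <- file.path(out_dir, "model.rds")
  metrics <- NULL

  if (mode == "TRAIN") {
    # labeled kept tiles across the cohort
    labeled <- purrr::map_dfr(tiled, function(t) {
      if (!"true_class" %in% names(t$kept)) {
        return(tibble::tibble())
      }
      keep <- t$kept$true_class %in% c("OKC", "NONKC")
      tibble::tibble(
        slide_id = t$kept$slide_id[keep],
        label = t$kept$true_class[keep],
        image = t$tiles[keep]
      )
    })
    # top up with directly generated labeled tiles so both classes are
    # well represented regardless of cohort composition
    n_extra <- config$training$n_per_class
    if (!is.null(n_extra) && n_extra > 0) {
      extra <- make_labeled_dataset(n_extra,
        tile_size = input_size,
        seed = derive_seed(seed, 601L)
      )
      labeled <- dplyr::bind_rows(
        labeled,
        tibble::tibble(
          slide_id = "synthetic_pool",
          label = as.character(extra$label), image = extra$image
        )
      )
    }
    say("training pool: %d tiles (%d OKC)", nrow(labeled), sum(labeled$label == "OKC"))

    # PCA components cannot exceed the labeled pool size; small demo runs
    # clamp the reduction/selection widths accordingly
    n_comp <- min(config$model$n_components, nrow(labeled))
    n_sel <- min(config$model$n_selected, n_comp)
    if (n_comp < config$model$n_components) {
      say(
        "clamping reduction to %d components / %d selected (pool size %d)",
        n_comp, n_sel, nrow(labeled)
      )
    }
    arch <- build_architecture(config$model$preset,
      input_shape = c(input_size, input_size, 3L),
      n_components = n_comp,
      n_selected = n_sel,
      hidden_units = config$model$hidden_units
    )

    pool_idx <- local_seed(derive_seed(seed, 602L), {
      per_class <- min(
        config$pretrain$n_per_class,
        sum(labeled$label == "OKC"), sum(labeled$label == "NONKC")
      )
      c(
        sample(which(labeled$label == "OKC"), per_class),
        sample(which(labeled$label == "NONKC"), per_class)
      )
    })
    say("pretraining extractor on %d tiles, %d epochs", length(pool_idx), config$pretrain$epochs)
    extractor <- pretrain_extractor(
      labeled$image[pool_idx], labeled$label[pool_idx],
      architecture = arch,
      epochs = config$pretrain$epochs,
      batch_size = config$pretrain$batch_size,
      seed = derive_seed(seed, 603L)
    )

    say("fitting PCA (%d components) and ReliefF", n_comp)
    feats <- extract_features(extractor, labeled$image)
    pca <- NULL
    rf_input <- feats
    if (config$model$relieff_on == "pca") {
      pca <- fit_pca(feats, n_comp)
      rf_input <- pca_transform(pca, feats)
    }
    rf <- relieff_weights(
      rf_input, labeled$label,
      relieff_config(
        k_neighbors = config$relieff$k_neighbors,
        n_iterations = config$relieff$n_iterations,
        seed = derive_seed(seed, 604L)
      )
    )
    sel <- top_k_indices(rf, n_sel)

    model <- assemble_model(extractor, pca, sel,
      head_spec(config$model$hidden_units),
      seed = derive_seed(seed, 605L)
    )
    aug <- if (isTRUE(config$augmentation$enabled)) {
      augmentation_config(
        rotation_range = config$augmentation$rotation_range,
        width_shift = config$augmentation$width_shift,
        height_shift = config$augmentation$height_shift,
        shear_range = config$augmentation$shear_range,
        zoom_range = config$augmentation$zoom_range,
        horizontal_flip = config$augmentation$horizontal_flip,
        seed = derive_seed(seed, 606L)
      )
    } else {
      NULL
    }
    say("training head: %d epochs", config$training$epochs)
    model <- train_head(model, labeled$image, labeled$label,
      training_config(
        learning_rate = config$training$learning_rate,
        epochs = config$training$epochs,
        batch_size = config$training$batch_size,
        split_fraction = config$training$split_fraction,
        split_unit = config$training$split_unit,
        seed = derive_seed(seed, 607L)
      ),
      augmentation = aug, slide_ids = labeled$slide_id
    )
    say(
      "validation accuracy %.3f", dplyr::last(model$history$val_accuracy)
    )

    val <- model$split$val
    if (length(val)) {
      vp <- predict_tiles(model, labeled$image[val])
      metrics <- metric_report(
        confusion(labeled$label[val], vp$label),
        probabilities = vp$prob_okc, truth = labeled$label[val]
      )
    }
    saveRDS(list(model = model, config = config), model_path)
  } else {
    missing <- model_path[!file.exists(model_path)]
    if (length(missing)) {
      stop("PREDICT mode requires saved artifacts; missing: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    model <- readRDS(model_path)$model
  }

  say("predicting and aggregating %d slides", nrow(cohort))
  acfg <- aggregation_config(config$aggregation$threshold, config$aggregation$denominator)
  decisions <- purrr::map_dfr(cohort$slide_id, function(sid) {
    t <- tiled[[sid]]
    if (nrow(t$kept) == 0L) {
      return(tibble::tibble(
        slide_id = sid, n_tiles = 0L, n_okc = 0L, n_nonkc = 0L,
        okc_fraction = NA_real_, threshold = acfg$threshold, label = NA_character_
      ))
    }
    preds <- predict_tiles(model, t$tiles)
    decide_slide(preds, acfg, slide_id = sid, n_total = nrow(t$records))
  })

  run <- structure(
    list(
      decisions = decisions, metrics = metrics, model = model,
      cohort = cohort, tile_counts = tile_counts,
      config = config, log = log_lines,
      paths = list(out_dir = out_dir, slides_dir = slides_dir, model = model_path)
    ),
    class = "kc_run"
  )
  write_report(run, out_dir)
  run
}

#' Write the run report
#'
#' Emits `summary.csv` (slide decisions, Table-style columns),
#' `metrics.json` (tidied metric report, when available),
#' `config_snapshot.yaml` and `run_log.txt`. The CSV and JSON are
#' byte-reproducible for a fixed config and seed.
#'
#' @param run A `kc_run` (or a bare decisions tibble).
#' @param out_dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  decisions <- if (inherits(run, "kc_run")) run$decisions else run
  if (is.null(decisions)) stop("`run` has no decisions to report", call. = FALSE)
  paths <- c(summary = file.path(out_dir, "summary.csv"))
  readr::write_csv(decisions, paths[["summary"]])
  if (inherits(run, "kc_run")) {
    if (!is.null(run$metrics)) {
      paths[["metrics"]] <- file.path(out_dir, "metrics.json")
      m <- tidy(run$metrics)
      jsonlite::write_json(
        as.list(stats::setNames(m$value, m$metric)),
        paths[["metrics"]],
        auto_unbox = TRUE, digits = NA, na = "null"
      )
    }
    paths[["config"]] <- file.path(out_dir, "config_snapshot.yaml")
    yaml::write_yaml(run$config, paths[["config"]])
    paths[["log"]] <- file.path(out_dir, "run_log.txt")
    writeLines(run$log, paths[["log"]])
  }
  invisible(paths)
}

#' @export
print.kc_run <- function(x, ...) {
  cat("<kc_run>", nrow(x$decisions), "slides\n")
  print(x$decisions, n = Inf)
  invisible(x)
}
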