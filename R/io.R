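# File formats, run configuration and pipeline orchestration. All artifacts
# are plain text: TSV for signals and epochs, PNG (plus lossless float TSV
# twins) for images, JSON for manifests and reports, YAML for configs.

fmt_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Write a recording as a TSV triplet
#'
#' Produces `<stem>_hbo.tsv` and `<stem>_hbr.tsv` (a `# sampling_rate:`
#' metadata line, a header row of channel ids, one row per sample) and
#' `<stem>_events.tsv` (`onset_s`, `duration_s`, `label`).
#'
#' @param recording a `nirs_recording`.
#' @param stem output path stem.
#' @return the three paths, invisibly.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "nirs_recording"))
  paths <- paste0(stem, c("_hbo.tsv", "_hbr.tsv", "_events.tsv"))
  for (i in 1:2) {
    M <- recording[[c("hbo", "hbr")[i]]]
    con <- file(paths[i], "w")
    writeLines(paste0("# sampling_rate: ", fmt_num(recording$sampling_rate)), con)
    writeLines(paste(rownames(M), collapse = "\t"), con)
    # %.17g preserves doubles exactly across the round trip
    writeLines(apply(matrix(sprintf("%.17g", t(M)), ncol(M), nrow(M)),
                     1, paste, collapse = "\t"), con)
    close(con)
  }
  ev <- recording$events
  utils::write.table(
    data.frame(onset_s = ev$onset, duration_s = ev$duration,
               label = as.character(ev$label)),
    paths[3], sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a recording from its TSV triplet
#'
#' Validates that both chromophore files share header and row count, that
#' the events parse with known labels and strictly increasing onsets, and
#' rebuilds the `nirs_recording` (channel laterality: first half left).
#'
#' @param stem path stem used by [write_recording()].
#' @return a `nirs_recording`.
#' @export
read_recording <- function(stem) {
  paths <- paste0(stem, c("_hbo.tsv", "_hbr.tsv", "_events.tsv"))
  for (p in paths) if (!file.exists(p)) stop_invalid("missing file: ", p)
  read_chrom <- function(p) {
    l1 <- readLines(p, n = 1)
    if (!grepl("^# sampling_rate:", l1)) {
      stop_invalid(p, " line 1: expected '# sampling_rate:' metadata header")
    }
    fs <- as.numeric(sub("^# sampling_rate:\\s*", "", l1))
    d <- utils::read.table(p, sep = "\t", header = TRUE, skip = 1,
                           check.names = FALSE)
    list(fs = fs, M = t(as.matrix(d)), header = colnames(d))
  }
  hbo <- read_chrom(paths[1]); hbr <- read_chrom(paths[2])
  if (!identical(hbo$header, hbr$header) ||
      !identical(dim(hbo$M), dim(hbr$M))) {
    stop_invalid("hbo/hbr shape or header mismatch between ", paths[1],
                 " and ", paths[2])
  }
  if (hbo$fs != hbr$fs) stop_invalid("sampling-rate mismatch between files")
  ev <- utils::read.table(paths[3], sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  bad <- which(!ev$label %in% TASK_LEVELS)
  if (length(bad) > 0) {
    stop_invalid(paths[3], " line ", bad[1] + 1, ": unknown label '",
                 ev$label[bad[1]], "'")
  }
  if (any(diff(ev$onset_s) <= 0)) {
    i <- which(diff(ev$onset_s) <= 0)[1]
    stop_invalid(paths[3], " line ", i + 2, ": onsets must be strictly increasing")
  }
  if (any(ev$onset_s + ev$duration_s > ncol(hbo$M) / hbo$fs + 1e-9)) {
    stop_invalid(paths[3], ": event extends past the end of the recording")
  }
  nc <- nrow(hbo$M)
  rownames(hbo$M) <- rownames(hbr$M) <- hbo$header
  structure(list(
    hbo = hbo$M, hbr = hbr$M, sampling_rate = hbo$fs,
    channel_side = rep(c("left", "right"), each = nc %/% 2, length.out = nc),
    events = tibble::tibble(onset = ev$onset_s, duration = ev$duration_s,
                            label = task_label(ev$label))
  ), class = "nirs_recording")
}

#' Write a GASF dataset as PNGs with lossless TSV twins and a manifest
#'
#' PNGs are 8-bit quantized previews; the float TSVs are the
#' accuracy-bearing representation used when reading back. The
#' `manifest.json` records path, MD5 content hash, label, provenance and
#' split for every image; provenance and split never change downstream.
#'
#' @param ds a `gasf_dataset`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_gasf_images <- function(ds, dir) {
  stopifnot(inherits(ds, "gasf_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- as.character(dataset_labels(ds))
  recs <- purrr::imap(ds$images, function(im, i) {
    stem <- sprintf("img_%04d_%s", i, labs[i])
    tsv <- file.path(dir, paste0(stem, ".tsv"))
    utils::write.table(signif(im$pixels, 12), tsv, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    if (requireNamespace("png", quietly = TRUE)) {
      png::writePNG(im$pixels, file.path(dir, paste0(stem, ".png")))
    }
    list(file = paste0(stem, ".tsv"),
         md5 = unname(tools::md5sum(tsv)),
         label = labs[i], provenance = im$provenance, split = ds$split)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(recs, manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a GASF dataset written by [write_gasf_images()]
#'
#' Verifies every image's MD5 content hash against the manifest.
#'
#' @param dir dataset directory.
#' @return a `gasf_dataset`.
#' @export
read_gasf_images <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) stop_invalid("no manifest.json in ", dir)
  recs <- jsonlite::read_json(manifest)
  if (length(recs) == 0) return(gasf_dataset(list(), "train"))
  images <- purrr::map(recs, function(r) {
    p <- file.path(dir, r$file)
    if (!file.exists(p)) stop_invalid("manifest names missing file ", p)
    if (unname(tools::md5sum(p)) != r$md5) {
      stop_invalid("content hash mismatch for ", p)
    }
    px <- as.matrix(utils::read.table(p, sep = "\t"))
    structure(list(pixels = unname(px), label = task_label(r$label),
                   provenance = r$provenance),
              class = "gasf_image")
  })
  gasf_dataset(images, recs[[1]]$split)
}

#' Full run configuration
#'
#' Nested, schema-validated configuration for [run_pipeline()]. Unknown
#' keys are rejected and a seed is required before any computation starts;
#' the global seed fans out deterministically to every stochastic stage.
#'
#' @param simulation arguments for [sim_config()] (a list).
#' @param filter list with `low`, `high`, `order` for [bandpass()].
#' @param window epoch window, seconds.
#' @param baseline baseline-correction reference interval, seconds.
#' @param encode_source `"channel"` (GASF of the selected channel) or
#'   `"kpca1"` (GASF of the epoch's first principal-component time course
#'   across channels).
#' @param chromophore encoded chromophore, `"hbo"` or `"hbr"`.
#' @param cgan a [cgan_config()].
#' @param cnn a [cnn_config()].
#' @param fractions augmentation-fraction grid.
#' @param n_test stratified test-set size.
#' @param seed master seed (required).
#' @return object of class `run_config`.
#' @export
run_config <- function(simulation = list(), filter = list(low = 0.01, high = 0.1, order = 3),
                       window = c(-2, 28), baseline = c(-1, 0),
                       encode_source = c("channel", "kpca1"),
                       chromophore = c("hbo", "hbr"),
                       cgan = cgan_config(), cnn = cnn_config(),
                       fractions = seq(0, 1.1, by = 0.1),
                       n_test = 30, seed = NULL) {
  if (is.null(seed)) stop_invalid("run_config requires an explicit seed")
  known_sim <- names(formals(sim_config))
  unknown <- setdiff(names(simulation), known_sim)
  if (length(unknown) > 0) {
    stop_invalid("unknown simulation key(s): ", paste(unknown, collapse = ", "))
  }
  known_filter <- c("low", "high", "order")
  unknown <- setdiff(names(filter), known_filter)
  if (length(unknown) > 0) {
    stop_invalid("unknown filter key(s): ", paste(unknown, collapse = ", "))
  }
  simulation$seed <- simulation$seed %||% derive_seed(seed, "sim")
  structure(list(simulation = do.call(sim_config, simulation),
                 filter = filter, window = window, baseline = baseline,
                 encode_source = match.arg(encode_source),
                 chromophore = match.arg(chromophore),
                 cgan = cgan, cnn = cnn, fractions = fractions,
                 n_test = as.integer(n_test), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; top-level keys mirror [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop_invalid("unknown config key(s) in ", path, ": ",
                 paste(unknown, collapse = ", "))
  }
  if (!is.null(y$cgan)) y$cgan <- do.call(cgan_config, y$cgan)
  if (!is.null(y$cnn)) y$cnn <- do.call(cnn_config, y$cnn)
  if (!is.null(y$simulation$noise_amplitudes)) {
    y$simulation$noise_amplitudes <- unlist(y$simulation$noise_amplitudes)
  }
  if (!is.null(y$fractions)) y$fractions <- unlist(y$fractions)
  if (!is.null(y$window)) y$window <- unlist(y$window)
  if (!is.null(y$baseline)) y$baseline <- unlist(y$baseline)
  do.call(run_config, y)
}

# Encode every epoch per the configured source/chromophore.
encode_epochs <- function(epochs, config, channel = NULL) {
  if (config$encode_source == "channel") {
    channel <- channel %||% select_channel(epochs)
    images <- purrr::map(epochs, encode_epoch, channel = channel,
                         chromophore = config$chromophore)
  } else {
    images <- purrr::map(epochs, function(ep) {
      idx <- epoch_window_idx(ep, 0, ep$t0_offset +
                                ncol(ep$hbo) / ep$sampling_rate)
      M <- t(ep[[config$chromophore]][, idx, drop = FALSE])  # time x channels
      pc1 <- kernel_pca_reduce(M, kernel = "linear", n_comp = 1)$scores$kpc1
      to_image(gasf(rescale_unit(paa_downsample(pc1, 28L))), ep$label)
    })
  }
  list(images = images, channel = channel)
}

#' Run the full pipeline: simulate, preprocess, encode, split, sweep
#'
#' Executes every stage on the synthetic generator's output, writes
#' manifested artifacts under `out_dir` when given (recording TSVs, image
#' PNG/TSV pairs with manifest, sweep report JSON), and returns the
#' [augmentation_sweep()] report. Re-running with an identical
#' configuration reproduces identical artifacts.
#'
#' @param config a `run_config`.
#' @param out_dir optional artifact directory.
#' @return a `sweep_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  rec <- generate_recording(config$simulation)
  filt <- bandpass(rec, config$filter$low, config$filter$high,
                   config$filter$order)
  epochs <- extract_epochs(filt, config$window)
  epochs <- purrr::map(epochs, baseline_correct,
                       ref_interval = config$baseline)
  enc <- encode_epochs(epochs, config)
  ds <- gasf_dataset(enc$images, "train")
  parts <- split_dataset(ds, n_test = config$n_test,
                         seed = derive_seed(config$seed, "split"))
  parts$train$split <- "train"
  report <- augmentation_sweep(parts$train, parts$test,
                               cgan_cfg = config$cgan, cnn_cfg = config$cnn,
                               fractions = config$fractions,
                               seed = derive_seed(config$seed, "sweep"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_recording(rec, file.path(out_dir, "recording"))
    write_gasf_images(parts$train, file.path(out_dir, "images_train"))
    write_gasf_images(parts$test, file.path(out_dir, "images_test"))
    res <- tidy(report)
    jsonlite::write_json(
      list(schema = "nirscgan/sweep/v1", seed = config$seed,
           selected_channel = enc$channel,
           results = res[setdiff(names(res), "confusion")]),
      file.path(out_dir, "sweep_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}
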