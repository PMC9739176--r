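#' Write or read an FOH dataset container
#'
#' A dataset is a directory holding `meta.yaml` (configuration snapshot,
#' package version, seed), `ground_truth.csv` (one row per position:
#' `position_id`, `x_mm`, `y_mm`, `z_mm`, `angle_deg`, `seed`) and one
#' full-precision `frames/frame_<i>.rds` per FOH frame, so waveforms
#' round-trip bit exactly. A raw-stream entry (`raw_stream.rds`) may be
#' included for exercising the framing stage.
#'
#' @param frames List of [foh_frame()] objects.
#' @param dir Dataset directory (created if needed).
#' @param truth Optional ground-truth tibble.
#' @param meta Named list of configuration values to snapshot.
#' @param scene_index Optional tibble mapping frame file index to
#'   `position_id`/`frame` (written as `scene_index.csv`).
#' @param raw Optional list from [simulate_raw_stream()].
#' @return The directory path, invisibly.
#' @export
write_foh_dataset <- function(frames, dir, truth = NULL, meta = list(),
                              scene_index = NULL, raw = NULL) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  meta$package_version <- as.character(utils::packageVersion("fohtrack"))
  meta$n_frames <- length(frames)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  if (!is.null(truth)) {
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  if (!is.null(scene_index)) {
    utils::write.csv(scene_index, file.path(dir, "scene_index.csv"),
                     row.names = FALSE)
  }
  for (i in seq_along(frames)) {
    saveRDS(frames[[i]], file.path(dir, "frames",
                                   sprintf("frame_%06d.rds", i)))
  }
  if (!is.null(raw)) saveRDS(raw, file.path(dir, "raw_stream.rds"))
  invisible(dir)
}

#' @rdname write_foh_dataset
#' @export
read_foh_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path)) {
    stop("not a dataset directory: missing meta.yaml", call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  files <- sort(list.files(file.path(dir, "frames"), pattern = "^frame_.*\\.rds$",
                           full.names = TRUE))
  frames <- lapply(files, readRDS)
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) {
    tibble::as_tibble(utils::read.csv(truth_path))
  } else NULL
  idx_path <- file.path(dir, "scene_index.csv")
  scene_index <- if (file.exists(idx_path)) {
    tibble::as_tibble(utils::read.csv(idx_path))
  } else NULL
  raw_path <- file.path(dir, "raw_stream.rds")
  raw <- if (file.exists(raw_path)) readRDS(raw_path) else NULL
  list(frames = frames, truth = truth, meta = meta,
       scene_index = scene_index, raw = raw)
}

#' Materialise frames of a simulation
#'
#' @param sim A `foh_simulation`.
#' @param indices Scene rows to synthesise (default: all).
#' @return List of [foh_frame()] objects.
#' @export
materialise_frames <- function(sim, indices = seq_len(nrow(sim$scenes))) {
  lapply(indices, function(i) sim_frame(sim, i))
}
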