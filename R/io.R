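#' Recording container
#'
#' On-disk layout for pipeline artifacts: a directory holding one
#' serialized R object per stage (`raw`, `reduced`, `truth`, `features`,
#' `labels`, `respiration`) plus a JSON `meta.json` with the configuration,
#' seeds and a configuration hash. Serialization is exact (bit-identical
#' round trip), which the pipeline relies on when stages are re-run
#' incrementally.
#'
#' @param path Container directory (created if missing).
#' @param name Stage name.
#' @param object Object to store.
#' @return Invisibly, the file path written.
#' @export
container_write <- function(path, name, object) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  f <- file.path(path, paste0(name, ".rds"))
  saveRDS(object, f)
  invisible(f)
}

#' @rdname container_write
#' @param required Error (naming the producing stage) when the entry is
#'   missing.
#' @export
container_read <- function(path, name, required = TRUE) {
  f <- file.path(path, paste0(name, ".rds"))
  if (!file.exists(f)) {
    if (!required) return(NULL)
    stage <- c(raw = "simulate", reduced = "simulate", truth = "simulate",
               features = "features", labels = "detect",
               respiration = "respiration")[name]
    stop("container entry '", name, "' not found in ", path,
         "; run the '", if (is.na(stage)) "producing" else stage,
         "' stage first", call. = FALSE)
  }
  readRDS(f)
}

#' Write/read container metadata
#' @param path Container directory.
#' @param meta Named list (written as JSON).
#' @return `meta_read` returns the parsed list (or NULL).
#' @export
meta_write <- function(path, meta) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(path, "meta.json"))
}

#' @rdname meta_write
#' @export
meta_read <- function(path) {
  f <- file.path(path, "meta.json")
  if (!file.exists(f)) return(NULL)
  jsonlite::read_json(f, simplifyVector = TRUE)
}

#' Hash of a configuration list
#'
#' MD5 of the canonical JSON serialization; used to detect stale stage
#' outputs.
#'
#' @param config Named list.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to the documented defaults: the full-size
#' radar preset, a supine 1.75 m / 0.40 m person, 14 cycles/min breathing
#' and the standard detector thresholds.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Nested named list with classes `radar`, `scene`, `script`,
#'   `detector`, `run`.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  def <- list(
    radar = list(preset = "desk"),
    scene = list(pose = "supine", height = 1.75, width = 0.40,
                 offset = c(0, 0), seed = 1),
    script = list(rate = 14, amp_chest = 0.004, amp_abd = 0.006,
                  phase_offset = 10, harmonic2 = 0.15),
    detector = list(),
    run = list(duration = 60, seed = 1, snr_db = 20, tau = 25, dtau = 5))
  merge2 <- function(d, u) {
    for (nm in names(u)) {
      d[[nm]] <- if (is.list(u[[nm]]) && is.list(d[[nm]]))
        merge2(d[[nm]], u[[nm]]) else u[[nm]]
    }
    d
  }
  merge2(def, user)
}

build_from_run_config <- function(rc) {
  preset <- rc$radar$preset
  ov <- rc$radar[setdiff(names(rc$radar), "preset")]
  config <- do.call(radar_config, c(list(preset = preset), ov))
  scene <- make_pose_scene(rc$scene$pose, rc$scene$height, rc$scene$width,
                           seed = rc$scene$seed,
                           offset = unlist(rc$scene$offset))
  script <- motion_script(breathing_rate = rc$script$rate,
                          amp_chest = rc$script$amp_chest,
                          amp_abd = rc$script$amp_abd,
                          phase_offset = rc$script$phase_offset,
                          harmonic2_frac = rc$script$harmonic2)
  detector <- do.call(detector_config, rc$detector)
  list(config = config, scene = scene, script = script,
       detector = detector)
}
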