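# Cohort serialization: one TSV array container per participant-session
# (channels * trials rows x time columns) plus a JSON sidecar carrying the
# montage and acquisition metadata.

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# Tiny polynomial rolling hash of a string; used to fingerprint run
# configurations in output manifests without a binary dependency.
string_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(config) {
  string_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE))
}

plant_manifest <- function(plants) {
  lapply(plants, function(p) list(
    target_channels = p$target_channels,
    band = list(name = p$band$name, lo = p$band$lo, hi = p$band$hi),
    structure = p$structure, amplitude = p$amplitude,
    group = p$group, session = p$session))
}

#' Write a cohort to disk
#'
#' Writes each participant-session epoch array as a TSV container
#' (`channels * trials` rows by `time` columns) together with a JSON sidecar
#' holding the sampling rate, channel names, group, session, seed, array
#' dimensions and the planted-structure manifest.
#'
#' @param cohort An `hoi_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hoi_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  for (key in names(cohort$epochs)) {
    e <- cohort$epochs[[key]]
    d <- dim(e)
    mat <- matrix(aperm(e, c(1L, 3L, 2L)), nrow = d[1] * d[3], ncol = d[2])
    write_tsv(data.table::as.data.table(mat), file.path(dir, paste0(key, ".tsv")))
    id <- sub("_(baseline|follow_up)$", "", key)
    ses <- sub("^.*_(baseline|follow_up)$", "\\1", key)
    side <- list(
      id = id, session = ses,
      group = cohort$participants$group[cohort$participants$id == id],
      fs = cfg$fs, channel_names = cohort$channel_names,
      dims = d, seed = cfg$seed,
      plants = plant_manifest(cfg$planted_effects))
    jsonlite::write_json(side, file.path(dir, paste0(key, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a cohort of epoch arrays from disk
#'
#' Reads the TSV + JSON sidecar container written by [write_cohort()] (or
#' produced externally in the same layout), validating that every sidecar
#' declares `fs`, `channel_names`, `group` and `session` and that the
#' montage is identical across participants.
#'
#' @param dir Directory holding `<id>_<session>.tsv` / `.json` pairs.
#' @param bands Band specs to attach to the loaded cohort (default
#'   [default_bands()]).
#' @return An `hoi_cohort`-style list usable by [prep_band_trials()].
#' @export
load_external_epochs <- function(dir, bands = default_bands()) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(sidecars)) stop("no sidecar JSON files found in ", dir)
  epochs <- list(); meta <- list()
  for (sc in sidecars) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    for (fld in c("fs", "channel_names", "group", "session", "dims"))
      if (is.null(side[[fld]]))
        stop("sidecar ", basename(sc), " is missing metadata field '", fld, "'")
    key <- sub("\\.json$", "", basename(sc))
    mat <- as.matrix(data.table::fread(file.path(dir, paste0(key, ".tsv"))))
    d <- as.integer(side$dims)
    if (nrow(mat) != d[1] * d[3] || ncol(mat) != d[2])
      stop("array shape mismatch for ", key)
    e <- aperm(array(mat, dim = c(d[1], d[3], d[2])), c(1L, 3L, 2L))
    epochs[[key]] <- e
    meta[[key]] <- side
  }
  nch <- vapply(meta, function(s) length(s$channel_names), integer(1))
  if (length(unique(nch)) != 1L)
    stop("montage mismatch across participants: ",
         paste(names(which(nch != nch[1])), collapse = ", "))
  fs <- unique(vapply(meta, function(s) as.numeric(s$fs), numeric(1)))
  if (length(fs) != 1L) stop("inconsistent sampling rates across sidecars")
  ids <- unique(vapply(meta, function(s) s$id, character(1)))
  groups <- vapply(ids, function(id)
    meta[[grep(paste0("^", id, "_"), names(meta))[1]]]$group, character(1))
  d1 <- dim(epochs[[1L]])
  structure(list(
    epochs = epochs,
    participants = data.frame(id = ids, group = unname(groups),
                              stringsAsFactors = FALSE),
    sessions = sort(unique(vapply(meta, function(s) s$session, character(1)))),
    channel_names = meta[[1L]]$channel_names,
    config = list(fs = fs, n_channels = d1[1], n_time = d1[2],
                  n_trials = d1[3], bands = lapply(bands, as_band_spec))),
    class = "hoi_cohort")
}

# Flat MeasureValue table (one row per participant x order) from traces.
measure_value_table <- function(traces, channel_names, session = "follow_up") {
  rows <- lapply(traces, function(tr) {
    do.call(rbind, lapply(tr$steps, function(s) {
      data.frame(
        participant = names(s$values), session = session, band = tr$band,
        measure = tr$measure, order = s$order,
        subset = paste(channel_names[s$subset], collapse = "+"),
        value = unname(s$values),
        value_normalized = unname(normalize_by_order(s$values, s$order)),
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

trace_json <- function(traces, channel_names) {
  lapply(traces, function(tr) list(
    band = tr$band, measure = tr$measure, direction = tr$direction,
    start_order = tr$start_order, max_order = tr$max_order,
    eval_count = tr$eval_count,
    steps = lapply(unname(tr$steps), function(s) list(
      order = s$order,
      channels = channel_names[s$subset],
      d = s$effect$d,
      values = as.list(s$values)))))
}
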