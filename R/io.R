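# Plain-text interchange: tracks as TSV with a YAML scheme sidecar, intervals
# as BED6, score tables as TSV, spectra as TSV.

#' Write tracks to TSV with a YAML scheme sidecar
#'
#' @param tracks Track tibble (see [simulate_tracks()]).
#' @param scheme The matching [illumination_scheme()].
#' @param path Output TSV path; the sidecar is written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, scheme, path) {
  utils::write.table(tracks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(list(name = scheme$name, exposure = scheme$exposure,
                        dark_time = scheme$dark_time,
                        n_frames = scheme$n_frames,
                        cycle_time = scheme$cycle_time,
                        tracking_radius = scheme$tracking_radius),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read tracks and their illumination scheme back from disk
#'
#' Validates the track invariants: frames strictly increasing within a
#' track, at most one missing frame between consecutive localizations, and
#' at least two localizations per track.
#'
#' @param path TSV path written by [write_tracks()] (sidecar `<path>.yaml`
#'   must exist).
#' @return List with `tracks` (tibble) and `scheme`.
#' @export
read_tracks <- function(path) {
  tracks <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                        stringsAsFactors = FALSE))
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar)) stop_bad_arg(sprintf("missing scheme sidecar: %s", sidecar))
  y <- yaml::read_yaml(sidecar)
  scheme <- illumination_scheme(y$name, exposure = y$exposure,
                                dark_time = y$dark_time,
                                n_frames = y$n_frames,
                                tracking_radius = y$tracking_radius)
  validate_tracks(tracks)
  list(tracks = tracks, scheme = scheme)
}

validate_tracks <- function(tracks) {
  by_track <- split(tracks$frame, tracks$track_id)
  for (id in names(by_track)) {
    fr <- by_track[[id]]
    if (length(fr) < 2L) {
      stop_bad_arg(sprintf("track %s has fewer than 2 localizations.", id))
    }
    d <- diff(fr)
    if (any(d <= 0)) {
      stop_bad_arg(sprintf("track %s frames are not strictly increasing.", id))
    }
    if (any(d > 2)) {
      stop_bad_arg(sprintf("track %s has a gap of more than one frame.", id))
    }
  }
  invisible(tracks)
}

#' Write intervals as BED6
#'
#' 0-based half-open coordinates; missing `name`, `score`, `strand` columns
#' are filled with `.`/0.
#'
#' @param bed Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  col_or <- function(col, default) {
    if (col %in% names(bed)) bed[[col]] else default
  }
  out <- tibble(chrom = bed$chrom, start = bed$start, end = bed$end,
                name = col_or("name", "."),
                score = col_or("score", 0),
                strand = col_or("strand", "."))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED path (3-6 columns, no header).
#' @return Tibble with `chrom`, `start`, `end` and any of `name`, `score`,
#'   `strand` present in the file.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(df))]
  as_tibble(df)
}

#' Write/read a peak score table as TSV
#'
#' Header `chrom`, `start`, `end`, `peak_id` followed by one column per
#' sample.
#'
#' @param peaks Peak tibble.
#' @param path File path.
#' @return `path` / the tibble.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}

#' Write a rate spectrum as TSV
#'
#' Columns `rate`, `event_amp`, `state_amp`, `event_sd`, `state_sd`.
#'
#' @param spectrum A `rate_spectrum`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "rate_spectrum"))
  utils::write.table(spectrum$spectrum, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
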