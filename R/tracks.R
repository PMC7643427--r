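#' Locus trajectories
#'
#' A `Track` holds one fluorescently tagged locus trajectory: an ordered
#' matrix of 2D or 3D positions in micrometres, sampled at a uniform frame
#' interval `dt` (seconds).  A `TrackSet` is a collection of tracks sharing
#' `dt` and dimensionality, typically one imaging condition.
#'
#' @param id character scalar, track identifier.
#' @param positions numeric matrix, one row per frame, 2 or 3 columns (um).
#' @param dt frame interval in seconds (default 0.02 s, i.e. 20-ms imaging).
#' @return `track()` returns an object of class `"track"`; `track_set()`
#'   an object of class `"track_set"`.
#' @examples
#' tr <- track("a", cbind(x = 0:4, y = 0), dt = 0.02)
#' n_frames(tr)
#' @export
track <- function(id, positions, dt = 0.02) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  if (nrow(positions) < 2L)
    stop("track '", id, "': need at least 2 frames")
  if (!ncol(positions) %in% c(2L, 3L))
    stop("track '", id, "': positions must be 2D or 3D")
  if (anyNA(positions))
    stop("track '", id, "': positions contain NA")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar")
  structure(list(id = as.character(id), positions = positions, dt = dt),
            class = "track")
}

#' @rdname track
#' @param tracks list of `track` objects.
#' @param condition optional condition label carried as metadata.
#' @export
track_set <- function(tracks, dt = NULL, condition = NA_character_) {
  if (length(tracks) == 0L) stop("no tracks")
  stopifnot(all(vapply(tracks, inherits, logical(1), "track")))
  dts <- vapply(tracks, `[[`, numeric(1), "dt")
  dims <- vapply(tracks, function(t) ncol(t$positions), integer(1))
  if (length(unique(dts)) != 1L) stop("tracks do not share a common dt")
  if (length(unique(dims)) != 1L) stop("tracks do not share a common dimension")
  if (!is.null(dt) && abs(dt - dts[1]) > 1e-12) stop("dt mismatch")
  structure(list(tracks = tracks, dt = dts[1], dim = dims[1],
                 condition = condition),
            class = "track_set")
}

#' @rdname track
#' @param x a track or track set.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.track <- function(x) nrow(x$positions)

#' @export
n_frames.track_set <- function(x) vapply(x$tracks, n_frames, integer(1))

#' @export
length.track_set <- function(x) length(x$tracks)

#' Track duration in seconds
#'
#' `(n_frames - 1) * dt`: the time spanned by the recorded frames.
#' @param x a `track`.
#' @export
track_duration <- function(x) (n_frames(x) - 1L) * x$dt

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track '%s': %d frames, %dD, dt = %g s, T = %g s>\n",
              x$id, n_frames(x), ncol(x$positions), x$dt, track_duration(x)))
  invisible(x)
}

#' @export
print.track_set <- function(x, ...) {
  nf <- n_frames(x)
  cat(sprintf("<track_set: %d tracks, %dD, dt = %g s, frames %d-%d%s>\n",
              length(x$tracks), x$dim, x$dt, min(nf), max(nf),
              if (is.na(x$condition)) "" else paste0(", '", x$condition, "'")))
  invisible(x)
}

#' Number of displacement pairs at a delay
#'
#' The number of (overlapping) displacement pairs a track contributes at
#' delay `tau = k * dt` is `n_frames - k`: every ordered pair of frames
#' separated by `k` frames.  This approximates `(T - tau)/dt` (the two
#' differ by exactly one because the duration counts intervals, not
#' frames).  Overlapping displacements are statistically dependent; the
#' weighted-mean MSD estimator is nevertheless defined over all of them.
#'
#' @param track a `track`.
#' @param delay delay in seconds; must be a positive integer multiple of
#'   `dt`, smaller than the track duration plus one frame.
#' @return integer count `N_i(tau)`.
#' @examples
#' tr <- track("a", cbind(0:3, 0), dt = 1)
#' displacement_count(tr, 1)  # 3
#' displacement_count(tr, 3)  # 1
#' @export
displacement_count <- function(track, delay) {
  k <- delay_to_lag(track, delay)
  n_frames(track) - k
}

delay_to_lag <- function(track, delay, tol = 1e-6) {
  k <- delay / track$dt
  if (abs(k - round(k)) > tol)
    stop("delay ", delay, " is not an integer multiple of dt = ", track$dt)
  k <- as.integer(round(k))
  if (k < 1L) stop("delay must be at least one frame interval")
  if (k >= n_frames(track))
    stop("delay ", delay, " exceeds track '", track$id, "' duration")
  k
}

#' Read and write locus trajectories
#'
#' Delimited text with columns `track_id, frame, x, y[, z]` (comma- or
#' tab-separated, autodetected from the `.csv`/`.tsv` extension or
#' sniffed from the header).  `frame` is the 0-based frame index; frame 0
#' is t = 0.  Coordinates are micrometres.  Runs of missing frames split
#' a track id into separate tracks (suffixes `.1`, `.2`, ...) rather than
#' interpolating across the gap, which would bias displacement statistics.
#' Fragments shorter than `min_frames` are dropped.
#'
#' @param path file path.
#' @param dt frame interval in seconds (default 0.02).
#' @param min_frames minimum number of frames a (sub)track must have to be
#'   retained.  The default 2 keeps everything usable; mobility analyses
#'   typically refilter with [filter_tracks()].
#' @param condition optional condition label.
#' @return a `track_set`.
#' @export
read_tracks <- function(path, dt = 0.02, min_frames = 2L,
                        condition = NA_character_) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no tracks in '", path, "'")
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(df)))
    stop("expected columns track_id, frame, x, y[, z]")
  coord_cols <- intersect(c("x", "y", "z"), names(df))
  tracks <- list()
  for (id in unique(df$track_id)) {
    sub <- df[df$track_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (anyDuplicated(sub$frame))
      stop("track '", id, "': duplicated frame indices")
    runs <- split(seq_len(nrow(sub)), cumsum(c(1, diff(sub$frame) != 1)))
    for (ri in seq_along(runs)) {
      rows <- runs[[ri]]
      if (length(rows) < max(2L, min_frames)) next
      tid <- if (length(runs) > 1L) paste0(id, ".", ri) else as.character(id)
      tracks[[length(tracks) + 1L]] <-
        track(tid, as.matrix(sub[rows, coord_cols, drop = FALSE]), dt = dt)
    }
  }
  if (length(tracks) == 0L) stop("no tracks of at least ", min_frames,
                                 " frames in '", path, "'")
  track_set(tracks, condition = condition)
}

#' @rdname read_tracks
#' @param ts a `track_set`.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  rows <- lapply(ts$tracks, function(tr) {
    pos <- tr$positions
    df <- data.frame(track_id = tr$id, frame = seq_len(nrow(pos)) - 1L)
    cbind(df, as.data.frame(pos)[, seq_len(ncol(pos)), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  names(out) <- c("track_id", "frame", c("x", "y", "z")[seq_len(ts$dim)])
  for (cc in names(out)[-(1:2)])  # %.17g survives a read round-trip bit-exactly
    out[[cc]] <- sprintf("%.17g", out[[cc]])
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter a track set by length
#'
#' Mobility statistics need enough frames that the longest fitted delay
#' still has displacement pairs; at dt = 0.02 s the default 26 frames
#' guarantees at least one displacement at tau = 0.5 s.
#'
#' @param ts a `track_set`.
#' @param min_frames minimum frames (default 26).
#' @export
filter_tracks <- function(ts, min_frames = 26L) {
  keep <- n_frames(ts) >= min_frames
  if (!any(keep)) stop("no tracks with at least ", min_frames, " frames")
  track_set(ts$tracks[keep], condition = ts$condition)
}
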