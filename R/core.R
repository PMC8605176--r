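# ---- domain constructors ----------------------------------------------------

#' Timestamped 2D position trace
#'
#' The behavioral substrate for occupancy, speed and spatial binning. Samples
#' are nominally regular (default 30 Hz camera frames); gaps longer than five
#' nominal frame intervals are flagged but retained.
#'
#' @param t Numeric vector of sample times, seconds from session start,
#'   monotone non-decreasing, first sample >= 0.
#' @param x,y Numeric vectors of position in cm (arena frame), same length as
#'   `t`.
#' @param frame_rate Nominal sampling rate in Hz. Default 30.
#' @return An object of class `position_trace`: a list with fields `t`, `x`,
#'   `y`, `frame_rate`, and `gaps` (integer indices i where
#'   `t[i+1] - t[i] > 5 / frame_rate`).
#' @export
position_trace <- function(t, x, y, frame_rate = 30) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have equal length")
  if (length(t) == 0L) stop("empty trace")
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in position trace")
  if (t[1] < 0) stop("t[1] must be >= 0")
  if (any(diff(t) < 0)) stop("t must be monotone non-decreasing")
  gaps <- which(diff(t) > 5 / frame_rate)
  structure(list(t = t, x = x, y = y, frame_rate = frame_rate, gaps = gaps),
            class = "position_trace")
}

#' Spike train for one cell in one session
#'
#' @param spike_times Numeric vector of spike timestamps in seconds, >= 0.
#'   Unsorted input is sorted with a warning; duplicate timestamps are
#'   permitted but flagged.
#' @param cell_id Character scalar, stable across the sessions of a triplet.
#' @return An object of class `spike_train`: list with `times`, `cell_id`,
#'   `n_duplicates`.
#' @export
spike_train <- function(spike_times, cell_id) {
  st <- as.numeric(spike_times)
  if (any(!is.finite(st))) stop("non-finite spike times")
  if (any(st < 0)) stop("negative spike times")
  if (is.unsorted(st)) {
    warning("spike times unsorted; sorting (cell ", cell_id, ")")
    st <- sort(st)
  }
  ndup <- sum(duplicated(st))
  structure(list(times = st, cell_id = as.character(cell_id),
                 n_duplicates = ndup),
            class = "spike_train")
}

#' Recording arena geometry
#'
#' @param shape One of `"square"`, `"rectangle"`, `"circle"`, `"none"`
#'   (`"none"` = wall-less platform of the stated extent).
#' @param extent_cm Numeric: side (square/none), c(width, height) (rectangle),
#'   or diameter (circle), in cm. Must be > 0.
#' @param rotation_deg Rotation of the arena relative to the room frame,
#'   degrees. Default 0.
#' @return An `arena` object.
#' @export
arena <- function(shape = c("square", "rectangle", "circle", "none"),
                  extent_cm = 125, rotation_deg = 0) {
  shape <- match.arg(shape)
  if (any(extent_cm <= 0)) stop("extent must be > 0")
  if (shape == "rectangle" && length(extent_cm) == 1L)
    extent_cm <- rep(extent_cm, 2L)
  structure(list(shape = shape, extent_cm = as.numeric(extent_cm),
                 rotation_deg = as.numeric(rotation_deg)),
            class = "arena")
}

# bounding box of an arena in cm, c(width, height)
arena_bbox <- function(a) {
  switch(a$shape,
         square    = c(a$extent_cm[1], a$extent_cm[1]),
         none      = c(a$extent_cm[1], a$extent_cm[1]),
         rectangle = a$extent_cm[1:2],
         circle    = c(a$extent_cm[1], a$extent_cm[1]))
}

#' A single recording session
#'
#' @param condition `"pre"`, `"manipulation"`, or `"post"`.
#' @param manipulation_type The manipulation family of the triplet this
#'   session belongs to: `"object"`, `"rotation"`, `"circle"`, `"expansion"`,
#'   `"no_walls"`, or `"baseline"`.
#' @param arena An [arena()] object.
#' @param trace A [position_trace()].
#' @param spikes Named list of [spike_train()] objects (names = cell ids).
#' @param duration Session duration in seconds; all spikes must be <= this.
#' @return A `session` object.
#' @export
session <- function(condition = c("pre", "manipulation", "post"),
                    manipulation_type = c("object", "rotation", "circle",
                                          "expansion", "no_walls", "baseline"),
                    arena, trace, spikes, duration) {
  condition <- match.arg(condition)
  manipulation_type <- match.arg(manipulation_type)
  stopifnot(inherits(arena, "arena"), inherits(trace, "position_trace"))
  if (is.null(names(spikes)) && length(spikes) > 0)
    names(spikes) <- vapply(spikes, function(s) s$cell_id, character(1))
  for (s in spikes) {
    if (!inherits(s, "spike_train")) stop("spikes must be spike_train objects")
    if (length(s$times) && max(s$times) > duration)
      stop("spike time ", max(s$times), " exceeds session duration ",
           duration, " (cell ", s$cell_id, ")")
  }
  structure(list(condition = condition,
                 manipulation_type = manipulation_type,
                 arena = arena, trace = trace, spikes = spikes,
                 duration = as.numeric(duration)),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %s / %s: %.1f s, %d cells, %d position samples\n",
              x$condition, x$manipulation_type, x$duration,
              length(x$spikes), length(x$trace$t)))
  invisible(x)
}

# ---- session directory I/O --------------------------------------------------

#' Write a session to a directory
#'
#' The on-disk layout is `tracking.csv` (columns `t,x,y`; seconds, cm),
#' `spikes.json` (object: cell id -> array of spike seconds) and `meta.json`
#' (condition, manipulation_type, arena, duration_s, frame_rate).
#'
#' @param s A `session`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  stopifnot(inherits(s, "session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(t = s$trace$t, x = s$trace$x, y = s$trace$y),
                   file.path(path, "tracking.csv"), row.names = FALSE)
  sp <- lapply(s$spikes, function(tr) tr$times)
  jsonlite::write_json(sp, file.path(path, "spikes.json"),
                       digits = NA, auto_unbox = FALSE)
  meta <- list(condition = s$condition,
               manipulation_type = s$manipulation_type,
               arena = list(shape = s$arena$shape,
                            extent_cm = s$arena$extent_cm,
                            rotation_deg = s$arena$rotation_deg),
               duration_s = s$duration,
               frame_rate = s$trace$frame_rate)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a session from a directory
#'
#' Reads the layout written by [write_session()]. Unsorted spike trains are
#' sorted with a warning; a spike timestamp beyond the session duration is a
#' validation error. Tracking gaps longer than five nominal frame intervals
#' are reported in the trace's `gaps` field.
#'
#' @param path Directory containing `tracking.csv`, `spikes.json`,
#'   `meta.json`.
#' @return A validated `session` (units: seconds, cm).
#' @export
load_session <- function(path) {
  need <- c("tracking.csv", "spikes.json", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("session at '", path, "' is missing file(s): ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  trk <- utils::read.csv(file.path(path, "tracking.csv"))
  if (!all(c("t", "x", "y") %in% names(trk)))
    stop("tracking.csv must have columns t,x,y")
  fr <- if (!is.null(meta$frame_rate)) meta$frame_rate else 30
  trace <- position_trace(trk$t, trk$x, trk$y, frame_rate = fr)
  spk <- jsonlite::read_json(file.path(path, "spikes.json"),
                             simplifyVector = TRUE)
  if (length(spk) == 0) spk <- stats::setNames(list(), character(0))
  spikes <- lapply(names(spk), function(id)
    spike_train(as.numeric(spk[[id]]), id))
  names(spikes) <- names(spk)
  ar <- arena(meta$arena$shape, meta$arena$extent_cm, meta$arena$rotation_deg)
  session(condition = meta$condition,
          manipulation_type = meta$manipulation_type,
          arena = ar, trace = trace, spikes = spikes,
          duration = meta$duration_s)
}

# ---- truncation and triplet validation --------------------------------------

#' Truncate a session to the common analysis window
#'
#' All analyses run on the first `t_max` seconds of each recording (765 s, the
#' duration of the shortest session in the design). Retention is half-open:
#' position samples and spikes with time strictly below `t_max` are kept, so a
#' spike at exactly `t_max` is dropped. Idempotent.
#'
#' @param s A `session` with `duration >= t_max`.
#' @param t_max Analysis window in seconds. Default 765.
#' @return The truncated `session` with `duration = t_max`.
#' @export
truncate_session <- function(s, t_max = 765) {
  stopifnot(inherits(s, "session"))
  if (s$duration < t_max)
    stop("session too short for inclusion: duration ", s$duration,
         " < ", t_max, " s")
  keep <- s$trace$t < t_max
  trace <- position_trace(s$trace$t[keep], s$trace$x[keep], s$trace$y[keep],
                          frame_rate = s$trace$frame_rate)
  spikes <- lapply(s$spikes, function(tr)
    spike_train(tr$times[tr$times < t_max], tr$cell_id))
  names(spikes) <- names(s$spikes)
  session(condition = s$condition, manipulation_type = s$manipulation_type,
          arena = s$arena, trace = trace, spikes = spikes, duration = t_max)
}

#' Assemble and validate an A-B-A' session triplet
#'
#' Cells entering the three-session classifier must be present in all three
#' sessions; the roster is the intersection of cell ids. Cells present in only
#' a subset are excluded with a logged reason (they remain loadable in the
#' individual sessions). All three sessions are truncated to the same analysis
#' window.
#'
#' @param pre,manip,post `session` objects with conditions pre, manipulation,
#'   post and the same manipulation family.
#' @param t_max Common analysis window (seconds). Default 765.
#' @return A `session_triplet`: list with `pre`, `manip`, `post`,
#'   `cell_roster` (sorted character vector), `excluded` (data.frame of
#'   cell_id, reason), `manipulation_type`.
#' @export
validate_triplet <- function(pre, manip, post, t_max = 765) {
  stopifnot(inherits(pre, "session"), inherits(manip, "session"),
            inherits(post, "session"))
  if (pre$condition != "pre" || manip$condition != "manipulation" ||
      post$condition != "post")
    stop("sessions must have conditions pre / manipulation / post in order")
  mt <- unique(c(pre$manipulation_type, manip$manipulation_type,
                 post$manipulation_type))
  mt <- setdiff(mt, "baseline")
  if (length(mt) > 1)
    stop("mismatched manipulation_type across sessions: ",
         paste(mt, collapse = ", "))
  if (length(mt) == 0) mt <- "baseline"
  ids <- lapply(list(pre, manip, post), function(s) names(s$spikes))
  roster <- sort(Reduce(intersect, ids))
  all_ids <- sort(unique(unlist(ids)))
  dropped <- setdiff(all_ids, roster)
  excluded <- data.frame(cell_id = dropped,
                         reason = vapply(dropped, function(id) {
                           present <- c("pre", "manip", "post")[
                             vapply(ids, function(v) id %in% v, logical(1))]
                           paste0("absent from ",
                                  paste(setdiff(c("pre", "manip", "post"),
                                                present), collapse = "+"))
                         }, character(1)),
                         stringsAsFactors = FALSE)
  if (length(roster) == 0)
    warning("empty cell roster: no cell present in all three sessions")
  structure(list(pre = truncate_session(pre, t_max),
                 manip = truncate_session(manip, t_max),
                 post = truncate_session(post, t_max),
                 cell_roster = roster, excluded = excluded,
                 manipulation_type = mt),
            class = "session_triplet")
}

#' @export
print.session_triplet <- function(x, ...) {
  cat(sprintf("<session_triplet> %s: %d roster cells (%d excluded), %.1f s window\n",
              x$manipulation_type, length(x$cell_roster), nrow(x$excluded),
              x$pre$duration))
  invisible(x)
}

#' Write a triplet to three session directories plus a manifest
#'
#' @param trip A `session_triplet`.
#' @param path Output directory; sessions are written to `pre/`, `manip/`,
#'   `post/` inside it and a `manifest.json` lists them in A, B, A' order.
#' @return Path to the manifest, invisibly.
#' @export
write_triplet <- function(trip, path) {
  stopifnot(inherits(trip, "session_triplet"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_session(trip$pre, file.path(path, "pre"))
  write_session(trip$manip, file.path(path, "manip"))
  write_session(trip$post, file.path(path, "post"))
  manifest <- list(sessions = c("pre", "manip", "post"))
  mf <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  invisible(mf)
}

#' Load a triplet from a manifest
#'
#' @param manifest Path to a `manifest.json` listing three session directories
#'   (relative to the manifest's directory) in A, B, A' order.
#' @param t_max Analysis window passed to [validate_triplet()].
#' @return A `session_triplet`.
#' @export
load_triplet <- function(manifest, t_max = 765) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  base <- dirname(manifest)
  ss <- lapply(file.path(base, m$sessions), load_session)
  validate_triplet(ss[[1]], ss[[2]], ss[[3]], t_max = t_max)
}
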