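#' Assemble a tracking dataset
#'
#' Bundles a table of localizations, a table of cell geometries, and the
#' acquisition parameters into a single object used by every downstream
#' stage. Localizations carry a trajectory id, a cell id, an experiment id, a
#' frame index, and x/y positions in micrometers in the image frame (origin
#' at the image corner; pixel-to-micrometer conversion is the caller's job).
#'
#' @param trajectories data.frame with columns `traj_id`, `cell_id`,
#'   `experiment_id`, `frame`, `x_um`, `y_um` and optionally `loc_sd_um`
#'   (per-point localization standard deviation, micrometers).
#' @param cells data.frame with columns `cell_id`, `experiment_id`,
#'   `center_x_um`, `center_y_um`, `orientation_rad`, `length_um`,
#'   `width_um`. Length is pole-to-pole, width is the diameter; the record
#'   is invalid unless `length_um >= width_um > 0`.
#' @param frame_interval camera frame interval in seconds.
#' @param pulse_duration laser pulse (stroboscopic exposure) duration in
#'   seconds; must satisfy `0 < pulse_duration <= frame_interval`.
#' @param condition optional condition label.
#' @return An object of class `spt_dataset`.
#' @seealso [read_trajectories()], [filter_trajectories()]
#' @export
spt_dataset <- function(trajectories, cells, frame_interval, pulse_duration,
                        condition = NA_character_) {
  req <- c("traj_id", "cell_id", "experiment_id", "frame", "x_um", "y_um")
  miss <- setdiff(req, names(trajectories))
  if (length(miss))
    stop("trajectory table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  creq <- c("cell_id", "experiment_id", "center_x_um", "center_y_um",
            "orientation_rad", "length_um", "width_um")
  cmiss <- setdiff(creq, names(cells))
  if (length(cmiss))
    stop("cell table is missing required column(s): ",
         paste(cmiss, collapse = ", "), call. = FALSE)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive number of seconds", call. = FALSE)
  if (!is.numeric(pulse_duration) || pulse_duration <= 0 ||
      pulse_duration > frame_interval)
    stop("pulse_duration must satisfy 0 < pulse_duration <= frame_interval",
         call. = FALSE)
  if (any(trajectories$frame < 0))
    stop("frame indices must be non-negative", call. = FALSE)
  if (!is.null(trajectories$loc_sd_um) &&
      any(trajectories$loc_sd_um < 0, na.rm = TRUE))
    stop("loc_sd_um must be non-negative", call. = FALSE)
  if (any(cells$width_um <= 0) || any(cells$length_um < cells$width_um))
    stop("cell geometry must satisfy length_um >= width_um > 0", call. = FALSE)

  trajectories$frame <- as.integer(trajectories$frame)
  trajectories$traj_id <- as.character(trajectories$traj_id)
  trajectories$cell_id <- as.character(trajectories$cell_id)
  trajectories$experiment_id <- as.character(trajectories$experiment_id)
  cells$cell_id <- as.character(cells$cell_id)
  cells$experiment_id <- as.character(cells$experiment_id)

  # frames strictly increasing within each trajectory, in storage order
  sp <- split(trajectories$frame, trajectories$traj_id)
  bad <- names(sp)[vapply(sp, function(f) any(diff(f) <= 0), logical(1))]
  if (length(bad))
    stop("frames are not strictly increasing within trajectory: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)

  unresolved <- setdiff(unique(trajectories$cell_id), cells$cell_id)
  if (length(unresolved))
    stop("trajectory cell_id(s) with no cell record: ",
         paste(utils::head(unresolved, 5), collapse = ", "), call. = FALSE)
  noexp <- setdiff(unique(trajectories$experiment_id), cells$experiment_id)
  if (length(noexp))
    stop("trajectory experiment_id(s) absent from cell table: ",
         paste(utils::head(noexp, 5), collapse = ", "), call. = FALSE)

  structure(list(trajectories = trajectories, cells = cells,
                 frame_interval = frame_interval,
                 pulse_duration = pulse_duration,
                 condition = condition),
            class = "spt_dataset")
}

#' @exportS3Method base::print
print.spt_dataset <- function(x, ...) {
  nt <- length(unique(x$trajectories$traj_id))
  cat("spt_dataset:", nt, "trajectories,",
      nrow(x$trajectories), "localizations,",
      nrow(x$cells), "cells,",
      length(unique(x$cells$experiment_id)), "experiment(s)\n")
  cat(sprintf("  frame interval %.4g ms, pulse %.4g ms",
              1e3 * x$frame_interval, 1e3 * x$pulse_duration))
  if (!is.na(x$condition)) cat(", condition:", x$condition)
  cat("\n")
  invisible(x)
}

#' Read trajectory and cell tables from CSV
#'
#' Parses the on-disk dialect: the trajectory file has header
#' `traj_id,cell_id,experiment_id,frame,x_um,y_um[,loc_sd_um]` and the cell
#' file `cell_id,experiment_id,center_x_um,center_y_um,orientation_rad,length_um,width_um`
#' (UTF-8, "." decimal separator). No length filtering is applied on read,
#' but a trajectory whose consecutive localizations are separated by more
#' than `max_gap` missing frames is either rejected with an error (default,
#' matching tracking software that terminates a track at such a gap) or
#' split into separate trajectories (`on_gap_violation = "split"`).
#'
#' @param path trajectory CSV path.
#' @param cells_path cell-geometry CSV path.
#' @param frame_interval,pulse_duration acquisition parameters in seconds
#'   (e.g. 0.005 and 0.003 for 3 ms pulses in 5 ms frames).
#' @param max_gap largest tolerated number of consecutive missing frames
#'   between two localizations (default 3).
#' @param on_gap_violation `"reject"` (default) or `"split"`.
#' @param condition optional condition label.
#' @return An [spt_dataset()].
#' @export
read_trajectories <- function(path, cells_path, frame_interval, pulse_duration,
                              max_gap = 3, on_gap_violation = c("reject", "split"),
                              condition = NA_character_) {
  on_gap_violation <- match.arg(on_gap_violation)
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  if (!file.exists(cells_path)) stop("cell file not found: ", cells_path, call. = FALSE)
  traj <- utils::read.csv(path, stringsAsFactors = FALSE)
  cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE)

  req <- c("traj_id", "cell_id", "experiment_id", "frame", "x_um", "y_um")
  miss <- setdiff(req, names(traj))
  if (length(miss))
    stop("trajectory file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  keep <- stats::complete.cases(traj[, req])
  if (any(!keep)) {
    message("read_trajectories: rejected ", sum(!keep), " malformed row(s)")
    traj <- traj[keep, , drop = FALSE]
  }
  traj$frame <- as.integer(traj$frame)

  traj <- .apply_gap_rule(traj, max_gap, on_gap_violation)
  spt_dataset(traj, cells, frame_interval, pulse_duration, condition)
}

.apply_gap_rule <- function(traj, max_gap, on_gap_violation) {
  sp <- split(seq_len(nrow(traj)), traj$traj_id)
  gapv <- vapply(sp, function(ix) {
    f <- traj$frame[ix]
    length(f) > 1 && any(diff(f) - 1L > max_gap)
  }, logical(1))
  if (!any(gapv)) return(traj)
  if (on_gap_violation == "reject") {
    stop("gap larger than ", max_gap, " frames within trajectory: ",
         paste(utils::head(names(sp)[gapv], 5), collapse = ", "), call. = FALSE)
  }
  # split at offending gaps, suffixing new segment ids
  pieces <- lapply(names(sp), function(id) {
    ix <- sp[[id]]
    d <- traj[ix, , drop = FALSE]
    if (!gapv[[id]]) return(d)
    brk <- cumsum(c(0L, as.integer(diff(d$frame) - 1L > max_gap)))
    d$traj_id <- paste0(d$traj_id, ".s", brk + 1L)
    d
  })
  do.call(rbind, pieces)
}

#' Write a dataset back to the CSV dialect
#'
#' @param ds an [spt_dataset()].
#' @param path,cells_path output CSV paths.
#' @return `ds`, invisibly.
#' @export
write_trajectories <- function(ds, path, cells_path) {
  stopifnot(inherits(ds, "spt_dataset"))
  utils::write.csv(ds$trajectories, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$cells, cells_path, row.names = FALSE, quote = FALSE)
  invisible(ds)
}

#' Filter trajectories by length and gap structure
#'
#' Retains trajectories with strictly more than `min_length` localizations
#' (the convention "longer than 5 frames" keeps tracks of 6 or more points)
#' whose inter-localization gaps never exceed `max_gap` missing frames.
#'
#' @param ds an [spt_dataset()].
#' @param min_length minimum length; strict inequality (default 5).
#' @param max_gap largest tolerated gap in missing frames (default 3).
#' @return The filtered [spt_dataset()]; counts removed are reported via
#'   `message()`. Filtering is idempotent.
#' @export
filter_trajectories <- function(ds, min_length = 5, max_gap = 3) {
  stopifnot(inherits(ds, "spt_dataset"))
  traj <- ds$trajectories
  sp <- split(seq_len(nrow(traj)), traj$traj_id)
  ok <- vapply(sp, function(ix) {
    f <- traj$frame[ix]
    length(f) > min_length && (length(f) < 2 || all(diff(f) - 1L <= max_gap))
  }, logical(1))
  removed <- sum(!ok)
  if (removed > 0)
    message("filter_trajectories: removed ", removed, " of ", length(ok),
            " trajectories")
  keep_rows <- sort(unlist(sp[ok], use.names = FALSE))
  out <- ds
  out$trajectories <- traj[keep_rows, , drop = FALSE]
  rownames(out$trajectories) <- NULL
  if (nrow(out$trajectories) == 0)
    warning("no trajectories left after filtering", call. = FALSE)
  out
}

#' Keep cells (and their trajectories) within a length window
#'
#' Size-based sorting used before building spatial maps, to exclude newly
#' divided (short) cells and long pre-division cells whose nucleoid layout
#' differs; the window is inclusive at both ends.
#'
#' @param ds an [spt_dataset()].
#' @param min_len,max_len window on the pole-to-pole cell length, micrometers.
#' @return The filtered [spt_dataset()].
#' @export
sort_cells_by_size <- function(ds, min_len = 0, max_len = Inf) {
  stopifnot(inherits(ds, "spt_dataset"))
  keep <- ds$cells$length_um >= min_len & ds$cells$length_um <= max_len
  removed <- sum(!keep)
  if (removed > 0)
    message("sort_cells_by_size: removed ", removed, " of ", length(keep),
            " cells")
  out <- ds
  out$cells <- ds$cells[keep, , drop = FALSE]
  tr_keep <- ds$trajectories$cell_id %in% out$cells$cell_id
  out$trajectories <- ds$trajectories[tr_keep, , drop = FALSE]
  rownames(out$cells) <- NULL
  rownames(out$trajectories) <- NULL
  out
}

# Internal: per-trajectory displacement table used by the likelihood.
# Returns a list with vectors r2 (squared 2D displacement), span (frames
# spanned by each displacement), extra (per-step additive localization
# variance from per-point loc_sd, or NULL), tstart/tlen (0-based step
# offsets and counts per trajectory), and ids.
.step_table <- function(ds) {
  traj <- ds$trajectories
  sp <- split(seq_len(nrow(traj)), traj$traj_id)
  # drop trajectories with <2 localizations (no displacement)
  len <- lengths(sp)
  if (any(len < 2)) {
    warning(sum(len < 2), " trajectory(ies) with <2 localizations skipped",
            call. = FALSE)
    sp <- sp[len >= 2]
  }
  if (!length(sp)) stop("no trajectory with at least one displacement", call. = FALSE)
  has_sd <- !is.null(traj$loc_sd_um) && !anyNA(traj$loc_sd_um)
  pieces <- lapply(sp, function(ix) {
    dx <- diff(traj$x_um[ix]); dy <- diff(traj$y_um[ix])
    span <- diff(traj$frame[ix])
    extra <- if (has_sd) {
      s <- traj$loc_sd_um[ix]
      s[-length(s)]^2 + s[-1]^2
    } else NULL
    list(r2 = dx^2 + dy^2, span = as.integer(span), extra = extra)
  })
  nst <- vapply(pieces, function(p) length(p$r2), integer(1))
  list(r2 = unlist(lapply(pieces, `[[`, "r2"), use.names = FALSE),
       span = unlist(lapply(pieces, `[[`, "span"), use.names = FALSE),
       extra = if (has_sd)
         unlist(lapply(pieces, `[[`, "extra"), use.names = FALSE) else NULL,
       tstart = as.integer(cumsum(c(0L, nst[-length(nst)]))),
       tlen = as.integer(nst),
       traj_id = names(sp),
       loc_index = unlist(sp, use.names = FALSE))
}
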