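#' Map localizations into normalized cell coordinates
#'
#' Rotates each localization into its cell's frame and rescales so the long
#' axis spans `u` in \[-1, 1\] and the short axis `v` in \[-1, 1\]. Points
#' falling farther than `1 + tol` outside the outline in either coordinate
#' (localization error can place points slightly outside) are excluded with
#' a reported count.
#'
#' @param ds an [spt_dataset()].
#' @param tol tolerance beyond the outline (default 0.05).
#' @return data.frame with `traj_id`, `cell_id`, `frame`, `u`, `v`, and
#'   `loc_row` (row index into `ds$trajectories`).
#' @export
normalize_positions <- function(ds, tol = 0.05) {
  stopifnot(inherits(ds, "spt_dataset"))
  traj <- ds$trajectories
  cells <- ds$cells
  ci <- match(traj$cell_id, cells$cell_id)
  th <- cells$orientation_rad[ci]
  dx <- traj$x_um - cells$center_x_um[ci]
  dy <- traj$y_um - cells$center_y_um[ci]
  xp <- cos(-th) * dx - sin(-th) * dy
  yp <- sin(-th) * dx + cos(-th) * dy
  u <- 2 * xp / cells$length_um[ci]
  v <- 2 * yp / cells$width_um[ci]
  keep <- abs(u) <= 1 + tol & abs(v) <= 1 + tol
  if (any(!keep))
    message("normalize_positions: excluded ", sum(!keep),
            " point(s) outside the cell outline")
  data.frame(traj_id = traj$traj_id[keep], cell_id = traj$cell_id[keep],
             frame = traj$frame[keep], u = u[keep], v = v[keep],
             loc_row = which(keep), stringsAsFactors = FALSE)
}

#' Class-resolved spatial occupancy map
#'
#' Builds a 2D histogram of localizations over normalized cell coordinates
#' `(u, v)`, each localization weighted by its posterior probability of
#' belonging to the selected coarse class under the fitted model (soft
#' assignment; `mode = "viterbi"` switches to hard maximum-posterior
#' assignment). With `normalize = "class"` the grid sums to 1; `"none"`
#' returns raw posterior mass, which is additive across nested classes.
#'
#' @param ds an [spt_dataset()].
#' @param fit a [dhmm()] fit.
#' @param thresholds coarse-graining thresholds, um^2/s.
#' @param class label or index of the class to map.
#' @param bins `c(nu, nv)` grid size along the long and short axis
#'   (default `c(50, 25)`).
#' @param fold quadrant folding: average the four mirror images.
#' @param mode `"posterior"` (soft weights) or `"viterbi"` (hard).
#' @param normalize `"class"` (sum 1), `"none"` (raw mass), or `"total"`
#'   (divide by the number of mapped localizations).
#' @return Matrix of `bins[2]` rows (v bins) by `bins[1]` columns (u bins),
#'   class `spt_heatmap`, with `u_breaks`/`v_breaks` attributes.
#' @export
occupancy_heatmap <- function(ds, fit, thresholds = c(1, 8), class = "bound",
                              bins = c(50, 25), fold = FALSE,
                              mode = c("posterior", "viterbi"),
                              normalize = c("class", "none", "total")) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  cg <- coarse_grain(fit, thresholds)
  if (is.character(class)) {
    gi <- match(class, cg$classes$label)
    if (is.na(gi)) stop("unknown class label: ", class, call. = FALSE)
  } else gi <- as.integer(class)

  post <- posterior(fit, ds)
  locp <- as.matrix(post$localizations[, -1, drop = FALSE])
  if (mode == "viterbi") {
    hard <- max.col(locp)
    locp <- matrix(0, nrow(locp), ncol(locp))
    locp[cbind(seq_len(nrow(locp)), hard)] <- 1
  }
  w_all <- rowSums(locp[, cg$membership == gi, drop = FALSE])

  np <- normalize_positions(ds)
  wi <- match(np$loc_row, post$localizations$loc_row)
  ok <- !is.na(wi)
  np <- np[ok, , drop = FALSE]
  w <- w_all[wi[ok]]
  if (!nrow(np) || sum(w) <= 0)
    stop("empty class selection: no posterior mass to map", call. = FALSE)

  ub <- seq(-1, 1, length.out = bins[1] + 1)
  vb <- seq(-1, 1, length.out = bins[2] + 1)
  iu <- pmin(pmax(findInterval(np$u, ub, all.inside = TRUE), 1), bins[1])
  iv <- pmin(pmax(findInterval(np$v, vb, all.inside = TRUE), 1), bins[2])
  grid <- matrix(0, bins[2], bins[1])
  for (i in seq_along(w)) grid[iv[i], iu[i]] <- grid[iv[i], iu[i]] + w[i]
  if (fold) {
    grid <- (grid + grid[rev(seq_len(bins[2])), ] +
               grid[, rev(seq_len(bins[1]))] +
               grid[rev(seq_len(bins[2])), rev(seq_len(bins[1]))]) / 4
  }
  if (normalize == "class") grid <- grid / sum(grid)
  else if (normalize == "total") grid <- grid / length(w)
  structure(grid, u_breaks = ub, v_breaks = vb, class_label = cg$classes$label[gi],
            class = c("spt_heatmap", "matrix", "array"))
}

#' Plot an occupancy map (untested decoration)
#'
#' @param x an `spt_heatmap`.
#' @param ... passed to [graphics::image()].
#' @export
plot.spt_heatmap <- function(x, ...) {
  graphics::image(attr(x, "u_breaks"), attr(x, "v_breaks"),
                  t(unclass(x)), xlab = "u (long axis)",
                  ylab = "v (short axis)",
                  main = attr(x, "class_label"), useRaster = TRUE, ...)
  invisible(x)
}

#' Write a heatmap as a CSV matrix (row = v bin)
#'
#' @param x an `spt_heatmap`.
#' @param path output path.
#' @export
write_heatmap <- function(x, path) {
  utils::write.table(unclass(x), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(x)
}
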