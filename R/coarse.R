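#' Coarse-grain a fitted model into labeled classes
#'
#' Lumps the K fitted diffusion states into classes delimited by
#' diffusion-coefficient thresholds (a state exactly at a threshold joins
#' the slower class). Class occupancy is the sum of member stationary
#' occupancies; the class-to-class steady-state flux is
#' `sum_{i in G, j in H} pi_i A_ij / dt` (events per second per molecule);
#' the mean dwell time of a class is its occupancy divided by its total
#' outward flux. Dwell times are therefore derived from fitted transition
#' frequencies at stationarity, not from observed binding-segment durations,
#' which allows dwells longer than the typical trajectory.
#'
#' @param fit a [dhmm()] fit.
#' @param thresholds strictly increasing diffusion thresholds, um^2/s.
#'   The defaults of tracking studies are `1` (bound/free) or `c(1, 8)`
#'   (bound/free/cleavage artifact).
#' @param labels class labels, one more than thresholds. Defaults:
#'   `("bound","free")` for one threshold, `("bound","free","artifact")` for
#'   two, otherwise `class_1..n`.
#' @return An object of class `coarse_dhmm`: classes, membership map,
#'   per-class `occ`, `dwell` (s; `NA` and flagged for empty classes),
#'   `flux` matrix (1/s), and the class-resolved transition matrix.
#' @export
coarse_grain <- function(fit, thresholds = c(1, 8), labels = NULL) {
  stopifnot(inherits(fit, "dhmm"))
  thresholds <- as.numeric(thresholds)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  nc <- length(thresholds) + 1L
  if (is.null(labels)) {
    labels <- if (nc == 2) c("bound", "free")
    else if (nc == 3 && isTRUE(all.equal(thresholds, c(1, 8))))
      c("bound", "free", "artifact")
    else paste0("class_", seq_len(nc))
  }
  if (length(labels) != nc)
    stop("need ", nc, " labels for ", length(thresholds), " thresholds",
         call. = FALSE)
  # closed-left classes: D in (thr[i-1], thr[i]]
  member <- findInterval(fit$D, thresholds, left.open = TRUE) + 1L
  occ <- vapply(seq_len(nc), function(g) sum(fit$pi[member == g]), numeric(1))

  flux <- matrix(0, nc, nc, dimnames = list(labels, labels))
  for (g in seq_len(nc)) for (h in seq_len(nc)) {
    if (g == h) next
    ig <- which(member == g); ih <- which(member == h)
    if (length(ig) && length(ih))
      flux[g, h] <- sum(fit$pi[ig] * rowSums(fit$A[ig, ih, drop = FALSE])) / fit$dt
  }
  outflux <- rowSums(flux)
  dwell <- ifelse(occ > 0 & outflux > 0, occ / outflux, NA_real_)
  empty <- occ <= 0
  if (any(empty))
    warning("class(es) with zero occupancy: ",
            paste(labels[empty], collapse = ", "),
            "; dwell reported as NA", call. = FALSE)
  names(occ) <- names(dwell) <- names(empty) <- labels
  structure(list(classes = data.frame(label = labels,
                                      D_lo = c(0, thresholds),
                                      D_hi = c(thresholds, Inf)),
                 thresholds = thresholds,
                 membership = member, occ = occ, dwell = dwell, flux = flux,
                 empty = empty, dt = fit$dt, K = fit$K, D = fit$D,
                 condition = fit$condition),
            class = "coarse_dhmm")
}

#' Split the bound cluster into sub-states
#'
#' Convenience wrapper over [coarse_grain()] with the finer default
#' threshold set `(0.05, 0.25, 1, 8)` um^2/s separating very slow
#' (nucleoid-associated) binding, factor on an mRNA-engaged 30S, factor on a
#' free 30S, freely diffusing factor, and fast cleavage artifacts.
#'
#' @param fit a [dhmm()] fit.
#' @param thresholds strictly increasing thresholds, um^2/s.
#' @param labels optional labels (thresholds + 1 entries).
#' @return A `coarse_dhmm`.
#' @export
subcluster_split <- function(fit, thresholds = c(0.05, 0.25, 1, 8),
                             labels = NULL) {
  if (is.null(labels) && length(thresholds) == 4)
    labels <- c("very_slow", "bound_mRNA", "bound_30S", "free", "artifact")
  coarse_grain(fit, thresholds = thresholds, labels = labels)
}

#' @exportS3Method base::print
print.coarse_dhmm <- function(x, ...) {
  cat("Coarse-grained model (", x$K, " states -> ",
      nrow(x$classes), " classes)\n", sep = "")
  tab <- data.frame(class = x$classes$label,
                    D_interval = sprintf("(%.3g, %.3g]",
                                         x$classes$D_lo, x$classes$D_hi),
                    occupancy = signif(x$occ, 4),
                    dwell_s = signif(x$dwell, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Segment-duration dwell estimator (for comparison)
#'
#' Estimates per-class dwell times from the durations of complete visits
#' (runs that both start and end inside a trajectory) of the
#' maximum-posterior class path. Unlike the flux-based dwell of
#' [coarse_grain()], this estimator cannot see events longer than the
#' trajectories and is biased low whenever the true dwell approaches the
#' trajectory length; it is provided to make that bias measurable.
#'
#' @param fit a [dhmm()] fit.
#' @param ds the dataset.
#' @param thresholds coarse-graining thresholds.
#' @return Named numeric vector of mean complete-segment durations (s);
#'   `NA` for classes without complete segments.
#' @export
dwell_segments <- function(fit, ds, thresholds = c(1, 8)) {
  cg <- coarse_grain(fit, thresholds)
  post <- posterior(fit, ds)
  state_hat <- max.col(as.matrix(post$steps[, -1, drop = FALSE]))
  class_hat <- cg$membership[state_hat]
  ids <- post$steps$traj_id
  nc <- nrow(cg$classes)
  durs <- vector("list", nc)
  for (tr in split(seq_along(class_hat), ids)) {
    r <- rle(class_hat[tr])
    n <- length(r$lengths)
    if (n <= 2) next
    inner <- 2:(n - 1)  # censored first/last runs excluded
    for (i in inner)
      durs[[r$values[i]]] <- c(durs[[r$values[i]]], r$lengths[i])
  }
  out <- vapply(durs, function(d)
    if (length(d)) mean(d) * fit$dt else NA_real_, numeric(1))
  names(out) <- cg$classes$label
  out
}
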