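#' Factor cycle time
#'
#' Average duration of one bound-plus-free cycle of a factor. At steady
#' state the bound occupancy is `tau_bound / (tau_bound + tau_free)`, so the
#' cycle time `tau_bound + tau_free` equals `dwell_bound / occ_bound`.
#'
#' @param occ_bound stationary bound-state occupancy, in (0, 1].
#' @param dwell_bound mean bound-state dwell time, seconds (> 0).
#' @return Cycle time in seconds; `NA` with a warning when `occ_bound` is 0.
#' @examples
#' cycle_time(0.47, 0.34)  # ~0.72 s
#' @export
cycle_time <- function(occ_bound, dwell_bound) {
  if (any(occ_bound < 0) || any(occ_bound > 1))
    stop("occ_bound must lie in [0, 1]", call. = FALSE)
  if (any(dwell_bound <= 0, na.rm = TRUE))
    stop("dwell_bound must be positive", call. = FALSE)
  out <- dwell_bound / occ_bound
  if (any(occ_bound == 0)) {
    warning("occ_bound = 0: cycle time undefined", call. = FALSE)
    out[occ_bound == 0] <- NA_real_
  }
  out
}

#' Concentration-scaled cycle-time threshold
#'
#' At steady state the productive cycling time of a factor is proportional
#' to its concentration relative to the ribosomes it serves: with one
#' factor per `1/ratio` ribosomes and a ribosome translation cycle of
#' `ribosome_cycle` seconds, a factor cycling faster than
#' `ratio * min(ribosome_cycle)` must bind more than once per translation
#' cycle. The lower bound of the ribosome-cycle window is used, which makes
#' the flag conservative.
#'
#' @param ratio factor-to-ribosome concentration ratio, in (0, 1].
#' @param ribosome_cycle ribosome translation-cycle time bounds (s),
#'   default `c(10, 17)`.
#' @return Threshold in seconds.
#' @examples
#' cycle_threshold(0.20)  # 2.0 s
#' cycle_threshold(0.25)  # 2.5 s
#' cycle_threshold(0.37)  # 3.7 s
#' @export
cycle_threshold <- function(ratio, ribosome_cycle = c(10, 17)) {
  if (any(ratio <= 0) || any(ratio > 1))
    stop("ratio must lie in (0, 1]", call. = FALSE)
  if (length(ribosome_cycle) < 1 || is.unsorted(ribosome_cycle))
    stop("ribosome_cycle bounds must be ordered", call. = FALSE)
  ratio * ribosome_cycle[1]
}

#' Flag cycling faster than one binding per translation cycle
#'
#' @param cycle measured factor cycle time, seconds.
#' @param threshold output of [cycle_threshold()].
#' @return Logical: `TRUE` when `cycle < threshold`, i.e. the factor must
#'   bind ribosomes more than once per translation cycle.
#' @export
flags_multiple_binding <- function(cycle, threshold) {
  cycle < threshold
}

#' Aggregate coarse-grained replicates into a kinetics summary
#'
#' Takes one coarse-grained model per independent experiment and reports
#' per-class occupancies and dwell times with mean and sample standard
#' deviation computed across experiments (not across pooled steps). The
#' cycle time is computed from the pooled means of the bound-class
#' occupancy and dwell.
#'
#' @param experiments list of [coarse_grain()] results sharing the same
#'   class structure, one per experiment.
#' @param condition condition label.
#' @param bound_class label of the bound class (default `"bound"`, falling
#'   back to the first class).
#' @return An object of class `kinetics_summary` with the per-experiment
#'   table, per-class mean/SD, and `cycle_time` (s).
#' @export
aggregate_kinetics <- function(experiments, condition = NA_character_,
                               bound_class = "bound") {
  if (!length(experiments)) stop("need at least one experiment", call. = FALSE)
  if (!all(vapply(experiments, inherits, logical(1), "coarse_dhmm")))
    stop("experiments must be coarse_dhmm objects", call. = FALSE)
  labels <- experiments[[1]]$classes$label
  for (e in experiments)
    if (!identical(e$classes$label, labels))
      stop("experiments have differing class structures", call. = FALSE)

  per <- do.call(rbind, lapply(seq_along(experiments), function(i) {
    e <- experiments[[i]]
    data.frame(experiment = i, class = labels,
               occ = as.numeric(e$occ), dwell = as.numeric(e$dwell),
               stringsAsFactors = FALSE)
  }))
  n_exp <- length(experiments)
  byclass <- function(x, f) setNames(vapply(labels, function(l)
    f(x[per$class == l]), numeric(1)), labels)
  mean_occ <- byclass(per$occ, mean)
  mean_dwell <- byclass(per$dwell, function(x) mean(x, na.rm = TRUE))
  if (n_exp >= 2) {
    sd_occ <- byclass(per$occ, stats::sd)
    sd_dwell <- byclass(per$dwell, function(x) stats::sd(x, na.rm = TRUE))
  } else {
    warning("single experiment: SD undefined", call. = FALSE)
    sd_occ <- sd_dwell <- setNames(rep(NA_real_, length(labels)), labels)
  }
  bc <- if (bound_class %in% labels) bound_class else labels[1]
  cyc <- if (is.finite(mean_occ[[bc]]) && mean_occ[[bc]] > 0 &&
             is.finite(mean_dwell[[bc]]))
    cycle_time(mean_occ[[bc]], mean_dwell[[bc]]) else NA_real_
  structure(list(condition = condition, classes = labels,
                 per_experiment = per, n_experiments = n_exp,
                 mean_occ = mean_occ, sd_occ = sd_occ,
                 mean_dwell = mean_dwell, sd_dwell = sd_dwell,
                 bound_class = bc, cycle_time = as.numeric(cyc)),
            class = "kinetics_summary")
}

#' @exportS3Method base::print
print.kinetics_summary <- function(x, ...) {
  cat("Kinetics summary")
  if (!is.na(x$condition)) cat(" [", x$condition, "]", sep = "")
  cat(":", x$n_experiments, "experiment(s)\n")
  tab <- data.frame(class = x$classes,
                    occ = signif(x$mean_occ, 3),
                    occ_sd = signif(x$sd_occ, 2),
                    dwell_s = signif(x$mean_dwell, 3),
                    dwell_sd = signif(x$sd_dwell, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("cycle time (%s): %.3g s\n", x$bound_class, x$cycle_time))
  invisible(x)
}

#' Compare a kinetic quantity between two conditions
#'
#' Two-sided unpaired t-test on per-experiment values of an occupancy or
#' dwell time, with the star coding convention P<0.05 `*`, P<0.01 `**`,
#' P<0.001 `***`, otherwise `ns`. The equal-variance Student test is the
#' default; set `welch = TRUE` for the Welch variant.
#'
#' @param a,b [aggregate_kinetics()] summaries (>= 2 experiments each).
#' @param quantity `"occ"` or `"dwell"`.
#' @param class class label to compare (default the bound class of `a`).
#' @param welch use the Welch (unequal-variance) test.
#' @return A list with `t`, `df`, `p`, `stars`, and the group values.
#' @export
compare_kinetics <- function(a, b, quantity = c("occ", "dwell"),
                             class = NULL, welch = FALSE) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(a, "kinetics_summary"), inherits(b, "kinetics_summary"))
  if (is.null(class)) class <- a$bound_class
  va <- a$per_experiment[a$per_experiment$class == class, quantity]
  vb <- b$per_experiment[b$per_experiment$class == class, quantity]
  va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
  if (length(va) < 2 || length(vb) < 2)
    stop("need at least 2 experiments per group", call. = FALSE)
  tt <- tryCatch(stats::t.test(va, vb, var.equal = !welch),
                 error = function(e) e)
  if (inherits(tt, "error")) {
    # degenerate case: both groups constant
    if (isTRUE(all.equal(mean(va), mean(vb)))) {
      tt <- list(statistic = c(t = 0),
                 parameter = c(df = length(va) + length(vb) - 2),
                 p.value = 1)
    } else stop(conditionMessage(tt), call. = FALSE)
  }
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = p,
       stars = stars, quantity = quantity, class = class,
       group_a = va, group_b = vb)
}
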