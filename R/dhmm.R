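#' Per-dimension displacement variance of a diffusion state
#'
#' Variance of one coordinate of an observed displacement spanning
#' `n_frames` frame intervals, for a molecule diffusing with coefficient `D`
#' under stroboscopic exposure (blur factor `R`) and localized with error SD
#' `sigma_loc` at both end points:
#' `v = 2 D (n dt) (1 - 2 R / n) + 2 sigma_loc^2`.
#' A displacement across a gap of `g` missing frames has `n = g + 1`; the
#' blur correction enters only through the two sampled frames, hence the
#' `1/n` scaling.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param n_frames number of frame intervals spanned (>= 1).
#' @param sigma_loc localization SD, um.
#' @param R blur factor, see [blur_factor()].
#' @param dt frame interval, seconds.
#' @return Variance in um^2 (vectorized over any argument).
#' @export
step_variance <- function(D, n_frames = 1, sigma_loc = 0, R = 0, dt) {
  if (missing(dt) || any(dt <= 0)) stop("dt must be positive", call. = FALSE)
  if (any(n_frames < 1)) stop("n_frames must be >= 1", call. = FALSE)
  2 * D * (n_frames * dt) * (1 - 2 * R / n_frames) + 2 * sigma_loc^2
}

# left stationary vector of a transition matrix
.stationary <- function(A) {
  K <- nrow(A)
  if (K == 1) return(1)
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  p <- Re(e$vectors[, i])
  if (all(p <= 0)) p <- -p
  if (any(p < -1e-8)) { # fall back to power iteration
    p <- rep(1 / K, K)
    for (it in 1:10000) {
      p2 <- as.vector(p %*% A)
      if (max(abs(p2 - p)) < 1e-14) break
      p <- p2
    }
  }
  p <- pmax(p, 0)
  p / sum(p)
}

# powers A^1 .. A^M as a K x K x M array
.A_powers <- function(A, M) {
  K <- nrow(A)
  out <- array(0, c(K, K, M))
  out[, , 1] <- A
  if (M > 1) for (m in 2:M) out[, , m] <- out[, , m - 1] %*% A
  out
}

# log emission matrix: n_steps x K, isotropic bivariate Gaussian
.log_emission <- function(st, D, sigma, Rblur, dt) {
  a <- 2 * st$span * dt * (1 - 2 * Rblur / st$span)
  v <- outer(a, D) + if (is.null(st$extra)) 2 * sigma^2 else
    (2 * sigma^2 + st$extra)
  v <- pmax(v, 1e-12)
  -log(2 * pi * v) - st$r2 / (2 * v)
}

# forward-backward wrapper; st from .step_table()
.fb <- function(st, D, A, pi, sigma, Rblur, dt) {
  M <- max(st$span)
  logB <- .log_emission(st, D, sigma, Rblur, dt)
  fb_cpp(logB, st$tstart, st$tlen, st$span, .A_powers(A, M), pi)
}

#' Log-likelihood of a dataset under a diffusional HMM
#'
#' Sum over trajectories of the forward-algorithm log-likelihood of the
#' observed displacement sequences. Emissions are isotropic bivariate
#' Gaussians with per-dimension variance [step_variance()]; a displacement
#' across a gap of `g` missing frames uses the `g+1`-frame emission variance
#' and the transition operator `A^(g+1)`; the first displacement's state is
#' drawn from the stationary distribution.
#'
#' @param ds an [spt_dataset()] (filtered).
#' @param model a fitted `dhmm` object, or a list with elements `D`, `A`,
#'   `sigma_loc` (and optionally `pi`).
#' @return The total log-likelihood (numeric scalar).
#' @export
dhmm_loglik <- function(ds, model) {
  stopifnot(inherits(ds, "spt_dataset"))
  D <- model$D
  A <- as.matrix(model$A)
  pi_ <- if (!is.null(model$pi)) model$pi else .stationary(A)
  sigma <- model$sigma_loc
  Rblur <- blur_factor(ds$pulse_duration, ds$frame_interval)
  st <- .step_table(ds)
  .fb(st, D, A, pi_, sigma, Rblur, ds$frame_interval)$loglik
}

# expected per-frame transition counts from endpoint pairwise posteriors
# xi (K x K x M, summed per span) through the composite operators A^m
.frame_counts <- function(xi, A, Apow) {
  K <- nrow(A)
  M <- dim(xi)[3]
  C <- matrix(0, K, K)
  I <- diag(K)
  for (m in seq_len(M)) {
    Xi <- xi[, , m]
    if (all(Xi == 0)) next
    if (m == 1) { C <- C + Xi; next }
    Am <- Apow[, , m]
    W <- Xi / pmax(Am, 1e-300)
    W[Xi == 0] <- 0
    S <- matrix(0, K, K)
    for (tt in 0:(m - 1)) {
      Al <- if (tt == 0) I else Apow[, , tt]
      Ar <- if (m - 1 - tt == 0) I else Apow[, , m - 1 - tt]
      S <- S + t(Al) %*% W %*% t(Ar)
    }
    C <- C + A * S
  }
  C
}

# one-dimensional M-step for a state's diffusion coefficient
.opt_D <- function(w, r2, a, base_var, lower = 0, upper = 100) {
  keep <- w > 0
  if (!any(keep)) return(NA_real_)
  w <- w[keep]; r2 <- r2[keep]; a <- a[keep]
  bv <- if (length(base_var) > 1) base_var[keep] else base_var
  f <- function(ld) {
    v <- pmax(a * exp(ld) + bv, 1e-12)
    -sum(w * (-log(v) - r2 / (2 * v)))
  }
  opt <- optimize(f, interval = log(c(1e-6, upper + 1)), tol = 1e-11)
  exp(opt$minimum)
}

.opt_sigma <- function(gamma, r2, a, D, extra) {
  f <- function(ls) {
    s2 <- exp(2 * ls)
    v <- outer(a, D) + 2 * s2 + if (is.null(extra)) 0 else extra
    v <- pmax(v, 1e-12)
    -sum(gamma * (-log(v) - r2 / (2 * v)))
  }
  opt <- optimize(f, interval = log(c(1e-4, 1)), tol = 1e-10)
  exp(opt$minimum)
}

# single EM run from a given initialization
.em_run <- function(st, D, A, sigma, fit_sigma, Rblur, dt, tol, max_iter) {
  K <- length(D)
  a <- 2 * st$span * dt * (1 - 2 * Rblur / st$span)
  pi_ <- .stationary(A)
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    e <- .fb(st, D, A, pi_, sigma, Rblur, dt)
    ll <- e$loglik
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-3)) break
    ll_prev <- ll
    gamma <- e$gamma
    # transition update (K = 1: nothing to do)
    if (K > 1) {
      C <- .frame_counts(e$xi, A, .A_powers(A, max(st$span)))
      rs <- rowSums(C)
      Anew <- A
      ok <- rs > 1e-12
      Anew[ok, ] <- C[ok, , drop = FALSE] / rs[ok]
      A <- Anew
      pi_ <- .stationary(A)
    }
    base <- if (is.null(st$extra)) 2 * sigma^2 else 2 * sigma^2 + st$extra
    for (k in seq_len(K)) {
      Dk <- .opt_D(gamma[, k], st$r2, a, base)
      if (is.finite(Dk)) D[k] <- Dk
    }
    if (fit_sigma)
      sigma <- .opt_sigma(gamma, st$r2, a, D, st$extra)
  }
  e <- .fb(st, D, A, pi_, sigma, Rblur, dt)
  list(D = D, A = A, pi = pi_, sigma = sigma, loglik = e$loglik,
       n_iter = length(ll_trace), ll_trace = ll_trace,
       converged = length(ll_trace) < max_iter)
}

# sort states by ascending D (ties: occupancy descending)
.sort_states <- function(fitres) {
  o <- order(fitres$D, -fitres$pi)
  fitres$D <- fitres$D[o]
  fitres$A <- fitres$A[o, o, drop = FALSE]
  fitres$pi <- fitres$pi[o]
  fitres
}

#' Fit a K-state diffusional hidden Markov model
#'
#' Global maximum-likelihood fit of a K-state diffusion model to all
#' trajectories of a dataset by Baum-Welch expectation maximization, with
#' motion-blur- and localization-error-corrected Gaussian displacement
#' emissions and exact marginalization over detection gaps (transition
#' operator `A^(g+1)` across a gap of `g` frames). The initial state
#' distribution is tied to the stationary vector of the per-frame transition
#' matrix. Several random initializations are run and the highest-likelihood
#' fit is returned, with states sorted by ascending diffusion coefficient.
#'
#' @param ds an [spt_dataset()], already filtered.
#' @param K number of diffusion states.
#' @param n_starts number of random initializations (D log-uniform on
#'   0.005-20 um^2/s, self-transitions uniform on 0.8-0.99).
#' @param seed master seed for the initializations.
#' @param sigma_loc localization error SD in um. `NULL` (default) fits a
#'   single global value; a number fixes it. Per-point `loc_sd_um` values in
#'   the dataset, when present, are used as fixed additive variances and the
#'   global parameter is not fitted.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @return An object of class `dhmm` with elements `K`, `D`, `A`, `pi`,
#'   `sigma_loc`, `R` (blur factor), `dt`, `logL`, `n_params`, `aic`,
#'   `n_steps`, `n_traj`, convergence diagnostics, and the call.
#' @examples
#' sim <- simulate_spt(sim_config(n_traj = 60, mean_traj_len = 15), seed = 1)
#' ds <- filter_trajectories(sim$dataset)
#' fit <- dhmm(ds, K = 2, n_starts = 2, seed = 1, sigma_loc = 0.03)
#' fit
#' @export
dhmm <- function(ds, K, n_starts = 10, seed = 1, sigma_loc = NULL,
                 tol = 1e-8, max_iter = 500) {
  stopifnot(inherits(ds, "spt_dataset"), K >= 1)
  st <- .step_table(ds)
  dt <- ds$frame_interval
  Rblur <- blur_factor(ds$pulse_duration, dt)
  fit_sigma <- is.null(sigma_loc) && is.null(st$extra)
  sigma0 <- if (is.null(sigma_loc)) 0.03 else sigma_loc

  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  diagnostics <- character(0)
  for (s in seq_len(max(1L, n_starts))) {
    D0 <- sort(exp(runif(K, log(0.005), log(20))))
    if (K == 1) {
      A0 <- matrix(1, 1, 1)
    } else {
      selfp <- runif(K, 0.8, 0.99)
      A0 <- matrix((1 - selfp) / (K - 1), K, K)
      diag(A0) <- selfp
    }
    res <- tryCatch(
      .em_run(st, D0, A0, sigma0, fit_sigma, Rblur, dt, tol, max_iter),
      error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(res))
      next
    }
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best))
    stop("no EM initialization converged; diagnostics: ",
         paste(unique(diagnostics), collapse = "; "), call. = FALSE)
  best <- .sort_states(best)
  n_params <- K + K * (K - 1) + as.integer(fit_sigma)
  structure(list(K = K, D = best$D, A = best$A, pi = best$pi,
                 sigma_loc = best$sigma, sigma_fitted = fit_sigma,
                 R = Rblur, dt = dt,
                 logL = best$loglik, n_params = n_params,
                 aic = 2 * n_params - 2 * best$loglik,
                 n_steps = length(st$r2), n_traj = length(st$tlen),
                 n_iter = best$n_iter, converged = best$converged,
                 ll_trace = best$ll_trace,
                 condition = ds$condition, call = match.call()),
            class = "dhmm")
}

#' Akaike information criterion of a fitted diffusion model
#'
#' `AIC = 2 p - 2 logL` with `p = K` diffusion coefficients plus
#' `K (K - 1)` free off-diagonal transition probabilities plus one for the
#' localization SD when it was fitted; the initial distribution is tied to
#' stationarity and contributes no parameters.
#'
#' @param object a `dhmm` fit.
#' @param ... ignored.
#' @param k penalty per parameter (2 for AIC).
#' @return AIC value.
#' @export
AIC.dhmm <- function(object, ..., k = 2) {
  k * object$n_params - 2 * object$logL
}

#' @export
logLik.dhmm <- function(object, ...) {
  structure(object$logL, df = object$n_params, nobs = object$n_steps,
            class = "logLik")
}

#' @export
coef.dhmm <- function(object, ...) {
  list(D = object$D, A = object$A, pi = object$pi,
       sigma_loc = object$sigma_loc)
}

#' @exportS3Method base::print
print.dhmm <- function(x, ...) {
  cat("Diffusional HMM fit:", x$K, "state(s),",
      x$n_traj, "trajectories,", x$n_steps, "steps\n")
  tab <- data.frame(state = seq_len(x$K),
                    D_um2_s = signif(x$D, 4),
                    occupancy = signif(x$pi, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("sigma_loc = %.4g um (%s), logL = %.2f, AIC = %.2f\n",
              x$sigma_loc, if (x$sigma_fitted) "fitted" else "fixed",
              x$logL, x$aic))
  invisible(x)
}

#' @exportS3Method base::summary
summary.dhmm <- function(object, ...) {
  x <- object
  print(x)
  cat("\nPer-frame transition matrix (", 1e3 * x$dt, " ms):\n", sep = "")
  print(signif(x$A, 4))
  dw <- x$dt / pmax(1 - diag(x$A), 1e-300)
  cat("\nPer-state mean dwell (s):", signif(dw, 3), "\n")
  invisible(x)
}

#' Simulate data from a fitted model
#'
#' Draws a synthetic dataset whose generative diffusion coefficients,
#' per-frame switching, and localization error are those of the fit (the
#' per-frame transition matrix is converted to switching rates via its
#' matrix logarithm when possible, otherwise embedded approximately).
#'
#' @param object a `dhmm` fit.
#' @param nsim number of trajectories.
#' @param seed integer seed.
#' @param ... passed on to [sim_config()].
#' @return See [simulate_spt()].
#' @export
simulate.dhmm <- function(object, nsim = 1000, seed = NULL, ...) {
  A <- object$A
  K <- object$K
  if (K == 1) {
    rates <- matrix(0, 1, 1)
  } else {
    Qt <- tryCatch(as.matrix(Matrix::logm(Matrix::Matrix(A))) / object$dt,
                   error = function(e) NULL)
    if (is.null(Qt) || any(Qt[row(Qt) != col(Qt)] < -1e-8)) {
      # approximate embedding from exit probabilities
      rates <- A / object$dt
      diag(rates) <- 0
    } else {
      rates <- pmax(Qt, 0)
      diag(rates) <- 0
    }
  }
  cf <- sim_config(K = K, D = pmax(object$D, 1e-6), rates = rates,
                   frame_interval = object$dt,
                   pulse_duration = 6 * object$R * object$dt,
                   loc_sd = object$sigma_loc, n_traj = nsim, ...)
  simulate_spt(cf, seed = seed)
}

#' Posterior state probabilities
#'
#' Runs the forward-backward recursions under a fitted model and returns
#' per-step (displacement) posterior state probabilities, plus
#' per-localization probabilities obtained by averaging the posteriors of
#' the incident displacements (used for soft spatial weighting).
#'
#' @param fit a `dhmm` object.
#' @param ds the [spt_dataset()] the posteriors are computed on.
#' @return List with `steps` (data.frame: traj_id, posterior matrix columns
#'   `p1..pK`) and `localizations` (row-matched to `ds$trajectories` for
#'   trajectories with >= 2 points, with `loc_row` giving the row index).
#' @export
posterior <- function(fit, ds) {
  stopifnot(inherits(fit, "dhmm"), inherits(ds, "spt_dataset"))
  st <- .step_table(ds)
  e <- .fb(st, fit$D, fit$A, fit$pi, fit$sigma_loc, fit$R, ds$frame_interval)
  gamma <- e$gamma
  colnames(gamma) <- paste0("p", seq_len(fit$K))
  # localization posteriors: average of incident step posteriors
  nloc <- st$tlen + 1L
  lstart <- cumsum(c(0L, nloc[-length(nloc)]))
  locp <- matrix(0, sum(nloc), fit$K)
  for (i in seq_along(st$tlen)) {
    g <- gamma[st$tstart[i] + seq_len(st$tlen[i]), , drop = FALSE]
    L <- st$tlen[i]
    lp <- rbind(g[1, , drop = FALSE],
                if (L > 1) (g[-L, , drop = FALSE] + g[-1, , drop = FALSE]) / 2,
                g[L, , drop = FALSE])
    locp[lstart[i] + seq_len(L + 1L), ] <- lp
  }
  colnames(locp) <- paste0("p", seq_len(fit$K))
  list(steps = data.frame(traj_id = rep(st$traj_id, st$tlen), gamma,
                          stringsAsFactors = FALSE),
       localizations = data.frame(loc_row = st$loc_index, locp,
                                  stringsAsFactors = FALSE))
}

#' Fit models of increasing size
#'
#' Fits every model size in `K_range` and tabulates diffusion coefficients,
#' occupancies, log-likelihoods, and AIC, mirroring the usual
#' state-count-scan summary of tracking studies.
#'
#' @param ds an [spt_dataset()].
#' @param K_range integer vector of model sizes (e.g. `1:9`).
#' @param ... passed to [dhmm()].
#' @return An object of class `dhmm_scan`: a list of fits plus a summary
#'   data.frame (`K`, `state`, `D`, `occupancy`, `logL`, `aic`).
#' @export
dhmm_scan <- function(ds, K_range = 1:9, ...) {
  fits <- lapply(K_range, function(k) dhmm(ds, K = k, ...))
  names(fits) <- paste0("K", K_range)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(K = f$K, state = seq_len(f$K), D = f$D, occupancy = f$pi,
               logL = f$logL, aic = f$aic)))
  rownames(tab) <- NULL
  structure(list(fits = fits, summary = tab, K_range = K_range),
            class = "dhmm_scan")
}

#' @exportS3Method base::print
print.dhmm_scan <- function(x, ...) {
  cat("Diffusional HMM scan over K =",
      paste(range(x$K_range), collapse = ".."), "\n")
  agg <- unique(x$summary[, c("K", "logL", "aic")])
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Plot a model-size scan
#'
#' One row per model size; each state is a circle at its diffusion
#' coefficient (log axis) with area proportional to occupancy. Dashed
#' vertical lines mark coarse-graining thresholds.
#'
#' @param x a `dhmm_scan`.
#' @param thresholds diffusion thresholds to mark (um^2/s).
#' @param ... further arguments to `plot`.
#' @export
plot.dhmm_scan <- function(x, thresholds = c(1, 8), ...) {
  tab <- x$summary
  plot(tab$D, tab$K, log = "x", type = "n",
       xlab = expression(D ~ (mu * m^2 / s)), ylab = "model size K",
       yaxt = "n", ...)
  graphics::axis(2, at = x$K_range)
  graphics::abline(v = thresholds, lty = 2, col = "red")
  graphics::symbols(tab$D, tab$K, circles = sqrt(tab$occupancy),
                    inches = 0.12, add = TRUE, fg = "steelblue",
                    bg = grDevices::adjustcolor("steelblue", 0.4))
  invisible(x)
}
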