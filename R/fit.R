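# Destruction-replenishment model fitting: y(t') = y0 + A * (1 - exp(-beta t')).
# A is the relative blood volume (RBV), beta the reperfusion rate (RR).

#' Replenishment model value
#'
#' Evaluates `y0 + A * (1 - exp(-beta * t_rel))`, the microbubble
#' replenishment curve after a flash-destruction pulse: `A` is the plateau
#' above baseline (relative blood volume, RBV) and `beta` the exponential
#' reperfusion rate (RR, 1/s).
#'
#' @param t_rel time since reflow onset, seconds, `>= 0` (vectorized).
#' @param A plateau amplitude, a.u., `>= 0`.
#' @param beta reperfusion rate, 1/s, `> 0`.
#' @param y0 baseline offset, a.u.
#' @return Model intensities, a.u.
#' @export
model_value <- function(t_rel, A, beta, y0 = 0) {
  if (any(t_rel < 0)) stop("`t_rel` must be >= 0", call. = FALSE)
  stop_if_not_scalar_pos(beta, "beta")
  y0 + A * (1 - exp(-beta * t_rel))
}

# Data-driven deterministic initialization: plateau from the last 20% of
# samples, A0 = plateau - floor, beta0 = 1/t63 where t63 is the first crossing
# of floor + 0.632 * A0 (0.01 1/s when the curve never gets there).
init_replenishment <- function(t, y) {
  plateau <- mean(utils::tail(y, max(3L, length(y) %/% 5L)))
  floor0 <- min(y)
  A0 <- max(plateau - floor0, 1e-8)
  cross <- which(y >= floor0 + 0.632 * A0 & t > 0)
  b0 <- if (length(cross) && t[cross[1]] > 0) 1 / t[cross[1]] else 0.01
  c(A = A0, beta = min(max(b0, 1e-6), 10), y0 = floor0)
}

#' Fit the replenishment model to a segment
#'
#' Bounded Levenberg-Marquardt least squares of
#' `y0 + A * (1 - exp(-beta * t'))` against a replenishment segment, with an
#' analytic Jacobian, deterministic data-driven initialization, and bounds
#' `A >= 0`, `beta` in `(1e-6, 10]` 1/s, `y0 >= 0`. When the segment carries
#' no usable signal (near-zero variance) or the optimizer stalls, the fit is
#' returned with `converged = FALSE` and a reason rather than raising.
#' 95% confidence intervals come from the local curvature (Gauss-Newton)
#' approximation.
#'
#' @param seg a `replenishment_segment` from [segment_replenishment()], or any
#'   list with numeric `times` (re-zeroed to reflow onset) and `intensities`.
#' @param fit_offset fit the baseline `y0` (default) or pin it to 0 to match
#'   the strict two-parameter model.
#' @return An object of class `perfusion_fit` with fields `A`, `beta`, `y0`,
#'   `sse`, `r2`, `n_samples`, `ci95` (parameter x (lo, hi) matrix),
#'   `converged`, `reason`, `fit_offset`, `niter`.
#' @export
fit_replenishment <- function(seg, fit_offset = TRUE) {
  t <- seg$times; y <- seg$intensities
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y))
  n <- length(y)
  fail <- function(reason) {
    structure(list(A = NA_real_, beta = NA_real_, y0 = NA_real_,
                   sse = NA_real_, r2 = NA_real_, n_samples = n,
                   ci95 = NULL, converged = FALSE, reason = reason,
                   fit_offset = fit_offset, niter = 0L,
                   roi_label = seg$roi_label %||% NA_character_),
              class = "perfusion_fit")
  }
  if (n < 3L + fit_offset) return(fail("too few samples"))
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-12 * max(mean(y)^2, 1e-12) * n) return(fail("unidentifiable beta"))
  p0 <- init_replenishment(t, y)
  if (fit_offset) {
    resid_fn <- function(p) y - (p[3] + p[1] * (1 - exp(-p[2] * t)))
    jac_fn <- function(p) {
      e <- exp(-p[2] * t)
      cbind(-(1 - e), -p[1] * t * e, rep(-1, n))
    }
    lower <- c(0, 1e-6, 0); upper <- c(Inf, 10, Inf); par0 <- p0
  } else {
    resid_fn <- function(p) y - p[1] * (1 - exp(-p[2] * t))
    jac_fn <- function(p) {
      e <- exp(-p[2] * t)
      cbind(-(1 - e), -p[1] * t * e)
    }
    lower <- c(0, 1e-6); upper <- c(Inf, 10); par0 <- p0[1:2]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-12, ptol = 1e-12, gtol = 0, maxiter = 500)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail("optimizer error"))
  converged <- fit$info %in% 1:4
  p <- unname(fit$par)
  A <- p[1]; beta <- p[2]; y0 <- if (fit_offset) p[3] else 0
  r <- resid_fn(p)
  sse <- sum(r^2)
  r2 <- 1 - sse / sst
  ci95 <- NULL
  np <- length(p)
  if (n > np) {
    J <- jac_fn(p)
    cov <- tryCatch(solve(crossprod(J)) * sse / (n - np), error = function(e) NULL)
    if (!is.null(cov)) {
      se <- sqrt(pmax(diag(cov), 0))
      est <- c(A, beta, if (fit_offset) y0)
      ci95 <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
      rownames(ci95) <- c("A", "beta", if (fit_offset) "y0")
    }
  }
  structure(list(A = A, beta = beta, y0 = y0, sse = sse, r2 = r2,
                 n_samples = n, ci95 = ci95, converged = converged,
                 reason = if (converged) NA_character_ else "did not converge",
                 fit_offset = fit_offset, niter = fit$niter,
                 roi_label = seg$roi_label %||% NA_character_),
            class = "perfusion_fit")
}

#' @export
print.perfusion_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<perfusion_fit> NOT converged (%s), n = %d\n", x$reason, x$n_samples))
  } else {
    cat(sprintf("<perfusion_fit> RBV A = %.4g a.u., RR beta = %.4g 1/s, y0 = %.4g (n = %d, R2 = %.4f)\n",
                x$A, x$beta, x$y0, x$n_samples, x$r2))
  }
  invisible(x)
}

#' Area under the fitted replenishment curve
#'
#' Closed-form integral of the fitted curve over `[0, T]`:
#' `y0*T + A*(T - (1 - exp(-beta*T)) / beta)`. The AUC folds RBV and RR into
#' a single perfusion metric.
#'
#' @param fit a converged [fit_replenishment()] result.
#' @param T integration horizon, seconds, `> 0`.
#' @return AUC in a.u. * s.
#' @export
perfusion_auc <- function(fit, T) {
  stopifnot(inherits(fit, "perfusion_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; AUC undefined", call. = FALSE)
  stop_if_not_scalar_pos(T, "T")
  fit$y0 * T + fit$A * (T - (1 - exp(-fit$beta * T)) / fit$beta)
}

#' Perfusion index (A * beta)
#'
#' The product of plateau and rate, the classic proxy for local blood flow in
#' destruction-replenishment imaging (volume times velocity).
#'
#' @param fit a converged [fit_replenishment()] result.
#' @return `A * beta`, a.u./s.
#' @export
perfusion_index <- function(fit) {
  stopifnot(inherits(fit, "perfusion_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; index undefined", call. = FALSE)
  fit$A * fit$beta
}
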