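# Profile-likelihood confidence intervals for standardized variance
# components. The target fraction f (e.g. a2/V) is held fixed while the
# total variance, the remaining fraction (3-component models) and the mean
# parameters are re-optimized; the bound is where -2LL rises by the
# chi-square(1) quantile (3.841 at 95%) above its minimum. Reporting is on
# the standardized scale; the lower bound may be searched below 0 (the
# likelihood remains defined as long as the implied covariance matrices
# stay positive definite), matching the convention of printing
# unconstrained bounds.

profile_m2ll <- function(fit, component, f) {
  dat <- fit$data
  model <- fit$model
  nb <- ncol(dat$X1)
  comp_names <- switch(model,
                       ACE = c("a2", "c2"),
                       ADE = c("a2", "d2"),
                       AE = "a2",
                       CE = "c2",
                       E = character(0))
  all_comp <- c(comp_names, "e2")
  if (!component %in% all_comp) {
    stop("component ", component, " is not free in model ", model)
  }
  remaining <- setdiff(all_comp, component)
  if (length(remaining) == 0) {
    stop("cannot profile the only component of an E model")
  }
  has_other <- length(remaining) == 2  # one stays free, the last is implied
  free_name <- remaining[1]
  implied_name <- remaining[length(remaining)]
  make_comp <- function(g) {
    comp <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 0)
    comp[component] <- f
    if (has_other) comp[free_name] <- g
    comp[implied_name] <- 1 - f - (if (has_other) g else 0)
    comp
  }
  obj <- function(par) {
    V <- exp(par[1])
    g <- if (has_other) par[2] else 0
    beta <- par[(1 + has_other) + seq_len(nb)]
    comp <- make_comp(g) * V
    twin_m2ll(comp["a2"], comp["c2"], comp["d2"], comp["e2"], beta, dat)
  }
  start <- c(log(max(fit$V, 1e-3)),
             if (has_other) max(1e-3, fit$std[free_name]) else NULL,
             fit$betas)
  lower <- c(-10, if (has_other) 0 else NULL, rep(-Inf, nb))
  upper <- c(10,
             if (has_other) max(1e-3, 1 - f - 1e-4) else NULL,
             rep(Inf, nb))
  if (has_other) start[2] <- min(max(start[2], lower[2]), upper[2])
  res <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 500, factr = 1e5)),
    error = function(e) list(value = 1e10))
  res$value
}

#' Profile-likelihood CI for a standardized variance component
#'
#' @param fit a `twin_fit` from [fit_twin_model()].
#' @param component `"a2"`, `"c2"`, `"d2"` or `"e2"` (must be free in the
#'   fitted model).
#' @param level confidence level, default 0.95.
#' @param lower_floor how far below 0 the lower bound may be searched,
#'   default -0.95 (the likelihood degenerates as the implied correlation
#'   approaches -1).
#' @return named numeric vector `lower`, `upper`; attribute
#'   `"at_boundary"` flags bounds that could not be bracketed and were
#'   reported at the search boundary.
#' @export
profile_ci <- function(fit, component = "a2", level = 0.95,
                       lower_floor = -0.95) {
  stopifnot(inherits(fit, "twin_fit"))
  f_hat <- unname(fit$std[component])
  if (!is.finite(f_hat)) stop("component ", component, " not in fit")
  crit_rise <- stats::qchisq(level, 1)
  m2_hat <- min(fit$minus2LL, profile_m2ll(fit, component, f_hat))
  crit <- m2_hat + crit_rise
  g <- function(f) profile_m2ll(fit, component, f) - crit

  search_bound <- function(direction) {
    limit <- if (direction < 0) lower_floor else
      (if (component == "e2") 1 else 1 - 1e-4)
    step <- 0.05 * direction
    f_prev <- f_hat
    g_prev <- m2_hat - crit  # negative
    f_cur <- f_hat + step
    repeat {
      if ((direction < 0 && f_cur < limit) ||
          (direction > 0 && f_cur > limit)) {
        f_cur <- limit
      }
      g_cur <- g(f_cur)
      if (is.finite(g_cur) && g_cur > 0) {
        r <- stats::uniroot(g, lower = min(f_prev, f_cur),
                            upper = max(f_prev, f_cur), tol = 1e-3)
        return(list(value = r$root, boundary = FALSE))
      }
      if (f_cur == limit) return(list(value = limit, boundary = TRUE))
      f_prev <- f_cur
      f_cur <- f_cur + step
    }
  }
  lo <- search_bound(-1)
  hi <- search_bound(+1)
  out <- c(lower = lo$value, upper = hi$value)
  attr(out, "at_boundary") <- c(lower = lo$boundary, upper = hi$boundary)
  out
}
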