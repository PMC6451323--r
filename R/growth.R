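# Growth models for embryonic vascular volume. The two log-time-rescaled
# models (scaled cumulative log-logistic and log-normal) are compared with
# four classical sigmoidal growth laws via the residual sum of squares.
# Every model shares the asymptote semantics: A is the volume already
# present at the start of observation (lower asymptote) and V_L the
# added volume (upper asymptote minus A).

#' Supported growth model identifiers
#' @return character vector of the six model ids.
#' @export
growthModelIds <- function() {
  c("log_logistic", "log_normal", "gompertz", "logistic", "weibull", "richards")
}

.modelParamNames <- function(modelId) {
  switch(modelId,
    log_logistic = c("A", "V_L", "alpha", "beta"),
    log_normal   = c("A", "V_L", "mu", "sigma"),
    gompertz     = c("A", "V_L", "k", "t_i"),
    logistic     = c("A", "V_L", "k", "t_i"),
    weibull      = c("A", "V_L", "lambda", "k"),
    richards     = c("A", "V_L", "k", "t_i", "nu"),
    stop("unknown model id: ", modelId))
}

# parameters constrained positive are fitted on the log scale
.positiveParams <- c("V_L", "alpha", "beta", "sigma", "k", "lambda", "nu")

.checkGrowthParams <- function(modelId, params) {
  nm <- .modelParamNames(modelId)
  if (!all(nm %in% names(params)))
    stop("model '", modelId, "' needs parameters: ", paste(nm, collapse = ", "))
  p <- params[nm]
  bad <- intersect(nm, .positiveParams)
  if (any(p[bad] <= 0))
    stop("parameters ", paste(bad[p[bad] <= 0], collapse = ", "),
         " must be strictly positive for model '", modelId, "'")
  p
}

#' Evaluate a growth model V(t)
#'
#' Cumulative volume curves. The log-time models are
#' log-logistic: \eqn{V = A + V_L / (1 + (t/\alpha)^{-\beta})} and
#' log-normal: \eqn{V = A + V_L \Phi((\ln t - \mu)/\sigma)}; the
#' comparison models are the classical Gompertz, logistic, Weibull and
#' Richards laws with the same offset/scale convention.
#'
#' @param modelId one of \code{\link{growthModelIds}}.
#' @param params named parameter vector (see \linkS4class{GrowthFit}).
#' @param t times in hours post fertilisation (> 0 for log-time models).
#' @return numeric vector of volumes.
#' @examples
#' modelValue("log_logistic", c(A = 1, V_L = 10, alpha = 30, beta = 3), 30)
#' @export
modelValue <- function(modelId, params, t) {
  p <- .checkGrowthParams(modelId, params)
  if (modelId %in% c("log_logistic", "log_normal") && any(t <= 0))
    stop("log-time models require t > 0")
  with(as.list(p), switch(modelId,
    log_logistic = A + V_L / (1 + (t / alpha)^(-beta)),
    log_normal   = A + V_L * stats::pnorm((log(t) - mu) / sigma),
    gompertz     = A + V_L * exp(-exp(-k * (t - t_i))),
    logistic     = A + V_L / (1 + exp(-k * (t - t_i))),
    weibull      = A + V_L * (1 - exp(-(t / lambda)^k)),
    richards     = A + V_L * (1 + nu * exp(-k * (t - t_i)))^(-1 / nu)))
}

#' Growth rate dV/dt of a model
#'
#' Analytic derivative of \code{\link{modelValue}}; for the log-logistic
#' model \eqn{dV/dt = V_L (\beta/\alpha)(t/\alpha)^{\beta-1} /
#' (1 + (t/\alpha)^{\beta})^2}, for the log-normal model
#' \eqn{dV/dt = V_L \exp(-(\ln t - \mu)^2 / 2\sigma^2) /
#' (t \sigma \sqrt{2\pi})}.
#'
#' @inheritParams modelValue
#' @return numeric vector of growth rates (volume per hour).
#' @export
modelRate <- function(modelId, params, t) {
  p <- .checkGrowthParams(modelId, params)
  if (modelId %in% c("log_logistic", "log_normal") && any(t <= 0))
    stop("log-time models require t > 0")
  with(as.list(p), switch(modelId,
    log_logistic = {
      u <- (t / alpha)^beta
      V_L * (beta / alpha) * (t / alpha)^(beta - 1) / (1 + u)^2
    },
    log_normal = V_L * exp(-(log(t) - mu)^2 / (2 * sigma^2)) /
      (t * sigma * sqrt(2 * pi)),
    gompertz = {
      u <- k * (t - t_i)
      V_L * k * exp(-u - exp(-u)) # stable for u -> -Inf
    },
    logistic = {
      u <- abs(k * (t - t_i)) # the logistic rate is symmetric in u
      V_L * k * exp(-u) / (1 + exp(-u))^2
    },
    weibull = V_L * (k / lambda) * (t / lambda)^(k - 1) * exp(-(t / lambda)^k),
    richards = {
      w <- log(nu) - k * (t - t_i) # log of nu * exp(-k (t - t_i))
      lse <- ifelse(w > 30, w, log1p(exp(w))) # log(1 + e^w), stable
      V_L * k / nu * exp(w - (1 / nu + 1) * lse)
    }))
}

#' Time of maximal growth rate
#'
#' Closed forms where available: log-logistic
#' \eqn{t^* = \alpha ((\beta-1)/(\beta+1))^{1/\beta}} (requires
#' \eqn{\beta > 1}), log-normal \eqn{t^* = e^{\mu - \sigma^2}}, Gompertz,
#' logistic and Richards peak at the inflection time \eqn{t_i}, Weibull
#' at \eqn{\lambda ((k-1)/k)^{1/k}} (requires \eqn{k > 1}).
#'
#' @inheritParams modelValue
#' @param method \code{"closed"} for the closed form or \code{"numeric"}
#'   for a grid-plus-refine argmax of \code{\link{modelRate}}.
#' @param interval search interval for the numeric method (hours).
#' @return list with \code{time} (NA when no interior maximum exists) and
#'   \code{boundary} flag.
#' @examples
#' peakGrowthTime("log_logistic", c(A = 0, V_L = 1, alpha = 30, beta = 3))$time
#' @export
peakGrowthTime <- function(modelId, params, method = c("closed", "numeric"),
                           interval = c(1e-3, 1e3)) {
  method <- match.arg(method)
  p <- .checkGrowthParams(modelId, params)
  if (method == "numeric") {
    grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 2000))
    r <- modelRate(modelId, p, grid)
    i <- which.max(r)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(function(t) modelRate(modelId, p, t),
                           lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-10)
    return(list(time = opt$maximum, boundary = i == 1 || i == length(grid)))
  }
  pl <- as.list(p)
  switch(modelId,
    log_logistic = if (pl$beta <= 1) list(time = NA_real_, boundary = TRUE)
                   else list(time = pl$alpha * ((pl$beta - 1) / (pl$beta + 1))^(1 / pl$beta),
                             boundary = FALSE),
    log_normal = list(time = exp(pl$mu - pl$sigma^2), boundary = FALSE),
    gompertz = list(time = pl$t_i, boundary = FALSE),
    logistic = list(time = pl$t_i, boundary = FALSE),
    richards = list(time = pl$t_i, boundary = FALSE),
    weibull = if (pl$k <= 1) list(time = NA_real_, boundary = TRUE)
              else list(time = pl$lambda * ((pl$k - 1) / pl$k)^(1 / pl$k),
                        boundary = FALSE))
}

# --- fitting ---------------------------------------------------------------

.toTransformed <- function(params, nm) {
  th <- as.numeric(params[nm])
  pos <- nm %in% .positiveParams
  th[pos] <- log(th[pos])
  names(th) <- nm
  th
}

.fromTransformed <- function(theta, nm) {
  p <- as.numeric(theta)
  pos <- nm %in% .positiveParams
  p[pos] <- exp(p[pos])
  names(p) <- nm
  p
}

# data-driven starting values shared by all models
.initGrowthParams <- function(modelId, times, volumes) {
  A0 <- min(volumes)
  VL0 <- max(max(volumes) - A0, 1e-8 * (abs(A0) + 1))
  crossT <- function(level) {
    i <- which(volumes >= level)[1]
    if (is.na(i)) return(max(times))
    if (i == 1) return(times[1])
    t0 <- times[i - 1]; t1 <- times[i]
    v0 <- volumes[i - 1]; v1 <- volumes[i]
    if (v1 == v0) return(t1)
    t0 + (level - v0) / (v1 - v0) * (t1 - t0)
  }
  t25 <- crossT(A0 + 0.25 * VL0)
  t50 <- crossT(A0 + 0.50 * VL0)
  t75 <- crossT(A0 + 0.75 * VL0)
  t50 <- max(t50, 1e-3)
  span <- max(t75 - t25, diff(range(times)) / 20, 1e-3)
  p <- switch(modelId,
    log_logistic = {
      b0 <- if (t75 > t50 * (1 + 1e-6)) log(3) / log(t75 / t50) else 2
      c(A = A0, V_L = VL0, alpha = t50, beta = min(max(b0, 0.3), 30))
    },
    log_normal = {
      s0 <- if (t75 > t25) (log(t75) - log(max(t25, 1e-3))) / 1.349 else 0.5
      c(A = A0, V_L = VL0, mu = log(t50), sigma = min(max(s0, 0.05), 5))
    },
    gompertz = c(A = A0, V_L = VL0, k = 2 * log(3) / span, t_i = t50),
    logistic = c(A = A0, V_L = VL0, k = 2 * log(3) / span, t_i = t50),
    weibull = {
      k0 <- if (t75 > t25 && t25 > 0)
        log(log(4) / log(4 / 3)) / log(t75 / t25) else 2
      k0 <- min(max(k0, 0.3), 30)
      c(A = A0, V_L = VL0, lambda = t50 / log(2)^(1 / k0), k = k0)
    },
    richards = c(A = A0, V_L = VL0, k = 2 * log(3) / span, t_i = t50, nu = 1))
  p
}

#' Fit a growth model by nonlinear least squares
#'
#' Minimises the residual sum of squares with the Levenberg--Marquardt
#' algorithm. Positive parameters are fitted on the log scale so the
#' solver is unconstrained; a multi-start strategy jitters the
#' data-driven initial values to avoid local minima. Non-convergence is
#' reported through the \code{converged} flag, never as an error.
#'
#' @param series a \linkS4class{VolumeSeries}, or numeric times if
#'   \code{volumes} is given.
#' @param modelId one of \code{\link{growthModelIds}}.
#' @param volumes optional numeric volumes when \code{series} is a
#'   plain time vector.
#' @param init optional named parameter vector overriding the automatic
#'   initialisation.
#' @param nRestarts number of jittered restarts after the base start.
#' @param seed seed controlling the restart jitter.
#' @return A \linkS4class{GrowthFit}.
#' @examples
#' t <- seq(18, 90, length.out = 60)
#' v <- modelValue("log_logistic", c(A = 2, V_L = 15, alpha = 33, beta = 3), t)
#' fitGrowthModel(t, "log_logistic", volumes = v)
#' @export
fitGrowthModel <- function(series, modelId, volumes = NULL, init = NULL,
                           nRestarts = 10, seed = 1) {
  if (is(series, "VolumeSeries")) {
    times <- series@times; v <- series@volumes
  } else {
    times <- as.numeric(series); v <- as.numeric(volumes)
  }
  modelId <- match.arg(modelId, growthModelIds())
  nm <- .modelParamNames(modelId)
  if (length(times) <= length(nm))
    stop("need more observations than free parameters")
  if (any(times <= 0)) stop("times must be positive")

  base <- if (is.null(init)) .initGrowthParams(modelId, times, v)
          else .checkGrowthParams(modelId, init)
  th0 <- .toTransformed(base, nm)

  residFun <- function(theta) {
    p <- .fromTransformed(theta, nm)
    r <- v - modelValue(modelId, p, times)
    r[!is.finite(r)] <- 1e6 * max(abs(v), 1)
    r
  }

  best <- NULL
  nUsed <- 0L
  for (r in 0:nRestarts) {
    th <- th0
    if (r > 0) {
      set.seed(as.integer((seed + r) %% .Machine$integer.max))
      th <- th0 + stats::rnorm(length(th0), 0, 0.25)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th, fn = residFun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    nUsed <- nUsed + 1L
    if (is.null(fit)) next
    rss <- sum(residFun(fit$par)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
    # stop early once an essentially perfect fit is found
    if (best$rss <= 1e-12 * max(sum(v^2), 1)) break
  }

  if (is.null(best)) {
    return(new("GrowthFit", modelId = modelId,
               params = stats::setNames(rep(NA_real_, length(nm)), nm),
               rss = Inf, nObs = length(v), converged = FALSE,
               nRestartsUsed = nUsed, boundary = FALSE))
  }
  pars <- .fromTransformed(best$fit$par, nm)
  vlBoundary <- pars[["V_L"]] < 1e-6 * max(diff(range(v)), abs(max(v)), 1e-12)
  new("GrowthFit", modelId = modelId, params = pars, rss = best$rss,
      nObs = length(v), converged = best$fit$info %in% 1:4,
      nRestartsUsed = nUsed, boundary = isTRUE(vlBoundary))
}

#' Fit several growth models and rank them by RSS
#'
#' A smaller residual sum of squares indicates a better fit; residual
#' vectors are returned for visual inspection.
#'
#' @param series a \linkS4class{VolumeSeries}.
#' @param modelIds at least two model identifiers.
#' @param ... passed on to \code{\link{fitGrowthModel}}.
#' @return list with a \code{table} data.frame sorted by RSS, the named
#'   \code{fits} and a named list of \code{residuals}.
#' @export
compareModels <- function(series, modelIds = growthModelIds(), ...) {
  stopifnot(is(series, "VolumeSeries"), length(modelIds) >= 2)
  fits <- lapply(modelIds, function(m) fitGrowthModel(series, m, ...))
  names(fits) <- modelIds
  resids <- lapply(fits, function(f) {
    if (all(is.finite(f@params)))
      series@volumes - modelValue(f@modelId, f@params, series@times)
    else rep(NA_real_, length(series@times))
  })
  tab <- data.frame(
    model = modelIds,
    rss = vapply(fits, fitRss, numeric(1)),
    converged = vapply(fits, function(f) f@converged, logical(1)),
    nParams = vapply(modelIds, function(m) length(.modelParamNames(m)), integer(1)),
    row.names = NULL)
  ord <- order(tab$rss)
  list(table = tab[ord, , drop = FALSE], fits = fits, residuals = resids)
}
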