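#' Hill dose-response function
#'
#' \eqn{Y = V_{max} I^q / (K_m^q + I^q)}, with no basal term: the response at
#' I = 0 is exactly 0 (basal promoter activity is far below Vmax for this
#' device and is omitted throughout).
#'
#' @param I input level(s), \eqn{\ge 0} (HSL in nM, or activated complex in
#'   AU cell^-1).
#' @param vmax maximum response, > 0.
#' @param km half-saturation input, > 0.
#' @param q Hill exponent, > 0.
#' @return Response value(s).
#' @export
hill <- function(I, vmax, km, q) {
  if (any(is.na(I)) || any(I < 0)) stop("input error: I must be >= 0")
  stopifnot(vmax > 0, km > 0, q > 0)
  y <- numeric(length(I))
  pos <- I > 0
  y[pos] <- vmax / (1 + (km / I[pos])^q)
  y[is.infinite(I)] <- vmax
  y
}

.hillRss <- function(I, Y, w, vmax, km, q) {
  sum(w * (Y - hill(I, vmax, km, q))^2)
}

# numerical Jacobian of the (unweighted) Hill residuals wrt natural-scale
# free parameters, by central differences
.hillJacobian <- function(I, pars, free) {
  J <- sapply(free, function(nm) {
    h <- max(1e-7, 1e-7 * abs(pars[[nm]]))
    up <- pars; up[[nm]] <- up[[nm]] + h
    dn <- pars; dn[[nm]] <- dn[[nm]] - h
    (hill(I, up$vmax, up$km, up$q) - hill(I, dn$vmax, dn$km, dn$q)) / (2 * h)
  })
  matrix(J, nrow = length(I), dimnames = list(NULL, free))
}

#' Fit the Hill function by nonlinear least squares
#'
#' Minimizes \eqn{\sum w_i (Y_i - hill(I_i))^2}. Parameters are optimized on
#' the log scale internally (enforcing positivity) with a deterministic
#' initialization -- \eqn{V_{max,0} = \max Y}, \eqn{K_{m,0}} the input whose
#' response is nearest \eqn{V_{max,0}/2}, \eqn{q_0 = 1} -- followed by a
#' Nelder-Mead search and a BFGS polish. Per-parameter coefficients of
#' variation are asymptotic: standard error from the residual Jacobian at the
#' optimum, divided by the estimate, in percent. An ill-conditioned Jacobian
#' flags the CVs as unreliable rather than failing the fit.
#'
#' @param I input levels (\eqn{\ge 0}); at least 4 points with both low and
#'   high responses are required for a 3-parameter fit.
#' @param Y observed responses.
#' @param weights optional non-negative weights, default all 1.
#' @param fixedVmax optional known Vmax; when supplied only (Km, q) are
#'   fitted (used for the activated-complex axis, where Vmax is carried over
#'   from the HSL-axis fit).
#' @return A [HillFit-class].
#' @examples
#' I <- c(0, 10^seq(-2, 3, length.out = 10))
#' fit <- fitHill(I, hill(I, vmax = 8.79, km = 2, q = 1.2))
#' fit
#' @export
fitHill <- function(I, Y, weights = NULL, fixedVmax = NULL) {
  stopifnot(length(I) == length(Y))
  if (any(is.na(I)) || any(I < 0)) stop("input error: I must be >= 0")
  ok <- !is.na(Y)
  I <- I[ok]; Y <- Y[ok]
  w <- if (is.null(weights)) rep(1, length(I)) else weights[ok]
  nFree <- if (is.null(fixedVmax)) 3L else 2L
  if (length(I) < nFree + 1L)
    stop(sprintf("fit error: need at least %d points", nFree + 1L))
  if (max(Y) <= 0)
    stop("fit error: no dynamic range (all responses are <= 0)")

  vmax0 <- if (is.null(fixedVmax)) max(Y) else fixedVmax
  posI <- I[I > 0]
  if (!length(posI)) stop("fit error: all inputs are zero")
  km0 <- I[I > 0][which.min(abs(Y[I > 0] - vmax0 / 2))]
  if (km0 <= 0) km0 <- median(posI)
  q0 <- 1

  if (is.null(fixedVmax)) {
    fn <- function(th) .hillRss(I, Y, w, exp(th[1L]), exp(th[2L]), exp(th[3L]))
    th0 <- log(c(vmax0, km0, q0))
  } else {
    fn <- function(th) .hillRss(I, Y, w, fixedVmax, exp(th[1L]), exp(th[2L]))
    th0 <- log(c(km0, q0))
  }
  o1 <- optim(th0, fn, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14))
  o2 <- optim(o1$par, fn, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14))
  o <- if (o2$value <= o1$value) o2 else o1
  if (o1$convergence != 0 && o2$convergence != 0)
    stop(sprintf("fit error: optimizer did not converge (codes %d/%d, RSS %.4g)",
                 o1$convergence, o2$convergence, o$value))
  est <- exp(o$par)
  pars <- if (is.null(fixedVmax))
    list(vmax = est[1L], km = est[2L], q = est[3L])
  else
    list(vmax = fixedVmax, km = est[1L], q = est[2L])

  free <- if (is.null(fixedVmax)) c("vmax", "km", "q") else c("km", "q")
  J <- .hillJacobian(I, pars, free)
  JtJ <- crossprod(J * sqrt(w))
  cvReliable <- TRUE
  cv <- setNames(rep(NA_real_, 3L), c("vmax", "km", "q"))
  dof <- length(I) - length(free)
  if (dof > 0) {
    sigma2 <- o$value / dof
    covm <- tryCatch(solve(JtJ) * sigma2, error = function(e) NULL)
    if (is.null(covm) || kappa(JtJ) > 1e12) cvReliable <- FALSE
    if (!is.null(covm)) {
      se <- sqrt(pmax(diag(covm), 0))
      cv[free] <- 100 * se / unlist(pars[free])
    }
  }
  new("HillFit",
    vmax = pars$vmax, km = pars$km, q = pars$q, cv = cv,
    rss = o$value, converged = TRUE,
    vmaxFixed = !is.null(fixedVmax), cvReliable = cvReliable,
    nPoints = length(I))
}
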