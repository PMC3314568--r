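#' Steady-state LuxR level
#'
#' The LuxR protein pool at steady state under constitutive synthesis from
#' \code{n} DNA copies and first-order degradation: \eqn{\bar X = n
#' \alpha_{tet} / \gamma_X}. Growth dilution is neglected for LuxR because its
#' degradation rate dominates the dilution rate.
#'
#' @param params a [LuxModelParameters-class] object.
#' @return LuxR level in AU cell^-1.
#' @examples
#' steadyStateLuxR(luxModelParameters(n = 1))  # 2.3 / 0.06 = 38.33
#' @export
steadyStateLuxR <- function(params) {
  stopifnot(is(params, "LuxModelParameters"))
  validObject(params)
  if (params@gammaX <= 0) stop("invalid parameter: gammaX must be positive")
  params@n * params@alphaTet / params@gammaX
}

#' HSL-LuxR activated complex at steady state
#'
#' The complex level given HSL concentration H and the available LuxR pool:
#' \eqn{A = X / (1 + (K_H/H)^{n_H})}. At H = 0 the value is defined as the
#' continuous limit 0 (exact for any \code{nH} > 0), avoiding the division by
#' zero in the Hill term.
#'
#' @param H HSL concentration(s) in nM, \eqn{\ge 0}. Vectorized.
#' @param Xss steady-state LuxR level (AU cell^-1), \eqn{\ge 0}.
#' @param params a [LuxModelParameters-class] object (uses \code{KH},
#'   \code{nH}).
#' @return Activated complex A in AU cell^-1, same length as \code{H}.
#' @examples
#' p <- luxModelParameters()
#' activatedComplex(553, steadyStateLuxR(p), p)  # half-saturation: Xss / 2
#' @export
activatedComplex <- function(H, Xss, params) {
  stopifnot(is(params, "LuxModelParameters"))
  if (any(is.na(H)) || any(H < 0)) stop("invalid input: H must be >= 0")
  if (length(Xss) != 1L || is.na(Xss) || Xss < 0)
    stop("invalid input: Xss must be a single non-negative value")
  A <- numeric(length(H))
  pos <- H > 0
  A[pos] <- Xss / (1 + (params@KH / H[pos])^params@nH)
  # H == Inf is caught by the arithmetic: (KH/Inf)^nH = 0, A = Xss
  A[is.infinite(H)] <- Xss
  A
}

#' Predicted per-cell reporter synthesis rate
#'
#' The steady-state observable of the model: \eqn{S_{cell} = n \alpha_{lux} /
#' (1 + (K_A/A)^{n_A})}. Basal (leaky) promoter activity is modeled as exactly
#' zero, so the value at A = 0 is 0 and the saturating limit is
#' \eqn{n \alpha_{lux}}.
#'
#' @param A activated-complex level(s) in AU cell^-1, \eqn{\ge 0}. Vectorized.
#' @param params a [LuxModelParameters-class] object with non-NA
#'   \code{alphaLux}, \code{KA}, \code{nA}.
#' @return S_cell in AU min^-1 cell^-1.
#' @export
predictedScell <- function(A, params) {
  stopifnot(is(params, "LuxModelParameters"))
  if (any(is.na(A)) || any(A < 0)) stop("invalid input: A must be >= 0")
  if (is.na(params@alphaLux) || is.na(params@KA) || is.na(params@nA))
    stop("alphaLux, KA and nA must be set to predict S_cell")
  s <- numeric(length(A))
  pos <- A > 0
  s[pos] <- params@n * params@alphaLux / (1 + (params@KA / A[pos])^params@nA)
  s[is.infinite(A)] <- params@n * params@alphaLux
  s
}

#' Predicted relative promoter units
#'
#' Predicted S_cell divided by the reference device's S_cell measured in the
#' same condition: \eqn{RPU = S_{cell}/S_{cell,ref}}. As A grows without
#' bound this tends to \eqn{\alpha_{lux} n / S_{cell,ref}}, the Vmax of the
#' induction curve in RPU.
#'
#' @inheritParams predictedScell
#' @param scellRef reference S_cell (AU min^-1 cell^-1), > 0.
#' @return RPU (dimensionless), same length as \code{A}.
#' @export
predictedRpu <- function(A, params, scellRef) {
  if (length(scellRef) != 1L || is.na(scellRef) || scellRef <= 0)
    stop("invalid reference: scellRef must be a single positive value")
  predictedScell(A, params) / scellRef
}

#' Simulate the dynamics of the HSL-inducible device
#'
#' Integrates the LuxR and reporter balance equations with the activated
#' complex given algebraically by its binding equilibrium:
#' \deqn{dX/dt = n \alpha_{tet} - \gamma_X X}
#' \deqn{A = X / (1 + (K_H/H)^{n_H})}
#' \deqn{dR/dt = n \alpha_{lux} / (1 + (K_A/A)^{n_A}) - \mu R}
#' using a fixed-step explicit 4th-order Runge-Kutta scheme. The system is
#' non-stiff at the default parameter scales; a fixed step keeps output
#' deterministic.
#'
#' @param params a [LuxModelParameters-class] with \code{alphaLux}, \code{KA},
#'   \code{nA} and \code{mu} set.
#' @param H HSL concentration (nM), held constant over the horizon.
#' @param horizon simulation length (min), > 0.
#' @param dt integration step (min), default 0.1.
#' @param initial named numeric \code{c(X = , R = )}, non-negative initial
#'   state; default both 0.
#' @return data.frame with columns \code{time}, \code{X}, \code{A}, \code{R}.
#' @examples
#' p <- luxModelParameters(alphaLux = 6.07, KA = 5.13e-4, nA = 0.747, mu = 0.008)
#' traj <- simulateDynamics(p, H = 1000, horizon = 300)
#' tail(traj, 1)$X  # approaches n * alphaTet / gammaX = 38.33
#' @export
simulateDynamics <- function(params, H, horizon, dt = 0.1,
                             initial = c(X = 0, R = 0)) {
  stopifnot(is(params, "LuxModelParameters"))
  validObject(params)
  if (is.na(params@mu)) stop("mu must be set to simulate dynamics")
  if (is.na(params@alphaLux) || is.na(params@KA) || is.na(params@nA))
    stop("alphaLux, KA and nA must be set to simulate dynamics")
  if (length(H) != 1L || is.na(H) || H < 0) stop("invalid input: H must be >= 0")
  if (horizon <= 0 || dt <= 0) stop("horizon and dt must be positive")
  X0 <- as.numeric(initial[["X"]]); R0 <- as.numeric(initial[["R"]])
  if (X0 < 0 || R0 < 0) stop("initial state must be non-negative")

  hillA <- if (H > 0) 1 / (1 + (params@KH / H)^params@nH) else 0
  deriv <- function(state) {
    X <- state[1L]; R <- state[2L]
    A <- max(X, 0) * hillA
    dR <- if (A > 0) {
      params@n * params@alphaLux / (1 + (params@KA / A)^params@nA) - params@mu * R
    } else {
      -params@mu * R
    }
    c(params@n * params@alphaTet - params@gammaX * X, dR)
  }
  nStep <- ceiling(horizon / dt)
  out <- matrix(NA_real_, nrow = nStep + 1L, ncol = 3L)
  state <- c(X0, R0)
  out[1L, ] <- c(0, state)
  for (i in seq_len(nStep)) {
    k1 <- deriv(state)
    k2 <- deriv(state + dt / 2 * k1)
    k3 <- deriv(state + dt / 2 * k2)
    k4 <- deriv(state + dt * k3)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(state < 0)) {
      if (all(state > -1e-9)) {
        state[state < 0] <- 0  # round-off at the zero boundary
      } else {
        stop(sprintf(
          "integration error: negative state at t = %.3f min (X = %.3g, R = %.3g); reduce dt",
          i * dt, state[1L], state[2L]))
      }
    }
    out[i + 1L, ] <- c(i * dt, state)
  }
  data.frame(
    time = out[, 1L], X = out[, 2L],
    A = pmax(out[, 2L], 0) * hillA, R = out[, 3L]
  )
}
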