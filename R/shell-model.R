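#' Complex relative permittivity of a lossy dielectric
#'
#' Standard dielectric dispersion: \eqn{\epsilon^* = \epsilon - j\sigma /
#' (\omega\epsilon_0)} with \eqn{\omega = 2\pi f}. The imaginary part is
#' always non-positive for non-negative conductivity.
#'
#' @param relPermittivity dimensionless relative permittivity
#' @param conductivity conductivity, S/m
#' @param frequency frequency, Hz (> 0); vectorised
#' @return Complex relative permittivity, same length as \code{frequency}.
#' @examples
#' complexPermittivity(78, 0.043, 1e5)
#' @export
complexPermittivity <- function(relPermittivity, conductivity, frequency) {
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequency must be positive and finite (Hz)")
  relPermittivity - 1i * conductivity / (2 * pi * frequency * EPS0)
}

# absolute (F/m) complex permittivity of medium/cytoplasm
.absPerm <- function(relPermittivity, conductivity, frequency)
  EPS0 * relPermittivity - 1i * conductivity / (2 * pi * frequency)

#' Effective permittivity of a single-shell cell
#'
#' Collapses the thin-membrane-plus-cytoplasm sphere to an equivalent
#' homogeneous sphere. With the membrane described by its complex specific
#' capacitance \eqn{C^*_m = C_m - jG_m/\omega} (F/m^2), the effective
#' absolute complex permittivity is the series combination
#' \deqn{\epsilon^*_{eff} = \frac{r C^*_m \epsilon^*_{cyt}}{r C^*_m +
#' \epsilon^*_{cyt}},}
#' the thin-shell limit of the two-layer shelled-sphere mixing formula.
#' At low frequency with an insulating membrane this reduces to the
#' whole-cell capacitance \eqn{r C_m}.
#'
#' @param cell a \linkS4class{ShellParams}
#' @param frequency frequency, Hz (> 0); vectorised
#' @return Complex \emph{relative} effective permittivity of the cell.
#' @export
singleShellPermittivity <- function(cell, frequency) {
  stopifnot(is(cell, "ShellParams"))
  validObject(cell)
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequency must be positive and finite (Hz)")
  w <- 2 * pi * frequency
  cmStar <- cell@membraneCapacitance - 1i * cell@membraneConductance / w
  ecyt <- .absPerm(cell@cytoplasmPermittivity, cell@cytoplasmConductivity, frequency)
  r <- cell@radius
  (r * cmStar * ecyt) / (r * cmStar + ecyt) / EPS0
}

#' Real part of the Clausius-Mossotti factor
#'
#' The frequency-dependent dielectric contrast between a single-shell cell
#' and its suspending medium,
#' \eqn{Re[(\epsilon^*_p - \epsilon^*_m)/(\epsilon^*_p + 2\epsilon^*_m)]},
#' which sets the sign and strength of the DEP response. Bounded in
#' [-0.5, 1] for any sphere.
#'
#' @param cell a \linkS4class{ShellParams}
#' @param medium a \linkS4class{DielectricMedium}
#' @param frequency frequency, Hz (> 0); vectorised
#' @return Numeric vector in [-0.5, 1].
#' @examples
#' cell <- ShellParams(10e-6, 0.01, 2000, 60, 0.25)
#' med <- DielectricMedium(78, 0.043)
#' reCM(cell, med, c(1e4, 1e6, 4.5e7))
#' @export
reCM <- function(cell, medium, frequency) {
  stopifnot(is(medium, "DielectricMedium"))
  validObject(medium)
  ep <- singleShellPermittivity(cell, frequency) * EPS0
  em <- .absPerm(medium@relPermittivity, medium@conductivity, frequency)
  Re((ep - em) / (ep + 2 * em))
}

#' Model DEP spectrum on a frequency grid
#'
#' Evaluates \code{\link{reCM}} pointwise over a strictly increasing grid of
#' positive frequencies, optionally scaled by an instrument gain.
#'
#' @param cell a \linkS4class{ShellParams}
#' @param medium a \linkS4class{DielectricMedium}
#' @param frequencies strictly increasing positive frequencies, Hz
#' @param gain dimensionless instrument scale factor (default 1)
#' @return Numeric vector of DEP response values, one per grid point.
#' @export
depSpectrum <- function(cell, medium, frequencies, gain = 1) {
  if (length(frequencies) == 0L) stop("frequency grid is empty")
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("frequencies must be strictly increasing")
  gain * reCM(cell, medium, frequencies)
}

#' Log-spaced measurement grid
#'
#' The default 20-point log-spaced grid spanning 10 kHz to 45 MHz, matching
#' a well-plate DEP cytometer sweep.
#'
#' @param n number of points (default 20)
#' @param fmin,fmax band edges, Hz
#' @return Strictly increasing numeric vector of frequencies.
#' @export
defaultGrid <- function(n = 20L, fmin = 1e4, fmax = 4.5e7) {
  stopifnot(n >= 2L, fmin > 0, fmax > fmin)
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Closed-form DEP crossover frequency
#'
#' Thin-shell low-frequency approximation
#' \eqn{f_{xo} = \sqrt{2}\,\sigma_m / (2\pi r C_m)}, valid when the
#' membrane conductance is negligible and the cytoplasm conductivity far
#' exceeds the medium conductivity.
#'
#' @param cell a \linkS4class{ShellParams}
#' @param medium a \linkS4class{DielectricMedium}
#' @return Crossover frequency estimate, Hz.
#' @export
crossoverClosedForm <- function(cell, medium) {
  sqrt(2) * medium@conductivity /
    (2 * pi * cell@radius * cell@membraneCapacitance)
}

#' Numerical crossover frequency of Re[CM]
#'
#' Finds the frequency at which the real Clausius-Mossotti factor changes
#' sign within a bracket. The bracket is scanned on a fine log grid from the
#' low end; the first sign-change interval is refined by root bisection
#' (\code{uniroot}) to a relative tolerance of 1e-6. If further sign changes
#' exist in the bracket, the lowest-frequency root is returned and
#' \code{multiple} is set.
#'
#' @param cell a \linkS4class{ShellParams}
#' @param medium a \linkS4class{DielectricMedium}
#' @param bracket length-2 frequency interval, Hz
#' @param nScan points in the sign-change scan (default 400)
#' @return A list with \code{frequency} (Hz, or NA), \code{found} (logical),
#'   \code{multiple} (logical: more than one crossover in the bracket) and
#'   \code{message}.
#' @examples
#' cell <- ShellParams(10e-6, 0.01, 0, 60, 1.0)
#' med <- DielectricMedium(78, 0.043)
#' crossoverFrequency(cell, med)$frequency
#' @export
crossoverFrequency <- function(cell, medium, bracket = c(1e4, 4.5e7),
                               nScan = 400L) {
  stopifnot(length(bracket) == 2L, all(bracket > 0), bracket[2] > bracket[1])
  fs <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = nScan))
  v <- reCM(cell, medium, fs)
  sgn <- sign(v)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(v == 0)
  if (length(flips) == 0L && length(exact) == 0L)
    return(list(frequency = NA_real_, found = FALSE, multiple = FALSE,
                message = "no crossover in band"))
  if (length(exact) > 0L && (length(flips) == 0L || exact[1] <= flips[1])) {
    root <- fs[exact[1]]
  } else {
    i <- flips[1]
    root <- uniroot(function(f) reCM(cell, medium, f),
                    lower = fs[i], upper = fs[i + 1],
                    tol = fs[i] * 1e-7)$root
  }
  list(frequency = root, found = TRUE,
       multiple = (length(flips) + length(exact)) > 1L,
       message = "ok")
}

#' Fit single-shell parameters to an observed DEP spectrum
#'
#' Least-squares inversion of the single-shell model: minimises
#' \eqn{\sum_i (y_i - g\,Re[CM](f_i; \theta))^2} over the chosen free
#' parameters (and optionally the instrument gain \eqn{g}) using
#' Levenberg-Marquardt on log-transformed parameters, which enforces
#' positivity without box constraints. Masked points are ignored.
#'
#' @param frequencies frequencies, Hz
#' @param values observed DEP response at each frequency
#' @param medium a \linkS4class{DielectricMedium}
#' @param init initial \linkS4class{ShellParams}
#' @param free character vector naming the free parameters (subset of
#'   radius, membraneCapacitance, membraneConductance,
#'   cytoplasmPermittivity, cytoplasmConductivity)
#' @param mask logical vector, TRUE = use the point (default all)
#' @param fitGain also estimate the instrument gain (default FALSE, gain
#'   fixed at \code{gain})
#' @param gain fixed gain when \code{fitGain} is FALSE (default 1)
#' @return A list with \code{params} (fitted \code{ShellParams}),
#'   \code{gain}, \code{residualNorm} (root-sum-square residual over used
#'   points), \code{converged} (logical) and \code{info} (optimizer status).
#' @export
fitShellParams <- function(frequencies, values, medium, init,
                           free = c("membraneCapacitance",
                                    "membraneConductance",
                                    "cytoplasmConductivity"),
                           mask = NULL, fitGain = FALSE, gain = 1) {
  stopifnot(is(init, "ShellParams"), length(values) == length(frequencies))
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  stopifnot(length(mask) == length(values))
  free <- match.arg(free, SHELL_PARAM_NAMES, several.ok = TRUE)
  fs <- frequencies[mask]
  ys <- values[mask]
  nFree <- length(free) + as.integer(fitGain)
  if (length(ys) < nFree)
    stop("need at least as many valid points (", length(ys),
         ") as free parameters (", nFree, ")")

  start <- sapply(SHELL_PARAM_NAMES, function(p) slot(init, p))
  # membraneConductance may legitimately be 0; floor it for the log scale
  start <- pmax(start, 1e-12)
  theta0 <- log(start[free])
  if (fitGain) theta0 <- c(theta0, logGain = log(max(gain, 1e-12)))

  build <- function(theta) {
    p <- start
    p[free] <- exp(theta[seq_along(free)])
    g <- if (fitGain) exp(theta[length(theta)]) else gain
    list(cell = new("ShellParams", radius = p[["radius"]],
                    membraneCapacitance = p[["membraneCapacitance"]],
                    membraneConductance = p[["membraneConductance"]],
                    cytoplasmPermittivity = p[["cytoplasmPermittivity"]],
                    cytoplasmConductivity = p[["cytoplasmConductivity"]]),
         gain = g)
  }
  resid <- function(theta) {
    b <- build(theta)
    ys - b$gain * reCM(b$cell, medium, fs)
  }
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  b <- build(fit$par)
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("shell-parameter fit did not converge: ", fit$message)
  list(params = b$cell, gain = b$gain,
       residualNorm = sqrt(sum(resid(fit$par)^2)),
       converged = converged, info = fit$info)
}
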