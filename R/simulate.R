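#' Simulate the flavin-reoxidation mechanism
#'
#' Integrates the mass-action rate laws of a \code{\link{kineticScheme}} from
#' a post-mix initial state over a time grid, using a stiff ODE solver
#' (\code{deSolve::lsoda}, relative tolerance 1e-8, absolute tolerance
#' 1e-12 M). Three conservation laws hold along any trajectory and are good
#' diagnostics for solver health: total enzyme flavin, total cytochrome, and
#' total reducing equivalents \eqn{2[FlH_2] + [FlSQ] + [C_{red}] + 2[H_2O_2]}.
#'
#' @param scheme a \code{\link{kineticScheme}}.
#' @param init a \code{\link{mixState}} (post-mix concentrations, M).
#' @param t_grid strictly increasing time grid (s) starting at 0.
#' @return A \code{"ConcentrationTrajectory"}: data.frame with column
#'   \code{time} (s) and one molar-concentration column per species.
#' @examples
#' sch <- kineticScheme(k1f = 1e6, k2f = 1e5)
#' tr <- simulateMechanism(sch, mixState(FlH2 = 18e-6, Cox = 60e-6),
#'                         seq(0, 0.5, length.out = 201))
#' head(tr)
#' @export
simulateMechanism <- function(scheme, init, t_grid) {
  stopifnot(inherits(scheme, "KineticScheme"), inherits(init, "MixState"))
  if (!is.numeric(t_grid) || length(t_grid) < 2L || anyNA(t_grid))
    stopf("t_grid must be a numeric vector of >= 2 time points")
  if (t_grid[1] != 0) stopf("t_grid must start at 0")
  if (any(diff(t_grid) <= 0)) stopf("t_grid must be strictly increasing")

  y0 <- as.numeric(init)[seq_along(SPECIES)]
  names(y0) <- SPECIES
  p <- scheme

  deriv <- function(t, y, parms) {
    vO2 <- parms$k_O2 * y["FlH2"] * y["O2"]
    v1 <- parms$k1f * y["FlH2"] * y["Cox"] - parms$k1r * y["FlSQ"] * y["Cred"]
    v2 <- parms$k2f * y["FlSQ"] * y["Cox"] - parms$k2r * y["Flox"] * y["Cred"]
    list(c(FlH2 = -vO2 - v1,
           FlSQ = v1 - v2,
           Flox = vO2 + v2,
           Cox = -v1 - v2,
           Cred = v1 + v2,
           O2 = -vO2,
           H2O2 = vO2))
  }

  out <- deSolve::lsoda(y = y0, times = t_grid, func = deriv, parms = p,
                        rtol = 1e-8, atol = 1e-12)
  if (attr(out, "istate")[1] < 0)
    stopf("stiff-solver failure (istate %d) for scheme k_O2=%g k1f=%g k2f=%g",
          attr(out, "istate")[1], p$k_O2, p$k1f, p$k2f)
  traj <- as.data.frame(out)
  names(traj)[1] <- "time"
  # tiny negative excursions at the solver's absolute-tolerance scale are
  # round-off and are clipped; anything larger is an error
  conc <- as.matrix(traj[SPECIES])
  if (any(conc < -1e-12))
    stopf("solver produced negative concentrations beyond tolerance")
  conc[conc < 0] <- 0
  traj[SPECIES] <- conc
  class(traj) <- c("ConcentrationTrajectory", "data.frame")
  traj
}

#' Long-time equilibrium of the cytochrome-c branch
#'
#' Solves the two mass-action equilibrium conditions
#' \eqn{K_1 = [FlSQ][C_{red}] / ([FlH_2][C_{ox}])} and
#' \eqn{K_2 = [Fl_{ox}][C_{red}] / ([FlSQ][C_{ox}])} jointly with the
#' conservation laws, parameterized by the two reaction extents. For an
#' irreversible scheme (both K infinite) the long-time limit transfers
#' electrons until either the enzyme is fully oxidized or the oxidant is
#' exhausted. The returned state is the limit of
#' \code{\link{simulateMechanism}} as time grows.
#'
#' @param scheme a \code{\link{kineticScheme}} with the CytC branch active.
#' @param init a \code{\link{mixState}} with \code{Cox > 0} (or already at
#'   equilibrium).
#' @return A \code{\link{mixState}} at equilibrium.
#' @examples
#' sch <- kineticScheme(k1f = 1e6, k2f = 0, K1 = 1)
#' eq <- equilibriumEndpoint(sch, mixState(FlH2 = 18e-6, Cox = 18e-6))
#' eq[["FlSQ"]] * 1e6   # 9 uM converted
#' @export
equilibriumEndpoint <- function(scheme, init) {
  stopifnot(inherits(scheme, "KineticScheme"), inherits(init, "MixState"))
  if (init[["O2"]] > 0)
    stopf("equilibriumEndpoint applies to the cytochrome-c branch only")
  y0 <- as.numeric(init)[seq_along(SPECIES)]
  names(y0) <- SPECIES

  # state from the two step extents (x1, x2)
  stateAt <- function(x1, x2) {
    x1 <- unname(x1); x2 <- unname(x2)
    c(FlH2 = y0[["FlH2"]] - x1,
      FlSQ = y0[["FlSQ"]] + x1 - x2,
      Flox = y0[["Flox"]] + x2,
      Cox = y0[["Cox"]] - x1 - x2,
      Cred = y0[["Cred"]] + x1 + x2,
      O2 = 0, H2O2 = y0[["H2O2"]])
  }

  irrev1 <- is.infinite(scheme$K1) || scheme$k1r == 0
  irrev2 <- is.infinite(scheme$K2) || scheme$k2r == 0
  step1 <- scheme$k1f > 0
  step2 <- scheme$k2f > 0

  if ((!step1 && !step2) || init[["Cox"]] == 0) return(init)

  if ((irrev1 || !step1) && (irrev2 || !step2)) {
    # fully oxidized (oxidant permitting): run each step to completion
    x1 <- if (step1) min(y0[["FlH2"]], y0[["Cox"]]) else 0
    x2 <- if (step2) min(y0[["FlSQ"]] + x1, y0[["Cox"]] - x1) else 0
    s <- stateAt(x1, x2)
    return(mixState(FlH2 = s[["FlH2"]], FlSQ = s[["FlSQ"]],
                    Flox = s[["Flox"]], Cox = s[["Cox"]], Cred = s[["Cred"]],
                    H2O2 = s[["H2O2"]],
                    temperature = attr(init, "temperature")))
  }

  scaleC <- max(y0[c("FlH2", "FlSQ", "Flox", "Cox", "Cred")], 1e-12)
  # residuals of the two equilibrium conditions in cross-multiplied form,
  # nondimensionalized; a step with k_f = 0 contributes extent 0 instead
  resid <- function(z) {
    x1 <- z[1]; x2 <- z[2]
    s <- stateAt(x1, x2)
    r1 <- if (!step1) x1 / scaleC else if (irrev1)
      s[["FlH2"]] * s[["Cox"]] / scaleC^2
    else
      (scheme$K1 * s[["FlH2"]] * s[["Cox"]] - s[["FlSQ"]] * s[["Cred"]]) /
        scaleC^2
    r2 <- if (!step2) x2 / scaleC else if (irrev2)
      s[["FlSQ"]] * s[["Cox"]] / scaleC^2
    else
      (scheme$K2 * s[["FlSQ"]] * s[["Cox"]] - s[["Flox"]] * s[["Cred"]]) /
        scaleC^2
    c(r1, r2)
  }

  # feasibility bounds on the extents keep every concentration >= 0
  lower <- c(-min(y0[["FlSQ"]] + y0[["Cox"]], y0[["Cred"]]),
             -min(y0[["Flox"]], y0[["Cred"]]))
  fit <- minpack.lm::nls.lm(par = c(x1 = y0[["FlH2"]] * 0.5, x2 = 0),
                            fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  z <- fit$par
  s <- stateAt(z[1], z[2])
  if (any(s < -1e-12) || sqrt(sum(resid(z)^2)) > 1e-8)
    stopf("equilibrium solve failed to converge")
  s[s < 0] <- 0
  mixState(FlH2 = s[["FlH2"]], FlSQ = s[["FlSQ"]], Flox = s[["Flox"]],
           Cox = s[["Cox"]], Cred = s[["Cred"]], H2O2 = s[["H2O2"]],
           temperature = attr(init, "temperature"))
}

#' Beer-Lambert absorbance trace from a concentration trajectory
#'
#' @param traj a \code{"ConcentrationTrajectory"} from
#'   \code{\link{simulateMechanism}}.
#' @param spec a \code{\link{spectralModel}}.
#' @param wavelength 450 or 550 (nm).
#' @param oxidant_conc optional post-mix oxidant concentration (M) recorded as
#'   trace metadata for downstream fitting.
#' @return A \code{\link{faoTrace}} with columns \code{time},
#'   \code{absorbance}.
#' @examples
#' sch <- kineticScheme(k_O2 = 27)
#' tr <- simulateMechanism(sch, mixState(FlH2 = 5e-6, O2 = 130e-6),
#'                         seq(0, 600, length.out = 301))
#' absorbanceTrace(tr, spectralModel(), 450, oxidant_conc = 130e-6)
#' @export
absorbanceTrace <- function(traj, spec, wavelength, oxidant_conc = NA_real_) {
  stopifnot(inherits(traj, "ConcentrationTrajectory"),
            inherits(spec, "SpectralModel"))
  eps <- epsVector(spec, wavelength)
  a <- as.matrix(traj[SPECIES]) %*% (eps[SPECIES] * spec$pathlength)
  faoTrace(time = traj$time, absorbance = as.numeric(a),
           wavelength = wavelength, oxidant_conc = oxidant_conc)
}

#' Concentration from absorbance
#'
#' Protein concentrations are estimated spectrophotometrically: FAO from the
#' flavin band at 450 nm (eps450 = 11300 M^-1 cm^-1 for bound FAD) and
#' cytochrome c from its Soret band at 410 nm (eps410 = 106000 M^-1 cm^-1).
#'
#' @param absorbance absorbance (AU), >= 0.
#' @param role \code{"FAO"} or \code{"CytC"}.
#' @param spec a \code{\link{spectralModel}}.
#' @return concentration in M.
#' @examples
#' estimateConcentration(0.4068, "FAO") * 1e6   # 36 uM
#' estimateConcentration(1.06, "CytC") * 1e6    # 10 uM
#' @export
estimateConcentration <- function(absorbance, role, spec = spectralModel()) {
  if (!isScalarNumber(absorbance) || absorbance < 0)
    stopf("absorbance must be a single number >= 0")
  stopifnot(inherits(spec, "SpectralModel"))
  eps <- switch(role,
                FAO = spec$eps450_Flox,
                CytC = spec$eps410_CytC,
                stopf("unknown role '%s' (use \"FAO\" or \"CytC\")", role))
  absorbance / (eps * spec$pathlength)
}
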