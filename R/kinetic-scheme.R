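#' Kinetic scheme for flavin reoxidation
#'
#' Describes the oxidative half-reaction of a reduced flavoprotein amine
#' oxidoreductase (FAO) by either of two oxidants:
#' \itemize{
#'   \item the O2 branch, a single two-electron step
#'     \eqn{E \cdot FlH_2 + O_2 \rightarrow E \cdot Fl_{ox} + H_2O_2} with
#'     bimolecular rate constant \code{k_O2};
#'   \item the cytochrome c branch, two sequential one-electron transfers
#'     \eqn{E \cdot FlH_2 + C_{ox} \rightleftharpoons E \cdot FlSQ + C_{red}}
#'     (rate \code{k1f}, equilibrium constant \code{K1}) and
#'     \eqn{E \cdot FlSQ + C_{ox} \rightleftharpoons E \cdot Fl_{ox} + C_{red}}
#'     (rate \code{k2f}, equilibrium constant \code{K2}).
#' }
#' Reverse rate constants are parameterized through the per-step equilibrium
#' constants (\code{kir = kif / Ki}); \code{Ki = Inf} makes a step
#' irreversible. Electron transfer to cytochrome c is experimentally
#' reversible (traces at low oxidant excess plateau at an equilibrium), so
#' finite defaults are provided, but their magnitude is a modelling assumption.
#'
#' @param k_O2 bimolecular rate constant (M^-1 s^-1) for the O2 branch.
#' @param k1f,k2f forward bimolecular rate constants (M^-1 s^-1) for the two
#'   one-electron transfers to cytochrome c.
#' @param K1,K2 dimensionless per-step equilibrium constants (> 0, may be
#'   \code{Inf} for an irreversible step). Default 10.
#'
#' @return An object of class \code{"KineticScheme"}: a list with the five
#'   parameters plus derived reverse constants \code{k1r}, \code{k2r}.
#' @examples
#' sch <- kineticScheme(k_O2 = 27)                    # O2-only (NicA2-like)
#' sch2 <- kineticScheme(k1f = 2.8e6, k2f = 3.7e5)    # CytC branch
#' @export
kineticScheme <- function(k_O2 = 0, k1f = 0, k2f = 0, K1 = 10, K2 = 10) {
  for (nm in c("k_O2", "k1f", "k2f")) {
    v <- get(nm)
    if (!isScalarNumber(v) || v < 0)
      stopf("%s must be a finite rate constant >= 0 (got %s)", nm, format(v))
  }
  for (nm in c("K1", "K2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stopf("%s must be > 0 (Inf allowed for an irreversible step)", nm)
  }
  k1r <- if (is.infinite(K1)) 0 else k1f / K1
  k2r <- if (is.infinite(K2)) 0 else k2f / K2
  structure(list(k_O2 = k_O2, k1f = k1f, k2f = k2f, K1 = K1, K2 = K2,
                 k1r = k1r, k2r = k2r),
            class = "KineticScheme")
}

#' @export
print.KineticScheme <- function(x, ...) {
  cat("Flavin-reoxidation kinetic scheme\n")
  cat(sprintf("  O2 branch   : k_O2 = %g M^-1 s^-1\n", x$k_O2))
  cat(sprintf("  CytC step 1 : k1f = %g M^-1 s^-1, K1 = %g (k1r = %g)\n",
              x$k1f, x$K1, x$k1r))
  cat(sprintf("  CytC step 2 : k2f = %g M^-1 s^-1, K2 = %g (k2r = %g)\n",
              x$k2f, x$K2, x$k2r))
  invisible(x)
}

# Ordered species vector used throughout the simulator.
SPECIES <- c("FlH2", "FlSQ", "Flox", "Cox", "Cred", "O2", "H2O2")

#' Post-mix initial state of a stopped-flow shot
#'
#' All concentrations are POST-MIX molar values: the stopped-flow instrument
#' mixes the enzyme and oxidant syringes 1:1, so 36 uM tonometer enzyme is
#' observed at 18 uM and 80-160 uM syringe cytochrome c at 40-80 uM. At most
#' one oxidant branch (O2 or oxidized cytochrome c) may be nonzero, matching
#' the anaerobic protocol in which the non-studied oxidant is excluded.
#'
#' @param FlH2,FlSQ,Flox enzyme-bound flavin hydroquinone, semiquinone and
#'   oxidized flavin concentrations (M).
#' @param Cox,Cred oxidized / reduced cytochrome c (M).
#' @param O2,H2O2 dioxygen and hydrogen peroxide (M).
#' @param temperature metadata label; the instrument default is "4 C".
#' @return An object of class \code{"MixState"}: named numeric vector of the
#'   seven species with a \code{temperature} attribute.
#' @examples
#' mixState(FlH2 = 18e-6, Cox = 60e-6)
#' @export
mixState <- function(FlH2 = 0, FlSQ = 0, Flox = 0, Cox = 0, Cred = 0,
                     O2 = 0, H2O2 = 0, temperature = "4 C") {
  conc <- c(FlH2 = FlH2, FlSQ = FlSQ, Flox = Flox, Cox = Cox, Cred = Cred,
            O2 = O2, H2O2 = H2O2)
  if (!is.numeric(conc) || anyNA(conc) || any(!is.finite(conc)))
    stopf("all concentrations must be finite numbers")
  if (any(conc < 0))
    stopf("negative concentration: %s",
          paste(names(conc)[conc < 0], collapse = ", "))
  if (conc[["O2"]] > 0 && conc[["Cox"]] > 0)
    stopf("at most one oxidant branch may be active (O2 or Cox, not both)")
  structure(conc, temperature = temperature, class = c("MixState", "numeric"))
}

#' @export
print.MixState <- function(x, ...) {
  cat("Post-mix state (", attr(x, "temperature"), "):\n", sep = "")
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(signif(v * 1e6, 6))
  cat("  (concentrations in uM)\n")
  invisible(x)
}

#' Spectral model: extinction coefficients for the observable species
#'
#' Beer-Lambert coefficients (M^-1 cm^-1) at the two wavelengths used to
#' follow the reaction: 450 nm reports the flavin redox state (oxidized FAD
#' has eps450 = 11300) and 550 nm reports heme reduction of cytochrome c.
#' Only eps450 of oxidized flavin and eps410 of cytochrome c (used for
#' concentration estimation) are experimentally anchored; the remaining
#' coefficients are documented assumptions and can be overridden. The
#' semiquinone contribution at 550 nm (\code{eps550_FlSQ}) defaults to 0; a
#' positive value makes the first kinetic phase of the cytochrome-c reaction
#' appear larger than the second, the proposed explanation for the observed
#' ~60/40 amplitude split.
#'
#' @param eps450_Flox,eps450_FlH2,eps450_FlSQ flavin coefficients at 450 nm.
#' @param eps550_Cred,eps550_Cox cytochrome c coefficients at 550 nm (the
#'   default reduced-minus-oxidized difference is 21000).
#' @param eps550_FlSQ flavin semiquinone coefficient at 550 nm (default 0).
#' @param eps410_CytC Soret-band coefficient used to estimate cytochrome c
#'   concentration (default 106000).
#' @param pathlength optical pathlength in cm (default 1).
#' @return An object of class \code{"SpectralModel"}.
#' @examples
#' spectralModel()
#' spectralModel(eps550_FlSQ = 5000)   # semiquinone visible at 550 nm
#' @export
spectralModel <- function(eps450_Flox = 11300, eps450_FlH2 = 900,
                          eps450_FlSQ = 4000, eps550_Cred = 21000,
                          eps550_Cox = 0, eps550_FlSQ = 0,
                          eps410_CytC = 106000, pathlength = 1) {
  eps <- c(eps450_Flox = eps450_Flox, eps450_FlH2 = eps450_FlH2,
           eps450_FlSQ = eps450_FlSQ, eps550_Cred = eps550_Cred,
           eps550_Cox = eps550_Cox, eps550_FlSQ = eps550_FlSQ,
           eps410_CytC = eps410_CytC)
  if (!is.numeric(eps) || anyNA(eps) || any(eps < 0))
    stopf("all extinction coefficients must be >= 0")
  if (!isScalarNumber(pathlength) || pathlength <= 0)
    stopf("pathlength must be a positive number (cm)")
  structure(c(as.list(eps), list(pathlength = pathlength)),
            class = "SpectralModel")
}

#' @export
print.SpectralModel <- function(x, ...) {
  cat("Spectral model (M^-1 cm^-1, pathlength", x$pathlength, "cm)\n")
  cat(sprintf("  450 nm: Flox %g, FlH2 %g, FlSQ %g\n",
              x$eps450_Flox, x$eps450_FlH2, x$eps450_FlSQ))
  cat(sprintf("  550 nm: Cred %g, Cox %g, FlSQ %g\n",
              x$eps550_Cred, x$eps550_Cox, x$eps550_FlSQ))
  cat(sprintf("  410 nm: CytC %g\n", x$eps410_CytC))
  invisible(x)
}

# Per-species extinction coefficients at a wavelength, in SPECIES order.
#' @noRd
epsVector <- function(spec, wavelength) {
  if (wavelength == 450)
    c(FlH2 = spec$eps450_FlH2, FlSQ = spec$eps450_FlSQ,
      Flox = spec$eps450_Flox, Cox = 0, Cred = 0, O2 = 0, H2O2 = 0)
  else if (wavelength == 550)
    c(FlH2 = 0, FlSQ = spec$eps550_FlSQ, Flox = 0,
      Cox = spec$eps550_Cox, Cred = spec$eps550_Cred, O2 = 0, H2O2 = 0)
  else stopf("unsupported wavelength %s nm (450 or 550)", wavelength)
}
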