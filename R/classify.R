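#' Oxidant preference ratio
#'
#' Ratio of the fast-phase cytochrome-c bimolecular constant to the O2
#' constant. Values far above 1 indicate cytochrome c is strongly preferred
#' over dioxygen as the electron acceptor.
#'
#' @param k_cytc fast-phase cytochrome-c rate constant (M^-1 s^-1), > 0.
#' @param k_o2 O2 rate constant (M^-1 s^-1), > 0.
#' @return dimensionless ratio \code{k_cytc / k_o2}.
#' @examples
#' preferenceRatio(4.7e5, 1.6e3)   # 293.75
#' @export
preferenceRatio <- function(k_cytc, k_o2) {
  if (!isScalarNumber(k_cytc) || k_cytc <= 0 ||
      !isScalarNumber(k_o2) || k_o2 <= 0)
    stopf("rate constants must be positive numbers")
  k_cytc / k_o2
}

#' Default classification thresholds
#'
#' The published reasoning is verbal; these numeric thresholds encode it so
#' every call is auditable:
#' \itemize{
#'   \item \code{r_dehydro} (default 100): an enzyme whose cytochrome-c
#'     constant exceeds its O2 constant by at least this factor is a
#'     dehydrogenase. Characterized dehydrogenases show ratios of ~290 to
#'     several 10^4; 100 leaves headroom below the smallest observed ratio.
#'   \item \code{k_oxidase_floor} (default 10^3.5 ~ 3.2e3 M^-1 s^-1): minimum
#'     O2 constant for credible oxidase activity, between free flavin
#'     (~250 M^-1 s^-1) and the low end of bona fide flavoprotein oxidases
#'     (~10^4-10^6 M^-1 s^-1).
#'   \item \code{k_oxidase_strict} (default 1e4): O2 constant at or above the
#'     bona fide oxidase range, required to call "oxidase" when no
#'     cytochrome-c data exist.
#' }
#' @return named list of thresholds.
#' @export
classifyThresholds <- function() {
  list(r_dehydro = 100, k_oxidase_floor = 10^3.5, k_oxidase_strict = 1e4)
}

#' Per-enzyme set of bimolecular rate constants
#'
#' @param enzyme enzyme label.
#' @param k_ox_O2 O2 bimolecular constant (M^-1 s^-1), > 0.
#' @param k_ox1_cytc,k_ox2_cytc optional fast/slow-phase cytochrome-c
#'   constants (M^-1 s^-1); if both given, \code{k_ox1_cytc > k_ox2_cytc}.
#' @param has_signal_peptide,has_adjacent_cytc genomic signpost flags.
#' @return A \code{"RateConstantSet"} list.
#' @export
rateConstantSet <- function(enzyme, k_ox_O2, k_ox1_cytc = NA_real_,
                            k_ox2_cytc = NA_real_,
                            has_signal_peptide = NA,
                            has_adjacent_cytc = NA) {
  if (!isScalarNumber(k_ox_O2) || k_ox_O2 <= 0)
    stopf("k_ox_O2 must be > 0")
  if (!is.na(k_ox2_cytc)) {
    if (is.na(k_ox1_cytc))
      stopf("k_ox2_cytc given without k_ox1_cytc")
    if (k_ox1_cytc <= k_ox2_cytc)
      stopf("ordering convention violated: k_ox1_cytc must exceed k_ox2_cytc")
  }
  if (!is.na(k_ox1_cytc) && k_ox1_cytc <= 0) stopf("k_ox1_cytc must be > 0")
  structure(list(enzyme = enzyme, k_ox_O2 = k_ox_O2,
                 k_ox1_cytc = k_ox1_cytc, k_ox2_cytc = k_ox2_cytc,
                 has_signal_peptide = has_signal_peptide,
                 has_adjacent_cytc = has_adjacent_cytc),
            class = "RateConstantSet")
}

#' Classify an enzyme's oxidant preference
#'
#' Rule set (first match wins), against \code{\link{classifyThresholds}}:
#' \enumerate{
#'   \item \strong{dehydrogenase}: cytochrome-c data present and
#'     \code{k_ox1_cytc / k_ox_O2 >= r_dehydro}.
#'   \item \strong{dual}: cytochrome-c data present,
#'     \code{k_ox_O2 >= k_oxidase_floor} and \code{1 <= ratio < r_dehydro} -
#'     appreciable reactivity with both oxidants.
#'   \item \strong{oxidase}: no cytochrome-c data and
#'     \code{k_ox_O2 >= k_oxidase_strict}.
#'   \item \strong{indeterminate}: anything else, e.g. a near-free-flavin O2
#'     rate with only modest cytochrome-c reactivity (solution assays may
#'     underreport membrane-bound c4-type cytochrome partners), or a slow-O2
#'     enzyme with a TAT signal but no cytochrome-c partner, which may use an
#'     unknown periplasmic oxidant.
#' }
#'
#' @param rc a \code{\link{rateConstantSet}}.
#' @param thresholds list as returned by \code{\link{classifyThresholds}}.
#' @return A \code{"PreferenceCall"} list: \code{enzyme}, \code{category},
#'   \code{ratio} (or NA), and a \code{rationale} string naming the rule that
#'   fired.
#' @examples
#' classify(rateConstantSet("NicA2", 27, 1.0e6, 2.7e5))$category
#' @export
classify <- function(rc, thresholds = classifyThresholds()) {
  stopifnot(inherits(rc, "RateConstantSet"))
  th <- thresholds
  ratio <- if (!is.na(rc$k_ox1_cytc))
    preferenceRatio(rc$k_ox1_cytc, rc$k_ox_O2) else NA_real_

  if (!is.na(ratio) && ratio >= th$r_dehydro) {
    category <- "dehydrogenase"
    why <- sprintf("k_ox1_CytC/k_ox_O2 = %.3g >= %g", ratio, th$r_dehydro)
  } else if (!is.na(ratio) && rc$k_ox_O2 >= th$k_oxidase_floor &&
             ratio >= 1) {
    category <- "dual"
    why <- sprintf("k_ox_O2 = %.3g >= %.3g and 1 <= ratio %.3g < %g",
                   rc$k_ox_O2, th$k_oxidase_floor, ratio, th$r_dehydro)
  } else if (is.na(ratio) && rc$k_ox_O2 >= th$k_oxidase_strict) {
    category <- "oxidase"
    why <- sprintf("no CytC constants and k_ox_O2 = %.3g >= %g (bona fide oxidase range)",
                   rc$k_ox_O2, th$k_oxidase_strict)
  } else {
    category <- "indeterminate"
    why <- if (is.na(ratio))
      sprintf("no CytC constants and k_ox_O2 = %.3g below oxidase range",
              rc$k_ox_O2)
    else
      sprintf("ratio %.3g < %g with k_ox_O2 = %.3g below oxidase floor",
              ratio, th$r_dehydro, rc$k_ox_O2)
  }
  structure(list(enzyme = rc$enzyme, category = category, ratio = ratio,
                 rationale = why),
            class = "PreferenceCall")
}

#' @export
print.PreferenceCall <- function(x, ...) {
  cat(sprintf("%s: %s (%s)\n", x$enzyme, x$category, x$rationale))
  invisible(x)
}

#' Classify every row of a rate-constant table
#'
#' @param rates data.frame with columns \code{enzyme}, \code{k_ox_O2},
#'   \code{k_ox1_cytc}, \code{k_ox2_cytc} (NA where not measured), as
#'   returned by \code{\link{faoReferenceRates}} or \code{\link{runKinetics}}.
#' @param thresholds see \code{\link{classifyThresholds}}.
#' @return data.frame with \code{enzyme}, \code{category}, \code{ratio},
#'   \code{rationale}.
#' @export
classifyRateTable <- function(rates, thresholds = classifyThresholds()) {
  calls <- lapply(seq_len(nrow(rates)), function(i) {
    r <- rates[i, ]
    classify(rateConstantSet(r$enzyme, r$k_ox_O2,
                             k_ox1_cytc = r$k_ox1_cytc,
                             k_ox2_cytc = r$k_ox2_cytc),
             thresholds)
  })
  data.frame(enzyme = vapply(calls, `[[`, "", "enzyme"),
             category = vapply(calls, `[[`, "", "category"),
             ratio = vapply(calls, `[[`, numeric(1), "ratio"),
             rationale = vapply(calls, `[[`, "", "rationale"),
             stringsAsFactors = FALSE)
}
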