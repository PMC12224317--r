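# End-to-end orchestration: trace manifest -> rate-constant table ->
# preference calls, and genomes + tree -> categories -> ancestral states ->
# transition counts.

#' Run configuration
#'
#' Collects every tunable threshold of the pipeline in one auditable list;
#' the configuration is serialized next to any written output for
#' provenance.
#'
#' @param seed RNG seed used by any stochastic step.
#' @param window_bp,window_genes operon adjacency window
#'   (\code{\link{scanFaoContext}}).
#' @param identity_cutoff duplicate-identity cutoff
#'   (\code{\link{dedupeByIdentity}}).
#' @param phase_margin,amp_floor_mult phase-count selection rules
#'   (\code{\link{selectPhaseCount}}).
#' @param thresholds classification thresholds
#'   (\code{\link{classifyThresholds}}).
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(seed = 1L, window_bp = 3000L, window_genes = 2L,
                      identity_cutoff = 0.98, phase_margin = 10,
                      amp_floor_mult = 3,
                      thresholds = classifyThresholds()) {
  structure(list(seed = seed, window_bp = window_bp,
                 window_genes = window_genes,
                 identity_cutoff = identity_cutoff,
                 phase_margin = phase_margin,
                 amp_floor_mult = amp_floor_mult,
                 thresholds = thresholds),
            class = "RunConfig")
}

#' @noRd
writeConfig <- function(config, dir) {
  jsonlite::write_json(unclass(config), file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Kinetics pipeline: trace manifest to rate constants and preference calls
#'
#' For each enzyme/oxidant group in the manifest: read every trace, choose
#' the phase count (forced to 1 for O2 per the single-exponential behavior
#' of the O2 reaction; selected by information criterion for CytC), fit,
#' regress k_obs against oxidant concentration, and report the slope(s) as
#' bimolecular constants. Rows are then classified by oxidant preference.
#'
#' @param manifest data.frame (or CSV path) with columns \code{file},
#'   \code{enzyme}, \code{oxidant} ("O2"/"CytC"), \code{oxidant_conc_M}.
#'   Trace lists from \code{\link{genStoppedFlowDataset}} can be passed via
#'   \code{traces} to skip file I/O.
#' @param config a \code{\link{runConfig}}.
#' @param traces optional named list mapping \code{manifest$file} to
#'   \code{\link{faoTrace}} objects (bypasses reading from disk).
#' @param dir optional output directory for the rate table, calls and
#'   configuration.
#' @return list with \code{rates} (data.frame: enzyme, k_ox_O2, k_ox1_cytc,
#'   k_ox2_cytc, intercepts), \code{calls}
#'   (\code{\link{classifyRateTable}} output), and per-group fit details.
#' @export
runKinetics <- function(manifest, config = runConfig(), traces = NULL,
                        dir = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  need <- c("file", "enzyme", "oxidant", "oxidant_conc_M")
  if (nrow(manifest) == 0L) {
    empty <- data.frame(enzyme = character(0), k_ox_O2 = numeric(0),
                        k_ox1_cytc = numeric(0), k_ox2_cytc = numeric(0))
    return(list(rates = empty, calls = classifyRateTable(empty),
                fits = list()))
  }
  if (!all(need %in% names(manifest)))
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))

  getTrace <- function(f) {
    if (!is.null(traces) && f %in% names(traces)) return(traces[[f]])
    if (is.na(f) || !file.exists(f))
      stopf("missing trace file: %s", f)
    readTraceCsv(f)
  }

  groups <- split(seq_len(nrow(manifest)),
                  paste(manifest$enzyme, manifest$oxidant, sep = "\r"))
  fits <- list()
  rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    enzyme <- manifest$enzyme[idx[1]]
    oxidant <- manifest$oxidant[idx[1]]
    trs <- lapply(manifest$file[idx], getTrace)
    conc <- manifest$oxidant_conc_M[idx]

    if (oxidant == "O2") {
      n_phases <- 1L
    } else {
      picks <- vapply(trs, function(tr)
        as.integer(selectPhaseCount(tr, margin = config$phase_margin,
                                    amp_floor_mult = config$amp_floor_mult)),
        integer(1))
      n_phases <- if (mean(picks == 2L) >= 0.5) 2L else 1L
    }
    frs <- lapply(trs, fitExponential, n_phases = n_phases)
    bad <- !vapply(frs, `[[`, logical(1), "converged")
    if (any(bad))
      stopf("unconverged fit for enzyme %s (%s), trace(s) %s", enzyme,
            oxidant, paste(manifest$file[idx][bad], collapse = ", "))
    k1 <- vapply(frs, function(f)
      if (f$n_phases == 2L) f$k_obs1 else f$k_obs, numeric(1))
    bf1 <- fitBimolecular(conc, k1)
    bf2 <- NULL
    if (n_phases == 2L) {
      k2 <- vapply(frs, `[[`, numeric(1), "k_obs2")
      bf2 <- fitBimolecular(conc, k2)
    }
    fits[[g]] <- list(enzyme = enzyme, oxidant = oxidant,
                      n_phases = n_phases, fit_results = frs,
                      regress_fast = bf1, regress_slow = bf2)
    rows[[g]] <- data.frame(enzyme = enzyme, oxidant = oxidant,
                            k_fast = bf1$k_ox,
                            k_slow = if (is.null(bf2)) NA_real_ else bf2$k_ox,
                            intercept_fast = bf1$intercept,
                            stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  enzymes <- unique(long$enzyme)
  rates <- do.call(rbind, lapply(enzymes, function(e) {
    o2 <- long[long$enzyme == e & long$oxidant == "O2", ]
    cc <- long[long$enzyme == e & long$oxidant == "CytC", ]
    data.frame(enzyme = e,
               k_ox_O2 = if (nrow(o2)) o2$k_fast[1] else NA_real_,
               k_ox1_cytc = if (nrow(cc)) cc$k_fast[1] else NA_real_,
               k_ox2_cytc = if (nrow(cc)) cc$k_slow[1] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  calls <- classifyRateTable(
    rates[!is.na(rates$k_ox_O2), , drop = FALSE], config$thresholds)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(rates, file.path(dir, "rate_constants.csv"),
                     row.names = FALSE)
    utils::write.csv(calls, file.path(dir, "preference_calls.csv"),
                     row.names = FALSE)
    writeConfig(config, dir)
  }
  list(rates = rates, calls = calls, fits = fits)
}

#' Screen-to-tree pipeline: genomes and phylogeny to ancestral categories
#'
#' Scans every FAO gene in the annotated records for its operon category,
#' joins categories onto the tree tips, estimates the Mk rate by maximum
#' likelihood, reconstructs marginal ancestral states, and counts category
#' transitions (independent origins).
#'
#' @param records gene-record data.frame (see
#'   \code{\link{readGenBankFeatures}}) or a GenBank flat-file path.
#' @param tree rooted \code{ape::phylo} or Newick path; tip labels must
#'   match FAO locus ids unless \code{tip_map} is given.
#' @param config a \code{\link{runConfig}}.
#' @param fao_pattern regex on \code{product} identifying FAO genes.
#' @param tip_map optional named character vector mapping tip labels to
#'   locus ids.
#' @param dir optional output directory (category table, node
#'   probabilities, annotated Newick, configuration).
#' @return list with \code{categories} (locus/category/evidence),
#'   \code{alpha} (ML rate), \code{node_probs}, \code{node_states},
#'   \code{transitions}, \code{annotated_tree}, and
#'   \code{unmatched_tips}.
#' @export
runScreenToTree <- function(records, tree, config = runConfig(),
                            fao_pattern = "amine oxidoreductase",
                            tip_map = NULL, dir = NULL) {
  if (is.character(records)) records <- readGenBankFeatures(records)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))

  fao_idx <- grep(fao_pattern, records$product)
  cats <- lapply(fao_idx, function(i)
    scanFaoContext(records, i, window_bp = config$window_bp,
                   window_genes = config$window_genes))
  categories <- data.frame(
    locus = vapply(cats, `[[`, "", "locus"),
    category = vapply(cats, `[[`, "", "category"),
    evidence = vapply(cats, `[[`, "", "evidence"),
    stringsAsFactors = FALSE)

  tips <- tree$tip.label
  locus_of <- if (is.null(tip_map))
    stats::setNames(tips, tips) else tip_map[tips]
  state_of <- categories$category[match(locus_of, categories$locus)]
  unmatched <- tips[is.na(state_of)]
  if (length(unmatched)) {
    warnf("tips without a scanned category (dropped): %s",
          paste(unmatched, collapse = ", "))
    tree <- ape::drop.tip(tree, unmatched)
    if (is.null(tree) || length(tree$tip.label) < 2L)
      stopf("fewer than 2 matched tips remain")
    tips <- tree$tip.label
    state_of <- categories$category[match(locus_of[tips], categories$locus)]
  }
  tip_states <- data.frame(tip_label = tips, category = state_of,
                           stringsAsFactors = FALSE)

  alpha <- estimateMkRate(tree, tip_states)
  probs <- marginalAncestralProbs(tree, tip_states, as.numeric(alpha))
  node_states <- maxProbStates(tree, tip_states, probs)
  trans <- countTransitions(tree, node_states)
  atree <- annotateTreeStates(tree, node_states)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(categories, file.path(dir, "categories.csv"),
                     row.names = FALSE)
    writeTipStates(tip_states, file.path(dir, "tip_states.csv"))
    utils::write.csv(
      data.frame(node = rownames(probs), probs, check.names = FALSE),
      file.path(dir, "node_probabilities.csv"), row.names = FALSE)
    ape::write.tree(atree, file.path(dir, "annotated_tree.nwk"))
    utils::write.csv(trans, file.path(dir, "transitions.csv"),
                     row.names = FALSE)
    writeConfig(config, dir)
  }
  list(categories = categories, tip_states = tip_states,
       alpha = as.numeric(alpha), node_probs = probs,
       node_states = node_states, transitions = trans,
       annotated_tree = atree, unmatched_tips = unmatched)
}
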