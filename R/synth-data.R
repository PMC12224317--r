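# Seeded generators for every input the pipeline consumes: stopped-flow
# trace sets, annotated synthetic genomes with planted operon
# configurations, and trees with discrete characters evolved under the Mk
# model. Fixing the seed makes every generator byte-reproducible.

#' Generate a stopped-flow dataset from a kinetic scheme
#'
#' Emulates one oxidant titration: one trace per ladder concentration,
#' simulated from the mass-action mechanism at post-mix concentrations, with
#' optional additive i.i.d. Gaussian absorbance noise (the instrument-noise
#' stand-in; default sigma 0.002 AU in the experimental protocol, 0 here for
#' exactness unless requested). The manifest records the generating
#' ground-truth constants.
#'
#' @param scheme a \code{\link{kineticScheme}}.
#' @param enzyme_conc post-mix reduced-enzyme concentration (M).
#' @param oxidant_ladder post-mix oxidant concentrations (M), non-empty.
#' @param oxidant \code{"O2"} or \code{"CytC"}; decides the branch and the
#'   monitored wavelength (450 vs 550 nm).
#' @param sigma Gaussian noise sd (AU), default 0.
#' @param seed RNG seed (used only when \code{sigma > 0}, but always
#'   recorded).
#' @param spec a \code{\link{spectralModel}}.
#' @param n_t points per trace.
#' @param dir optional directory: when given, traces are written as CSV (+
#'   JSON sidecars) plus a \code{manifest.csv}.
#' @return list with \code{traces} (list of \code{\link{faoTrace}}),
#'   \code{manifest} (data.frame: file, oxidant_conc_M, wavelength_nm,
#'   true constants, sigma, seed).
#' @export
genStoppedFlowDataset <- function(scheme, enzyme_conc, oxidant_ladder,
                                  oxidant = c("CytC", "O2"), sigma = 0,
                                  seed = 1L, spec = spectralModel(),
                                  n_t = 800L, dir = NULL) {
  oxidant <- match.arg(oxidant)
  if (!length(oxidant_ladder)) stopf("oxidant ladder is empty")
  if (any(oxidant_ladder <= 0)) stopf("ladder concentrations must be > 0")
  wavelength <- if (oxidant == "O2") 450 else 550

  makeTrace <- function(conc) {
    if (oxidant == "O2") {
      kapp <- scheme$k_O2 * conc
      if (kapp <= 0) stopf("O2 branch inactive")
      tg <- c(0, exp(seq(log(1 / (50 * kapp)), log(7 / kapp),
                         length.out = n_t - 1L)))
      init <- mixState(FlH2 = enzyme_conc, O2 = conc)
    } else {
      if (scheme$k1f <= 0) stopf("CytC branch inactive")
      tg <- cytcTimeGrid(scheme, conc, n_t = n_t)
      init <- mixState(FlH2 = enzyme_conc, Cox = conc)
    }
    traj <- simulateMechanism(scheme, init, tg)
    absorbanceTrace(traj, spec, wavelength, oxidant_conc = conc)
  }

  traces <- lapply(oxidant_ladder, makeTrace)
  if (sigma > 0) {
    traces <- withSeed(seed, lapply(traces, function(tr) {
      faoTrace(tr$time,
               tr$absorbance + stats::rnorm(nrow(tr), 0, sigma),
               wavelength = attr(tr, "wavelength"),
               oxidant_conc = attr(tr, "oxidant_conc"))
    }))
  }

  files <- rep(NA_character_, length(traces))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, sprintf("trace_%02d.csv", seq_along(traces)))
    for (i in seq_along(traces))
      writeTraceCsv(traces[[i]], files[i], scheme = scheme, seed = seed)
  }
  manifest <- data.frame(
    file = files,
    oxidant = oxidant,
    oxidant_conc_M = oxidant_ladder,
    wavelength_nm = wavelength,
    enzyme_conc_M = enzyme_conc,
    true_k_O2 = scheme$k_O2, true_k1f = scheme$k1f, true_k2f = scheme$k2f,
    sigma_AU = sigma, seed = seed,
    stringsAsFactors = FALSE)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(traces = traces, manifest = manifest)
}

#' @noRd
randomProtein <- function(n) paste(sample(AA_ALPHABET20, n, TRUE),
                                   collapse = "")

# random protein with no accidental TAT/CytC motifs: strip R, C, H
#' @noRd
randomDecoyProtein <- function(n) {
  alpha <- setdiff(AA_ALPHABET20, c("R", "C", "H", "W"))
  paste(sample(alpha, n, TRUE), collapse = "")
}

#' @noRd
tatLeader <- function() paste0("MSTRRNFLK", "AAVLLGALAG")

# planted protein builders; mature domains avoid R/C/H so the only motifs
# are the planted ones
#' @noRd
plantFaoProtein <- function(tat = TRUE, fused = FALSE, length_aa = 500L) {
  lead <- if (tat) tatLeader() else paste0("M", randomDecoyProtein(18L))
  if (fused) {
    body <- randomDecoyProtein(length_aa - nchar(lead) - 85L)
    cterm <- paste0(randomDecoyProtein(40L), "CAGCH", randomDecoyProtein(40L))
    paste0(lead, body, cterm)
  } else {
    paste0(lead, randomDecoyProtein(length_aa - nchar(lead)))
  }
}

#' @noRd
plantCytcProtein <- function(class = c("class_I_monoheme", "c4_diheme")) {
  class <- match.arg(class)
  if (class == "class_I_monoheme")
    paste0("M", randomDecoyProtein(39L), "CAGCH", randomDecoyProtein(55L))
  else
    paste0("M", randomDecoyProtein(49L), "CAGCH", randomDecoyProtein(69L),
           "CTTCH", randomDecoyProtein(60L))
}

#' Generate synthetic annotated genomes with planted operon configurations
#'
#' Builds one contig per requested FAO gene, planting the gene in the
#' requested category together with decoy genes and (for "blue") an adjacent
#' class I cytochrome-c gene:
#' \itemize{
#'   \item \strong{black}: FAO without signal peptide, no cytochrome nearby;
#'   \item \strong{blue}: TAT-signal FAO with a monoheme cytochrome c gene
#'     within the adjacency window;
#'   \item \strong{green}: single FAO-cytochrome fusion gene with TAT signal;
#'   \item \strong{red}: TAT-signal FAO with no cytochrome gene on the
#'     contig.
#' }
#'
#' @param categories character vector of planted categories (one FAO/contig
#'   each), from \code{\link{operonStates}}.
#' @param seed RNG seed.
#' @param intergenic_gap gap (bp) between planted operon genes, default 150
#'   (inside the 3000-bp adjacency window).
#' @param decoys decoy genes per contig, default 2.
#' @param dir optional directory: writes \code{genomes.gbk},
#'   \code{proteins.faa} and \code{truth.csv}.
#' @return list with \code{records} (gene-record data.frame),
#'   \code{truth} (data.frame: locus, contig, category).
#' @export
genSyntheticOperons <- function(categories, seed = 1L,
                                intergenic_gap = 150L, decoys = 2L,
                                dir = NULL) {
  bad <- setdiff(categories, operonStates())
  if (length(bad)) stopf("unknown categories: %s", paste(bad, collapse = ", "))
  withSeed(seed, {
    all_records <- list(); truth <- list()
    for (ci in seq_along(categories)) {
      cat_i <- categories[ci]
      contig <- sprintf("ctg%02d", ci)
      genes <- list()
      # upstream decoys
      for (d in seq_len(decoys))
        genes[[length(genes) + 1L]] <- list(
          product = "hypothetical protein",
          protein = paste0("M", randomDecoyProtein(149L)), fao = FALSE)
      fao_locus_idx <- NULL
      if (cat_i == "black") {
        genes[[length(genes) + 1L]] <- list(
          product = "flavin amine oxidoreductase",
          protein = plantFaoProtein(tat = FALSE), fao = TRUE)
      } else if (cat_i == "red") {
        genes[[length(genes) + 1L]] <- list(
          product = "flavin amine oxidoreductase",
          protein = plantFaoProtein(tat = TRUE), fao = TRUE)
      } else if (cat_i == "green") {
        genes[[length(genes) + 1L]] <- list(
          product = "flavin amine oxidoreductase-cytochrome c fusion",
          protein = plantFaoProtein(tat = TRUE, fused = TRUE), fao = TRUE)
      } else { # blue: FAO + adjacent monoheme CytC
        genes[[length(genes) + 1L]] <- list(
          product = "flavin amine oxidoreductase",
          protein = plantFaoProtein(tat = TRUE), fao = TRUE)
        genes[[length(genes) + 1L]] <- list(
          product = "cytochrome c",
          protein = plantCytcProtein("class_I_monoheme"), fao = FALSE)
      }
      # downstream decoy
      genes[[length(genes) + 1L]] <- list(
        product = "hypothetical protein",
        protein = paste0("M", randomDecoyProtein(119L)), fao = FALSE)

      pos <- 101L
      for (g in seq_along(genes)) {
        len_nt <- 3L * (nchar(genes[[g]]$protein) + 1L)
        locus <- sprintf("%s_g%02d", contig, g)
        all_records[[length(all_records) + 1L]] <- data.frame(
          locus = locus, contig = contig,
          start = pos, end = pos + len_nt - 1L, strand = "+",
          product = genes[[g]]$product, protein = genes[[g]]$protein,
          stringsAsFactors = FALSE)
        if (genes[[g]]$fao)
          truth[[length(truth) + 1L]] <- data.frame(
            locus = locus, contig = contig, category = cat_i,
            stringsAsFactors = FALSE)
        pos <- pos + len_nt + intergenic_gap
      }
    }
    records <- if (length(all_records)) do.call(rbind, all_records)
      else data.frame(locus = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product = character(0),
                      protein = character(0), stringsAsFactors = FALSE)
    truth <- if (length(truth)) do.call(rbind, truth)
      else data.frame(locus = character(0), contig = character(0),
                      category = character(0), stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      writeGenBankFeatures(records, file.path(dir, "genomes.gbk"))
      writeProteinFasta(stats::setNames(records$protein, records$locus),
                        file.path(dir, "proteins.faa"))
      utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    }
    list(records = records, truth = truth)
  })
}

# simulate Mk character evolution along one branch; returns final state and
# number of change events
#' @noRd
evolveBranch <- function(state, t, alpha, states) {
  changes <- 0L
  time <- 0
  repeat {
    if (alpha <= 0) break
    wait <- stats::rexp(1, alpha)
    if (time + wait > t) break
    time <- time + wait
    state <- sample(setdiff(states, state), 1L)
    changes <- changes + 1L
  }
  list(state = state, changes = changes)
}

#' Generate a Yule tree with an Mk-evolved discrete character
#'
#' Simulates a pure-birth (Yule) tree, draws the root state uniformly, and
#' evolves the character along each branch with exponential waiting times at
#' total rate \code{alpha} (jumping uniformly among the other states), i.e.
#' exactly the equal-rates Mk process the reconstruction assumes. The true
#' node states and the number of change events are recorded.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate Yule speciation rate, default 1.
#' @param alpha Mk transition rate (>= 0; 0 means no change).
#' @param seed RNG seed.
#' @param states state space, default \code{\link{operonStates}}.
#' @param dir optional directory: writes \code{tree.nwk} and
#'   \code{tip_states.csv}.
#' @return list with \code{tree} (\code{ape::phylo}), \code{tip_states}
#'   (data.frame tip_label/category), \code{node_states} (true states, ape
#'   numbering), \code{n_changes} (true change events over the tree).
#' @export
genCharacterTree <- function(n_tips, birth_rate = 1, alpha = 0.5, seed = 1L,
                             states = operonStates(), dir = NULL) {
  if (n_tips < 2L) stopf("n_tips must be >= 2")
  withSeed(seed, {
    tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    root <- ntip + 1L
    node_states <- character(nnode)
    node_states[root] <- sample(states, 1L)
    n_changes <- 0L
    edge <- ape::reorder.phylo(tree, "postorder")$edge
    blen <- ape::reorder.phylo(tree, "postorder")$edge.length
    for (e in rev(seq_len(nrow(edge)))) {   # preorder: parents first
      par <- edge[e, 1]; child <- edge[e, 2]
      ev <- evolveBranch(node_states[par], blen[e], alpha, states)
      node_states[child] <- ev$state
      n_changes <- n_changes + ev$changes
    }
    names(node_states) <- c(tree$tip.label, paste0("n", (ntip + 1L):nnode))
    tip_states <- data.frame(tip_label = tree$tip.label,
                             category = node_states[seq_len(ntip)],
                             stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      ape::write.tree(tree, file.path(dir, "tree.nwk"))
      writeTipStates(tip_states, file.path(dir, "tip_states.csv"))
    }
    list(tree = tree, tip_states = tip_states, node_states = node_states,
         n_changes = n_changes)
  })
}
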