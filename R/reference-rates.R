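#' Published stopped-flow rate constants for characterized FAOs
#'
#' Second-order rate constants (M^-1 s^-1) for flavin reoxidation by O2
#' (single phase, 450 nm) and by the genome-associated cytochrome c (two
#' phases, 550 nm) for the experimentally characterized members of the three
#' dehydrogenase-containing FAO clades, together with their genomic signpost
#' flags (TAT signal peptide; adjacent cytochrome-c gene). \code{NA} in the
#' cytochrome-c columns means the measurement could not be performed because
#' the enzyme has no genome-associated cytochrome c.
#'
#' These values serve as inputs: seeds for simulation-based recovery checks
#' and rows for \code{\link{classifyRateTable}}.
#'
#' @return data.frame with columns \code{enzyme}, \code{clade},
#'   \code{k_ox_O2}, \code{k_ox1_cytc}, \code{k_ox2_cytc},
#'   \code{has_signal_peptide}, \code{has_adjacent_cytc}.
#' @examples
#' rates <- faoReferenceRates()
#' subset(rates, clade == 3 & !is.na(k_ox1_cytc))
#' @export
faoReferenceRates <- function() {
  df <- rbind(
    # clade 2
    data.frame(enzyme = "T. dinghuensis", clade = 2, k_ox_O2 = 380,
               k_ox1_cytc = 2.4e5, k_ox2_cytc = 3.5e4, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "B. anthina", clade = 2, k_ox_O2 = 4.8e3,
               k_ox1_cytc = 2.9e4, k_ox2_cytc = 1.1e3, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "E. alkalisoli", clade = 2, k_ox_O2 = 670,
               k_ox1_cytc = 3.4e5, k_ox2_cytc = 1.1e4, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "B. cepacia", clade = 2, k_ox_O2 = 1.9e3,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = FALSE, cytc = FALSE),
    data.frame(enzyme = "R. sordida", clade = 2, k_ox_O2 = 6.1e3,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = FALSE, cytc = FALSE),
    data.frame(enzyme = "Janthinobacterium sp. PC23-8", clade = 2,
               k_ox_O2 = 1.2e4,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = FALSE, cytc = FALSE),
    data.frame(enzyme = "P. reinekei", clade = 2, k_ox_O2 = 2.6e4,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = TRUE, cytc = FALSE),
    data.frame(enzyme = "P. putida OR45a", clade = 2, k_ox_O2 = 1.6e4,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = FALSE, cytc = FALSE),
    # clade 3
    data.frame(enzyme = "Pseudomonas sp. GL-RE-19", clade = 3, k_ox_O2 = 24,
               k_ox1_cytc = 3.5e5, k_ox2_cytc = 6.8e4, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "K. lipolytica", clade = 3, k_ox_O2 = 1.8e3,
               k_ox1_cytc = 1.0e6, k_ox2_cytc = 1.3e5, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "M. nitratireducens", clade = 3, k_ox_O2 = 390,
               k_ox1_cytc = 4.3e5, k_ox2_cytc = 3.9e4, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "P. taiwanensis", clade = 3, k_ox_O2 = 6.6e3,
               k_ox1_cytc = 2.8e6, k_ox2_cytc = 3.7e5, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "P. nitroreducens", clade = 3, k_ox_O2 = 1.9e3,
               k_ox1_cytc = 7.2e5, k_ox2_cytc = 2.1e4, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "T. aromatica", clade = 3, k_ox_O2 = 1.6e3,
               k_ox1_cytc = 4.7e5, k_ox2_cytc = 1.1e5, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "NicA2", clade = 3, k_ox_O2 = 27,
               k_ox1_cytc = 1.0e6, k_ox2_cytc = 2.7e5, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "Pnao", clade = 3, k_ox_O2 = 600,
               k_ox1_cytc = 1.4e5, k_ox2_cytc = 3.2e4, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "NctB", clade = 3, k_ox_O2 = 1.9e3,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = FALSE, cytc = FALSE),
    data.frame(enzyme = "A. digitatis", clade = 3, k_ox_O2 = 1.6e4,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = FALSE, cytc = FALSE),
    data.frame(enzyme = "Sphingopyxis sp. YR83", clade = 3, k_ox_O2 = 2.7e3,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = TRUE, cytc = FALSE),
    data.frame(enzyme = "Streptomyces sp. CJ13", clade = 3, k_ox_O2 = 5.1e4,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = FALSE, cytc = FALSE),
    data.frame(enzyme = "Synechococcus sp. UW140", clade = 3, k_ox_O2 = 5.6e4,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = FALSE, cytc = FALSE),
    data.frame(enzyme = "Erythrobacter sp. 1414", clade = 3, k_ox_O2 = 470,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = TRUE, cytc = FALSE),
    data.frame(enzyme = "R. tatauoinensis", clade = 3, k_ox_O2 = 3.1e3,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = TRUE, cytc = FALSE),
    # clade 1 (membrane-bound diheme c4-type cytochrome partners)
    data.frame(enzyme = "B. metallica", clade = 1, k_ox_O2 = 320,
               k_ox1_cytc = 990, k_ox2_cytc = NA, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "P. aeruginosa", clade = 1, k_ox_O2 = 160,
               k_ox1_cytc = 290, k_ox2_cytc = NA, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "B. stagnalis", clade = 1, k_ox_O2 = 590,
               k_ox1_cytc = 2.7e3, k_ox2_cytc = 210, sp = TRUE, cytc = TRUE),
    data.frame(enzyme = "P. otitidis", clade = 1, k_ox_O2 = 4.5e3,
               k_ox1_cytc = NA, k_ox2_cytc = NA, sp = TRUE, cytc = FALSE)
  )
  names(df)[names(df) == "sp"] <- "has_signal_peptide"
  names(df)[names(df) == "cytc"] <- "has_adjacent_cytc"
  df
}
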