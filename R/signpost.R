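# Sequence-motif screen for the two genomic signposts of dehydrogenase
# function: a twin-arginine (TAT) export signal on the FAO and a c-type
# cytochrome gene in the immediate operon neighborhood.

HYDROPHOBIC <- c("A", "F", "G", "I", "L", "M", "V", "W")

# length of the longest hydrophobic run inside chars[from:to]; also returns
# the start of the first run of at least min_len
#' @noRd
hydrophobicRun <- function(chars, from, to, min_len) {
  from <- max(1L, from); to <- min(length(chars), to)
  if (from > to) return(NULL)
  run <- 0L; run_start <- NA_integer_
  for (i in from:to) {
    if (chars[i] %in% HYDROPHOBIC) {
      if (run == 0L) run_start <- i
      run <- run + 1L
      if (run >= min_len) return(list(start = run_start, length = run))
    } else run <- 0L
  }
  NULL
}

#' Detect a twin-arginine (TAT) export signal peptide
#'
#' Heuristic motif rule standing in for a trained signal-peptide predictor:
#' a protein is called TAT iff the twin-arginine consensus
#' \code{[S/T]-R-R-x-Phi} (Phi hydrophobic: A,F,G,I,L,M,V,W) occurs within
#' the first 35 residues AND is followed within 25 residues by a run of at
#' least 6 consecutive hydrophobic residues (the signal's h-region). The
#' rule is transparent and exactly testable; users screening real proteomes
#' can substitute an external predictor and feed its calls into
#' \code{\link{scanFaoContext}} via the \code{signal_fun} plug-in.
#'
#' @param protein amino-acid sequence (single string, 20-letter alphabet),
#'   length >= 30.
#' @return A \code{"SignalCall"} list: \code{type} ("TAT" or "none"),
#'   \code{motif_position} (position of the S/T), \code{evidence}.
#' @examples
#' tat <- paste0("MSTRRNFLK", "AAVLLGALAG", strrep("D", 80))
#' detectTatSignal(tat)$type
#' @export
detectTatSignal <- function(protein) {
  protein <- checkProtein(protein)
  if (nchar(protein) < 30L) stopf("protein too short (< 30 aa)")
  chars <- strsplit(protein, "")[[1]]
  pat <- sprintf("[ST]RR.[%s]", paste(HYDROPHOBIC, collapse = ""))
  m <- regexpr(pat, substr(protein, 1L, 39L))   # motif must START <= 35
  pos <- as.integer(m)
  if (pos > 0L && pos <= 35L) {
    motif_end <- pos + 4L
    run <- hydrophobicRun(chars, motif_end + 1L, motif_end + 25L, 6L)
    if (!is.null(run))
      return(structure(list(type = "TAT", motif_position = pos,
                            cleavage_position = NA_integer_,
                            evidence = sprintf(
                              "twin-arginine consensus at %d; hydrophobic run of %d at %d",
                              pos, run$length, run$start)),
                       class = "SignalCall"))
  }
  structure(list(type = "none", motif_position = NA_integer_,
                 cleavage_position = NA_integer_,
                 evidence = "no twin-arginine consensus with h-region"),
            class = "SignalCall")
}

#' Detect a general-secretory (Sec) signal peptide
#'
#' Heuristic rule, mutually exclusive with \code{\link{detectTatSignal}}: a
#' protein is called Sec iff it is NOT called TAT, has at least one K/R in
#' residues 1-7 (n-region charge), a run of >= 7 consecutive hydrophobic
#' residues within residues 5-25 (h-region), and an A-x-A cleavage motif
#' within residues 15-35.
#'
#' @inheritParams detectTatSignal
#' @return A \code{"SignalCall"} list: \code{type} ("Sec" or "none"),
#'   \code{motif_position} (h-region start), \code{cleavage_position}
#'   (first A of the A-x-A), \code{evidence}.
#' @examples
#' pelb <- paste0("MKYLLPTAAAGLLLLAAQPAMA", strrep("E", 80))
#' detectSecSignal(pelb)$type
#' @export
detectSecSignal <- function(protein) {
  protein <- checkProtein(protein)
  if (nchar(protein) < 30L) stopf("protein too short (< 30 aa)")
  if (detectTatSignal(protein)$type == "TAT")
    return(structure(list(type = "none", motif_position = NA_integer_,
                          cleavage_position = NA_integer_,
                          evidence = "TAT call takes precedence"),
                     class = "SignalCall"))
  chars <- strsplit(protein, "")[[1]]
  nregion <- chars[1:7]
  run <- hydrophobicRun(chars, 5L, 25L, 7L)
  cle <- regexpr("A.A", substr(protein, 15L, 35L))
  cle_pos <- if (as.integer(cle) > 0L) as.integer(cle) + 14L else NA_integer_
  if (any(nregion %in% c("K", "R")) && !is.null(run) && !is.na(cle_pos))
    structure(list(type = "Sec", motif_position = run$start,
                   cleavage_position = cle_pos,
                   evidence = sprintf(
                     "charged n-region; hydrophobic core at %d; A-x-A at %d",
                     run$start, cle_pos)),
              class = "SignalCall")
  else
    structure(list(type = "none", motif_position = NA_integer_,
                   cleavage_position = NA_integer_,
                   evidence = "Sec criteria not met"),
              class = "SignalCall")
}

#' Detect c-type cytochrome heme-binding motifs
#'
#' Counts non-overlapping C-x-x-C-H heme-attachment motifs and assigns a
#' cytochrome class by motif count and size: one motif in a protein of <=
#' 130 aa is a prototypical ~11 kDa class I monoheme cytochrome c; two
#' motifs at 150-250 aa is a ~20 kDa diheme c4-type cytochrome. Any other
#' combination is reported as \code{not_cytc} (the classifier is
#' deliberately conservative; a single-motif protein above 130 aa is not
#' called).
#'
#' @param protein amino-acid sequence, length >= 50.
#' @return A \code{"CytcEvidence"} list: \code{motif_count},
#'   \code{motif_positions}, \code{length_aa}, \code{class} in
#'   \code{c("class_I_monoheme", "c4_diheme", "not_cytc")}.
#' @examples
#' detectCytc(paste0(strrep("K", 40), "CAGCH", strrep("K", 55)))$class
#' @export
detectCytc <- function(protein) {
  protein <- checkProtein(protein)
  len <- nchar(protein)
  if (len < 50L) stopf("protein too short (< 50 aa)")
  hits <- gregexpr("C..CH", protein)[[1]]
  pos <- if (hits[1] > 0L) as.integer(hits) else integer(0)
  count <- length(pos)
  cls <- if (count == 1L && len <= 130L) "class_I_monoheme"
         else if (count == 2L && len >= 150L && len <= 250L) "c4_diheme"
         else "not_cytc"
  structure(list(motif_count = count, motif_positions = pos,
                 length_aa = len, class = cls),
            class = "CytcEvidence")
}

#' Detect an FAO-cytochrome c fusion protein
#'
#' A single polypeptide carrying both functions: called a fusion iff the
#' protein is at least \code{fao_length_floor} residues long (an FAO domain
#' is present), carries at least one C-x-x-C-H motif in its C-terminal 150
#' residues (the appended cytochrome domain), and has a TAT signal at the
#' N-terminus.
#'
#' @param protein amino-acid sequence.
#' @param fao_length_floor minimum length (aa) for an FAO domain, default 450.
#' @return logical.
#' @export
detectFusion <- function(protein, fao_length_floor = 450L) {
  protein <- checkProtein(protein)
  len <- nchar(protein)
  if (len < fao_length_floor) return(FALSE)
  cterm <- substr(protein, max(1L, len - 149L), len)
  if (!grepl("C..CH", cterm)) return(FALSE)
  detectTatSignal(protein)$type == "TAT"
}

#' Categorize an FAO gene by its operon context
#'
#' Applies the two genetic signposts of dehydrogenase function to one FAO
#' locus in its annotated neighborhood and returns one of four categories:
#' \describe{
#'   \item{green}{FAO and cytochrome c fused as a single polypeptide.}
#'   \item{blue}{FAO with a TAT signal peptide and an adjacent cytochrome-c
#'     gene (putative dehydrogenase operon).}
#'   \item{red}{FAO with a TAT signal peptide but no adjacent cytochrome c.}
#'   \item{black}{FAO with neither signpost.}
#' }
#' "Adjacent" means at most \code{window_genes} intervening genes AND at
#' most \code{window_bp} between gene boundaries, strand-agnostic (a
#' same-strand flag is reported in the evidence).
#'
#' @param records data.frame of gene records on one contig, ordered by
#'   \code{start}: columns \code{locus}, \code{contig}, \code{start},
#'   \code{end} (1-based inclusive), \code{strand} ("+"/"-"),
#'   \code{product}, \code{protein}.
#' @param fao_index row index of the FAO gene in \code{records}.
#' @param window_bp maximum boundary-to-boundary gap (default 3000).
#' @param window_genes maximum intervening genes (default 2).
#' @param signal_fun plug-in signal-peptide predictor taking a protein
#'   string and returning a \code{SignalCall}; default
#'   \code{\link{detectTatSignal}}.
#' @return An \code{"OperonCategory"} list: \code{category}, \code{locus},
#'   \code{supporting} (loci of supporting genes), \code{evidence}.
#' @export
scanFaoContext <- function(records, fao_index, window_bp = 3000L,
                           window_genes = 2L, signal_fun = detectTatSignal) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stopf("records must be a non-empty data.frame of gene records")
  if (fao_index < 1L || fao_index > nrow(records))
    stopf("fao_index %d out of range", fao_index)
  fao <- records[fao_index, ]
  same_contig <- which(records$contig == fao$contig)
  ord <- same_contig[order(records$start[same_contig])]
  i <- match(fao_index, ord)

  if (detectFusion(fao$protein))
    return(structure(list(category = "green", locus = fao$locus,
                          supporting = fao$locus,
                          evidence = "FAO-CytC fusion polypeptide"),
                     class = "OperonCategory"))

  tat <- signal_fun(fao$protein)$type == "TAT"
  support <- character(0); same_strand <- logical(0)
  if (tat) {
    for (j in seq_along(ord)) {
      if (j == i) next
      if (abs(j - i) - 1L > window_genes) next
      other <- records[ord[j], ]
      gap <- if (other$start > fao$end) other$start - fao$end - 1L
             else if (fao$start > other$end) fao$start - other$end - 1L
             else 0L
      if (gap > window_bp) next
      ev <- tryCatch(detectCytc(other$protein), error = function(e) NULL)
      if (!is.null(ev) && ev$class != "not_cytc") {
        support <- c(support, other$locus)
        same_strand <- c(same_strand, other$strand == fao$strand)
      }
    }
  }
  category <- if (tat && length(support)) "blue"
              else if (tat) "red" else "black"
  evidence <- if (category == "blue")
    sprintf("TAT signal; adjacent CytC: %s (same strand: %s)",
            paste(support, collapse = ","),
            paste(same_strand, collapse = ","))
  else if (category == "red") "TAT signal; no adjacent CytC within window"
  else "no TAT signal"
  structure(list(category = category, locus = fao$locus,
                 supporting = support, evidence = evidence),
            class = "OperonCategory")
}

#' Global pairwise protein identity
#'
#' Identity of the optimal global alignment (BLOSUM62, ends-free so terminal
#' overhangs are not counted), defined as matches divided by aligned columns
#' including internal gaps and excluding terminal gaps.
#'
#' @param a,b amino-acid sequences (non-empty strings).
#' @return fraction in [0, 1].
#' @examples
#' pairwiseIdentity("MKVLITAG", "MKVLITAG")   # 1
#' @export
pairwiseIdentity <- function(a, b) {
  a <- checkProtein(a, "a"); b <- checkProtein(b, "b")
  if (nchar(a) == 0L || nchar(b) == 0L) stopf("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "overlap", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # ends-free alignment already clips terminal overhangs; drop any residual
  # terminal gap columns defensively
  keep <- seq_along(p)
  while (length(keep) && (p[keep[1]] == "-" || s[keep[1]] == "-"))
    keep <- keep[-1]
  while (length(keep) &&
         (p[keep[length(keep)]] == "-" || s[keep[length(keep)]] == "-"))
    keep <- keep[-length(keep)]
  if (!length(keep)) return(0)
  sum(p[keep] == s[keep]) / length(keep)
}

#' Greedy deduplication by pairwise identity
#'
#' Iterates over the sequences in input order and drops any sequence whose
#' identity to an already-kept sequence exceeds \code{cutoff} (single
#' linkage, deterministic for a fixed input order). The conventional
#' redundancy cutoff for building a non-redundant set is > 0.98.
#'
#' @param seqs named character vector of sequences.
#' @param cutoff identity above which a sequence is a duplicate (default
#'   0.98).
#' @return list with \code{kept} (names or indices of retained sequences)
#'   and \code{cluster} (integer vector mapping every input to the index of
#'   the kept representative).
#' @export
dedupeByIdentity <- function(seqs, cutoff = 0.98) {
  if (length(seqs) == 0L) return(list(kept = character(0), cluster = integer(0)))
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  kept <- integer(0)
  cluster <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    rep_i <- 0L
    for (k in kept) {
      if (pairwiseIdentity(seqs[[i]], seqs[[k]]) > cutoff) { rep_i <- k; break }
    }
    if (rep_i == 0L) { kept <- c(kept, i); cluster[i] <- i }
    else cluster[i] <- rep_i
  }
  list(kept = names(seqs)[kept], cluster = stats::setNames(cluster, names(seqs)))
}
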