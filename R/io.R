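# File formats: trace CSV + JSON sidecar, GenBank-style feature tables,
# protein FASTA, tip-state CSV.

#' Write a stopped-flow trace to CSV with a JSON sidecar
#'
#' The CSV has columns \code{time_s}, \code{absorbance_AU}; provenance
#' (wavelength, oxidant concentration, optional scheme and seed) goes to
#' \code{<file>.json}.
#'
#' @param trace a \code{\link{faoTrace}}.
#' @param file output CSV path.
#' @param scheme optional \code{\link{kineticScheme}} recorded in the sidecar.
#' @param seed optional RNG seed recorded in the sidecar.
#' @return \code{file}, invisibly.
#' @export
writeTraceCsv <- function(trace, file, scheme = NULL, seed = NULL) {
  stopifnot(inherits(trace, "faoTrace"))
  utils::write.csv(
    data.frame(time_s = trace$time, absorbance_AU = trace$absorbance),
    file, row.names = FALSE)
  meta <- list(wavelength_nm = attr(trace, "wavelength"),
               oxidant_conc_M = attr(trace, "oxidant_conc"))
  if (!is.null(scheme)) meta$scheme <- unclass(scheme)
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Read a stopped-flow trace CSV (with optional JSON sidecar)
#'
#' @param file CSV path with columns \code{time_s}, \code{absorbance_AU}; a
#'   sidecar \code{<file>.json} written by \code{\link{writeTraceCsv}} is
#'   picked up automatically.
#' @return a \code{\link{faoTrace}}.
#' @export
readTraceCsv <- function(file) {
  if (!file.exists(file)) stopf("trace file not found: %s", file)
  df <- utils::read.csv(file)
  if (!all(c("time_s", "absorbance_AU") %in% names(df)))
    stopf("trace CSV %s must have columns time_s, absorbance_AU", file)
  wl <- NA_real_; oc <- NA_real_
  side <- paste0(file, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    wl <- meta$wavelength_nm %||% NA_real_
    oc <- meta$oxidant_conc_M %||% NA_real_
  }
  faoTrace(df$time_s, df$absorbance_AU, wavelength = wl, oxidant_conc = oc)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write gene records as a GenBank-style flat file
#'
#' Minimal writer for annotated feature tables: one LOCUS block per contig
#' with CDS features carrying \code{/locus_tag}, \code{/product} and
#' \code{/translation} qualifiers. The sequence (ORIGIN) is omitted; the
#' screen operates on coordinates and translations only.
#'
#' @param records data.frame with columns \code{locus}, \code{contig},
#'   \code{start}, \code{end} (1-based inclusive), \code{strand},
#'   \code{product}, \code{protein}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeGenBankFeatures <- function(records, file) {
  need <- c("locus", "contig", "start", "end", "strand", "product", "protein")
  if (!all(need %in% names(records)))
    stopf("records must have columns: %s", paste(need, collapse = ", "))
  con <- file(file, "w"); on.exit(close(con))
  wrapQual <- function(name, value) {
    text <- sprintf("/%s=\"%s\"", name, value)
    idx <- seq(1L, nchar(text), by = 58L)
    chunks <- substring(text, idx, pmin(idx + 57L, nchar(text)))
    paste0(strrep(" ", 21L), chunks)
  }
  for (ctg in unique(records$contig)) {
    sub <- records[records$contig == ctg, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    len <- max(sub$end)
    writeLines(sprintf(
      "LOCUS       %-16s %d bp    DNA     linear   BCT 01-JAN-2000", ctg, len),
      con)
    writeLines(sprintf("DEFINITION  synthetic contig %s.", ctg), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", len), con)
    for (r in seq_len(nrow(sub))) {
      loc <- sprintf("%d..%d", sub$start[r], sub$end[r])
      if (sub$strand[r] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(wrapQual("locus_tag", sub$locus[r]), con)
      writeLines(wrapQual("product", sub$product[r]), con)
      writeLines(wrapQual("translation", sub$protein[r]), con)
    }
    writeLines("//", con)
  }
  invisible(file)
}

#' Read CDS features from a GenBank-style flat file
#'
#' Companion reader for \code{\link{writeGenBankFeatures}}: parses LOCUS
#' blocks and CDS features with \code{/locus_tag}, \code{/product} and
#' \code{/translation} qualifiers (multi-line qualifiers supported; other
#' features and qualifiers are ignored).
#'
#' @param file GenBank flat-file path.
#' @return data.frame with columns \code{locus}, \code{contig},
#'   \code{start}, \code{end}, \code{strand}, \code{product}, \code{protein}.
#' @export
readGenBankFeatures <- function(file) {
  if (!file.exists(file)) stopf("GenBank file not found: %s", file)
  lines <- readLines(file)
  out <- list()
  contig <- NA_character_
  cds <- NULL
  qual_lines <- character(0)

  flushCds <- function() {
    if (is.null(cds)) return()
    qtext <- paste(trimws(qual_lines), collapse = "")
    getq <- function(name) {
      m <- regmatches(qtext, regexpr(sprintf('/%s="[^"]*"', name), qtext))
      if (!length(m)) return(NA_character_)
      sub(sprintf('/%s="', name), "", sub('"$', "", m))
    }
    out[[length(out) + 1L]] <<- data.frame(
      locus = getq("locus_tag"), contig = contig,
      start = cds$start, end = cds$end, strand = cds$strand,
      product = getq("product"), protein = getq("translation"),
      stringsAsFactors = FALSE)
    cds <<- NULL; qual_lines <<- character(0)
  }

  for (ln in lines) {
    if (grepl("^LOCUS", ln)) {
      flushCds()
      contig <- strsplit(trimws(sub("^LOCUS", "", ln)), "\\s+")[[1]][1]
    } else if (grepl("^     CDS             ", ln)) {
      flushCds()
      loc <- trimws(sub("^     CDS", "", ln))
      strand <- if (grepl("^complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      cds <- list(start = nums[1], end = nums[2], strand = strand)
    } else if (!is.null(cds) && grepl("^\\s{21}", ln)) {
      qual_lines <- c(qual_lines, ln)
    } else if (grepl("^//", ln) || grepl("^     [A-Za-z]", ln)) {
      flushCds()
    }
  }
  flushCds()
  if (!length(out))
    return(data.frame(locus = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product = character(0),
                      protein = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeProteinFasta <- function(seqs, file) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, file)
  invisible(file)
}

#' Read protein sequences from FASTA
#'
#' @param file FASTA path.
#' @return named character vector.
#' @export
readProteinFasta <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  stats::setNames(as.character(aa), names(aa))
}

#' Write / read a tip-state table
#'
#' Two-column CSV (\code{tip_label}, \code{category}) linking phylogeny tips
#' to operon categories; the same file the genomic screen writes and the
#' ancestral-state module reads.
#'
#' @param states data.frame with columns \code{tip_label}, \code{category}.
#' @param file CSV path.
#' @return \code{file} (write) or the data.frame (read).
#' @export
writeTipStates <- function(states, file) {
  if (!all(c("tip_label", "category") %in% names(states)))
    stopf("states must have columns tip_label, category")
  utils::write.csv(states[c("tip_label", "category")], file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname writeTipStates
#' @export
readTipStates <- function(file) {
  if (!file.exists(file)) stopf("tip-state file not found: %s", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("tip_label", "category") %in% names(df)))
    stopf("tip-state CSV must have columns tip_label, category")
  df
}
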