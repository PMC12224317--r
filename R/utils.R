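# Internal helpers shared across modules.

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Amino-acid alphabet used for sequence validation and synthesis.
#' @noRd
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @noRd
checkProtein <- function(protein, what = "protein") {
  if (!is.character(protein) || length(protein) != 1L || is.na(protein))
    stopf("%s must be a single character string", what)
  protein <- toupper(protein)
  bad <- setdiff(unique(strsplit(protein, "")[[1]]), AA_ALPHABET20)
  if (length(bad))
    stopf("%s contains non-amino-acid characters: %s", what,
          paste(bad, collapse = ", "))
  protein
}
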