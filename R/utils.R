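# Internal helpers shared across modules.

# E-values of exactly 0 are floored here before any log10 operation.
.EVALUE_FLOOR <- 1e-180

#' Derive a stage-specific sub-seed from a master seed
#'
#' A splitmix-style integer mix so that each pipeline stage gets an
#' independent, reproducible stream from one user-facing seed.  All
#' arithmetic stays below 2^53 so it is exact in doubles; the result is a
#' valid 32-bit R seed.
#'
#' @param seed Master seed (non-negative integer).
#' @param stage Character stage label (e.g. \code{"proteomes"}).
#' @return A single integer in \code{[0, 2^31 - 2]}.
#' @export
#' @examples
#' deriveSeed(1L, "proteomes")
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  x <- (as.numeric(seed) %% 2147483647)
  # two rounds of multiply-xor-style mixing, kept in exact-double range
  x <- (x * 69069 + h + 1) %% 2147483647
  x <- (x * 69069 + 12345) %% 2147483647
  as.integer(x)
}

#' Extract the species tag from a protein identifier
#'
#' Protein IDs carry their species as the prefix up to the first underscore
#' (e.g. \code{"Zm_FIP37_3"} is a \emph{Z. marina} protein).  An optional
#' species map overrides the prefix rule for IDs that do not follow it.
#'
#' @param ids Character vector of protein identifiers.
#' @param speciesMap Optional named character vector (names = protein IDs,
#'   values = species labels) consulted before the prefix rule.
#' @return Character vector of species labels.
#' @export
#' @examples
#' speciesOf(c("Zm_FIP37_1", "At_MTA_1"))
speciesOf <- function(ids, speciesMap = NULL) {
  out <- sub("_.*$", "", ids)
  if (!is.null(speciesMap)) {
    hit <- ids %in% names(speciesMap)
    out[hit] <- unname(speciesMap[ids[hit]])
  }
  out
}

# log10 E-value with the zero floor applied
.log10E <- function(e) log10(pmax(e, .EVALUE_FLOOR))

# stop() with a consistent prefix, no call
.err <- function(...) stop(..., call. = FALSE)

.isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)
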