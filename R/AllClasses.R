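# S4 class definitions for the package's central containers.

#' FamilySpec: specification of one planted gene family
#'
#' Describes a gene family for the synthetic proteome generator: how many
#' copies each species carries, the ancestral sequence length, per-branch
#' substitution rates (substitutions/site) for speciation (ortholog) and
#' duplication (paralog) branches, and how many near-identical transcript
#' variants to add per member (emulating assembled-transcriptome isoform
#' redundancy).
#'
#' @slot familyName Single character label, e.g. \code{"FIP37"}.
#' @slot copiesPerSpecies Named integer vector, species -> copy number
#'   (>= 0).
#' @slot ancestralLength Ancestral protein length in residues (>= 30).
#' @slot subRateOrtholog Substitution rate on each speciation branch,
#'   in \code{[0, 1)}.
#' @slot subRateParalog Substitution rate on each duplication branch,
#'   in \code{[0, 1)}.
#' @slot variantCount Number of extra near-identical variants per member
#'   (>= 0).
#' @export
setClass("FamilySpec",
  representation(
    familyName = "character",
    copiesPerSpecies = "integer",
    ancestralLength = "numeric",
    subRateOrtholog = "numeric",
    subRateParalog = "numeric",
    variantCount = "integer"
  )
)

setValidity("FamilySpec", function(object) {
  msgs <- character()
  if (length(object@familyName) != 1L || !nzchar(object@familyName))
    msgs <- c(msgs, "familyName must be a single non-empty string")
  if (is.null(names(object@copiesPerSpecies)) ||
      any(!nzchar(names(object@copiesPerSpecies))))
    msgs <- c(msgs, "copiesPerSpecies must be named by species")
  if (any(object@copiesPerSpecies < 0L))
    msgs <- c(msgs, "copy numbers must be >= 0")
  if (object@ancestralLength < 30)
    msgs <- c(msgs, "ancestralLength must be >= 30 residues")
  for (r in c(object@subRateOrtholog, object@subRateParalog))
    if (r < 0 || r >= 1) msgs <- c(msgs, "substitution rates must be in [0, 1)")
  if (object@variantCount < 0L)
    msgs <- c(msgs, "variantCount must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FamilySpec
#'
#' @param familyName Family label (e.g. \code{"FIP37"}).
#' @param copiesPerSpecies Named numeric/integer vector, species -> copies.
#' @param ancestralLength Ancestral length in residues (default 120).
#' @param subRateOrtholog Speciation-branch substitution rate (default 0.10).
#' @param subRateParalog Duplication-branch substitution rate (default 0.05).
#' @param variantCount Near-identical variants per member (default 0).
#' @return A \linkS4class{FamilySpec}.
#' @export
#' @examples
#' FamilySpec("FIP37", c(Zm = 6, At = 1, Os = 1))
FamilySpec <- function(familyName, copiesPerSpecies, ancestralLength = 120,
                       subRateOrtholog = 0.10, subRateParalog = 0.05,
                       variantCount = 0) {
  new("FamilySpec",
    familyName = as.character(familyName),
    copiesPerSpecies = setNames(
      as.integer(copiesPerSpecies), names(copiesPerSpecies)),
    ancestralLength = as.numeric(ancestralLength),
    subRateOrtholog = as.numeric(subRateOrtholog),
    subRateParalog = as.numeric(subRateParalog),
    variantCount = as.integer(variantCount)
  )
}

#' RhythmSpec: one gene's diel expression rhythm
#'
#' Cosinor parameterisation of a gene-of-interest CT trajectory over a 24-h
#' cycle: \code{CT(t) = baseline - amplitude * cos(2*pi*(t - peakTime)/24)},
#' so that the CT minimum (= expression maximum) falls at \code{peakTime}.
#' The reference gene is flat at \code{referenceBaselineCt}.
#'
#' @slot gene Gene label.
#' @slot species Species label.
#' @slot baselineCt Mean CT of the gene of interest (cycles).
#' @slot amplitudeCt Cosinor amplitude in CT cycles (>= 0).
#' @slot peakTime Hour of peak expression in \code{[0, 24)}.
#' @slot noiseSd Technical-replicate Gaussian noise sd in cycles (>= 0).
#' @slot referenceBaselineCt Reference-gene CT baseline (cycles).
#' @export
setClass("RhythmSpec",
  representation(
    gene = "character", species = "character",
    baselineCt = "numeric", amplitudeCt = "numeric", peakTime = "numeric",
    noiseSd = "numeric", referenceBaselineCt = "numeric"
  )
)

setValidity("RhythmSpec", function(object) {
  msgs <- character()
  if (object@amplitudeCt < 0) msgs <- c(msgs, "amplitudeCt must be >= 0")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (object@peakTime < 0 || object@peakTime >= 24)
    msgs <- c(msgs, "peakTime must be in [0, 24)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RhythmSpec
#'
#' @param gene,species Labels.
#' @param baselineCt Mean CT of the gene of interest (default 25).
#' @param amplitudeCt Cosinor amplitude in cycles (default 1).
#' @param peakTime Hour of peak expression in \code{[0, 24)} (default 0,
#'   i.e. midnight).
#' @param noiseSd Technical noise sd in cycles (default 0.1).
#' @param referenceBaselineCt Reference-gene CT (default 20).
#' @return A \linkS4class{RhythmSpec}.
#' @export
#' @examples
#' RhythmSpec("MTA", "Cn", amplitudeCt = 1.5, peakTime = 0)
RhythmSpec <- function(gene, species, baselineCt = 25, amplitudeCt = 1,
                       peakTime = 0, noiseSd = 0.1,
                       referenceBaselineCt = 20) {
  new("RhythmSpec",
    gene = as.character(gene), species = as.character(species),
    baselineCt = as.numeric(baselineCt),
    amplitudeCt = as.numeric(amplitudeCt),
    peakTime = as.numeric(peakTime), noiseSd = as.numeric(noiseSd),
    referenceBaselineCt = as.numeric(referenceBaselineCt)
  )
}

#' ElisaSpec: parameters of a simulated colorimetric m6A plate
#'
#' The plate model is linear: a standard well with \code{ng} of methylated
#' positive control reads \code{OD = ncOd + curveSlope * ng + noise}; a
#' sample's true m6A mass is \code{truePercent/100 * inputRnaNg}.
#'
#' @slot curveSlope OD per ng (> 0).
#' @slot ncOd Negative-control OD.
#' @slot standardPoints Known ng of the standard dilution points (>= 4).
#' @slot truePercent data.frame with columns species, time_h, bio_rep,
#'   percent: ground-truth m6A\% per biological sample.
#' @slot inputRnaNg Input RNA per sample well in ng (> 0).
#' @slot noiseSd Additive OD noise sd (>= 0).
#' @slot techReplicates Technical replicates per sample (default 2).
#' @export
setClass("ElisaSpec",
  representation(
    curveSlope = "numeric", ncOd = "numeric", standardPoints = "numeric",
    truePercent = "data.frame", inputRnaNg = "numeric", noiseSd = "numeric",
    techReplicates = "integer"
  )
)

setValidity("ElisaSpec", function(object) {
  msgs <- character()
  if (object@curveSlope <= 0) msgs <- c(msgs, "curveSlope must be > 0")
  if (length(unique(object@standardPoints)) < 4L)
    msgs <- c(msgs, "at least four distinct standard dilution points required")
  if (object@inputRnaNg <= 0) msgs <- c(msgs, "inputRnaNg must be > 0")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  need <- c("species", "time_h", "bio_rep", "percent")
  if (!all(need %in% names(object@truePercent)))
    msgs <- c(msgs, paste("truePercent needs columns:",
                          paste(need, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct an ElisaSpec
#'
#' @param truePercent data.frame (species, time_h, bio_rep, percent) of
#'   ground-truth m6A percentages per biological sample.
#' @param curveSlope OD per ng (default 0.02).
#' @param ncOd Negative-control OD (default 0.10).
#' @param standardPoints Known standard amounts in ng
#'   (default \code{c(0.02, 0.04, 0.1, 0.2, 0.5)} per-well ng, a typical
#'   kit dilution ladder).
#' @param inputRnaNg Input RNA ng per sample well (default 100).
#' @param noiseSd OD noise sd (default 0).
#' @param techReplicates Technical replicates per sample (default 2).
#' @return An \linkS4class{ElisaSpec}.
#' @export
#' @examples
#' tp <- expand.grid(species = "Zm", time_h = c(0, 13), bio_rep = 1:3)
#' tp$percent <- 0.1
#' ElisaSpec(tp)
ElisaSpec <- function(truePercent, curveSlope = 0.02, ncOd = 0.10,
                      standardPoints = c(0.02, 0.04, 0.1, 0.2, 0.5),
                      inputRnaNg = 100, noiseSd = 0, techReplicates = 2) {
  tp <- as.data.frame(truePercent)
  if (!"bio_rep" %in% names(tp)) tp$bio_rep <- 1L
  new("ElisaSpec",
    curveSlope = as.numeric(curveSlope), ncOd = as.numeric(ncOd),
    standardPoints = as.numeric(standardPoints),
    truePercent = tp[, c("species", "time_h", "bio_rep", "percent")],
    inputRnaNg = as.numeric(inputRnaNg), noiseSd = as.numeric(noiseSd),
    techReplicates = as.integer(techReplicates)
  )
}

#' HomologyNetworkSet: ortholog/paralog networks
#'
#' Connected components of the union of cross-species bidirectional-best-hit
#' (ortholog) edges and within-species cutoff-filtered (paralog) edges.
#' Components are numbered \code{NET_1, NET_2, ...} after sorting by
#' (size decreasing, lexicographically smallest member).  Singleton proteins
#' (no retained edge) are not part of any network.
#'
#' @slot membership Named character vector: protein ID -> network ID.
#' @slot edges data.frame with columns a, b, kind (\code{"ortholog"} or
#'   \code{"paralog"}), evalue, network_id.
#' @slot labels Named character vector of function labels (filled by
#'   \code{\link{annotateNetworks}}; empty before annotation).
#' @export
setClass("HomologyNetworkSet",
  representation(
    membership = "character",
    edges = "data.frame",
    labels = "character"
  )
)

setValidity("HomologyNetworkSet", function(object) {
  msgs <- character()
  ed <- object@edges
  need <- c("a", "b", "kind", "evalue", "network_id")
  if (!all(need %in% names(ed)))
    msgs <- c(msgs, paste("edges needs columns:", paste(need, collapse = ", ")))
  if (nrow(ed) && !all(c(ed$a, ed$b) %in% names(object@membership)))
    msgs <- c(msgs, "every edge endpoint must be a network member")
  if (length(object@labels) &&
      !all(names(object@labels) %in% names(object@membership)))
    msgs <- c(msgs, "labels refer to unknown proteins")
  if (length(msgs)) msgs else TRUE
})

#' StandardCurve: fitted ELISA standard curve
#'
#' Origin-forced least-squares fit of background-subtracted OD on known ng.
#' Only the slope and the negative-control OD enter downstream
#' quantification.
#'
#' @slot points data.frame (known_ng, mean_od) of duplicate-averaged
#'   standards.
#' @slot ncOd Mean OD of negative-control wells.
#' @slot slope OD per ng.
#' @slot r2 Coefficient of determination of the origin fit.
#' @export
setClass("StandardCurve",
  representation(points = "data.frame", ncOd = "numeric", slope = "numeric",
                 r2 = "numeric"))

setValidity("StandardCurve", function(object) {
  msgs <- character()
  if (nrow(object@points) < 4L)
    msgs <- c(msgs, "at least four standard points required")
  if (object@slope <= 0) msgs <- c(msgs, "slope must be > 0 for a valid assay")
  if (length(msgs)) msgs else TRUE
})

#' PermanovaResult: two-way PERMANOVA output
#'
#' @slot table data.frame with one row per source (factor A, factor B,
#'   interaction, Residual, Total): df, SS, MS, pseudo_F, p_perm,
#'   unique_perms.
#' @slot pairwise data.frame of pairwise contrasts (may have zero rows):
#'   group_within, level_1, level_2, t, p_perm, p_mc, n_unique_perms,
#'   low_resolution.
#' @slot nPerm Number of permutations requested.
#' @slot seed Seed used for the permutation stream.
#' @export
setClass("PermanovaResult",
  representation(table = "data.frame", pairwise = "data.frame",
                 nPerm = "numeric", seed = "numeric"))

setValidity("PermanovaResult", function(object) {
  tab <- object@table
  msgs <- character()
  need <- c("source", "df", "SS", "MS", "pseudo_F", "p_perm", "unique_perms")
  if (!all(need %in% names(tab)))
    msgs <- c(msgs, paste("table needs columns:", paste(need, collapse = ", ")))
  if (all(c("source", "SS", "df") %in% names(tab)) && nrow(tab) >= 2) {
    tot <- tab$SS[tab$source == "Total"]
    parts <- sum(tab$SS[!tab$source %in% "Total"])
    if (length(tot) == 1 && abs(parts - tot) > 1e-6 * max(1, abs(tot)))
      msgs <- c(msgs, "sums of squares do not add up to the total")
    dtot <- tab$df[tab$source == "Total"]
    if (length(dtot) == 1 && sum(tab$df[!tab$source %in% "Total"]) != dtot)
      msgs <- c(msgs, "degrees of freedom do not add up to N - 1")
  }
  if (length(msgs)) msgs else TRUE
})
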