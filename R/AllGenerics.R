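# Generics, accessors and show methods.

#' Network identifiers of a HomologyNetworkSet
#' @param x A \linkS4class{HomologyNetworkSet}.
#' @return Character vector of network IDs, in rank order.
#' @export
setGeneric("networkIds", function(x) standardGeneric("networkIds"))

#' @rdname networkIds
#' @export
setMethod("networkIds", "HomologyNetworkSet", function(x) {
  ids <- unique(unname(x@membership))
  ids[order(as.integer(sub("^NET_", "", ids)))]
})

#' Members of each network
#' @param x A \linkS4class{HomologyNetworkSet}.
#' @return Named list: network ID -> character vector of protein IDs.
#' @export
setGeneric("networkMembers", function(x) standardGeneric("networkMembers"))

#' @rdname networkMembers
#' @export
setMethod("networkMembers", "HomologyNetworkSet", function(x) {
  sp <- split(names(x@membership), unname(x@membership))
  lapply(sp[networkIds(x)], sort)
})

#' Edge table of a HomologyNetworkSet
#' @param x A \linkS4class{HomologyNetworkSet}.
#' @return data.frame with columns a, b, kind, evalue, network_id.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "HomologyNetworkSet", function(x) x@edges)

#' Function labels attached to network members
#' @param x A \linkS4class{HomologyNetworkSet}.
#' @return Named character vector protein ID -> label (empty before
#'   \code{\link{annotateNetworks}}).
#' @export
setGeneric("memberLabels", function(x) standardGeneric("memberLabels"))

#' @rdname memberLabels
#' @export
setMethod("memberLabels", "HomologyNetworkSet", function(x) x@labels)

#' Source table of a PermanovaResult
#' @param x A \linkS4class{PermanovaResult}.
#' @return data.frame of df/SS/MS/pseudo-F/p(perm)/unique permutations.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname resultTable
#' @export
setMethod("resultTable", "PermanovaResult", function(x) x@table)

#' Pairwise contrasts of a PermanovaResult
#' @param x A \linkS4class{PermanovaResult}.
#' @return data.frame of pairwise t, p(perm), p(MC) rows.
#' @export
setGeneric("pairwiseTable", function(x) standardGeneric("pairwiseTable"))

#' @rdname pairwiseTable
#' @export
setMethod("pairwiseTable", "PermanovaResult", function(x) x@pairwise)

setMethod("show", "HomologyNetworkSet", function(object) {
  ids <- networkIds(object)
  cat("HomologyNetworkSet with", length(ids), "networks,",
      length(object@membership), "proteins,",
      nrow(object@edges), "edges\n")
  if (length(ids)) {
    sizes <- table(object@membership)[ids]
    shown <- head(ids, 5L)
    for (id in shown)
      cat("  ", id, ": ", sizes[[id]], " members\n", sep = "")
    if (length(ids) > 5L) cat("  ...\n")
  }
  if (length(object@labels))
    cat("  annotated:", sum(object@labels != "unknown"), "labelled members\n")
})

setMethod("show", "StandardCurve", function(object) {
  cat("StandardCurve:", nrow(object@points), "points; slope",
      format(object@slope, digits = 4), "OD/ng; NC OD",
      format(object@ncOd, digits = 4), "; R^2",
      format(object@r2, digits = 4), "\n")
})

setMethod("show", "PermanovaResult", function(object) {
  cat("Two-way PERMANOVA (", object@nPerm, " permutations)\n", sep = "")
  print(object@table, row.names = FALSE, digits = 5)
  if (nrow(object@pairwise)) {
    cat("Pairwise contrasts:\n")
    print(object@pairwise, row.names = FALSE, digits = 4)
  }
})

setMethod("show", "FamilySpec", function(object) {
  cat("FamilySpec", object@familyName, "- copies:",
      paste(names(object@copiesPerSpecies), object@copiesPerSpecies,
            sep = ":", collapse = " "),
      "\n  length", object@ancestralLength,
      "aa; rates ortholog", object@subRateOrtholog,
      "paralog", object@subRateParalog,
      "; variants", object@variantCount, "\n")
})

setMethod("show", "RhythmSpec", function(object) {
  cat("RhythmSpec", object@gene, "in", object@species,
      "- baseline", object@baselineCt, "CT, amplitude", object@amplitudeCt,
      "CT, peak", object@peakTime, "h, noise sd", object@noiseSd, "\n")
})
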