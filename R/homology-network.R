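# Ortholog/paralog network inference from all-vs-all similarity tables:
# bidirectional best hits across species, a paralog-network-maximising
# E-value cutoff within species, connected-component networks, annotation
# transfer and the writer/eraser inventory.

.WRITER_LABELS <- c("MTA", "MTB", "FIP37", "VIRILIZER", "HAKAI")
.ERASER_LABELS <- c("ALKBH9B", "ALKBH10B")

.OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) similarity file
#'
#' Lines starting with \code{#} are ignored; self-hits (query == subject)
#' are dropped and counted; rows whose numeric fields do not parse are
#' dropped with a warning naming their line numbers.
#'
#' @param path Path to a 12-column TSV.
#' @return data.frame of hits with outfmt-6 column names; the number of
#'   self-hits removed is attached as attribute \code{"selfHitsDropped"}.
#' @export
readSimilarity <- function(path) {
  lines <- readLines(path)
  lineNo <- seq_along(lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineNo <- lineNo[keep]
  if (!length(lines)) {
    out <- .emptySimTable()
    attr(out, "selfHitsDropped") <- 0L
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 12L))
    .err("similarity file ", path, ": line ", lineNo[which(nc < 12L)[1L]],
         " has ", nc[which(nc < 12L)[1L]], " columns (12 required)")
  m <- do.call(rbind, lapply(parts, function(p) p[1:12]))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- .OUTFMT6_COLS
  numCols <- setdiff(.OUTFMT6_COLS, c("qseqid", "sseqid"))
  suppressWarnings(
    for (cc in numCols) df[[cc]] <- as.numeric(df[[cc]]))
  bad <- !complete.cases(df[numCols])
  if (any(bad)) {
    warning("dropped ", sum(bad), " row(s) with unparseable numerics at ",
            "line(s) ", paste(lineNo[bad], collapse = ", "), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  self <- df$qseqid == df$sseqid
  df <- df[!self, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "selfHitsDropped") <- sum(self)
  df
}

#' Best similarity hit per query and target species
#'
#' For each (query, target species), retains the subject with the smallest
#' E-value; ties are broken by the larger bit score, then the
#' lexicographically smallest subject ID, so the map is deterministic under
#' any input row order.
#'
#' @param hits data.frame of similarity hits (qseqid, sseqid, evalue,
#'   bitscore).
#' @param scope \code{"cross_species"} (queries against other species; the
#'   BBH ortholog input) or \code{"within_species"}.
#' @param speciesMap Optional named character vector overriding the
#'   ID-prefix species rule (see \code{\link{speciesOf}}).
#' @return data.frame with columns query_id, target_species, subject_id,
#'   evalue, bitscore.
#' @export
bestHitMap <- function(hits, scope = c("cross_species", "within_species"),
                       speciesMap = NULL) {
  scope <- match.arg(scope)
  out <- data.frame(query_id = character(), target_species = character(),
                    subject_id = character(), evalue = numeric(),
                    bitscore = numeric())
  if (!nrow(hits)) return(out)
  qsp <- speciesOf(hits$qseqid, speciesMap)
  ssp <- speciesOf(hits$sseqid, speciesMap)
  keep <- if (scope == "cross_species") qsp != ssp else qsp == ssp
  h <- hits[keep, , drop = FALSE]
  ssp <- ssp[keep]
  if (!nrow(h)) return(out)
  ord <- order(h$qseqid, ssp, h$evalue, -h$bitscore, h$sseqid,
               method = "radix")
  h <- h[ord, , drop = FALSE]; ssp <- ssp[ord]
  first <- !duplicated(paste0(h$qseqid, "\r", ssp))
  data.frame(query_id = h$qseqid[first], target_species = ssp[first],
             subject_id = h$sseqid[first], evalue = h$evalue[first],
             bitscore = h$bitscore[first], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Ortholog edges by bidirectional best hit
#'
#' An undirected ortholog edge (a, b) is emitted iff a's best hit in b's
#' species is b and b's best hit in a's species is a.
#'
#' @param best Best-hit map from \code{\link{bestHitMap}} built with
#'   \code{scope = "cross_species"}.
#' @param speciesMap Optional species override map.
#' @return data.frame with columns a, b, kind (\code{"ortholog"}), evalue
#'   (the smaller of the two directed E-values); each unordered pair once,
#'   with \code{a < b}.
#' @export
bbhOrthologs <- function(best, speciesMap = NULL) {
  empty <- data.frame(a = character(), b = character(), kind = character(),
                      evalue = numeric())
  if (!nrow(best)) return(empty)
  key <- paste0(best$query_id, "\r", best$target_species)
  subj <- setNames(best$subject_id, key)
  eval <- setNames(best$evalue, key)
  qsp <- speciesOf(best$query_id, speciesMap)
  a <- best$query_id; b <- best$subject_id
  backKey <- paste0(b, "\r", qsp)
  reciprocal <- !is.na(subj[backKey]) & subj[backKey] == a
  reciprocal[is.na(reciprocal)] <- FALSE
  if (!any(reciprocal)) return(empty)
  a2 <- pmin(a[reciprocal], b[reciprocal])
  b2 <- pmax(a[reciprocal], b[reciprocal])
  e2 <- pmin(best$evalue[reciprocal], eval[backKey[reciprocal]])
  dup <- duplicated(paste0(a2, "\r", b2))
  ord <- order(a2[!dup], b2[!dup], method = "radix")
  data.frame(a = a2[!dup][ord], b = b2[!dup][ord], kind = "ortholog",
             evalue = unname(e2[!dup][ord]), stringsAsFactors = FALSE)
}

# Reciprocal within-species pair list with the better (smaller) of the two
# directed E-values; shared by paralogEdges and the cutoff scan.
.reciprocalWithin <- function(hits, species, speciesMap = NULL) {
  empty <- data.frame(a = character(), b = character(), evalue = numeric())
  if (!nrow(hits)) return(empty)
  qsp <- speciesOf(hits$qseqid, speciesMap)
  ssp <- speciesOf(hits$sseqid, speciesMap)
  h <- hits[qsp == species & ssp == species, , drop = FALSE]
  if (!nrow(h)) return(empty)
  # best (min) E per direction, then require both directions
  dirKey <- paste0(h$qseqid, "\r", h$sseqid)
  minE <- tapply(h$evalue, dirKey, min)
  keys <- names(minE)
  qa <- sub("\r.*$", "", keys); sb <- sub("^.*\r", "", keys)
  lo <- pmin(qa, sb); hi <- pmax(qa, sb)
  pairKey <- paste0(lo, "\r", hi)
  cnt <- table(pairKey)
  both <- names(cnt)[cnt == 2L]
  if (!length(both)) return(empty)
  e <- tapply(as.numeric(minE), pairKey, min)[both]
  a <- sub("\r.*$", "", both); b <- sub("^.*\r", "", both)
  ord <- order(a, b, method = "radix")
  data.frame(a = a[ord], b = b[ord], evalue = unname(e[both][ord]),
             stringsAsFactors = FALSE)
}

#' Paralog edges within one species at a fixed E-value cutoff
#'
#' An undirected paralog edge requires reported hits in both directions
#' (reciprocity guards against asymmetric-reporting artifacts) with the
#' better of the two E-values at or below the cutoff.
#'
#' @param hits Similarity hits data.frame.
#' @param species Species label.
#' @param cutoff E-value threshold (> 0).
#' @param speciesMap Optional species override map.
#' @return data.frame with columns a, b, kind (\code{"paralog"}), evalue.
#' @export
paralogEdges <- function(hits, species, cutoff, speciesMap = NULL) {
  stopifnot(cutoff > 0)
  rec <- .reciprocalWithin(hits, species, speciesMap)
  rec <- rec[rec$evalue <= cutoff, , drop = FALSE]
  if (!nrow(rec))
    return(data.frame(a = character(), b = character(), kind = character(),
                      evalue = numeric()))
  data.frame(a = rec$a, b = rec$b, kind = "paralog", evalue = rec$evalue,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default E-value threshold grid, loose to strict
#'
#' @param from,to log10 endpoints (defaults -5 and -120).
#' @param by log10 step (default 1, i.e. decade steps).
#' @return Numeric vector of thresholds, decreasing.
#' @export
evalueGrid <- function(from = -5, to = -120, by = 1) {
  10^seq(from, to, by = -abs(by))
}

# count connected components with >= 2 members among the given edges
.componentCount <- function(edges) {
  if (!nrow(edges)) return(0L)
  g <- graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  sum(components(g)$csize >= 2L)
}

#' Select the E-value cutoff that maximises the number of paralog networks
#'
#' Scans a threshold grid; at each threshold the within-species paralog
#' graph is built and its connected components with at least two members
#' are counted.  The selected cutoff is the argmax; ties go to the loosest
#' threshold (retaining the most sequences).  A species with no
#' within-species reciprocal hits yields an all-zero count map, the loosest
#' grid value, and \code{flagged = TRUE}.
#'
#' @param hits Similarity hits data.frame.
#' @param species Species label.
#' @param grid Thresholds from \code{\link{evalueGrid}} (sorted loose to
#'   strict internally).
#' @param speciesMap Optional species override map.
#' @return List with elements species, grid, counts (named by threshold),
#'   selected, flagged.
#' @export
selectCutoff <- function(hits, species, grid = evalueGrid(),
                         speciesMap = NULL) {
  stopifnot(length(grid) >= 1L, all(grid > 0))
  grid <- sort(unique(grid), decreasing = TRUE)
  rec <- .reciprocalWithin(hits, species, speciesMap)
  counts <- vapply(grid, function(th) {
    .componentCount(rec[rec$evalue <= th, , drop = FALSE])
  }, integer(1L))
  names(counts) <- format(grid, scientific = TRUE, digits = 3)
  flagged <- nrow(rec) == 0L
  selected <- grid[which.max(counts)]  # first = loosest on ties
  list(species = species, grid = grid, counts = counts,
       selected = selected, flagged = flagged)
}

#' Build ortholog/paralog networks as connected components
#'
#' Takes the union of ortholog (BBH) and paralog (cutoff-filtered) edges
#' and returns its connected components as a
#' \linkS4class{HomologyNetworkSet}.  Proteins with no retained edge belong
#' to no network.  Components are ranked by (size decreasing, smallest
#' member ID) and numbered \code{NET_1 ...} from 1.
#'
#' @param orthologEdges data.frame from \code{\link{bbhOrthologs}}.
#' @param paralogEdges data.frame from \code{\link{paralogEdges}} (possibly
#'   several species' worth, row-bound).
#' @return A \linkS4class{HomologyNetworkSet}.
#' @export
buildNetworks <- function(orthologEdges, paralogEdges) {
  edges <- rbind(
    orthologEdges[, c("a", "b", "kind", "evalue")],
    paralogEdges[, c("a", "b", "kind", "evalue")])
  if (!nrow(edges))
    return(new("HomologyNetworkSet",
               membership = setNames(character(), character()),
               edges = data.frame(a = character(), b = character(),
                                  kind = character(), evalue = numeric(),
                                  network_id = character()),
               labels = setNames(character(), character())))
  g <- graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  comp <- components(g)
  verts <- names(comp$membership)
  groups <- split(verts, comp$membership)
  sizes <- lengths(groups)
  minId <- vapply(groups, min, character(1L))
  rank <- order(-sizes, minId, method = "radix")
  netOf <- character(length(groups))
  netOf[rank] <- paste0("NET_", seq_along(groups))
  membership <- setNames(netOf[comp$membership], verts)
  edges$network_id <- unname(membership[edges$a])
  ord <- order(as.integer(sub("^NET_", "", edges$network_id)),
               edges$a, edges$b, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  new("HomologyNetworkSet", membership = membership, edges = edges,
      labels = setNames(character(), character()))
}

#' Attach function labels to network members
#'
#' Emulates annotation transfer from a best-hit search against a curated
#' protein database: each member receives the label of its annotation
#' entry, or \code{"unknown"} when absent (never fatal).
#'
#' @param networks A \linkS4class{HomologyNetworkSet}.
#' @param annotation Named character vector protein ID -> label, drawn from
#'   the controlled vocabulary (MTA, MTB, FIP37, VIRILIZER, HAKAI,
#'   ALKBH9B, ALKBH10B, other).
#' @return The network set with its \code{labels} slot filled.
#' @export
annotateNetworks <- function(networks, annotation) {
  stopifnot(is(networks, "HomologyNetworkSet"))
  ids <- names(networks@membership)
  lab <- unname(annotation[ids])
  lab[is.na(lab)] <- "unknown"
  networks@labels <- setNames(lab, ids)
  validObject(networks)
  networks
}

#' Writer/eraser inventory table
#'
#' Restricts to networks with at least one member labelled as an m6A writer
#' or eraser and tabulates one row per (type, gene name, species, network)
#' with the member count and IDs, sorted by type (Writers first), gene
#' name, species.
#'
#' @param networks An annotated \linkS4class{HomologyNetworkSet}.
#' @param speciesMap Optional species override map.
#' @return data.frame with columns type, gene_name, species, n_members,
#'   member_ids (semicolon-joined), network_id.
#' @export
inventoryTable <- function(networks, speciesMap = NULL) {
  stopifnot(is(networks, "HomologyNetworkSet"))
  if (!length(networks@labels))
    .err("networks must be annotated first (annotateNetworks)")
  vocab <- c(.WRITER_LABELS, .ERASER_LABELS)
  mem <- networks@membership
  lab <- networks@labels[names(mem)]
  keepNets <- unique(mem[lab %in% vocab])
  sel <- mem %in% keepNets & lab %in% vocab
  if (!any(sel))
    return(data.frame(type = character(), gene_name = character(),
                      species = character(), n_members = integer(),
                      member_ids = character(), network_id = character()))
  df <- data.frame(protein_id = names(mem)[sel],
                   network_id = unname(mem[sel]),
                   gene_name = unname(lab[sel]),
                   stringsAsFactors = FALSE)
  df$species <- speciesOf(df$protein_id, speciesMap)
  key <- interaction(df$gene_name, df$species, df$network_id, drop = TRUE)
  agg <- lapply(split(df, key), function(d) {
    ids <- sort(d$protein_id)
    data.frame(
      type = if (d$gene_name[1L] %in% .WRITER_LABELS) "Writer" else "Eraser",
      gene_name = d$gene_name[1L], species = d$species[1L],
      n_members = length(ids), member_ids = paste(ids, collapse = ";"),
      network_id = d$network_id[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, unname(agg))
  ord <- order(match(out$type, c("Writer", "Eraser")), out$gene_name,
               out$species, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse near-identical sequences to representatives
#'
#' Greedy identity clustering: sequences are visited longest first (ties by
#' ID); a sequence joins the first representative whose local alignment
#' covers at least \code{overlapThreshold} of the shorter sequence with
#' identity at or above \code{identityThreshold}; otherwise it founds a new
#' cluster.  The longest member of each cluster is its representative.
#'
#' @param sequences An \code{AAStringSet} (named).
#' @param identityThreshold Identity fraction in (0, 1] (default 0.98).
#' @param overlapThreshold Minimum aligned-span fraction of the shorter
#'   sequence, in (0, 1] (default 0.5).
#' @return List with \code{representatives} (an \code{AAStringSet}) and
#'   \code{collapseMap} (named character: collapsed member -> its
#'   representative; representatives themselves are absent).
#' @export
collapseRedundant <- function(sequences, identityThreshold = 0.98,
                              overlapThreshold = 0.5) {
  stopifnot(identityThreshold > 0, identityThreshold <= 1,
            overlapThreshold > 0, overlapThreshold <= 1)
  if (!length(sequences))
    return(list(representatives = AAStringSet(),
                collapseMap = setNames(character(), character())))
  ord <- order(-width(sequences), names(sequences), method = "radix")
  sequences <- sequences[ord]
  repIdx <- integer()
  collapseMap <- character()
  for (i in seq_along(sequences)) {
    assigned <- FALSE
    for (j in repIdx) {
      aln <- pairwiseAlignment(sequences[[i]], sequences[[j]],
                               type = "local",
                               substitutionMatrix = "BLOSUM62",
                               gapOpening = 10, gapExtension = 4)
      span <- Biostrings::nchar(aln)
      shorter <- min(width(sequences)[c(i, j)])
      if (span / shorter >= overlapThreshold &&
          Biostrings::nmatch(aln) / span >= identityThreshold) {
        collapseMap[names(sequences)[i]] <- names(sequences)[j]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) repIdx <- c(repIdx, i)
  }
  list(representatives = sequences[repIdx], collapseMap = collapseMap)
}

#' Run the full homology stage on one similarity table
#'
#' Per-species cutoff selection, paralog and BBH ortholog edges, network
#' construction and (optionally) annotation.
#'
#' @param hits Similarity hits data.frame (see
#'   \code{\link{readSimilarity}}).
#' @param annotation Optional named label vector for
#'   \code{\link{annotateNetworks}}.
#' @param grid Cutoff grid (see \code{\link{evalueGrid}}).
#' @param speciesMap Optional species override map.
#' @return List with elements networks
#'   (\linkS4class{HomologyNetworkSet}), cutoffs (per-species list from
#'   \code{\link{selectCutoff}}), and inventory (data.frame or NULL when
#'   unannotated).
#' @export
inferHomology <- function(hits, annotation = NULL, grid = evalueGrid(),
                          speciesMap = NULL) {
  allSpecies <- sort(unique(speciesOf(
    unique(c(hits$qseqid, hits$sseqid)), speciesMap)))
  cutoffs <- lapply(allSpecies, function(sp)
    selectCutoff(hits, sp, grid, speciesMap))
  names(cutoffs) <- allSpecies
  par <- do.call(rbind, lapply(allSpecies, function(sp)
    paralogEdges(hits, sp, cutoffs[[sp]]$selected, speciesMap)))
  if (is.null(par))
    par <- data.frame(a = character(), b = character(), kind = character(),
                      evalue = numeric())
  best <- bestHitMap(hits, "cross_species", speciesMap)
  orth <- bbhOrthologs(best, speciesMap)
  nets <- buildNetworks(orth, par)
  inv <- NULL
  if (!is.null(annotation)) {
    nets <- annotateNetworks(nets, annotation)
    inv <- inventoryTable(nets, speciesMap)
  }
  list(networks = nets, cutoffs = cutoffs, inventory = inv)
}

#' Export networks as JSON and an edge-list TSV
#'
#' @param networks A \linkS4class{HomologyNetworkSet}.
#' @param dir Output directory.
#' @return Invisibly, the two paths written.
#' @export
writeNetworks <- function(networks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mem <- networkMembers(networks)
  lab <- networks@labels
  obj <- lapply(names(mem), function(id) {
    e <- networks@edges[networks@edges$network_id == id, , drop = FALSE]
    list(id = id, members = mem[[id]],
         edges = e[, c("a", "b", "kind", "evalue")],
         labels = if (length(lab)) unname(lab[mem[[id]]]) else character())
  })
  jsonPath <- file.path(dir, "networks.json")
  write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tsvPath <- file.path(dir, "edges.tsv")
  utils::write.table(networks@edges, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(jsonPath, tsvPath))
}
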