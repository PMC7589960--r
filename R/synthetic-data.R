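# Seeded generators for every input the pipeline consumes: proteomes with
# planted gene families, all-vs-all similarity tables, diel CT series and
# ELISA plates.  Each generator returns its ground truth so downstream
# recovery is testable.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Replace each site independently with probability `rate` by a uniformly
# chosen *different* residue, so `rate` equals the expected divergence.
.mutateSeq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    repl <- vapply(chars[hit], function(a) {
      sample(.AA20[.AA20 != a], 1L)
    }, character(1L))
    chars[hit] <- repl
  }
  chars
}

# Transcript variant: exactly ~1% of sites substituted, so variants stay
# strictly below 2% divergence from their parent.
.variantSeq <- function(chars) {
  k <- max(1L, round(0.01 * length(chars)))
  pos <- sample(length(chars), k)
  chars[pos] <- vapply(chars[pos], function(a) {
    sample(.AA20[.AA20 != a], 1L)
  }, character(1L))
  chars
}

#' Generate synthetic proteomes with planted gene families
#'
#' Draws one ancestral sequence per family, then derives each species' first
#' copy by mutating the ancestor at the ortholog (speciation) rate, extra
#' copies by mutating that species copy at the paralog (duplication) rate,
#' and transcript variants by mutating a member at 1\% divergence
#' (near-identical isoform redundancy).  Sites evolve i.i.d. with uniform
#' residue replacement; adequate because downstream consumes only E-values,
#' never alignments.
#'
#' @param specs List of \linkS4class{FamilySpec} objects.
#' @param species Character vector of species labels (used in sequence IDs
#'   as the prefix up to the first underscore).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return List with elements \code{proteomes} (named list of
#'   \code{AAStringSet}, one per species) and \code{truth} (data.frame with
#'   columns protein_id, species, family, variant_of).
#' @export
#' @examples
#' fam <- FamilySpec("FIP37", c(Zm = 6, At = 1, Os = 1))
#' out <- generateProteomes(list(fam), c("Zm", "At", "Os"), seed = 1)
#' table(out$truth$species, out$truth$family)
generateProteomes <- function(specs, species, seed) {
  stopifnot(length(species) >= 1L)
  set.seed(deriveSeed(seed, "proteomes"))
  truth <- list()
  seqs <- setNames(vector("list", length(species)), species)
  for (spec in specs) {
    stopifnot(is(spec, "FamilySpec"))
    validObject(spec)
    copies <- spec@copiesPerSpecies
    copies <- copies[names(copies) %in% species]
    if (sum(copies) == 0L) {
      warning("family ", spec@familyName,
              " has zero total copies; omitted", call. = FALSE)
      next
    }
    anc <- sample(.AA20, spec@ancestralLength, replace = TRUE)
    for (sp in species) {
      k <- if (sp %in% names(copies)) copies[[sp]] else 0L
      if (k == 0L) next
      base <- .mutateSeq(anc, spec@subRateOrtholog)
      for (i in seq_len(k)) {
        member <- if (i == 1L) base else .mutateSeq(base, spec@subRateParalog)
        id <- sprintf("%s_%s_%d", sp, spec@familyName, i)
        seqs[[sp]][[id]] <- paste(member, collapse = "")
        truth[[id]] <- data.frame(
          protein_id = id, species = sp, family = spec@familyName,
          variant_of = NA_character_, stringsAsFactors = FALSE)
        for (v in seq_len(spec@variantCount)) {
          vid <- sprintf("%s_v%d", id, v)
          seqs[[sp]][[vid]] <- paste(.variantSeq(member), collapse = "")
          truth[[vid]] <- data.frame(
            protein_id = vid, species = sp, family = spec@familyName,
            variant_of = id, stringsAsFactors = FALSE)
        }
      }
    }
  }
  proteomes <- lapply(seqs, function(x) {
    if (is.null(x)) AAStringSet() else AAStringSet(unlist(x))
  })
  truth <- if (length(truth)) do.call(rbind, unname(truth)) else
    data.frame(protein_id = character(), species = character(),
               family = character(), variant_of = character())
  rownames(truth) <- NULL
  list(proteomes = proteomes, truth = truth)
}

#' Write generated proteomes as one FASTA per species
#'
#' @param proteomes Named list of \code{AAStringSet} (from
#'   \code{\link{generateProteomes}}).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeProteomes <- function(proteomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(proteomes), function(sp) {
    p <- file.path(dir, paste0(sp, ".faa"))
    writeXStringSet(proteomes[[sp]], p)
    p
  }, character(1L))
  invisible(paths)
}

#' Similarity-simulation model parameters
#'
#' Within-family hits are divergence-anchored, the way real search
#' E-values track sequence similarity:
#' \code{log10(E) = within[1] + slope * d + U(0, noise)} for a pair with
#' realized amino-acid divergence \code{d}, clamped to the \code{within}
#' support.  Because duplicate copies radiate from one species base copy,
#' base-duplicate pairs are systematically stronger than
#' duplicate-duplicate pairs, and the within-species similarity graph
#' thins from the outside in (never into two multi-member fragments) as a
#' cutoff tightens.  Between families no hit is reported unless
#' \code{betweenEnabled} ("hard mode"), in which case each ordered
#' between-family pair is reported with probability \code{betweenProb} and
#' log10(E) uniform on \code{between}; by default the two supports must
#' not overlap, so family structure is exactly recoverable.
#'
#' @param within Numeric length-2 support of within-family log10
#'   E-values.
#' @param slope Decades of log10(E) per unit divergence (default 280,
#'   placing all default-rate family pairs inside \code{within}).
#' @param noise Per-direction uniform log10(E) jitter width in decades
#'   (default 1); the two directions of a pair are drawn independently.
#' @param between Numeric length-2 support of between-family log10
#'   E-values.
#' @param betweenEnabled Logical; emit noisy between-family hits?
#' @param betweenProb Probability a between-family ordered pair is
#'   reported when enabled.
#' @param allowOverlap Permit overlapping within/between supports (stress
#'   mode); otherwise overlap is an error.
#' @return A list of model parameters for
#'   \code{\link{simulateSimilarity}}.
#' @export
similarityModel <- function(within = c(-120, -20), slope = 280, noise = 1,
                            between = c(-8, -3), betweenEnabled = FALSE,
                            betweenProb = 0.10, allowOverlap = FALSE) {
  stopifnot(length(within) == 2L, length(between) == 2L, slope > 0,
            noise >= 0)
  within <- sort(within); between <- sort(between)
  if (!allowOverlap && between[1] <= within[2])
    stop("within- and between-family log10-E supports overlap; ",
         "set allowOverlap = TRUE for stress mode", call. = FALSE)
  list(within = within, slope = as.numeric(slope),
       noise = as.numeric(noise), between = between,
       betweenEnabled = isTRUE(betweenEnabled),
       betweenProb = as.numeric(betweenProb))
}

# fraction of differing positions between two equal-length sequences
# (generated proteins of one family share their ancestral length)
.divergence <- function(x, y) {
  a <- strsplit(x, "")[[1L]]; b <- strsplit(y, "")[[1L]]
  if (length(a) != length(b)) {
    k <- min(length(a), length(b))
    return(1 - sum(a[seq_len(k)] == b[seq_len(k)]) / k)
  }
  mean(a != b)
}

#' Simulate an all-vs-all similarity table
#'
#' Emits BLAST tabular (outfmt 6) rows for every reportable ordered pair
#' of distinct proteins: all within-family pairs (their E-value follows
#' from the pair's realized sequence divergence under the model), plus,
#' in hard mode, random weak between-family hits.  Both directions are
#' drawn independently, self-hits are never emitted, and under the
#' default model every within-family E-value lies below any
#' between-family hit.
#'
#' @param proteomes Named list of \code{AAStringSet} from
#'   \code{\link{generateProteomes}}.
#' @param truth Matching ground-truth data.frame.
#' @param model Model list from \code{\link{similarityModel}}.
#' @param seed Integer seed.
#' @return data.frame with the 12 outfmt-6 columns (qseqid, sseqid,
#'   pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#'   evalue, bitscore).
#' @export
#' @examples
#' fam <- FamilySpec("MTA", c(Zm = 1, At = 1))
#' pr <- generateProteomes(list(fam), c("Zm", "At"), seed = 1)
#' simulateSimilarity(pr$proteomes, pr$truth, seed = 1)
simulateSimilarity <- function(proteomes, truth, model = similarityModel(),
                               seed) {
  set.seed(deriveSeed(seed, "similarity"))
  seqs <- unlist(lapply(proteomes, as.character))
  names(seqs) <- unlist(lapply(proteomes, names))
  ids <- truth$protein_id
  stopifnot(all(ids %in% names(seqs)))
  fam <- setNames(truth$family, ids)
  n <- length(ids)
  if (n < 2L) return(.emptySimTable())
  pairs <- expand.grid(qi = seq_len(n), si = seq_len(n))
  pairs <- pairs[pairs$qi != pairs$si, , drop = FALSE]
  # deterministic row order: by query then subject index
  pairs <- pairs[order(pairs$qi, pairs$si), , drop = FALSE]
  q <- ids[pairs$qi]; s <- ids[pairs$si]
  same <- unname(fam[q] == fam[s])
  keep <- same
  if (model$betweenEnabled) {
    noiseHit <- !same & runif(length(same)) < model$betweenProb
    keep <- same | noiseHit
  }
  q <- q[keep]; s <- s[keep]; same <- same[keep]
  m <- length(q)
  if (m == 0L) return(.emptySimTable())
  d <- numeric(m)
  d[same] <- mapply(function(a, b) .divergence(seqs[[a]], seqs[[b]]),
                    q[same], s[same])
  log10e <- numeric(m)
  log10e[same] <- pmin(pmax(
    model$within[1] + model$slope * d[same] +
      runif(sum(same), 0, model$noise),
    model$within[1]), model$within[2])
  if (any(!same)) {
    log10e[!same] <- runif(sum(!same), model$between[1], model$between[2])
    d[!same] <- runif(sum(!same), 0.6, 0.75)
  }
  evalue <- 10^log10e
  bits <- round(-1.9 * log10e + 30 + runif(m, 0, 4), 1)
  pid <- round(100 * (1 - d), 1)
  len <- vapply(q, function(id) nchar(seqs[[id]]), numeric(1L))
  data.frame(
    qseqid = q, sseqid = s, pident = pid, length = as.integer(len),
    mismatch = as.integer(round(len * d)), gapopen = 0L,
    qstart = 1L, qend = as.integer(len), sstart = 1L,
    send = as.integer(len), evalue = evalue, bitscore = bits,
    stringsAsFactors = FALSE, row.names = NULL)
}

.emptySimTable <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric())
}

#' Write a similarity table as outfmt-6 TSV
#' @param sim data.frame from \code{\link{simulateSimilarity}}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeSimilarity <- function(sim, path) {
  utils::write.table(sim, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Define a diel sampling design
#'
#' @param species Character vector of species (or population) labels.
#' @param times Numeric sampling hours since local midnight, in
#'   \code{[0, 24)}.
#' @param bioReps Biological replicates per species x time (default 3).
#' @param techReps qPCR technical replicates per biological sample
#'   (default 3).
#' @return A list of class-free design parameters used by the generators
#'   and the statistics layer.
#' @export
studyDesign <- function(species, times, bioReps = 3, techReps = 3) {
  if (any(times < 0 | times >= 24))
    stop("time points must lie in [0, 24) hours", call. = FALSE)
  stopifnot(.isCount(bioReps), .isCount(techReps), bioReps >= 1, techReps >= 1)
  list(species = as.character(species), times = as.numeric(times),
       bioReps = as.integer(bioReps), techReps = as.integer(techReps))
}

# Expected CT of a gene of interest at time t under a cosinor rhythm:
# minimum CT (= expression peak) at peakTime.
.cosinorCt <- function(rhythm, t) {
  rhythm@baselineCt -
    rhythm@amplitudeCt * cos(2 * pi * (t - rhythm@peakTime) / 24)
}

#' Ground-truth -dCT profile implied by a RhythmSpec
#'
#' @param rhythm A \linkS4class{RhythmSpec}.
#' @param times Numeric hours.
#' @return Numeric vector of noise-free -dCT values
#'   (\code{CT_RG - CT_GOI}) at \code{times}.
#' @export
trueNegDeltaCt <- function(rhythm, times) {
  rhythm@referenceBaselineCt - .cosinorCt(rhythm, times)
}

#' Generate a diel CT table
#'
#' For every species x time x biological replicate x technical replicate,
#' draws \code{CT = cosinor(t) + N(0, noiseSd)} for each gene of interest
#' and \code{CT = referenceBaseline + N(0, noiseSd)} for the shared
#' reference gene.
#'
#' @param design Design from \code{\link{studyDesign}}.
#' @param rhythms List of \linkS4class{RhythmSpec} (one per gene x
#'   species); all rhythms of a species must agree on
#'   \code{referenceBaselineCt}.
#' @param seed Integer seed.
#' @param referenceGene Name of the reference gene (default
#'   \code{"eIF4A"}).
#' @return data.frame with columns species, gene, time_h, bio_rep,
#'   tech_rep, ct.
#' @export
#' @examples
#' d <- studyDesign("Cn", c(0, 6, 13, 20.5))
#' r <- RhythmSpec("MTA", "Cn", amplitudeCt = 1, peakTime = 0, noiseSd = 0)
#' ct <- generateDielCt(d, list(r), seed = 1)
generateDielCt <- function(design, rhythms, seed, referenceGene = "eIF4A") {
  set.seed(deriveSeed(seed, "diel_ct"))
  if (any(design$times < 0 | design$times >= 24))
    stop("time points must lie in [0, 24) hours", call. = FALSE)
  rows <- list()
  for (sp in design$species) {
    spRhythms <- Filter(function(r) r@species == sp, rhythms)
    if (!length(spRhythms)) next
    refs <- unique(vapply(spRhythms, function(r) r@referenceBaselineCt,
                          numeric(1L)))
    if (length(refs) != 1L)
      stop("rhythms for species ", sp,
           " disagree on referenceBaselineCt", call. = FALSE)
    refSd <- spRhythms[[1L]]@noiseSd
    grid <- expand.grid(time_h = design$times,
                        bio_rep = seq_len(design$bioReps),
                        tech_rep = seq_len(design$techReps))
    grid <- grid[order(grid$time_h, grid$bio_rep, grid$tech_rep), ]
    for (r in spRhythms) {
      validObject(r)
      ct <- .cosinorCt(r, grid$time_h) + rnorm(nrow(grid), 0, r@noiseSd)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, gene = r@gene, grid, ct = ct,
        stringsAsFactors = FALSE)
    }
    ctRg <- refs + rnorm(nrow(grid), 0, refSd)
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, gene = referenceGene, grid, ct = ctRg,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("species", "gene", "time_h", "bio_rep", "tech_rep", "ct")]
}

#' Generate an ELISA plate table
#'
#' Standards are laid out in duplicate with
#' \code{OD = ncOd + slope * ng + noise}; one negative-control well reads
#' the background; each biological sample contributes
#' \code{techReplicates} wells whose OD is implied by its true m6A percent
#' and the input RNA mass.
#'
#' @param spec An \linkS4class{ElisaSpec}.
#' @param seed Integer seed.
#' @return data.frame with columns well, role (standard/nc/sample),
#'   known_ng, species, time_h, bio_rep, tech_rep, od.
#' @export
#' @examples
#' tp <- data.frame(species = "Zm", time_h = 0, bio_rep = 1:3,
#'                  percent = 0.1)
#' plate <- generateElisaPlate(ElisaSpec(tp), seed = 1)
generateElisaPlate <- function(spec, seed) {
  stopifnot(is(spec, "ElisaSpec"))
  validObject(spec)
  set.seed(deriveSeed(seed, "elisa"))
  noise <- function(k) rnorm(k, 0, spec@noiseSd)
  std <- do.call(rbind, lapply(seq_along(spec@standardPoints), function(i) {
    ng <- spec@standardPoints[i]
    data.frame(
      well = sprintf("S%d_%d", i, 1:2), role = "standard", known_ng = ng,
      species = NA_character_, time_h = NA_real_, bio_rep = NA_integer_,
      tech_rep = 1:2,
      od = spec@ncOd + spec@curveSlope * ng + noise(2L),
      stringsAsFactors = FALSE)
  }))
  nc <- data.frame(
    well = "NC1", role = "nc", known_ng = 0, species = NA_character_,
    time_h = NA_real_, bio_rep = NA_integer_, tech_rep = 1L,
    od = spec@ncOd + noise(1L), stringsAsFactors = FALSE)
  tp <- spec@truePercent
  smp <- do.call(rbind, lapply(seq_len(nrow(tp)), function(i) {
    ng <- tp$percent[i] / 100 * spec@inputRnaNg
    k <- spec@techReplicates
    data.frame(
      well = sprintf("A%d_%d", i, seq_len(k)), role = "sample",
      known_ng = NA_real_, species = tp$species[i], time_h = tp$time_h[i],
      bio_rep = as.integer(tp$bio_rep[i]), tech_rep = seq_len(k),
      od = spec@ncOd + spec@curveSlope * ng + noise(k),
      stringsAsFactors = FALSE)
  }))
  out <- rbind(std, nc, smp)
  rownames(out) <- NULL
  out
}
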