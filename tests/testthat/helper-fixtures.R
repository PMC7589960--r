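# Shared fixtures and independent brute-force oracles.

# one outfmt-6 row as a data.frame
mkHit <- function(q, s, e, bits = 100) {
  data.frame(qseqid = q, sseqid = s, pident = 90, length = 100L,
             mismatch = 10L, gapopen = 0L, qstart = 1L, qend = 100L,
             sstart = 1L, send = 100L, evalue = e, bitscore = bits,
             stringsAsFactors = FALSE)
}

mkHits <- function(...) do.call(rbind, list(...))

# symmetric pair of directed hits
mkPair <- function(a, b, e1, e2 = e1, bits = 100) {
  rbind(mkHit(a, b, e1, bits), mkHit(b, a, e2, bits))
}

# connected-component count (>= minSize members) by label propagation;
# independent of igraph
bruteComponentCount <- function(edges, minSize = 2L) {
  if (!nrow(edges)) return(0L)
  verts <- unique(c(edges$a, edges$b))
  lab <- seq_along(verts)
  names(lab) <- verts
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      la <- lab[[edges$a[i]]]; lb <- lab[[edges$b[i]]]
      if (la != lb) {
        lab[lab == max(la, lb)] <- min(la, lb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sum(table(lab) >= minSize)
}

# component membership as a named label vector (same algorithm)
bruteComponents <- function(edges) {
  verts <- unique(c(edges$a, edges$b))
  lab <- seq_along(verts)
  names(lab) <- verts
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      la <- lab[[edges$a[i]]]; lb <- lab[[edges$b[i]]]
      if (la != lb) {
        lab[lab == max(la, lb)] <- min(la, lb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# brute-force best-hit: explicit loops, minimal E then max bits then id
bruteBestHit <- function(hits, crossSpecies = TRUE) {
  sp <- function(id) sub("_.*$", "", id)
  out <- list()
  for (q in unique(hits$qseqid)) {
    h <- hits[hits$qseqid == q, ]
    same <- sp(h$sseqid) == sp(q)
    h <- if (crossSpecies) h[!same, ] else h[same, ]
    for (ts in unique(sp(h$sseqid))) {
      g <- h[sp(h$sseqid) == ts, ]
      g <- g[g$evalue == min(g$evalue), ]
      g <- g[g$bitscore == max(g$bitscore), ]
      g <- g[order(g$sseqid), ][1, ]
      out[[paste(q, ts)]] <- data.frame(
        query_id = q, target_species = ts, subject_id = g$sseqid,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, unname(out))
}

# small three-family fixture used across homology tests
toyFamilySpecs <- function() {
  list(FamilySpec("MTA", c(Zm = 2, At = 2)),
       FamilySpec("FIP37", c(Zm = 2, At = 2)),
       FamilySpec("ALKBH9B", c(Zm = 2, At = 2)))
}

# balanced two-factor layout used by the stats tests
balancedLayout <- function(a = 2, b = 6, r = 3) {
  list(fa = factor(rep(seq_len(a), each = b * r)),
       fb = factor(rep(rep(seq_len(b), each = r), a)),
       n = a * b * r)
}
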