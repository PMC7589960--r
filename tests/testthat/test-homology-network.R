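# BBH orthologs, cutoff scan, network construction, annotation and the
# writer/eraser inventory.

test_that("readSimilarity parses, drops self-hits and flags bad rows", {
  f <- tempfile(fileext = ".tsv")
  rows <- c("# comment line",
            paste(c("Zm_A1", "At_B1", 90, 100, 10, 0, 1, 100, 1, 100,
                    "1e-50", 200), collapse = "\t"),
            paste(c("Zm_A1", "Zm_A1", 100, 100, 0, 0, 1, 100, 1, 100,
                    "0", 300), collapse = "\t"),
            paste(c("At_B1", "Zm_A1", 90, 100, 10, 0, 1, 100, 1, 100,
                    "2e-48", 195), collapse = "\t"))
  writeLines(rows, f)
  hits <- readSimilarity(f)
  expect_identical(nrow(hits), 2L)
  expect_identical(attr(hits, "selfHitsDropped"), 1L)
  expect_equal(hits$evalue, c(1e-50, 2e-48))

  writeLines(c(rows, "Zm_A1\tAt_B2\tshort"), f)
  expect_error(readSimilarity(f), "line 5")

  writeLines(paste(c("Zm_A1", "At_B1", 90, 100, 10, 0, 1, 100, 1, 100,
                     "not_a_number", 200), collapse = "\t"), f)
  expect_warning(h2 <- readSimilarity(f), "line\\(s\\) 1")
  expect_identical(nrow(h2), 0L)
})

test_that("best hits follow the E-value / bitscore / ID tie-break chain", {
  h <- mkHits(mkHit("Zm_A1", "At_B1", 1e-50), mkHit("Zm_A1", "At_B2", 1e-10))
  b <- bestHitMap(h)
  expect_identical(b$subject_id, "At_B1")

  h2 <- mkHits(mkHit("Zm_A1", "At_B1", 1e-50, bits = 180),
               mkHit("Zm_A1", "At_B2", 1e-50, bits = 200))
  expect_identical(bestHitMap(h2)$subject_id, "At_B2")

  h3 <- mkHits(mkHit("Zm_A1", "At_B2", 1e-50, bits = 200),
               mkHit("Zm_A1", "At_B1", 1e-50, bits = 200))
  expect_identical(bestHitMap(h3)$subject_id, "At_B1")
})

test_that("BBH emits exactly the reciprocal best pairs", {
  h <- mkHits(mkPair("Zm_A1", "At_B1", 1e-50, 1e-48))
  edges <- bbhOrthologs(bestHitMap(h))
  expect_identical(nrow(edges), 1L)
  expect_equal(edges$evalue, 1e-50)

  # asymmetry: A1's best is B1 but B1's best is A2
  h2 <- mkHits(mkHit("Zm_A1", "At_B1", 1e-50),
               mkHit("At_B1", "Zm_A2", 1e-60),
               mkHit("At_B1", "Zm_A1", 1e-50),
               mkHit("Zm_A2", "At_B1", 1e-60))
  e2 <- bbhOrthologs(bestHitMap(h2))
  expect_identical(nrow(e2), 1L)
  expect_identical(sort(c(e2$a, e2$b)), c("At_B1", "Zm_A2"))
})

test_that("BBH edges match an O(n^2) reciprocity oracle on random tables", {
  sp <- c("Zm", "At", "Os")
  for (seed in 1:20) {
    set.seed(seed)
    ids <- paste0(rep(sp, each = 2), "_P", rep(1:2, 3))
    rows <- list()
    for (q in ids) for (s in ids) {
      if (q == s || sub("_.*", "", q) == sub("_.*", "", s)) next
      if (runif(1) < 0.8)
        rows[[paste(q, s)]] <- mkHit(q, s, 10^-runif(1, 5, 100),
                                     bits = round(runif(1, 50, 300)))
    }
    hits <- do.call(rbind, unname(rows))
    mine <- bbhOrthologs(bestHitMap(hits))
    oracle <- bruteBestHit(hits, crossSpecies = TRUE)
    key <- with(oracle, setNames(subject_id,
                                 paste(query_id, target_species)))
    expEdges <- character()
    for (i in seq_len(nrow(oracle))) {
      a <- oracle$query_id[i]; b <- oracle$subject_id[i]
      back <- key[paste(b, sub("_.*", "", a))]
      if (!is.na(back) && back == a)
        expEdges <- c(expEdges, paste(min(a, b), max(a, b)))
    }
    expect_setequal(paste(mine$a, mine$b), unique(expEdges))
  }
})

test_that("paralog edges require reciprocity and respect the cutoff", {
  h <- mkPair("Zm_A1", "Zm_A2", 1e-30, 1e-28)
  expect_identical(nrow(paralogEdges(h, "Zm", 1e-20)), 1L)
  expect_identical(nrow(paralogEdges(h, "Zm", 1e-40)), 0L)
  # single direction -> no edge
  h1 <- mkHit("Zm_A1", "Zm_A2", 1e-30)
  expect_identical(nrow(paralogEdges(h1, "Zm", 1e-20)), 0L)
})

test_that("cutoff sweep matches a brute-force filter and is monotone", {
  set.seed(4)
  ids <- paste0("Zm_P", 1:5)
  rows <- list()
  for (a in ids) for (b in ids) if (a != b)
    rows[[paste(a, b)]] <- mkHit(a, b, 10^-runif(1, 5, 60))
  hits <- do.call(rbind, unname(rows))
  prev <- NULL
  for (cut in c(1e-5, 1e-10, 1e-20, 1e-40, 1e-60)) {
    mine <- paralogEdges(hits, "Zm", cut)
    # oracle: exhaustive pair filter
    exp <- character()
    for (i in 1:4) for (j in (i + 1):5) {
      a <- ids[i]; b <- ids[j]
      eab <- hits$evalue[hits$qseqid == a & hits$sseqid == b]
      eba <- hits$evalue[hits$qseqid == b & hits$sseqid == a]
      if (length(eab) && length(eba) && min(eab, eba) <= cut)
        exp <- c(exp, paste(a, b))
    }
    expect_setequal(paste(mine$a, mine$b), exp)
    # tightening never adds an edge
    if (!is.null(prev))
      expect_true(all(paste(mine$a, mine$b) %in% prev))
    prev <- paste(mine$a, mine$b)
  }
})

test_that("selectCutoff maximises paralog-network count, ties loosest", {
  # 1e-5 keeps one 4-member chain; 1e-20 keeps two 2-member pairs;
  # 1e-50 keeps nothing
  hits <- mkHits(mkPair("Zm_A1", "Zm_A2", 1e-25),
                 mkPair("Zm_A3", "Zm_A4", 1e-25),
                 mkPair("Zm_A2", "Zm_A3", 1e-10))
  sel <- selectCutoff(hits, "Zm", grid = c(1e-5, 1e-20, 1e-50))
  expect_equal(unname(sel$counts), c(1L, 2L, 0L))
  expect_equal(sel$selected, 1e-20)
  expect_false(sel$flagged)

  # fully connected at every threshold -> tie -> loosest
  hits2 <- mkHits(mkPair("Zm_A1", "Zm_A2", 1e-130),
                  mkPair("Zm_A2", "Zm_A3", 1e-135))
  sel2 <- selectCutoff(hits2, "Zm", grid = c(1e-5, 1e-20, 1e-50))
  expect_equal(sel2$selected, 1e-5)
  expect_equal(unname(sel2$counts), c(1L, 1L, 1L))

  # no within-species hits -> zeros, loosest, flagged
  sel3 <- selectCutoff(mkHit("Zm_A1", "At_B1", 1e-30), "Zm",
                       grid = c(1e-5, 1e-20))
  expect_true(sel3$flagged)
  expect_true(all(sel3$counts == 0))
  expect_equal(sel3$selected, 1e-5)
})

test_that("cutoff scan equals an independent brute-force count", {
  grid <- 10^seq(-5, -60, by = -5)
  for (seed in 1:25) {
    set.seed(100 + seed)
    n <- sample(4:8, 1)
    ids <- paste0("Zm_P", seq_len(n))
    rows <- list()
    for (a in ids) for (b in ids)
      if (a != b && runif(1) < 0.7)
        rows[[paste(a, b)]] <- mkHit(a, b, 10^-runif(1, 3, 70))
    hits <- do.call(rbind, unname(rows))
    sel <- selectCutoff(hits, "Zm", grid)
    oracleCounts <- vapply(sort(grid, decreasing = TRUE), function(th) {
      e <- paralogEdges(hits, "Zm", th)
      bruteComponentCount(e)
    }, integer(1))
    expect_equal(unname(sel$counts), unname(oracleCounts))
    expect_equal(sel$selected,
                 sort(grid, decreasing = TRUE)[which.max(oracleCounts)])
  }
})

test_that("networks are components of the union graph with stable IDs", {
  orth <- data.frame(a = c("Zm_A1", "At_B1"), b = c("At_B1", "Os_C1"),
                     kind = "ortholog", evalue = 1e-40)
  par0 <- data.frame(a = character(), b = character(), kind = character(),
                     evalue = numeric())
  nets <- buildNetworks(orth, par0)
  expect_identical(length(networkIds(nets)), 1L)
  expect_setequal(networkMembers(nets)$NET_1,
                  c("At_B1", "Os_C1", "Zm_A1"))

  empty <- buildNetworks(par0, par0)
  expect_identical(length(networkIds(empty)), 0L)
})

test_that("two subfamilies joined by a bridging species form one network", {
  # dense subfamily 1 (Zm/At), dense subfamily 2 (Zm2/At2), bridged only
  # through the Os proteins, emulating the eraser-network topology
  par1 <- data.frame(a = c("Zm_A1", "At_A1"), b = c("Zm_A2", "At_A2"),
                     kind = "paralog", evalue = 1e-60)
  orth <- data.frame(
    a = c("At_A1", "Os_X1", "Os_X1", "At_B1", "Zm_B1"),
    b = c("Zm_A1", "Zm_A1", "Zm_B1", "Os_X1", "Zm_B2"),
    kind = "ortholog", evalue = 1e-35)
  nets <- buildNetworks(orth, par1)
  expect_identical(length(networkIds(nets)), 1L)
  # union-find oracle agrees
  edges <- rbind(par1[, c("a", "b")], orth[, c("a", "b")])
  lab <- bruteComponents(edges)
  expect_identical(length(unique(lab)), 1L)
})

test_that("annotation retains writer/eraser networks and labels members", {
  orth <- data.frame(a = c("Zm_A1", "Zm_B1"), b = c("At_A1", "At_B1"),
                     kind = "ortholog", evalue = 1e-40)
  par0 <- orth[0, ]
  nets <- buildNetworks(orth, par0)
  ann <- c(Zm_A1 = "MTA", At_A1 = "MTB", Zm_B1 = "other")
  nets <- annotateNetworks(nets, ann)
  expect_identical(unname(memberLabels(nets)["At_B1"]), "unknown")
  inv <- inventoryTable(nets)
  # mixed MTA+MTB network retained once, both genes represented
  expect_setequal(inv$gene_name, c("MTA", "MTB"))
  expect_identical(unique(inv$network_id),
                   unname(nets@membership["Zm_A1"]))
  # all-"other" network excluded
  expect_false(any(grepl("_B1", inv$member_ids)))
  expect_true(all(inv$type == "Writer"))
})

test_that("inventory mirrors the planted family cross-tabulation", {
  pr <- generateProteomes(
    list(FamilySpec("FIP37", c(Zm = 6, At = 1, Os = 1)),
         FamilySpec("ALKBH9B", c(Zm = 1, At = 3))),
    c("Zm", "At", "Os"), seed = 13)
  sim <- simulateSimilarity(pr$proteomes, pr$truth, seed = 13)
  ann <- setNames(pr$truth$family, pr$truth$protein_id)
  hom <- inferHomology(sim, ann)
  inv <- hom$inventory
  zmRow <- inv[inv$gene_name == "FIP37" & inv$species == "Zm", ]
  expect_identical(zmRow$n_members, 6L)
  expect_identical(zmRow$type, "Writer")
  # no row for absent family-species pairs
  expect_false(any(inv$gene_name == "ALKBH9B" & inv$species == "Os"))
  # full pivot agreement with the ground truth
  pivot <- as.data.frame(table(pr$truth$family, pr$truth$species),
                         stringsAsFactors = FALSE)
  pivot <- pivot[pivot$Freq > 0, ]
  got <- inv[, c("gene_name", "species", "n_members")]
  expect_identical(nrow(got), nrow(pivot))
  for (i in seq_len(nrow(pivot)))
    expect_identical(
      got$n_members[got$gene_name == pivot$Var1[i] &
                      got$species == pivot$Var2[i]],
      as.integer(pivot$Freq[i]))
})

test_that("outputs are invariant to input row order", {
  pr <- generateProteomes(toyFamilySpecs(), c("Zm", "At"), seed = 21)
  sim <- simulateSimilarity(pr$proteomes, pr$truth, seed = 21)
  ann <- setNames(pr$truth$family, pr$truth$protein_id)
  set.seed(1)
  simPerm <- sim[sample.int(nrow(sim)), ]
  a <- inferHomology(sim, ann)
  b <- inferHomology(simPerm, ann)
  expect_identical(a$networks@membership, b$networks@membership)
  expect_identical(a$inventory, b$inventory)
  expect_identical(lapply(a$cutoffs, `[[`, "selected"),
                   lapply(b$cutoffs, `[[`, "selected"))
})

test_that("networks partition the proteins that carry retained edges", {
  pr <- generateProteomes(toyFamilySpecs(), c("Zm", "At"), seed = 31)
  sim <- simulateSimilarity(pr$proteomes, pr$truth, seed = 31)
  hom <- inferHomology(sim)
  mem <- hom$networks@membership
  ed <- networkEdges(hom$networks)
  expect_setequal(names(mem), unique(c(ed$a, ed$b)))
  # one network per protein, edges stay inside their network
  expect_identical(anyDuplicated(names(mem)), 0L)
  expect_true(all(mem[ed$a] == mem[ed$b]))
})

test_that("collapseRedundant merges near-identical sequences only", {
  base <- paste(rep(c("A", "C", "D", "E", "F"), 20), collapse = "")
  mutate_at <- function(s, pos, to) {
    x <- strsplit(s, "")[[1]]; x[pos] <- to; paste(x, collapse = "")
  }
  s99 <- mutate_at(base, 50, "W")               # 99% identical
  s90 <- base
  for (p in seq(1, 100, by = 10)) s90 <- mutate_at(s90, p, "Y")  # 90%
  seqs <- Biostrings::AAStringSet(c(a = base, b = base))
  out <- collapseRedundant(seqs, 0.98, 0.5)
  expect_identical(length(out$representatives), 1L)
  expect_identical(length(out$collapseMap), 1L)

  out99 <- collapseRedundant(
    Biostrings::AAStringSet(c(a = base, b = s99)), 0.98, 0.5)
  expect_identical(length(out99$representatives), 1L)

  out90 <- collapseRedundant(
    Biostrings::AAStringSet(c(a = base, b = s90)), 0.98, 0.5)
  expect_identical(length(out90$representatives), 2L)
  expect_identical(length(out90$collapseMap), 0L)
})
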