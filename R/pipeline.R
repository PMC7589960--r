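# End-to-end orchestration: simulate -> homology -> inventory ->
# expression -> methylation -> statistics, driven by one validated config
# with a single seed fanned out to per-stage sub-seeds.

.CONFIG_KEYS <- list(
  top = c("seed", "species", "families", "similarity", "grid", "design",
          "rhythms", "m6a", "elisa", "stats", "night"),
  families = c("name", "copies", "ancestral_length", "rate_ortholog",
               "rate_paralog", "variants"),
  similarity = c("within_log10e", "between_log10e", "between_enabled",
                 "between_prob"),
  grid = c("from", "to", "by"),
  design = c("species", "times", "bio_reps", "tech_reps"),
  rhythms = c("gene", "species", "baseline_ct", "amplitude_ct",
              "peak_time", "noise_sd", "reference_baseline_ct"),
  m6a = c("baseline_percent", "amplitude_percent", "peak_time"),
  elisa = c("curve_slope", "nc_od", "standard_points", "input_rna_ng",
            "noise_sd", "tech_replicates"),
  stats = c("n_perm", "n_mc", "alpha"),
  night = c("sunrise", "sunset"))

.checkKeys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    .err("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "))
}

#' Validate a pipeline configuration
#'
#' Schema check run before any stage: unknown keys anywhere are rejected,
#' required blocks must be present, and numeric fields must be in range.
#'
#' @param config Named list (e.g. from \code{yaml::read_yaml}).
#' @return The config, invisibly, if valid; otherwise an error.
#' @export
validateConfig <- function(config) {
  .checkKeys(config, .CONFIG_KEYS$top, "top level")
  need <- c("seed", "species", "families", "design", "rhythms", "m6a",
            "elisa")
  missing <- setdiff(need, names(config))
  if (length(missing))
    .err("config lacks required block(s): ", paste(missing, collapse = ", "))
  for (f in config$families)
    .checkKeys(f[setdiff(names(f), "copies")],
               setdiff(.CONFIG_KEYS$families, "copies"), "families entry")
  for (blk in c("similarity", "grid", "design", "m6a", "elisa", "stats",
                "night"))
    if (!is.null(config[[blk]]))
      .checkKeys(config[[blk]], .CONFIG_KEYS[[blk]], blk)
  for (r in config$rhythms) .checkKeys(r, .CONFIG_KEYS$rhythms, "rhythms entry")
  if (any(config$design$times < 0 | config$design$times >= 24))
    .err("design times must lie in [0, 24)")
  invisible(config)
}

#' Read and validate a pipeline config from YAML
#'
#' @param path Path to a YAML file with the schema of
#'   \code{\link{defaultPipelineConfig}}.
#' @return The validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- read_yaml(path)
  validateConfig(cfg)
  cfg
}

#' Default pipeline configuration
#'
#' Emulates the study layout: four proteomes (two terrestrial references,
#' two seagrasses) with the writer/eraser family copy numbers of the
#' published inventory; an interspecific diel design (2 species x 6 times
#' x 3 biological x 3 technical replicates); night-peaking writer/eraser
#' rhythms; and an m6A percent rhythm quantified from a 5-point ELISA
#' curve with 100 ng input RNA.
#'
#' @param seed Master seed (default 1).
#' @return A validated config list.
#' @export
defaultPipelineConfig <- function(seed = 1) {
  fam <- function(name, copies)
    list(name = name, copies = copies, ancestral_length = 150,
         rate_ortholog = 0.1, rate_paralog = 0.05, variants = 0)
  cfg <- list(
    seed = seed,
    species = c("At", "Os", "Zm", "Cn"),
    families = list(
      fam("MTA", list(At = 1, Os = 1, Zm = 1, Cn = 2)),
      fam("MTB", list(At = 2, Os = 3, Zm = 1, Cn = 4)),
      fam("FIP37", list(At = 1, Os = 1, Zm = 6, Cn = 7)),
      fam("VIRILIZER", list(At = 2, Os = 0, Zm = 1, Cn = 3)),
      fam("HAKAI", list(At = 1, Os = 1, Zm = 1, Cn = 1)),
      fam("ALKBH9B", list(At = 10, Os = 1, Zm = 1, Cn = 13)),
      fam("ALKBH10B", list(At = 4, Os = 2, Zm = 3, Cn = 20))),
    similarity = list(within_log10e = c(-120, -20),
                      between_log10e = c(-8, -3),
                      between_enabled = FALSE, between_prob = 0.1),
    grid = list(from = -5, to = -120, by = 1),
    design = list(species = c("Cn", "Zm"),
                  times = c(0, 4.5, 6.5, 13, 20.5, 22),
                  bio_reps = 3, tech_reps = 3),
    rhythms = list(
      list(gene = "MTA", species = "Cn", baseline_ct = 25,
           amplitude_ct = 1.2, peak_time = 0, noise_sd = 0.1,
           reference_baseline_ct = 20),
      list(gene = "MTB", species = "Cn", baseline_ct = 26,
           amplitude_ct = 1.0, peak_time = 0, noise_sd = 0.1,
           reference_baseline_ct = 20),
      list(gene = "ALKBH9B", species = "Cn", baseline_ct = 27,
           amplitude_ct = 0.8, peak_time = 0, noise_sd = 0.1,
           reference_baseline_ct = 20),
      list(gene = "MTA", species = "Zm", baseline_ct = 24,
           amplitude_ct = 1.2, peak_time = 16, noise_sd = 0.1,
           reference_baseline_ct = 20),
      list(gene = "MTB", species = "Zm", baseline_ct = 25,
           amplitude_ct = 1.0, peak_time = 16, noise_sd = 0.1,
           reference_baseline_ct = 20),
      list(gene = "ALKBH9B", species = "Zm", baseline_ct = 26,
           amplitude_ct = 0.4, peak_time = 13, noise_sd = 0.1,
           reference_baseline_ct = 20)),
    m6a = list(baseline_percent = 0.10, amplitude_percent = 0.03,
               peak_time = list(Cn = 22, Zm = 0)),
    elisa = list(curve_slope = 0.02, nc_od = 0.10,
                 standard_points = c(0.02, 0.04, 0.1, 0.2, 0.5),
                 input_rna_ng = 100, noise_sd = 0.002,
                 tech_replicates = 2),
    stats = list(n_perm = 999, n_mc = 10000, alpha = 0.05),
    night = list(sunrise = 6.5, sunset = 20.5))
  validateConfig(cfg)
  cfg
}

.famSpecsFromConfig <- function(config) {
  lapply(config$families, function(f)
    FamilySpec(f$name, unlist(f$copies),
               ancestralLength = f$ancestral_length,
               subRateOrtholog = f$rate_ortholog,
               subRateParalog = f$rate_paralog,
               variantCount = f$variants))
}

.rhythmSpecsFromConfig <- function(config) {
  lapply(config$rhythms, function(r)
    RhythmSpec(r$gene, r$species, baselineCt = r$baseline_ct,
               amplitudeCt = r$amplitude_ct, peakTime = r$peak_time,
               noiseSd = r$noise_sd,
               referenceBaselineCt = r$reference_baseline_ct))
}

.truePercentFromConfig <- function(config) {
  d <- config$design
  m <- config$m6a
  grid <- expand.grid(species = d$species, time_h = d$times,
                      bio_rep = seq_len(d$bio_reps),
                      stringsAsFactors = FALSE)
  peak <- vapply(grid$species, function(sp) {
    pk <- m$peak_time
    if (is.list(pk)) pk[[sp]] else pk
  }, numeric(1L))
  grid$percent <- m$baseline_percent + m$amplitude_percent *
    cos(2 * pi * (grid$time_h - peak) / 24)
  grid
}

.hashConfig <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(toJSON(config, auto_unbox = TRUE, digits = NA)),
             tmp)
  unname(md5sum(tmp))
}

.stageLog <- function(stage, ...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Executes every stage against one config and seed, writing a report
#' bundle (inventory, profiles, m6A table, PERMANOVA/ANOVA/SNK tables,
#' diagnostics) plus a manifest of input/output checksums.  Re-running
#' over an existing bundle with an identical config and seed is a no-op
#' (checksums verified) unless \code{force = TRUE}.
#'
#' @param config Config list (see \code{\link{defaultPipelineConfig}}).
#' @param out Output directory.
#' @param seed Optional override of \code{config$seed}.
#' @param force Re-run even when an identical manifest exists.
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), out,
                        seed = NULL, force = FALSE) {
  validateConfig(config)
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfgHash <- .hashConfig(config)
  manPath <- file.path(out, "manifest.json")
  if (!force && file.exists(manPath)) {
    old <- jsonlite::read_json(manPath, simplifyVector = TRUE)
    if (identical(old$config_hash, unname(cfgHash)) &&
        identical(as.numeric(old$seed), as.numeric(seed))) {
      files <- file.path(out, names(old$checksums))
      if (all(file.exists(files)) &&
          identical(unname(md5sum(files)), unname(unlist(old$checksums)))) {
        .stageLog("pipeline", "outputs up to date; skipping (use force)")
        return(invisible(old))
      }
    }
  }
  paths <- character()

  .stageLog("proteomes", "generating synthetic proteomes")
  fams <- .famSpecsFromConfig(config)
  pr <- generateProteomes(fams, config$species, seed)
  writeProteomes(pr$proteomes, file.path(out, "proteomes"))
  truthPath <- file.path(out, "truth_families.csv")
  write.csv(pr$truth, truthPath, row.names = FALSE)
  paths <- c(paths, "truth_families.csv")

  .stageLog("similarity", "simulating all-vs-all similarity")
  simCfg <- config$similarity
  model <- similarityModel(
    within = unlist(simCfg$within_log10e),
    between = unlist(simCfg$between_log10e),
    betweenEnabled = isTRUE(simCfg$between_enabled),
    betweenProb = simCfg$between_prob %||% 0.1)
  sim <- simulateSimilarity(pr$proteomes, pr$truth, model, seed)
  simPath <- file.path(out, "similarity.tsv")
  writeSimilarity(sim, simPath)
  paths <- c(paths, "similarity.tsv")

  .stageLog("homology", "inferring ortholog/paralog networks")
  hits <- readSimilarity(simPath)
  annotation <- setNames(pr$truth$family, pr$truth$protein_id)
  grid <- evalueGrid(config$grid$from %||% -5, config$grid$to %||% -120,
                     config$grid$by %||% 1)
  hom <- inferHomology(hits, annotation, grid)
  writeNetworks(hom$networks, file.path(out, "networks"))
  invPath <- file.path(out, "inventory.csv")
  write.csv(hom$inventory, invPath, row.names = FALSE)
  paths <- c(paths, "inventory.csv")

  .stageLog("expression", "generating diel CT table and -dCT profiles")
  d <- config$design
  design <- studyDesign(d$species, d$times, d$bio_reps, d$tech_reps)
  ct <- generateDielCt(design, .rhythmSpecsFromConfig(config), seed)
  ctPath <- file.path(out, "ct_table.csv")
  write.csv(ct, ctPath, row.names = FALSE)
  dct <- negDeltaCt(ct)
  profPath <- file.path(out, "neg_delta_ct_profile.csv")
  prof <- dct$profile
  night <- config$night %||% list(sunrise = 6.5, sunset = 20.5)
  prof$night <- prof$time_h < night$sunrise | prof$time_h >= night$sunset
  write.csv(prof, profPath, row.names = FALSE)
  paths <- c(paths, "ct_table.csv", "neg_delta_ct_profile.csv")

  .stageLog("methylation", "generating ELISA plate and quantifying m6A")
  e <- config$elisa
  espec <- ElisaSpec(.truePercentFromConfig(config),
                     curveSlope = e$curve_slope, ncOd = e$nc_od,
                     standardPoints = unlist(e$standard_points),
                     inputRnaNg = e$input_rna_ng, noiseSd = e$noise_sd,
                     techReplicates = e$tech_replicates %||% 2)
  plate <- generateElisaPlate(espec, seed)
  platePath <- file.path(out, "elisa_plate.csv")
  write.csv(plate, platePath, row.names = FALSE)
  qm <- quantifyPlate(plate, espec@inputRnaNg)
  m6aPath <- file.path(out, "m6a_percent.csv")
  write.csv(qm$measurements, m6aPath, row.names = FALSE)
  paths <- c(paths, "elisa_plate.csv", "m6a_percent.csv")

  .stageLog("stats", "PERMANOVA / ANOVA / SNK / diagnostics")
  st <- config$stats %||% list(n_perm = 999, n_mc = 10000, alpha = 0.05)
  sm <- sampleMatrix(dct$samples)
  D <- distanceMatrix(sm$mat, normalise = TRUE)
  fa <- factor(sm$meta$species); fb <- factor(sm$meta$time_h)
  perma <- permanovaTwoWay(D, fa, fb, nPerm = st$n_perm, seed = seed,
                           aName = "Species", bName = "Time")
  permaPath <- file.path(out, "permanova.csv")
  write.csv(resultTable(perma), permaPath, row.names = FALSE)
  pw <- pairwisePermanova(D, fa, fb, nPerm = st$n_perm,
                          nMc = st$n_mc %||% 10000, seed = seed)
  pwPath <- file.path(out, "permanova_pairwise.csv")
  write.csv(pw, pwPath, row.names = FALSE)

  genes <- colnames(sm$mat)
  anovaRows <- list(); snkRows <- list(); diag <- list()
  alpha <- st$alpha %||% 0.05
  for (g in genes) {
    y <- sm$mat[, g]
    tab <- anovaTwoWay(y, fa, fb, aName = "Species", bName = "Time")
    tab <- cbind(response = g, tab)
    anovaRows[[g]] <- tab
    fit <- aov(y ~ fa * fb)
    diag[[g]] <- assumptionChecks(stats::residuals(fit),
                                  interaction(fa, fb))
    pInt <- tab$p[tab$effect == "Species x Time"]
    if (is.finite(pInt) && pInt < alpha) {
      mse <- tab$MS[tab$effect == "Error"]
      dfe <- tab$df[tab$effect == "Error"]
      for (sp in levels(fa)) {
        cellMeans <- tapply(y[fa == sp], droplevels(fb[fa == sp]), mean)
        snk <- snkPosthoc(cellMeans, mse, dfe,
                          n = sum(fa == sp & fb == levels(fb)[1L]),
                          alpha = alpha)
        snkRows[[paste(g, sp)]] <- cbind(response = g, species = sp,
                                         snk$decisions)
      }
    }
  }
  m6aWide <- qm$measurements
  yM <- m6aWide$m6a_percent
  faM <- factor(m6aWide$species); fbM <- factor(m6aWide$time_h)
  tabM <- cbind(response = "m6A_percent",
                anovaTwoWay(yM, faM, fbM, aName = "Species",
                            bName = "Time"))
  anovaRows[["m6A_percent"]] <- tabM
  anovaPath <- file.path(out, "anova.csv")
  write.csv(do.call(rbind, anovaRows), anovaPath, row.names = FALSE)
  snkPath <- file.path(out, "snk.csv")
  if (length(snkRows)) {
    write.csv(do.call(rbind, snkRows), snkPath, row.names = FALSE)
  } else {
    write.csv(data.frame(), snkPath, row.names = FALSE)
  }
  diagPath <- file.path(out, "diagnostics.json")
  write_json(diag, diagPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, "permanova.csv", "permanova_pairwise.csv", "anova.csv",
             "snk.csv", "diagnostics.json")

  files <- file.path(out, paths)
  manifest <- list(
    config_hash = unname(cfgHash), seed = seed,
    tool_version = as.character(utils::packageVersion("m6ARhythms")),
    stages = c("proteomes", "similarity", "homology", "expression",
               "methylation", "stats"),
    checksums = as.list(setNames(unname(md5sum(files)), paths)))
  write_json(manifest, manPath, auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  .stageLog("pipeline", "done: ", length(paths), " outputs in ", out)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
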