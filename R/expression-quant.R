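# RT-qPCR relative quantification: -dCT = CT_RG - CT_GOI per biological
# sample (technical replicates averaged first), primer-efficiency fits from
# dilution series, and Pearson correlation of daily profiles.

# Average technical replicates after dropping outliers more than
# `tol` cycles from the within-sample median (a common qPCR QC rule).
.techMean <- function(ct, tol = 0.5) {
  if (length(ct) > 2L) {
    keep <- abs(ct - stats::median(ct)) <= tol
    if (any(keep)) ct <- ct[keep]
  }
  mean(ct)
}

#' Per-sample -dCT values and aggregated profiles
#'
#' Technical replicates are averaged per biological sample (after a 0.5
#' cycle median-deviation QC filter), then each gene of interest is
#' normalised against the reference gene measured on the same sample:
#' \code{-dCT = CT_RG - CT_GOI}.  Higher values mean higher relative
#' transcript abundance.  Samples lacking a reference-gene measurement are
#' dropped with a warning.
#'
#' @param ctTable data.frame with columns species, gene, time_h, bio_rep,
#'   tech_rep, ct (see \code{\link{generateDielCt}}); \code{ct} must be
#'   positive.
#' @param referenceGene Reference gene name (default \code{"eIF4A"}).
#' @return List with \code{samples} (data.frame species, gene, time_h,
#'   bio_rep, neg_delta_ct) and \code{profile} (data.frame species, gene,
#'   time_h, mean_neg_dct, se, n; SE = sd over biological replicates /
#'   sqrt(n)).
#' @export
#' @examples
#' ct <- data.frame(species = "Cn", gene = c("MTA", "eIF4A"),
#'                  time_h = 0, bio_rep = 1, tech_rep = 1,
#'                  ct = c(25, 20))
#' negDeltaCt(ct)$samples
negDeltaCt <- function(ctTable, referenceGene = "eIF4A") {
  need <- c("species", "gene", "time_h", "bio_rep", "tech_rep", "ct")
  stopifnot(all(need %in% names(ctTable)))
  if (any(ctTable$ct <= 0)) .err("CT values must be positive")
  if (!referenceGene %in% ctTable$gene)
    .err("reference gene '", referenceGene, "' absent from the CT table")
  key <- c("species", "gene", "time_h", "bio_rep")
  avg <- aggregate(ct ~ species + gene + time_h + bio_rep, ctTable,
                   .techMean)
  rg <- avg[avg$gene == referenceGene, c("species", "time_h", "bio_rep",
                                         "ct")]
  names(rg)[4L] <- "ct_rg"
  goi <- avg[avg$gene != referenceGene, , drop = FALSE]
  merged <- merge(goi, rg, by = c("species", "time_h", "bio_rep"),
                  all.x = TRUE)
  miss <- is.na(merged$ct_rg)
  if (any(miss)) {
    warning(sum(miss), " sample(s) dropped: no reference-gene measurement",
            call. = FALSE)
    merged <- merged[!miss, , drop = FALSE]
  }
  merged$neg_delta_ct <- merged$ct_rg - merged$ct
  samples <- merged[order(merged$species, merged$gene, merged$time_h,
                          merged$bio_rep),
                    c("species", "gene", "time_h", "bio_rep",
                      "neg_delta_ct")]
  rownames(samples) <- NULL
  prof <- do.call(rbind, lapply(
    split(samples,
          interaction(samples$species, samples$gene, samples$time_h,
                      drop = TRUE)),
    function(d) data.frame(
      species = d$species[1L], gene = d$gene[1L], time_h = d$time_h[1L],
      mean_neg_dct = mean(d$neg_delta_ct),
      se = if (nrow(d) > 1L) sd(d$neg_delta_ct) / sqrt(nrow(d)) else 0,
      n = nrow(d), stringsAsFactors = FALSE)))
  prof <- prof[order(prof$species, prof$gene, prof$time_h), , drop = FALSE]
  rownames(prof) <- NULL
  list(samples = samples, profile = prof)
}

#' Fit primer amplification efficiency from a dilution series
#'
#' Ordinary least squares of mean CT on log10 relative concentration; the
#' amplification efficiency is \code{E = 10^(-1/slope)}, reported as
#' \code{(E - 1) * 100} percent (so perfect doubling, slope -3.3219, is
#' 100\%).  At least five distinct dilution points are required; a
#' non-negative slope flags the series as invalid (amplification must
#' reduce CT with concentration).
#'
#' @param points data.frame with columns log10_conc, ct (replicate CTs are
#'   averaged per concentration).
#' @return List with points (mean CT per concentration), slope (cycles per
#'   decade), r2, efficiency (E), efficiency_percent (nearest integer),
#'   valid (logical).
#' @export
#' @examples
#' d <- data.frame(log10_conc = 0:-4, ct = 20 + 3.3219 * (0:4))
#' fitEfficiency(d)$efficiency_percent
fitEfficiency <- function(points) {
  stopifnot(all(c("log10_conc", "ct") %in% names(points)))
  pts <- aggregate(ct ~ log10_conc, points, mean)
  if (nrow(pts) < 5L)
    .err("at least five distinct dilution points are required (got ",
         nrow(pts), ")")
  fit <- lm(ct ~ log10_conc, data = pts)
  slope <- unname(coef(fit)[2L])
  # noise-free series fit exactly; the perfect-fit warning is expected
  r2 <- suppressWarnings(summary(fit)$r.squared)
  valid <- slope < 0
  if (!valid)
    warning("non-negative slope: dilution series flagged invalid",
            call. = FALSE)
  E <- 10^(-1 / slope)
  list(points = pts, slope = slope, r2 = r2, efficiency = E,
       efficiency_percent = round((E - 1) * 100), valid = valid)
}

#' Pearson correlation between two genes' per-sample -dCT profiles
#'
#' Samples are paired by (species, time, biological replicate); the
#' correlation and its two-sided p-value come from the t-distribution with
#' n - 2 degrees of freedom.
#'
#' @param samplesA,samplesB Per-sample data.frames from
#'   \code{\link{negDeltaCt}} (one gene each; if several genes are present
#'   the first is used with a warning).
#' @return data.frame with columns gene_a, gene_b, r, p, n.
#' @export
correlateProfiles <- function(samplesA, samplesB) {
  pick1 <- function(d) {
    g <- unique(d$gene)
    if (length(g) > 1L) {
      warning("multiple genes present; using ", g[1L], call. = FALSE)
      d <- d[d$gene == g[1L], , drop = FALSE]
    }
    d
  }
  a <- pick1(samplesA); b <- pick1(samplesB)
  m <- merge(a, b, by = c("species", "time_h", "bio_rep"),
             suffixes = c("_a", "_b"))
  n <- nrow(m)
  if (n < 3L) .err("fewer than 3 complete pairs (n = ", n, ")")
  if (sd(m$neg_delta_ct_a) == 0 || sd(m$neg_delta_ct_b) == 0)
    .err("zero variance in a profile: correlation undefined")
  ct <- cor.test(m$neg_delta_ct_a, m$neg_delta_ct_b, method = "pearson")
  data.frame(gene_a = a$gene[1L], gene_b = b$gene[1L],
             r = unname(ct$estimate), p = ct$p.value, n = n,
             stringsAsFactors = FALSE)
}

#' Fit a 24-h cosinor to per-sample -dCT values
#'
#' Linear regression on cosine and sine regressors of a 24-h period; the
#' acrophase (peak time) and amplitude follow from the two coefficients.
#' Used to recover planted rhythm parameters from generated data.
#'
#' @param time_h Numeric hours.
#' @param y Response values (e.g. per-sample -dCT).
#' @param period Period in hours (default 24).
#' @return List with mesor, amplitude, peak_time (hours in
#'   \code{[0, period)}), r2.
#' @export
fitCosinor <- function(time_h, y, period = 24) {
  stopifnot(length(time_h) == length(y), length(y) >= 4L)
  w <- 2 * pi / period
  fit <- lm(y ~ cos(w * time_h) + sin(w * time_h))
  b <- coef(fit)
  amp <- sqrt(b[2L]^2 + b[3L]^2)
  peak <- (atan2(b[3L], b[2L]) / w) %% period
  if (period - peak < 1e-9) peak <- 0
  list(mesor = unname(b[1L]), amplitude = unname(amp),
       peak_time = unname(peak),
       r2 = suppressWarnings(summary(fit)$r.squared))
}
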