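# Global m6A quantification from colorimetric ELISA plates: an
# origin-forced standard curve on background-subtracted OD, then
#   m6A (ng) = (sample OD - NC OD) / slope
#   m6A %   = m6A ng / input RNA ng * 100.

#' Fit an ELISA standard curve
#'
#' Duplicate standard wells are averaged per known amount; the slope is the
#' least-squares fit of (mean OD - NC OD) on known ng through the origin
#' (the quantification formula uses only a slope and the negative-control
#' OD, so no intercept is estimated).
#'
#' @param plate ELISA plate data.frame (see
#'   \code{\link{generateElisaPlate}}) or any data.frame with columns
#'   role, known_ng, od.
#' @return A \linkS4class{StandardCurve}.
#' @export
#' @examples
#' tp <- data.frame(species = "Zm", time_h = 0, bio_rep = 1, percent = 0.1)
#' plate <- generateElisaPlate(ElisaSpec(tp), seed = 1)
#' fitStandardCurve(plate)
fitStandardCurve <- function(plate) {
  stopifnot(all(c("role", "known_ng", "od") %in% names(plate)))
  std <- plate[plate$role == "standard", , drop = FALSE]
  ncw <- plate[plate$role == "nc", , drop = FALSE]
  if (!nrow(ncw)) .err("no negative-control well on the plate")
  if (length(unique(std$known_ng)) < 4L)
    .err("at least four distinct standard dilution points are required")
  ncOd <- mean(ncw$od)
  pts <- aggregate(od ~ known_ng, std, mean)
  names(pts) <- c("known_ng", "mean_od")
  y <- pts$mean_od - ncOd
  x <- pts$known_ng
  slope <- sum(x * y) / sum(x^2)
  if (slope <= 0) .err("invalid assay: standard-curve slope is not positive")
  ssRes <- sum((y - slope * x)^2)
  ssTot <- sum(y^2)  # origin-forced fit: total SS about zero
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  new("StandardCurve", points = pts, ncOd = ncOd, slope = slope, r2 = r2)
}

#' Quantify m6A mass and percent from sample wells
#'
#' Technical replicates are averaged per biological sample; the m6A mass
#' follows from the background-subtracted OD and the curve slope, clamped
#' at zero (with a below-background flag) when the mean OD falls below the
#' negative control; the percentage scales by the input RNA mass.
#'
#' @param curve A \linkS4class{StandardCurve}.
#' @param plate ELISA plate data.frame containing sample wells.
#' @param inputRnaNg Input RNA per sample in ng (default 100).
#' @return data.frame with columns species, time_h, bio_rep, mean_od,
#'   m6a_ng, m6a_percent, below_background.
#' @export
quantifyM6a <- function(curve, plate, inputRnaNg = 100) {
  stopifnot(is(curve, "StandardCurve"), inputRnaNg > 0)
  validObject(curve)
  smp <- plate[plate$role == "sample", , drop = FALSE]
  if (!nrow(smp)) .err("no sample wells on the plate")
  if (!"bio_rep" %in% names(smp)) smp$bio_rep <- 1L
  agg <- aggregate(od ~ species + time_h + bio_rep, smp, mean)
  names(agg)[4L] <- "mean_od"
  ng <- (agg$mean_od - curve@ncOd) / curve@slope
  below <- ng < 0
  ng[below] <- 0
  agg$m6a_ng <- ng
  agg$m6a_percent <- ng / inputRnaNg * 100
  agg$below_background <- below
  agg <- agg[order(agg$species, agg$time_h, agg$bio_rep), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Quantify a whole plate in one step
#'
#' Convenience wrapper: fits the standard curve and quantifies every
#' sample well.
#'
#' @param plate ELISA plate data.frame.
#' @param inputRnaNg Input RNA per sample in ng (default 100).
#' @return List with \code{curve} (a \linkS4class{StandardCurve}) and
#'   \code{measurements} (see \code{\link{quantifyM6a}}).
#' @export
quantifyPlate <- function(plate, inputRnaNg = 100) {
  curve <- fitStandardCurve(plate)
  list(curve = curve,
       measurements = quantifyM6a(curve, plate, inputRnaNg))
}
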