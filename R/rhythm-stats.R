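# Inferential layer for the diel analysis: two-way crossed-design
# PERMANOVA on a distance matrix (permutation and asymptotic Monte-Carlo
# p-values), pairwise two-group contrasts, balanced two-way ANOVA, the SNK
# stepwise post-hoc procedure, and assumption diagnostics.

#' Wide sample-by-gene matrix of -dCT values
#'
#' Reshapes the per-sample output of \code{\link{negDeltaCt}} into one row
#' per biological sample (species x time x replicate) and one column per
#' gene, the multivariate response for the PERMANOVA.
#'
#' @param samples Per-sample data.frame (species, gene, time_h, bio_rep,
#'   neg_delta_ct).
#' @return List with \code{mat} (numeric matrix) and \code{meta}
#'   (data.frame species, time_h, bio_rep aligned with the rows).
#' @export
sampleMatrix <- function(samples) {
  wide <- stats::reshape(
    samples, direction = "wide",
    idvar = c("species", "time_h", "bio_rep"), timevar = "gene",
    v.names = "neg_delta_ct")
  ord <- order(wide$species, wide$time_h, wide$bio_rep)
  wide <- wide[ord, , drop = FALSE]
  meta <- wide[, c("species", "time_h", "bio_rep")]
  mat <- as.matrix(wide[, setdiff(names(wide), names(meta)), drop = FALSE])
  colnames(mat) <- sub("^neg_delta_ct\\.", "", colnames(mat))
  rownames(mat) <- NULL
  rownames(meta) <- NULL
  list(mat = mat, meta = meta)
}

#' Euclidean distance matrix with optional per-variable normalisation
#'
#' Optionally z-scores each variable (the convention for response variables
#' on different scales), then computes pairwise Euclidean distances.
#' Zero-variance variables cannot be z-scored and are dropped with a
#' warning.
#'
#' @param mat Numeric samples-by-variables matrix (or data.frame).
#' @param normalise Z-score variables first? (default TRUE)
#' @return A symmetric numeric matrix of distances with zero diagonal.
#' @export
distanceMatrix <- function(mat, normalise = TRUE) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) .err("distanceMatrix: missing or non-finite values")
  if (normalise) {
    sds <- apply(mat, 2L, sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance variable(s): ",
              paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
      mat <- mat[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    mat <- scale(mat)
  }
  as.matrix(dist(mat))
}

# Gower-centred inner-product matrix of a distance matrix:
# G = (I - J/n) (-D^2/2) (I - J/n); tr(G) is the total sum of squares.
.gowerCenter <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  H <- diag(n) - matrix(1 / n, n, n)
  H %*% A %*% H
}

# Orthogonal projectors of the balanced two-way crossed design.
.twoWayProjectors <- function(fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  n <- length(fa)
  cellCounts <- table(fa, fb)
  if (length(unique(as.vector(cellCounts))) != 1L || any(cellCounts == 0))
    .err("design must be balanced and fully crossed")
  proj <- function(f) {
    X <- stats::model.matrix(~ f - 1)
    X %*% (t(X) / colSums(X))  # rows of t(X) scaled by group sizes
  }
  P1 <- matrix(1 / n, n, n)
  Pa <- proj(fa); Pb <- proj(fb)
  Pab <- proj(interaction(fa, fb, drop = TRUE))
  a <- nlevels(fa); b <- nlevels(fb)
  list(
    H = list(A = Pa - P1, B = Pb - P1, AB = Pab - Pa - Pb + P1,
             Res = diag(n) - Pab),
    df = c(A = a - 1, B = b - 1, AB = (a - 1) * (b - 1), Res = n - a * b),
    n = n)
}

#' Two-way crossed-design PERMANOVA
#'
#' Partitions the total sum of squares of a distance matrix over the two
#' main effects, their interaction and the residual via the Gower-centred
#' inner-product matrix and the orthogonal projectors of the balanced
#' design; pseudo-F is each effect's mean square over the residual mean
#' square.  Permutation p-values come from unrestricted permutation of
#' observation labels (exact for balanced fixed-effects designs under the
#' global null), with the observed statistic included in the reference
#' set: \code{p = (b + 1) / (m + 1)}.  \code{unique_perms} counts distinct
#' permutation statistic values sampled.
#'
#' @param d Distance matrix (symmetric matrix or \code{dist}).
#' @param factorA,factorB Factors (length = rows of \code{d}); the design
#'   must be balanced and fully crossed.
#' @param nPerm Number of permutations (>= 999; default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param aName,bName Display names for the two factors.
#' @return A \linkS4class{PermanovaResult}.
#' @export
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(36 * 3), 36)
#' fa <- gl(2, 18); fb <- rep(gl(6, 3), 2)
#' permanovaTwoWay(distanceMatrix(y), fa, fb, nPerm = 999, seed = 1)
permanovaTwoWay <- function(d, factorA, factorB, nPerm = 9999, seed = 1,
                            aName = "A", bName = "B") {
  if (nPerm < 999) .err("nPerm must be at least 999")
  G <- .gowerCenter(d)
  n <- nrow(G)
  stopifnot(length(factorA) == n, length(factorB) == n)
  pr <- .twoWayProjectors(factorA, factorB)
  ssTot <- sum(diag(G))
  if (ssTot <= .Machine$double.eps * n)
    .err("total sum of squares is zero: pseudo-F undefined")
  ss <- vapply(pr$H, function(H) sum(H * G), numeric(1L))
  ms <- ss / pr$df
  fObs <- ms[c("A", "B", "AB")] / ms[["Res"]]
  set.seed(deriveSeed(seed, "permanova"))
  fPerm <- matrix(NA_real_, nPerm, 3L,
                  dimnames = list(NULL, c("A", "B", "AB")))
  for (i in seq_len(nPerm)) {
    p <- sample.int(n)
    Gp <- G[p, p]
    ssP <- vapply(pr$H, function(H) sum(H * Gp), numeric(1L))
    msP <- ssP / pr$df
    fPerm[i, ] <- msP[c("A", "B", "AB")] / msP[["Res"]]
  }
  ge <- sweep(fPerm, 2L, fObs, ">=")
  pPerm <- (colSums(ge) + 1) / (nPerm + 1)
  uniq <- apply(fPerm, 2L, function(x) length(unique(signif(x, 12))))
  srcNames <- c(aName, bName, paste(aName, "x", bName))
  tab <- data.frame(
    source = c(srcNames, "Residual", "Total"),
    df = c(pr$df[c("A", "B", "AB", "Res")], n - 1),
    SS = c(ss[c("A", "B", "AB", "Res")], ssTot),
    MS = c(ms[c("A", "B", "AB", "Res")], NA),
    pseudo_F = c(fObs, NA, NA),
    p_perm = c(pPerm, NA, NA),
    unique_perms = c(uniq, NA, NA),
    stringsAsFactors = FALSE, row.names = NULL)
  new("PermanovaResult", table = tab,
      pairwise = .emptyPairwise(), nPerm = as.numeric(nPerm),
      seed = as.numeric(seed))
}

.emptyPairwise <- function() {
  data.frame(group_within = character(), level_1 = character(),
             level_2 = character(), t = numeric(), p_perm = numeric(),
             p_mc = numeric(), n_unique_perms = numeric(),
             low_resolution = logical())
}

# One-way two-group pseudo-F on a distance-matrix subset.
.twoGroupF <- function(G, grp) {
  n <- nrow(G)
  X <- stats::model.matrix(~ factor(grp) - 1)
  Pg <- X %*% (t(X) / colSums(X))
  P1 <- matrix(1 / n, n, n)
  Hb <- Pg - P1
  Hw <- diag(n) - Pg
  ssB <- sum(Hb * G); ssW <- sum(Hw * G)
  (ssB / 1) / (ssW / (n - 2))
}

#' Pairwise two-group PERMANOVA contrasts
#'
#' For each level of \code{groupFactor} (e.g. species), tests the requested
#' pairs of \code{levelFactor} levels (e.g. time points) with a one-way
#' two-group PERMANOVA on the distance-matrix subset; reports
#' \code{t = sqrt(pseudo-F)}.  When all distinct label splits can be
#' enumerated the permutation p-value is exhaustive (the identity split
#' counts as the observed member of the reference set); otherwise
#' \code{nPerm} random permutations are sampled.  The Monte-Carlo p-value
#' draws the numerator and denominator quadratic forms as
#' eigenvalue-weighted chi-square sums from the spectrum of the subset's
#' Gower-centred matrix (an asymptotic null, useful when few unique
#' permutations exist); contrasts with fewer than 100 distinct splits are
#' flagged low-resolution.
#'
#' @param d Distance matrix over all samples.
#' @param groupFactor Factor whose levels define the strata within which
#'   contrasts are run.
#' @param levelFactor Factor whose level pairs are contrasted.
#' @param contrasts Optional list of character pairs of
#'   \code{levelFactor} levels; default all pairs.
#' @param nPerm Random permutations when enumeration is infeasible
#'   (default 999).
#' @param nMc Monte-Carlo draws (default 10000).
#' @param seed Integer seed.
#' @return data.frame with columns group_within, level_1, level_2, t,
#'   p_perm, p_mc, n_unique_perms, low_resolution.
#' @export
pairwisePermanova <- function(d, groupFactor, levelFactor, contrasts = NULL,
                              nPerm = 999, nMc = 10000, seed = 1) {
  D <- as.matrix(d)
  groupFactor <- factor(groupFactor)
  levelFactor <- factor(levelFactor)
  if (is.null(contrasts))
    contrasts <- combn(levels(levelFactor), 2L, simplify = FALSE)
  set.seed(deriveSeed(seed, "pairwise"))
  rows <- list()
  for (g in levels(groupFactor)) {
    for (pairLv in contrasts) {
      sel <- groupFactor == g & levelFactor %in% pairLv
      grp <- droplevels(levelFactor[sel])
      if (nlevels(grp) != 2L || min(table(grp)) < 2L)
        .err("contrast ", paste(pairLv, collapse = " vs "), " within ", g,
             " needs >= 2 observations per side")
      G <- .gowerCenter(D[sel, sel])
      n <- nrow(G)
      n1 <- sum(grp == levels(grp)[1L])
      fObs <- .twoGroupF(G, grp)
      nSplit <- choose(n, n1)
      nDistinct <- if (n1 == n - n1) nSplit / 2 else nSplit
      if (nSplit <= max(nPerm, 2000)) {
        splits <- combn(n, n1, simplify = FALSE)
        fAll <- vapply(splits, function(ix) {
          lab <- rep(2L, n); lab[ix] <- 1L
          .twoGroupF(G, lab)
        }, numeric(1L))
        pPerm <- mean(fAll >= fObs - 1e-12)
      } else {
        fStar <- vapply(seq_len(nPerm), function(i) {
          .twoGroupF(G, grp[sample.int(n)])
        }, numeric(1L))
        pPerm <- (sum(fStar >= fObs - 1e-12) + 1) / (nPerm + 1)
      }
      lam <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
      lam <- lam[abs(lam) > max(abs(lam)) * 1e-10]
      df1 <- 1L; df2 <- n - 2L
      num <- as.vector(
        matrix(stats::rchisq(nMc * length(lam), df1), nMc) %*% lam) / df1
      den <- as.vector(
        matrix(stats::rchisq(nMc * length(lam), df2), nMc) %*% lam) / df2
      fMc <- num / den
      pMc <- (sum(fMc >= fObs - 1e-12) + 1) / (nMc + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        group_within = g, level_1 = as.character(pairLv[1L]),
        level_2 = as.character(pairLv[2L]), t = sqrt(max(fObs, 0)),
        p_perm = pPerm, p_mc = pMc, n_unique_perms = nDistinct,
        low_resolution = nDistinct < 100, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Balanced two-way ANOVA
#'
#' Classical fixed-effects two-way crossed ANOVA on one response variable,
#' fitted with \code{stats::aov}; the balanced design makes the sequential
#' partition unique.  Zero within-cell variance yields an infinite F and a
#' flag.
#'
#' @param y Numeric response vector.
#' @param factorA,factorB Crossed factors (balanced).
#' @param aName,bName Display names.
#' @return data.frame with one row per effect (A, B, A x B, Error): df,
#'   SS, MS, F, p, plus attribute \code{"degenerate"} when the error mean
#'   square is zero.
#' @export
anovaTwoWay <- function(y, factorA, factorB, aName = "A", bName = "B") {
  fa <- factor(factorA); fb <- factor(factorB)
  .twoWayProjectors(fa, fb)  # validates balance
  fit <- aov(y ~ fa * fb)
  tab <- summary(fit)[[1L]]
  out <- data.frame(
    effect = c(aName, bName, paste(aName, "x", bName), "Error"),
    df = tab[["Df"]], SS = tab[["Sum Sq"]], MS = tab[["Mean Sq"]],
    F = c(tab[["F value"]][1:3], NA), p = c(tab[["Pr(>F)"]][1:3], NA),
    stringsAsFactors = FALSE, row.names = NULL)
  # squash numerically-zero partitions (constant responses)
  tol <- 1e-10 * max(stats::var(y), .Machine$double.eps)
  degenerate <- out$MS[4L] <= tol || !is.finite(out$F[1L])
  if (degenerate) {
    zero <- out$SS <= tol
    out$SS[zero] <- 0; out$MS[zero] <- 0
    out$F[1:3] <- ifelse(out$MS[1:3] > 0, Inf, NaN)
    out$p[1:3] <- NaN
    warning("zero within-cell variance: F undefined or infinite",
            call. = FALSE)
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Student-Newman-Keuls stepwise post-hoc test
#'
#' Means are ordered; each pair is compared with the studentized-range
#' statistic \code{q = (m_j - m_i) / sqrt(MSE / n)} against the critical
#' value \code{qtukey(1 - alpha, p, dfError)} for its span \code{p}.
#' Testing proceeds from the widest span inward, and once a span is
#' declared non-significant no pair inside it is tested (they inherit
#' non-significance), which keeps the decisions coherent with the
#' homogeneous-group partition.
#'
#' @param means Named numeric vector of cell means.
#' @param mse Error mean square from the ANOVA.
#' @param dfError Error degrees of freedom (>= 1).
#' @param n Observations per cell (equal cell sizes required).
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @return List with \code{orderedMeans}, \code{decisions} (data.frame
#'   level_1, level_2, span, q, q_crit, significant, tested) and
#'   \code{groups} (list of homogeneous level sets).
#' @export
#' @examples
#' snkPosthoc(c(a = 1, b = 1.2, c = 5), mse = 0.5, dfError = 12, n = 4)
snkPosthoc <- function(means, mse, dfError, n, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) .err("alpha must be in (0, 1)")
  stopifnot(dfError >= 1, n >= 1, mse >= 0)
  k <- length(means)
  if (k < 2L) .err("need at least two means")
  m <- sort(means)
  se <- sqrt(mse / n)
  sig <- matrix(NA, k, k)        # TRUE = significant
  tested <- matrix(FALSE, k, k)
  for (p in k:2) {
    for (i in seq_len(k - p + 1L)) {
      j <- i + p - 1L
      # inherited non-significance from a containing non-significant span
      inherited <- FALSE
      if (p < k) {
        cover <- which(!is.na(sig) & !sig, arr.ind = TRUE)
        if (nrow(cover))
          inherited <- any(cover[, 1L] <= i & cover[, 2L] >= j)
      }
      if (inherited) {
        sig[i, j] <- FALSE
      } else {
        q <- (m[j] - m[i]) / se
        crit <- qtukey(1 - alpha, p, dfError)
        sig[i, j] <- q > crit
        tested[i, j] <- TRUE
      }
    }
  }
  dec <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    p <- j - i + 1L
    q <- (m[j] - m[i]) / se
    dec[[length(dec) + 1L]] <- data.frame(
      level_1 = names(m)[i], level_2 = names(m)[j], span = p, q = q,
      q_crit = qtukey(1 - alpha, p, dfError),
      significant = sig[i, j], tested = tested[i, j],
      stringsAsFactors = FALSE)
  }
  decisions <- do.call(rbind, dec)
  rownames(decisions) <- NULL
  # homogeneous groups: maximal spans of pairwise non-significance
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !isTRUE(sig[i, j + 1L])) j <- j + 1L
    grp <- names(m)[i:j]
    if (!length(groups) ||
        !all(grp %in% groups[[length(groups)]])) groups <- c(groups, list(grp))
  }
  list(orderedMeans = m, decisions = decisions, groups = groups,
       alpha = alpha)
}

#' Normality and variance-homogeneity diagnostics
#'
#' Shapiro-Wilk on the residuals and a mean-centred Levene test across
#' groups.  Residual vectors with no variation are flagged as degenerate
#' (both tests undefined).
#'
#' @param residuals Numeric vector (length >= 3).
#' @param groups Factor of group membership, same length.
#' @return List with \code{shapiro} (W, p), \code{levene} (F, df1, df2,
#'   p) and \code{degenerate}.
#' @export
assumptionChecks <- function(residuals, groups) {
  stopifnot(length(residuals) >= 3L, length(groups) == length(residuals))
  if (stats::var(residuals) == 0) {
    warning("all residuals identical: diagnostics undefined", call. = FALSE)
    return(list(shapiro = list(W = NA_real_, p = NA_real_),
                levene = list(F = NA_real_, df1 = NA_integer_,
                              df2 = NA_integer_, p = NA_real_),
                degenerate = TRUE))
  }
  sw <- shapiro.test(residuals)
  lev <- car::leveneTest(residuals ~ factor(groups), center = mean)
  list(
    shapiro = list(W = unname(sw$statistic), p = sw$p.value),
    levene = list(F = lev[["F value"]][1L], df1 = lev[["Df"]][1L],
                  df2 = lev[["Df"]][2L], p = lev[["Pr(>F)"]][1L]),
    degenerate = FALSE)
}
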