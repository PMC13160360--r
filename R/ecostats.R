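## Catch standardization, diversity, correlation with multiple-testing
## adjustment, and community ANOSIM.

#' Standardize trawl catches by filtered volume
#'
#' Divides counts (and weights) by the volume of water trawled, net mouth
#' area times distance towed, giving densities per m3.
#'
#' @param catch data.frame with one row per station.
#' @param taxaCols names of the columns to standardize.
#' @param areaCol,distCol columns holding net mouth area (m2) and tow
#'   distance (m).
#' @return the data.frame with the taxa columns divided by volume and a
#'   \code{volume_m3} column appended.
#' @export
standardizeCatch <- function(catch, taxaCols,
                             areaCol = "mouth_area_m2",
                             distCol = "tow_distance_m") {
  vol <- catch[[areaCol]] * catch[[distCol]]
  if (any(!is.finite(vol) | vol <= 0))
    stop("trawl volume (mouth area x tow distance) must be positive")
  catch[taxaCols] <- catch[taxaCols] / vol
  catch$volume_m3 <- vol
  catch
}

#' Shannon-Wiener diversity index
#'
#' H' = -sum p log p with natural logarithms; zero-count taxa contribute 0.
#'
#' @param counts non-negative abundance vector with positive sum.
#' @return H' (>= 0).
#' @export
shannonIndex <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("all-zero abundance vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Simpson diversity index (1 - D)
#'
#' Reported as 1 - sum p^2 (the probability that two random individuals
#' belong to different taxa); the complement \code{sum(p^2)} form is
#' available via \code{complement = FALSE}.
#'
#' @param counts non-negative abundance vector with positive sum.
#' @param complement return 1 - D (default) rather than D.
#' @return Simpson index in [0, 1).
#' @export
simpsonIndex <- function(counts, complement = TRUE) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("all-zero abundance vector")
  D <- sum((counts / tot)^2)
  if (complement) 1 - D else D
}

#' Per-station diversity table
#'
#' Shannon-Wiener and Simpson indices per station, optionally excluding a
#' pooled taxon (e.g. a mixed-mesozooplankton fraction enumerated only by
#' biomass) from the index computation while leaving it in the data.
#'
#' @param catch standardized catch data.frame.
#' @param taxaCols taxon column names.
#' @param exclude taxon columns to drop from the index computation.
#' @param stationCol station id column (default "station").
#' @return data.frame: station, shannon, simpson.
#' @export
diversityTable <- function(catch, taxaCols, exclude = NULL,
                           stationCol = "station") {
  use <- setdiff(taxaCols, exclude)
  data.frame(
    station = catch[[stationCol]],
    shannon = apply(catch[use], 1, shannonIndex),
    simpson = apply(catch[use], 1, simpsonIndex))
}

#' Kendall rank correlation (tau-b)
#'
#' Tau-b with tie correction via \code{stats::cor.test}. The p-value uses
#' the exact null distribution when \code{method = "exact"} (untied data,
#' feasible for small n, equivalent to exhaustive permutation) and the
#' normal approximation otherwise; \code{"auto"} picks exact for untied
#' n <= 8.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @param method "auto", "normal" or "exact".
#' @return list: tau, p, method. A constant vector leaves tau undefined
#'   (NA, with a warning).
#' @export
kendallTau <- function(x, y, method = c("auto", "normal", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least three observations required")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: tau undefined")
    return(list(tau = NA_real_, p = NA_real_, method = method))
  }
  ties <- anyDuplicated(x) || anyDuplicated(y)
  useExact <- switch(method, exact = TRUE, normal = FALSE,
                     auto = !ties && length(x) <= 8)
  if (useExact && ties) {
    warning("ties present: falling back to the normal approximation")
    useExact <- FALSE
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = useExact))
  list(tau = unname(ct$estimate), p = ct$p.value,
       method = if (useExact) "exact" else "normal")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment of p-values (returned in input order),
#' via \code{stats::p.adjust(method = "BH")}.
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bray-Curtis distances on square-root relative abundance
#'
#' Rows are converted to relative abundance, square-root transformed (to
#' down-weight the few dominant taxa), and pairwise Bray-Curtis
#' dissimilarities BC = sum|xi - xj| / sum(xi + xj) are computed.
#'
#' @param mat station x taxon abundance matrix (>= 2 stations, no
#'   zero-sum rows).
#' @return a \code{dist} object.
#' @export
brayCurtis <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("at least two stations required")
  rs <- rowSums(mat)
  if (any(rs <= 0)) stop("zero-sum station row")
  vegan::vegdist(sqrt(mat / rs), method = "bray")
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's R statistic on ranked pairwise dissimilarities:
#' R = (mean between-group rank - mean within-group rank) / (M/2) with
#' M = n(n-1)/2 and average ranks for ties. Significance by seeded label
#' permutation: p = (1 + #[permuted R >= observed R]) / (1 + nPerm).
#'
#' @param d a \code{dist} object (e.g. from \code{\link{brayCurtis}}).
#' @param groups grouping factor, >= 2 groups with >= 2 members each.
#' @param nPerm number of permutations (default 999); ignored when
#'   \code{exact}.
#' @param seed optional integer seed for the permutation stream.
#' @param exact enumerate all label permutations (feasible for n <= 8)
#'   instead of sampling; p = #\[R_perm >= R_obs\] / n! (the identity
#'   permutation is part of the enumeration).
#' @return list: statistic (R), p, nPerm, perm (the permuted R values).
#' @export
anosim <- function(d, groups, nPerm = 999, seed = NULL, exact = FALSE) {
  groups <- as.factor(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups must match the distance matrix size")
  if (nlevels(droplevels(groups)) < 2) stop("at least two groups required")
  if (any(table(groups) < 2)) stop("every group needs at least two members")
  rk <- rank(as.vector(d))
  M <- n * (n - 1) / 2
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE) # col-major: matches dist order
  statR <- function(g) {
    within <- g[ij[, 1]] == g[ij[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  obs <- statR(groups)
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- .permutations(n)
    perm <- apply(perms, 1, function(idx) statR(groups[idx]))
    return(list(statistic = obs, p = sum(perm >= obs - 1e-12) / nrow(perms),
                nPerm = nrow(perms), perm = perm))
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(nPerm), function(i) statR(sample(groups)), numeric(1))
  list(statistic = obs, p = (1 + sum(perm >= obs)) / (1 + nPerm),
       nPerm = nPerm, perm = perm)
}

## all permutations of 1..n as an n! x n index matrix
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Kendall correlation table with BH adjustment
#'
#' Pairwise Kendall tau between each response and each covariate,
#' with a single Benjamini-Hochberg adjustment across all tests; the
#' layout of a frontal NASC correlation table (abundance series against
#' latitude, frontal distances, temperature and salinity).
#'
#' @param df data.frame holding all columns.
#' @param responses response column names (e.g. NASC series).
#' @param covariates covariate column names.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame: response, covariate, n, tau, p, p_adj, significant.
#' @export
correlationTable <- function(df, responses, covariates, alpha = 0.05) {
  rows <- expand.grid(response = responses, covariate = covariates,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    x <- df[[rows$response[i]]]; y <- df[[rows$covariate[i]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2)
      return(c(n = sum(ok), tau = NA_real_, p = NA_real_))
    kt <- kendallTau(x[ok], y[ok], method = "normal")
    c(n = sum(ok), tau = kt$tau, p = kt$p)
  })
  res <- do.call(rbind, res)
  out <- cbind(rows, as.data.frame(res))
  out$p_adj <- bhAdjust(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}
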