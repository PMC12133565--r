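## Count normalization (median-of-ratios size factors, variance
## stabilization), PCA summary, negative-binomial Wald testing with
## Benjamini-Hochberg correction and threshold-based calling.

.getCountsGroups <- function(x, group = NULL) {
  if (is(x, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(x, "counts")
    if (is.null(group)) group <- SummarizedExperiment::colData(x)$group
  } else counts <- x
  list(counts = as.matrix(counts),
       group = if (is.null(group)) NULL else as.character(group))
}

#' Median-of-ratios size factors
#'
#' For every feature with all-positive counts, each sample's count is
#' divided by the feature's geometric mean across samples; a sample's size
#' factor is the median of these ratios, rescaled so the factors have
#' geometric mean 1.
#'
#' @param counts Integer feature x sample matrix, or a
#'   `SummarizedExperiment` with a `"counts"` assay.
#' @return Named numeric vector of per-sample size factors.
#' @export
medianOfRatios <- function(counts) {
  counts <- .getCountsGroups(counts)$counts
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has positive counts in every sample; ",
         "consider adding a pseudocount", call. = FALSE)
  lx <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lx)
  f <- apply(exp(lx - geo), 2, stats::median)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Variance-stabilizing transformation of counts
#'
#' Two monotone transforms of size-factor-normalized counts `x/s`:
#' `log2p1` is `log2(x/s + 1)`; `asinh_nb` is
#' `(2 / sqrt(a)) * asinh(sqrt(a * x/s))` with `a` a common moment-based
#' negative-binomial dispersion (the classical variance-stabilizer for
#' NB counts, linear in `log(x)` for large `x`). Both map 0 to 0.
#'
#' @param counts Integer matrix or `SummarizedExperiment`.
#' @param sizeFactors Per-sample positive factors; estimated by
#'   [medianOfRatios()] when `NULL`.
#' @param method `"log2p1"` (default) or `"asinh_nb"`.
#' @return A [NormalizedCounts-class].
#' @export
vstNormalize <- function(counts, sizeFactors = NULL,
                         method = c("log2p1", "asinh_nb")) {
  method <- match.arg(method)
  counts <- .getCountsGroups(counts)$counts
  if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(counts)
  if (any(sizeFactors <= 0)) stop("size factors must be positive",
                                  call. = FALSE)
  norm <- sweep(counts, 2, sizeFactors, "/")
  disp <- NA_real_
  if (method == "log2p1") {
    y <- log2(norm + 1)
  } else {
    mu <- rowMeans(norm)
    v <- apply(norm, 1, stats::var)
    a <- (v - mu) / mu^2
    a <- a[is.finite(a) & a > 0]
    disp <- if (length(a)) stats::median(a) else 1e-8
    disp <- max(disp, 1e-8)
    y <- (2 / sqrt(disp)) * asinh(sqrt(disp * norm))
  }
  dimnames(y) <- dimnames(counts)
  new("NormalizedCounts", values = y, sizeFactors = sizeFactors,
      method = method, dispersion = disp)
}

#' PCA embedding of samples
#'
#' Samples are embedded by SVD of the feature-centered matrix. The sign of
#' each component is fixed so its largest-magnitude feature loading is
#' positive. Variance-explained fractions are eigenvalues over the total
#' variance (all components), so the reported fractions sum to <= 1.
#'
#' @param x A [NormalizedCounts-class] or numeric feature x sample matrix.
#' @param nComponents Number of components (default 2).
#' @return List with `coordinates` (samples x components),
#'   `varianceExplained` (length `nComponents`) and `loadings`.
#' @export
pcaEmbed <- function(x, nComponents = 2L) {
  m <- if (is(x, "NormalizedCounts")) normValues(x) else as.matrix(x)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (ncol(m) < nComponents)
    stop("fewer samples than requested components", call. = FALSE)
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- seq_len(nComponents)
  rot <- pc$rotation[, k, drop = FALSE]
  sc <- pc$x[, k, drop = FALSE]
  for (j in k) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
  }
  total <- sum(pc$sdev^2)
  list(coordinates = sc,
       varianceExplained = pc$sdev[k]^2 / total,
       loadings = rot)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the p-values ascending, takes `q_i = min_{j >= i} p_j * m / j`
#' capped at 1, and returns the adjusted values in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Negative-binomial Wald test for a two-group design
#'
#' Per feature, counts are size-factor normalized and the two group means
#' compared on the log2 scale: `lfc = log2((muB + c) / (muA + c))` with
#' pseudocount `c`. A moment estimate of the NB dispersion is pooled
#' across the two groups, `a = ((varA - muA) + (varB - muB)) /
#' (muA^2 + muB^2)`, floored at 1e-8 and inflated by `n / (n - 2)` to
#' offset its small-sample bias. The delta-method standard error of the
#' lfc uses the NB variance `mu + a mu^2`, and the Wald statistic is
#' referred to a t distribution with `n - 2` degrees of freedom (which
#' keeps the test calibrated at the replicate numbers this pipeline
#' targets). Adjusted p-values are Benjamini-Hochberg.
#'
#' @param counts Integer matrix or `SummarizedExperiment` (with
#'   `colData()$group`).
#' @param group Per-sample labels with exactly two levels; the second
#'   level (alphabetical, or factor order) is the numerator of the fold
#'   change.
#' @param sizeFactors Optional per-sample factors; [medianOfRatios()] when
#'   `NULL`.
#' @param pseudocount Pseudocount `c` in the fold change (default 0.5).
#' @param alpha,lfcMin Calling thresholds applied to `p_adj` and `lfc`
#'   (defaults 0.05 and 1).
#' @return data.frame with columns `feature_id`, `base_mean`, `lfc`, `se`,
#'   `p_raw`, `p_adj`, `call` (`"up"`, `"down"`, `"ns"`).
#' @export
nbWaldTest <- function(counts, group = NULL, sizeFactors = NULL,
                       pseudocount = 0.5, alpha = 0.05, lfcMin = 1) {
  cg <- .getCountsGroups(counts, group)
  counts <- cg$counts; group <- cg$group
  if (is.null(group)) stop("group labels required", call. = FALSE)
  lev <- if (is.factor(group)) levels(factor(group)) else sort(unique(group))
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  iA <- which(group == lev[1]); iB <- which(group == lev[2])
  if (length(iA) < 2L || length(iB) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  if (any(colSums(counts) == 0))
    stop("sample with all-zero library: ",
         colnames(counts)[which(colSums(counts) == 0)[1]], call. = FALSE)
  if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(counts)
  norm <- sweep(counts, 2, sizeFactors, "/")
  nA <- length(iA); nB <- length(iB); n <- nA + nB
  mA <- rowMeans(norm[, iA, drop = FALSE])
  mB <- rowMeans(norm[, iB, drop = FALSE])
  vA <- apply(norm[, iA, drop = FALSE], 1, stats::var)
  vB <- apply(norm[, iB, drop = FALSE], 1, stats::var)
  disp <- ((vA - mA) + (vB - mB)) / (mA^2 + mB^2)
  disp[!is.finite(disp)] <- 0
  disp <- pmax(disp, 1e-8) * n / (n - 2)
  c0 <- pseudocount
  lfc <- log2((mB + c0) / (mA + c0))
  varA <- (mA + disp * mA^2) / nA
  varB <- (mB + disp * mB^2) / nB
  se <- sqrt(varA / (mA + c0)^2 + varB / (mB + c0)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(z), df = n - 2)
  padj <- bhAdjust(p)
  res <- data.frame(
    feature_id = if (!is.null(rownames(counts))) rownames(counts) else
      sprintf("feature_%d", seq_len(nrow(counts))),
    base_mean = rowMeans(norm), lfc = lfc, se = se,
    p_raw = p, p_adj = padj, stringsAsFactors = FALSE)
  res$call <- with(res, ifelse(p_adj < alpha & lfc >= lfcMin, "up",
                        ifelse(p_adj < alpha & lfc <= -lfcMin, "down", "ns")))
  rownames(res) <- NULL
  res
}

#' Threshold-based differential calls
#'
#' `up` features have `p_adj < alpha` and `lfc >= lfcMin`; `down` is
#' symmetric with `lfc <= -lfcMin`.
#'
#' @param records data.frame from [nbWaldTest()] (needs `feature_id`,
#'   `lfc`, `p_adj`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfcMin Minimum absolute log2 fold change (default 1).
#' @return List with character vectors `up` and `down`.
#' @export
callDifferential <- function(records, alpha = 0.05, lfcMin = 1) {
  stopifnot(all(c("feature_id", "lfc", "p_adj") %in% names(records)))
  list(up = records$feature_id[records$p_adj < alpha &
                                 records$lfc >= lfcMin],
       down = records$feature_id[records$p_adj < alpha &
                                   records$lfc <= -lfcMin])
}
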