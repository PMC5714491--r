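#' Primer amplification efficiency from a dilution series
#'
#' Fits the standard curve CP ~ log10(relative concentration) by least
#' squares and converts the slope `m` to the per-cycle amplification factor
#' `E = 10^(-1/m)`.  A perfect doubling assay has slope `-1/log10(2)` =
#' -3.32 and `E = 2`.
#'
#' @param concentration Relative template concentrations (e.g. `1, 1/4,
#'   1/8, 1/16, 1/32`); at least three distinct positive values, replicates
#'   allowed.
#' @param cp Crossing-point (threshold-crossing) cycles, one per
#'   concentration entry.
#' @return A list: `E`, `slope`, `r.squared`.
#' @examples
#' primerEfficiency(c(1, 0.25, 0.0625), c(20, 22, 24))$E   # exactly 2
#' @export
primerEfficiency <- function(concentration, cp) {
    if (length(concentration) != length(cp))
        stop("concentration and cp must have equal length")
    if (any(concentration <= 0))
        stop("concentrations must be strictly positive")
    if (length(unique(concentration)) < 3L)
        stop("at least three distinct concentrations are required")
    x <- log10(concentration)
    fit <- stats::lm(cp ~ x)
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || abs(slope) < 1e-9)
        stop("fit error: standard-curve slope is zero (flat CP series)")
    r2 <- if (stats::var(cp) > 0)
        suppressWarnings(summary(fit)$r.squared) else 1
    list(E = 10^(-1 / slope), slope = slope, r.squared = r2)
}

#' Efficiency-corrected relative expression
#'
#' Computes the reference-normalized expression of a target gene as
#' `E_ref^CP_ref / E_target^CP_target`, the efficiency-corrected ratio
#' (higher CP of the target means lower expression).  Replicate CP values
#' are averaged before the formula; when replicates are supplied, a
#' first-order (delta-method) standard error of the ratio is attached as
#' attribute `"se"`.
#'
#' @param eRef,eTarget Amplification efficiencies of the reference and
#'   target assays, each in (1, 2.2].
#' @param cpRef,cpTarget CP values (replicate vectors allowed).
#' @return Numeric expression ratio, with attribute `se` when both CP
#'   arguments carry more than one replicate.
#' @examples
#' relativeExpression(2, 20, 2, 22)   # 0.25
#' @export
relativeExpression <- function(eRef, cpRef, eTarget, cpTarget) {
    for (E in c(eRef, eTarget))
        if (!is.finite(E) || E <= 1 || E > 2.2)
            stop("efficiency must lie in (1, 2.2]")
    if (any(c(cpRef, cpTarget) <= 0))
        stop("CP values must be positive")
    mRef <- mean(cpRef); mTar <- mean(cpTarget)
    ratio <- eRef^mRef / eTarget^mTar
    if (length(cpRef) > 1L && length(cpTarget) > 1L) {
        vRef <- stats::var(cpRef) / length(cpRef)
        vTar <- stats::var(cpTarget) / length(cpTarget)
        se <- ratio * sqrt(log(eRef)^2 * vRef + log(eTarget)^2 * vTar)
        attr(ratio, "se") <- se
    }
    ratio
}

#' Knockdown fraction of a transgenic line relative to wild type
#'
#' @param transgenicRel Relative expression in the transgenic line.
#' @param wildtypeRel Relative expression in the wild type (positive).
#' @return `1 - transgenicRel/wildtypeRel`; negative values indicate
#'   upregulation.
#' @examples
#' knockdownFraction(0.2, 1)   # 80 percent knockdown
#' @export
knockdownFraction <- function(transgenicRel, wildtypeRel) {
    if (any(wildtypeRel <= 0))
        stop("usage error: wild-type relative expression must be positive")
    1 - transgenicRel / wildtypeRel
}

#' Chi-square goodness of fit of observed counts to a Mendelian ratio
#'
#' Pearson goodness-of-fit of phenotype class counts against an expected
#' integer ratio (default 1:2:1, the single-locus F2 expectation), with
#' `df = classes - 1`.
#'
#' @param observed Non-negative integer counts per class (at least two
#'   classes, positive total).
#' @param ratio Expected ratio (positive in every class).
#' @return A list: `statistic`, `df`, `p.value`, `expected`.
#' @examples
#' segregationTest(c(112, 235, 98))   # consistent with 1:2:1
#' @export
segregationTest <- function(observed, ratio = c(1, 2, 1)) {
    if (length(observed) < 2L)
        stop("at least two phenotype classes are required")
    if (length(ratio) != length(observed))
        stop("config error: ratio and observed lengths differ")
    if (any(ratio <= 0))
        stop("config error: expected ratio must be positive in every class")
    if (any(observed < 0) || sum(observed) <= 0)
        stop("counts must be non-negative with a positive total")
    p <- ratio / sum(ratio)
    ht <- suppressWarnings(stats::chisq.test(observed, p = p))
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, expected = unname(ht$expected))
}
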