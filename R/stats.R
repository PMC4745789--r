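## Statistical primitives with fully specified behavior: Fisher's exact
## test reporting the sample odds ratio, Welch's t test, and the
## Mann-Whitney U test with an exact small-sample path. Results are
## base-R "htest" lists so they print like stats:: tests.

#' Fisher's exact test for a 2x2 table (sample odds ratio)
#'
#' Two-sided p-value by summation of hypergeometric point probabilities no
#' larger than that of the observed table (fixed margins), the same
#' convention as `stats::fisher.test`. Unlike `fisher.test`, the reported
#' odds ratio is the sample (cross-product) estimate `(a*d)/(b*c)`, not the
#' conditional MLE: `Inf` when `b*c == 0` and `a*d > 0`, 0 when `a*d == 0`
#' and `b*c > 0`, `NaN` when both products are 0.
#'
#' @param table A 2x2 matrix of nonnegative counts `[[a, b], [c, d]]`
#'   (rows = region class, columns = feature present/absent), or the count
#'   `a` with `b`, `c`, `d` supplied separately.
#' @param b,c,d Optional scalar counts when `table` is given as `a`.
#' @return An object of class `"htest"` with `estimate` (sample odds
#'   ratio) and `p.value`.
#' @examples
#' fisherExact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # p = 34/70
#' @export
fisherExact <- function(table, b = NULL, c = NULL, d = NULL) {
    if (is.matrix(table)) {
        stopifnot(identical(dim(table), c(2L, 2L)))
        a <- table[1, 1]; bb <- table[1, 2]
        cc <- table[2, 1]; dd <- table[2, 2]
    } else {
        a <- table; bb <- b; cc <- c; dd <- d
    }
    counts <- c(a, bb, cc, dd)
    if (any(is.na(counts)) || any(counts < 0) ||
        any(counts != floor(counts)))
        stop("counts must be nonnegative integers")
    n <- sum(counts)
    if (n == 0) stop("table total must be positive")
    r1 <- a + bb; c1 <- a + cc
    lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
    supp <- lo:hi
    pr <- dhyper(supp, c1, n - c1, r1)
    p <- min(1, sum(pr[pr <= pr[a - lo + 1] * (1 + 1e-7)]))
    or <- if (a * dd == 0 && bb * cc == 0) NaN
          else if (bb * cc == 0) Inf
          else (a * dd) / (bb * cc)
    structure(list(
        statistic = NULL,
        estimate = c(`sample odds ratio` = or),
        p.value = p,
        method = "Fisher's exact test for a 2x2 table (sample odds ratio)",
        data.name = sprintf("[[%d, %d], [%d, %d]]", a, bb, cc, dd),
        table = matrix(counts, 2, 2, byrow = TRUE)
    ), class = "htest")
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Requires at least two observations per sample
#' and positive variance in at least one sample.
#'
#' @param x,y Numeric samples.
#' @return An object of class `"htest"` with `statistic` (t), `parameter`
#'   (df), `p.value` and per-group `estimate` (means).
#' @export
welchT <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
        stop("welchT needs at least 2 observations per sample")
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx == 0 && vy == 0)
        stop("welchT needs positive variance in at least one sample")
    nx <- length(x); ny <- length(y)
    se2x <- vx / nx; se2y <- vy / ny
    tstat <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 /
        (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
    p <- 2 * pt(-abs(tstat), df)
    structure(list(
        statistic = c(t = tstat),
        parameter = c(df = df),
        p.value = p,
        estimate = c(`mean of x` = mean(x), `mean of y` = mean(y)),
        method = "Welch two-sample t-test (two-sided)",
        data.name = "x and y"
    ), class = "htest")
}

## U distribution (counts of each achievable U) by exhaustive enumeration of
## all C(nx+ny, nx) labelings of the pooled sample; used on the exact path.
.mwExactDistribution <- function(pooled, nx) {
    idx <- combn(length(pooled), nx)
    apply(idx, 2L, function(ii) {
        xs <- pooled[ii]; ys <- pooled[-ii]
        sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    })
}

#' Mann-Whitney U test
#'
#' U statistic for `x` versus `y` with 0.5 credit for ties. The p-value is
#' exact -- by enumeration of all `choose(nx+ny, nx)` labelings -- when
#' `nx + ny <= 16` and the data contain no ties; otherwise it uses the
#' normal approximation with continuity and tie correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger
#'   than y) or `"less"`.
#' @return An object of class `"htest"` with `statistic` (U for `x`),
#'   `p.value`, and `method` naming the exact or approximate path.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))$p.value  # exact: 2/20 = 0.1
#' @export
mannWhitney <- function(x, y,
                        alternative = c("two.sided", "greater", "less")) {
    alternative <- match.arg(alternative)
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y))
        stop("mannWhitney needs non-empty samples")
    nx <- length(x); ny <- length(y)
    u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    pooled <- c(x, y)
    ties <- anyDuplicated(pooled) > 0L
    exact <- (nx + ny) <= 16L && !ties
    if (exact) {
        dist <- .mwExactDistribution(pooled, nx)
        m <- length(dist)
        p <- switch(alternative,
            greater = sum(dist >= u) / m,
            less = sum(dist <= u) / m,
            two.sided = min(1, 2 * min(sum(dist <= u), sum(dist >= u)) / m))
        method <- "Mann-Whitney U test (exact, labeling enumeration)"
    } else {
        nn <- nx + ny
        mu <- nx * ny / 2
        tie_tab <- table(pooled)
        tie_term <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
        sigma2 <- nx * ny / 12 * ((nn + 1) - tie_term)
        if (sigma2 <= 0) {
            p <- 1
        } else {
            sigma <- sqrt(sigma2)
            p <- switch(alternative,
                greater = pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
                less = pnorm((u - mu + 0.5) / sigma),
                two.sided = min(1, 2 * pnorm(
                    (abs(u - mu) - 0.5) / sigma, lower.tail = FALSE)))
            p <- min(1, max(0, p))
        }
        method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
    }
    structure(list(
        statistic = c(U = u),
        p.value = p,
        alternative = alternative,
        method = method,
        data.name = "x and y",
        estimate = c(`median of x` = median(x), `median of y` = median(y))
    ), class = "htest")
}
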