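# Inferential toolbox: exact two-sample Mann-Whitney, Spearman/Pearson
# correlation, circular summaries, grouped mean +/- SD.
#
# Per-embryo mean angles are compared with the exact Mann-Whitney test: at
# the sample sizes typical of embryo cohorts (3-10 per group) the normal
# approximation is unreliable and the printed p-values of such studies are
# exact-enumeration values, so the exact null distribution is computed by
# the classic count recursion whenever there are no ties and both samples
# are small enough.

# cache of exact null CDFs keyed by "n1,n2"
.mw_cache <- new.env(parent = emptyenv())

# Counts of the Mann-Whitney U statistic under the null, u = 0..n1*n2,
# via the recursion N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
mw_null_counts <- function(n1, n2) {
  key <- paste0("c", n1, ",", n2)
  if (!is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
  rec <- function(m, n) {
    if (m == 0 || n == 0) return(1)
    k <- paste0("c", m, ",", n)
    hit <- .mw_cache[[k]]
    if (!is.null(hit)) return(hit)
    a <- rec(m - 1, n)           # length (m-1)*n + 1
    b <- rec(m, n - 1)           # length m*(n-1) + 1
    out <- numeric(m * n + 1)
    out[seq_along(a) + n] <- a
    out[seq_along(b)] <- out[seq_along(b)] + b
    assign(k, out, envir = .mw_cache)
    out
  }
  rec(n1, n2)
}

# Exact null CDF P(U <= u) for u = 0..n1*n2 (vector indexed u + 1).
mw_null_cdf <- function(n1, n2) {
  key <- paste0("F", n1, ",", n2)
  if (!is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
  counts <- mw_null_counts(n1, n2)
  cdf <- cumsum(counts) / sum(counts)
  assign(key, cdf, envir = .mw_cache)
  cdf
}

#' Two-sample Mann-Whitney test with exact small-sample p-values
#'
#' Computes the Mann-Whitney rank-sum statistic `U` for the first sample and
#' a two-sided p-value. When there are no ties and both samples have at most
#' `exact_threshold` observations, the p-value is exact: the full null
#' distribution of `U` is computed by the count recursion and the two-sided
#' p-value is twice the smaller tail probability, capped at 1. Otherwise the
#' normal approximation with continuity and tie correction is used.
#'
#' With completely separated samples the exact two-sided p-value equals
#' `2 / choose(n1 + n2, n1)`, the smallest value attainable at those sizes.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_threshold use the exact enumeration when
#'   `max(n1, n2) <= exact_threshold` and there are no ties. Default 20,
#'   which covers per-embryo comparisons.
#' @return an object of class `mw_test`: a list with elements `U`, `n1`,
#'   `n2`, `p_two_sided`, `method` (`"exact"` or `"normal_approx"`) and
#'   `tie_corrected`.
#' @examples
#' mann_whitney(1:5, 6:10)   # complete separation: p = 2 / choose(10, 5)
#' @export
mann_whitney <- function(x, y, exact_threshold = 20) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("samples must be finite", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && max(n1, n2) <= exact_threshold) {
    cdf <- mw_null_cdf(n1, n2)
    ui <- as.integer(round(u))
    p_lo <- cdf[ui + 1L]
    p_hi <- if (ui >= 1L) 1 - cdf[ui] else 1
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    nn <- n1 + n2
    mu <- n1 * n2 / 2
    tab <- table(c(x, y))
    sig2 <- n1 * n2 / 12 * ((nn + 1) - sum(tab^3 - tab) / (nn * (nn - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(
    list(U = u, n1 = n1, n2 = n2, p_two_sided = p,
         method = method, tie_corrected = ties && method == "normal_approx"),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Two-sample Mann-Whitney (%s%s)\n", x$method,
              if (isTRUE(x$tie_corrected)) ", tie-corrected" else ""))
  cat(sprintf("  U = %g, n1 = %d, n2 = %d, two-sided p = %.6g\n",
              x$U, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

# All permutations of 1..n as an n! x n matrix (deterministic order).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(rep.int(k, nrow(p)), p + (p >= k))
  }))
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' The coefficient is Pearson's correlation of the average-rank transforms.
#' For `n <= exact_threshold` with no ties, the two-sided p-value is exact:
#' all `n!` permutations of one rank vector are enumerated and the p-value
#' is the fraction with `|rho|` at least as large as observed. Otherwise the
#' t-approximation with `n - 2` degrees of freedom is used.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @param exact_threshold largest `n` for exact permutation enumeration
#'   (default 9).
#' @return list with `spearman_rho`, `p_two_sided`, `method`, `n`.
#' @export
spearman_cor <- function(x, y, exact_threshold = 9) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("samples must be finite", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero rank variance: correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (!ties && n <= exact_threshold) {
    perms <- all_permutations(n)
    # rho for ranks 1..n against a permutation sigma:
    # rho = 12 * sum(rx * sigma) / (n (n^2 - 1)) - 3 (n + 1) / (n - 1)
    s <- as.vector(perms %*% rx)
    rho_all <- 12 * s / (n * (n^2 - 1)) - 3 * (n + 1) / (n - 1)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- .Machine$double.xmin
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
    }
    method <- "t_approx"
  }
  list(spearman_rho = rho, p_two_sided = p, method = method, n = n)
}

#' Pearson correlation and coefficient of determination
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, each with nonzero
#'   variance.
#' @return list with `pearson_r`, `r_squared`, `p_two_sided` (t-test against
#'   r = 0) and `n`.
#' @export
pearson_r2 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
  }
  list(pearson_r = r, r_squared = r^2, p_two_sided = p, n = n)
}

#' Circular mean of angles
#'
#' Angles are mapped to unit vectors (after rescaling by `360 / period` so
#' that axial data with period 180 can be averaged), averaged, and mapped
#' back. The resultant length measures concentration (1 = all identical).
#'
#' @param angles numeric vector of angles in degrees.
#' @param period 360 for directed angles, 180 for axes.
#' @return list with `circular_mean` (degrees, in `(-period/2, period/2]`),
#'   `resultant_length` and `n`.
#' @export
circular_mean <- function(angles, period = 360) {
  if (length(angles) < 1) stop("need at least one angle", call. = FALSE)
  if (!period %in% c(180, 360)) stop("period must be 180 or 360", call. = FALSE)
  k <- 360 / period
  t <- angles * k * pi / 180
  zx <- mean(cos(t)); zy <- mean(sin(t))
  r <- sqrt(zx^2 + zy^2)
  m <- atan2(zy, zx) * 180 / pi / k
  m <- (m + period / 2) %% period - period / 2
  if (m == -period / 2) m <- period / 2
  list(circular_mean = m, resultant_length = r, n = length(angles))
}

#' Mean and sample SD by group
#'
#' Reports arithmetic mean and sample standard deviation (n - 1 denominator)
#' for each group; groups with a single observation get `NA` SD and a flag.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return data.frame with columns `group`, `n`, `mean`, `sd`,
#'   `sd_undefined`.
#' @export
group_summary <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  g <- split(as.numeric(values), groups)
  out <- data.frame(
    group = names(g),
    n = vapply(g, length, integer(1)),
    mean = vapply(g, mean, numeric(1)),
    sd = vapply(g, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                numeric(1)),
    stringsAsFactors = FALSE
  )
  out$sd_undefined <- out$n < 2
  rownames(out) <- NULL
  out
}
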