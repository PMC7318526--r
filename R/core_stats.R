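#' Spearman rank correlation with the t-approximation p-value
#'
#' Computes the Spearman correlation of two numeric vectors on pairwise-complete
#' observations, with average ranks for ties, and a two-sided p-value from the
#' t-approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees
#' of freedom. This is the single p-value convention used throughout the
#' package: every reported p-value can be regenerated from its coefficient and
#' `n_used` via [spearman_p_from_rho()].
#'
#' Undefined tests (fewer than 3 complete pairs, or either rank vector
#' constant) return a row with `NA` coefficient and p-value rather than an
#' error, so that callers can log and exclude them from FDR families.
#'
#' @param x,y Numeric vectors of equal length; `NA` allowed.
#' @return A one-row tibble with columns `coefficient`, `p_value`, `n_used`
#'   and `method`.
#' @examples
#' spearman_cor(1:10, exp(1:10))   # rho = 1 under a monotone transform
#' @seealso [pearson_cor()], [spearman_p_from_rho()]
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("`x` and `y` must have equal length.", class = "methylscreen_validation_error")
  }
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) {
    return(cor_result(NA_real_, NA_real_, n, "spearman"))
  }
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(cor_result(NA_real_, NA_real_, n, "spearman"))
  }
  rho <- stats::cor(rx, ry)
  cor_result(rho, spearman_p_from_rho(rho, n), n, "spearman")
}

#' Pearson correlation with the t-approximation p-value
#'
#' Product-moment correlation on pairwise-complete observations with a
#' two-sided p-value on \eqn{n-2} degrees of freedom. Used for
#' expression-response associations, where the measurements are already on a
#' log2 scale.
#'
#' @inheritParams spearman_cor
#' @return A one-row tibble with columns `coefficient`, `p_value`, `n_used`
#'   and `method`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("`x` and `y` must have equal length.", class = "methylscreen_validation_error")
  }
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) {
    return(cor_result(NA_real_, NA_real_, n, "pearson"))
  }
  xs <- x[ok]
  ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(cor_result(NA_real_, NA_real_, n, "pearson"))
  }
  r <- stats::cor(xs, ys)
  cor_result(r, spearman_p_from_rho(r, n), n, "pearson")
}

cor_result <- function(coefficient, p_value, n_used, method) {
  tibble::tibble(
    coefficient = coefficient,
    p_value = p_value,
    n_used = as.integer(n_used),
    method = method
  )
}

#' Two-sided p-value for a correlation coefficient under the t-approximation
#'
#' Converts a correlation coefficient at sample size `n` into a two-sided
#' p-value via \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} with \eqn{n-2} degrees
#' of freedom. P-values are floored at the smallest representable positive
#' double so that \eqn{-\log_{10} p} stays finite; a coefficient at or beyond
#' the \eqn{|\rho| = 1} boundary returns that floor.
#'
#' @param rho Correlation coefficient(s) in `[-1, 1]`; vectorized.
#' @param n Number of complete pairs (scalar or vector, recycled); must be
#'   at least 3.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' spearman_p_from_rho(0.6927, 66)   # ~1.16e-10
#' @export
spearman_p_from_rho <- function(rho, n) {
  if (any(!is.finite(n)) || any(n < 3)) {
    rlang::abort("`n` must be finite and >= 3.", class = "methylscreen_validation_error")
  }
  p <- rep(.Machine$double.xmin, length(rho))
  inside <- is.finite(rho) & abs(rho) < 1
  if (any(inside)) {
    nn <- rep_len(n, length(rho))[inside]
    r <- rho[inside]
    tval <- r * sqrt((nn - 2) / (1 - r^2))
    p[inside] <- 2 * stats::pt(abs(tval), df = nn - 2, lower.tail = FALSE)
  }
  p[is.na(rho)] <- NA_real_
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Smallest coefficient magnitude significant at a given alpha
#'
#' Finds the smallest \eqn{|\rho|} whose two-sided t-approximation p-value at
#' sample size `n` falls below `alpha`, by root-finding to high precision. At
#' `n = 66` this reproduces the operating points of the fixed probe
#' thresholds: `critical_rho(66, 9.42e-8)` is just above 0.6 and
#' `critical_rho(66, 5e-7)` just above 0.57.
#'
#' @param n Number of complete pairs, at least 4.
#' @param alpha Two-sided significance level in `(0, 1]`.
#' @return The critical coefficient magnitude, a scalar in `[0, 1)`.
#' @export
critical_rho <- function(n, alpha) {
  stopifnot(length(n) == 1L, length(alpha) == 1L)
  if (!is.finite(n) || n < 4) {
    rlang::abort("`n` must be >= 4.", class = "methylscreen_validation_error")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    rlang::abort("`alpha` must be in (0, 1].", class = "methylscreen_validation_error")
  }
  if (alpha >= 1) {
    return(0)
  }
  f <- function(r) spearman_p_from_rho(r, n) - alpha
  lo <- 1e-12
  hi <- 1 - 1e-12
  if (f(hi) > 0) {
    # alpha below the floor p-value: no attainable rho, return the boundary
    return(1)
  }
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-8)$root
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values for one declared test family. The family must
#' already have undefined-test placeholders removed: all inputs are required
#' to lie in `(0, 1]`. Delegates to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return A tibble with columns `raw` and `adjusted` (same order as the
#'   input) and attribute `family_size` equal to the input length.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))$adjusted  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) {
    out <- tibble::tibble(raw = numeric(), adjusted = numeric())
    attr(out, "family_size") <- 0L
    return(out)
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    rlang::abort("All p-values must be finite and in (0, 1].",
      class = "methylscreen_validation_error"
    )
  }
  out <- tibble::tibble(raw = p, adjusted = stats::p.adjust(p, method = "BH"))
  attr(out, "family_size") <- length(p)
  out
}

# Vectorized correlation of feature rows against response rows.
# X: features x samples, Y: agents x samples (same sample columns).
# Returns list(coefficient, n_used) matrices (features x agents). Undefined
# tests (constant ranks, < 3 complete pairs) are NA in `coefficient`.
cor_rows <- function(X, Y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(ncol(X) == ncol(Y))
  ns <- ncol(X)
  rho <- matrix(NA_real_, nrow(X), ncol = nrow(Y), dimnames = list(rownames(X), rownames(Y)))
  nmat <- matrix(0L, nrow(X), nrow(Y), dimnames = dimnames(rho))
  x_complete <- rowSums(is.na(X)) == 0L
  for (j in seq_len(nrow(Y))) {
    yj <- Y[j, ]
    oky <- !is.na(yj)
    # fast path: features complete on the agent's sample set
    fast <- x_complete | rowSums(is.na(X[, oky, drop = FALSE])) == 0L
    nj <- sum(oky)
    nmat[fast, j] <- nj
    if (nj >= 3L) {
      Xf <- X[fast, oky, drop = FALSE]
      if (nrow(Xf)) {
        if (method == "spearman") {
          Rf <- t(apply(Xf, 1L, rank))
          ry <- rank(yj[oky])
        } else {
          Rf <- Xf
          ry <- yj[oky]
        }
        sds <- apply(Rf, 1L, stats::sd)
        sy <- stats::sd(ry)
        ok <- sds > 0 & sy > 0
        if (any(ok)) {
          Z <- sweep(Rf[ok, , drop = FALSE], 1L, rowMeans(Rf[ok, , drop = FALSE]))
          Z <- Z / sqrt(rowSums(Z^2))
          zy <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
          rho[which(fast)[ok], j] <- as.numeric(Z %*% zy)
        }
      }
    }
    # slow path: per-pair complete deletion for features with missing cells
    for (i in which(!fast)) {
      ok <- oky & !is.na(X[i, ])
      n <- sum(ok)
      nmat[i, j] <- n
      if (n < 3L) next
      if (method == "spearman") {
        rx <- rank(X[i, ok])
        ryy <- rank(yj[ok])
      } else {
        rx <- X[i, ok]
        ryy <- yj[ok]
      }
      if (stats::sd(rx) == 0 || stats::sd(ryy) == 0) next
      rho[i, j] <- stats::cor(rx, ryy)
    }
  }
  list(coefficient = rho, n_used = nmat)
}
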