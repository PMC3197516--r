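# Null distribution of the Mann-Whitney U statistic (no ties):
# counts[u + 1] = number of n1-subsets of ranks 1..n1+n2 with U1 = u.
# Recurrence f(i, j, u) = f(i-1, j, u-j) + f(i, j-1, u): the largest
# observation goes to sample 1 (beating all j in sample 2) or sample 2.
# Counts reach choose(26, 13) ~ 1e7 at the default exact limit, well
# within exact double-precision integer range.
.mw_null_counts <- function(n1, n2) {
  umax <- n1 * n2
  one <- function() { v <- numeric(umax + 1); v[1] <- 1; v }
  prev <- replicate(n2 + 1, one(), simplify = FALSE)  # i1 = 0 row
  for (i in seq_len(n1)) {
    cur <- vector("list", n2 + 1)
    cur[[1]] <- one()
    for (j in seq_len(n2)) {
      shifted <- c(numeric(j), prev[[j + 1]][seq_len(umax + 1 - j)])
      cur[[j + 1]] <- shifted + cur[[j]]
    }
    prev <- cur
  }
  prev[[n2 + 1]]
}

# U1 from midranks: rank sum of x within the pooled sample
.mw_u <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

# exact p by exhaustive enumeration over all choose(n1+n2, n1) labelings
# of the pooled values (valid with ties); used for small n and as the
# tie-capable exact route
.mw_p_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); n1 <- length(x)
  u_obs <- .mw_u(x, y)
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(ii)
    .mw_u(pooled[ii], pooled[-ii]))
  eps <- 1e-9
  p <- 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps))
  min(1, p)
}

#' Exact two-sided Mann-Whitney U test
#'
#' Computes the Mann-Whitney U statistic from rank sums (midranks for
#' ties) and a two-sided p-value as twice the smaller tail probability,
#' capped at 1. The null distribution is exact whenever feasible:
#' without ties and `n1 + n2 <= exact_limit`, a dynamic-programming
#' count over the full distribution of U; with ties and
#' `n1 + n2 <= tie_enum_limit`, exhaustive enumeration over all
#' labelings of the pooled sample. Otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples (each nonempty, finite).
#' @param exact_limit Largest `n1 + n2` for the exact no-ties
#'   distribution (default 30).
#' @param tie_enum_limit Largest `n1 + n2` for exhaustive enumeration in
#'   the presence of ties (default 12).
#' @return An object of class `mw_test`: list with `u_statistic` (U for
#'   `x`), `n1`, `n2`, `p_two_sided`, `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 30,
                               tie_enum_limit = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("both samples must be nonempty")
  if (any(!is.finite(c(x, y))))
    stop("samples must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u1 <- .mw_u(x, y)
  ties <- anyDuplicated(c(x, y)) > 0L

  if (!ties && n <= exact_limit) {
    counts <- .mw_null_counts(n1, n2)
    total <- sum(counts)
    u_int <- round(u1)  # integral without ties
    p_lo <- sum(counts[seq_len(u_int + 1)]) / total
    p_hi <- sum(counts[(u_int + 1):(n1 * n2 + 1)]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else if (ties && n <= tie_enum_limit) {
    p <- .mw_p_enumerate(x, y)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tab <- table(c(x, y))
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u1 - mu - sign(u1 - mu) * 0.5) / sigma
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(u_statistic = u1, n1 = n1, n2 = n2,
                 p_two_sided = p, method = method),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, "): U = ",
      format(x$u_statistic), ", n1 = ", x$n1, ", n2 = ", x$n2,
      ", two-sided p = ", format.pval(x$p_two_sided, digits = 3),
      "\n", sep = "")
  invisible(x)
}
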