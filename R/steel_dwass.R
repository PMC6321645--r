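# Steel-Dwass all-pairs nonparametric multiple comparison.

#' Steel-Dwass all-pairs rank test
#'
#' For every pair of groups (i, j), ranks the pooled values (midranks for
#' ties), forms the standardized rank-sum statistic
#' `t = (R_i - m (m + n + 1) / 2) / sqrt(Var)` with the tie-corrected
#' variance `Var = m n / (N (N - 1)) * (sum r^2 - N (N + 1)^2 / 4)`, and
#' refers `sqrt(2) |t|` to the studentized-range distribution with `k` groups
#' and infinite degrees of freedom. An exact mode enumerates the permutation
#' distribution of `t` within the pair (feasible for small groups) and
#' reports the unadjusted two-sided permutation p-value.
#'
#' @param x named list of numeric vectors (one per group), or a numeric
#'   vector if `g` is given.
#' @param g optional grouping factor parallel to a numeric `x`.
#' @param method `"asymptotic"` (studentized-range) or `"exact"`
#'   (pairwise permutation enumeration; intended for groups of up to ~8).
#' @return object of class `steel_dwass`: a data frame with one row per
#'   group pair (`group_i`, `group_j`, `n_i`, `n_j`, `statistic`, `p_value`)
#'   plus attributes `k` (number of groups used) and `method`. Groups with
#'   fewer than 2 values are dropped with a warning.
#' @examples
#' steel_dwass(list(a = c(1, 2, 3, 4), b = c(10, 11, 12, 13)))
#' @export
steel_dwass <- function(x, g = NULL, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  if (!is.null(g)) x <- split(as.numeric(x), g)
  if (!is.list(x)) stop("x must be a list of group samples or a vector with g")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0("g", seq_along(x))
  x <- lapply(x, function(v) as.numeric(v[!is.na(v)]))
  small <- lengths(x) < 2
  if (any(small)) {
    warning("dropping group(s) with fewer than 2 values: ",
            paste(names(x)[small], collapse = ", "))
    x <- x[!small]
  }
  k <- length(x)
  if (k < 2) stop("need at least 2 usable groups")

  combs <- utils::combn(k, 2)
  res <- data.frame(group_i = character(0), group_j = character(0),
                    n_i = integer(0), n_j = integer(0),
                    statistic = numeric(0), p_value = numeric(0),
                    stringsAsFactors = FALSE)
  for (c in seq_len(ncol(combs))) {
    i <- combs[1, c]; j <- combs[2, c]
    xi <- x[[i]]; xj <- x[[j]]
    t_obs <- sd_pair_statistic(xi, xj)
    p <- if (method == "asymptotic") {
      stats::ptukey(sqrt(2) * abs(t_obs), nmeans = k, df = Inf,
                    lower.tail = FALSE)
    } else {
      sd_pair_exact_p(xi, xj)
    }
    res[nrow(res) + 1L, ] <- list(names(x)[i], names(x)[j],
                                  length(xi), length(xj), t_obs, p)
  }
  attr(res, "k") <- k
  attr(res, "method") <- method
  class(res) <- c("steel_dwass", "data.frame")
  res
}

# standardized pairwise rank-sum statistic with tie correction
sd_pair_statistic <- function(xi, xj) {
  m <- length(xi); n <- length(xj); N <- m + n
  r <- rank(c(xi, xj))
  Ri <- sum(r[seq_len(m)])
  Ei <- m * (N + 1) / 2
  V <- m * n / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(0)
  (Ri - Ei) / sqrt(V)
}

# exact two-sided permutation p-value of |t| within one pair
sd_pair_exact_p <- function(xi, xj) {
  m <- length(xi); n <- length(xj); N <- m + n
  if (choose(N, m) > 2e5)
    stop("exact enumeration infeasible for these group sizes; use method = \"asymptotic\"")
  r <- rank(c(xi, xj))
  V <- m * n / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(1)
  Ei <- m * (N + 1) / 2
  t_obs <- abs(sum(r[seq_len(m)]) - Ei) / sqrt(V)
  sets <- utils::combn(N, m)
  Rsum <- colSums(matrix(r[sets], nrow = m))
  t_all <- abs(Rsum - Ei) / sqrt(V)
  mean(t_all >= t_obs - 1e-9)
}

#' @export
print.steel_dwass <- function(x, ...) {
  cat(sprintf("Steel-Dwass all-pairs comparison (%s, %d groups)\n",
              attr(x, "method"), attr(x, "k")))
  df <- as.data.frame(x)
  df$p_value <- format.pval(df$p_value, digits = 3)
  print(df, row.names = FALSE)
  invisible(x)
}
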