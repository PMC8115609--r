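#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, the correction used
#' for every multiple-testing scan in the package (FDR of 5% for
#' differential abundance, 25% for covariate associations).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# Per-block rank-sum pieces of the van Elteren statistic. Mid-ranks; the
# tie-corrected variance of the group-1 rank sum within a block of size N is
# n1*n2/12 * ((N+1) - sum(t^3 - t) / (N*(N-1))).
block_ranksum <- function(v, g1) {
  N <- length(v)
  r <- rank(v)
  W <- sum(r[g1])
  n1 <- sum(g1)
  n2 <- N - n1
  ties <- table(v)
  E <- n1 * (N + 1) / 2
  V <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  list(W = W, E = E, V = V)
}

#' Blocked (van Elteren) Wilcoxon rank-sum test
#'
#' Stratified two-group rank-sum test: within each block (typically
#' `study`), the rank sum of the first group is computed with mid-ranks,
#' centred at its permutation expectation, and the blocks are combined as
#' `Z = sum_b (W_b - E_b) / sqrt(sum_b Var_b)` with tie-corrected variances.
#' With a single block this is the ordinary normal-approximation Wilcoxon
#' rank-sum test. Blocks containing only one of the groups contribute
#' nothing. `exact = TRUE` replaces the normal approximation with the
#' exhaustive within-block permutation distribution of `sum_b (W_b - E_b)`
#' (two-sided), feasible for small blocks.
#'
#' @param values numeric vector.
#' @param groups two-level factor/vector, same length.
#' @param blocks blocking factor, same length (default: one block).
#' @param exact use the exhaustive permutation distribution.
#' @return list of class `blocked_test`: `statistic` (Z), `p_value`,
#'   `direction` (group with the larger mean), `n`, `method`.
#' @export
blocked_wilcoxon <- function(values, groups, blocks = NULL, exact = FALSE) {
  if (is.null(blocks)) blocks <- rep(1L, length(values))
  ok <- !is.na(values) & !is.na(groups) & !is.na(blocks)
  values <- values[ok]; groups <- as.character(groups)[ok]
  blocks <- as.character(blocks)[ok]
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("groups must have exactly 2 levels")
  num <- 0; den <- 0
  per_block <- split(seq_along(values), blocks)
  for (idx in per_block) {
    g1 <- groups[idx] == lev[1L]
    if (!any(g1) || all(g1)) next  # single-group block contributes nothing
    b <- block_ranksum(values[idx], g1)
    num <- num + (b$W - b$E)
    den <- den + b$V
  }
  means <- tapply(values, groups, mean)
  direction <- names(means)[which.max(means)]
  if (den <= 0) {
    res <- list(statistic = 0, p_value = 1, direction = direction,
                n = length(values), method = "blocked Wilcoxon (degenerate)")
    class(res) <- "blocked_test"
    return(res)
  }
  z <- num / sqrt(den)
  if (exact) {
    p <- exact_blocked_p(values, groups, blocks, lev, num)
    method <- "blocked Wilcoxon (exact permutation)"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "blocked Wilcoxon (normal approximation)"
  }
  res <- list(statistic = z, p_value = p, direction = direction,
              n = length(values), method = method)
  class(res) <- "blocked_test"
  res
}

# Exhaustive two-sided p for T = sum_b (W_b - E_b): per block, enumerate
# every choice of group-1 positions, then convolve block distributions.
# Mid-ranks are half-integers, so 2*W is integer and distributions can be
# tabulated exactly.
exact_blocked_p <- function(values, groups, blocks, lev, t_obs) {
  per_block <- split(seq_along(values), blocks)
  dists <- list()
  total <- 1
  for (idx in per_block) {
    g1 <- groups[idx] == lev[1L]
    n1 <- sum(g1); N <- length(idx)
    if (n1 == 0L || n1 == N) next
    total <- total * choose(N, n1)
    if (total > 5e6) stop("exact enumeration too large; use exact = FALSE")
    r2 <- as.integer(round(2 * rank(values[idx])))
    E2 <- n1 * (N + 1)  # = 2*E
    sums <- utils::combn(r2, n1, sum)
    tab <- table(sums - E2)
    dists[[length(dists) + 1L]] <- tab
  }
  if (length(dists) == 0L) return(1)
  # convolve
  acc <- dists[[1L]]
  if (length(dists) > 1L) for (i in 2:length(dists)) {
    x <- as.integer(names(acc)); y <- as.integer(names(dists[[i]]))
    cx <- as.numeric(acc); cy <- as.numeric(dists[[i]])
    s <- outer(x, y, "+")
    w <- outer(cx, cy)
    acc <- tapply(as.vector(w), as.vector(s), sum)
    acc <- stats::setNames(as.numeric(acc), names(acc))
  }
  vals <- as.integer(names(acc))
  wts <- as.numeric(acc)
  obs2 <- round(2 * t_obs)
  sum(wts[abs(vals) >= abs(obs2) - 1e-9]) / sum(wts)
}

#' Blocked (stratified) Kruskal-Wallis test
#'
#' Generalization of [blocked_wilcoxon()] to two or more groups: within each
#' block, group rank sums are centred at their permutation expectations;
#' block-wise conditional covariances of the linear rank statistics are
#' summed and the quadratic form of the centred sums against the
#' pseudo-inverted covariance gives a chi-square statistic on
#' (number of groups - 1) degrees of freedom. With one block and two groups
#' the p-value coincides with [blocked_wilcoxon()]; with one block and any
#' number of groups it is the tie-corrected Kruskal-Wallis test.
#' `exact = TRUE` enumerates all within-block label permutations (joint
#' across blocks) and is only feasible for very small samples.
#'
#' @inheritParams blocked_wilcoxon
#' @param groups factor/vector with at least two levels.
#' @return list of class `blocked_test` with `statistic` (chi-square),
#'   `df`, `p_value`, `n`, `method`.
#' @export
blocked_kruskal_wallis <- function(values, groups, blocks = NULL,
                                   exact = FALSE) {
  if (is.null(blocks)) blocks <- rep(1L, length(values))
  ok <- !is.na(values) & !is.na(groups) & !is.na(blocks)
  values <- values[ok]; groups <- as.character(groups)[ok]
  blocks <- as.character(blocks)[ok]
  lev <- sort(unique(groups))
  g <- length(lev)
  if (g < 2L) stop("need at least two groups")
  stat_fun <- function(vals, grps) {
    Tv <- stats::setNames(numeric(g), lev)
    Ev <- Tv
    Sig <- matrix(0, g, g, dimnames = list(lev, lev))
    for (idx in split(seq_along(vals), blocks)) {
      gb <- grps[idx]
      present <- unique(gb)
      if (length(present) < 2L) next
      N <- length(idx)
      r <- rank(vals[idx])
      S2 <- stats::var(r)            # conditional rank variance, ties included
      nb <- stats::setNames(numeric(g), lev)
      tb <- tapply(r, factor(gb, levels = lev), sum)
      tb[is.na(tb)] <- 0
      cnt <- table(factor(gb, levels = lev))
      nb[names(cnt)] <- as.numeric(cnt)
      Tv <- Tv + tb
      Ev <- Ev + nb * (N + 1) / 2
      Sig <- Sig + S2 * (diag(nb) - outer(nb, nb) / N)
    }
    d <- Tv - Ev
    ev <- eigen(Sig, symmetric = TRUE)
    tol <- max(ev$values, 0) * 1e-10
    pos <- ev$values > tol & ev$values > 0
    if (!any(pos)) return(list(stat = 0, df = g - 1L))
    U <- ev$vectors[, pos, drop = FALSE]
    x2 <- sum((crossprod(U, d))^2 / ev$values[pos])
    list(stat = x2, df = sum(pos))
  }
  obs <- stat_fun(values, groups)
  if (obs$df == 0 || obs$stat == 0) {
    res <- list(statistic = 0, df = g - 1L, p_value = 1, n = length(values),
                method = "blocked Kruskal-Wallis (degenerate)")
    class(res) <- "blocked_test"
    return(res)
  }
  if (exact) {
    perms <- enumerate_block_perms(groups, blocks)
    stats_perm <- vapply(perms, function(gp) stat_fun(values, gp)$stat,
                         numeric(1))
    p <- mean(stats_perm >= obs$stat - 1e-9)
    method <- "blocked Kruskal-Wallis (exact permutation)"
  } else {
    p <- stats::pchisq(obs$stat, df = obs$df, lower.tail = FALSE)
    method <- "blocked Kruskal-Wallis (chi-square approximation)"
  }
  res <- list(statistic = obs$stat, df = obs$df, p_value = p,
              n = length(values), method = method)
  class(res) <- "blocked_test"
  res
}

# All joint within-block permutations of group labels (distinct
# arrangements), as a list of full-length label vectors.
enumerate_block_perms <- function(groups, blocks) {
  per_block <- split(seq_along(groups), blocks)
  block_arr <- lapply(per_block, function(idx) {
    unique_perms(groups[idx])
  })
  total <- prod(vapply(block_arr, length, numeric(1)))
  if (total > 2e5) stop("exact enumeration too large; use exact = FALSE")
  grid <- expand.grid(lapply(block_arr, seq_along))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gp <- groups
    for (b in seq_along(per_block))
      gp[per_block[[b]]] <- block_arr[[b]][[grid[i, b]]]
    out[[i]] <- gp
  }
  out
}

# distinct permutations of a label multiset
unique_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (u in unique(x)) {
    rest <- x[-match(u, x)]
    for (p in unique_perms(rest)) out[[length(out) + 1L]] <- c(u, p)
  }
  out
}

#' @export
print.blocked_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("statistic = %.4g, p = %.4g, n = %d\n",
              x$statistic, x$p_value, x$n))
  invisible(x)
}
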