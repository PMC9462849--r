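# Exact small-sample rank tests. Null distributions are obtained by full
# enumeration of the randomization distribution, computed with integer
# generating-function convolutions (equivalent to, and cross-checked in the
# test suite against, literal enumeration of all sign vectors / rank
# assignments). Distributions are cached per rank configuration.

.null_cache <- new.env(parent = emptyenv())

new_comparison <- function(test, statistic, p, n, n_a = NA_integer_,
                           n_b = NA_integer_, effect = NA_real_,
                           effect_name = NA_character_,
                           method_path, note = "") {
  structure(list(test = test, statistic = statistic,
                 p_value = p, n = n, n_a = n_a, n_b = n_b,
                 effect = effect, effect_name = effect_name,
                 method_path = method_path, note = note),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<", x$test, "> statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4), " (", x$method_path, "), n = ",
      x$n, "\n", sep = "")
  if (!is.na(x$effect))
    cat("  ", x$effect_name, " = ", signif(x$effect, 4), "\n", sep = "")
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(test = x$test, statistic = x$statistic, p_value = x$p_value,
             n = x$n, n_a = x$n_a, n_b = x$n_b, effect = x$effect,
             effect_name = x$effect_name, method_path = x$method_path,
             note = x$note)
}

#' Paired t-test on per-disc values
#'
#' Classical two-sided paired t-test on the within-disc differences, used
#' for mean intensities when comparing two regions of the same discs.
#'
#' @param x,y numeric vectors of equal length, paired by disc.
#' @return A `comparison_result`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_quant("x and y must be paired")
  if (length(x) < 2L) stop_quant("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0)
    stop_quant("degenerate paired sample: all differences identical")
  tt <- t.test(x, y, paired = TRUE)
  new_comparison("paired t-test", unname(tt$statistic), tt$p.value,
                 n = length(x), effect = mean(d),
                 effect_name = "mean difference",
                 method_path = "paired-t")
}

# Null distribution of the doubled signed-rank statistic 2*W for midranks
# r: probabilities over 0..sum(2r), by convolution over the 2^n equally
# likely sign assignments.
signed_rank_null <- function(ranks2) {
  key <- paste0("sr:", paste(sort(ranks2), collapse = ","))
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    g <- f
    f[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] +
      g[1L:(total + 1L - r)]
  }
  probs <- f / 2^length(ranks2)
  .null_cache[[key]] <- probs
  probs
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (and logged in the result's note). For up to `exact_max`
#' remaining pairs the p-value is exact over the full randomization
#' distribution of sign assignments (midranks handle ties); above that, a
#' normal approximation with tie and continuity correction is used.
#'
#' @param x,y numeric vectors paired by disc.
#' @param exact_max largest n for which the exact path is taken.
#' @return A `comparison_result` with statistic `W` (sum of positive
#'   ranks).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) stop_quant("x and y must be paired")
  d <- x - y
  dropped <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop_quant("all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  note <- if (dropped > 0)
    paste0(dropped, " zero difference(s) dropped") else ""
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    probs <- signed_rank_null(r2)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    path <- "exact-enumeration"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - mu - 0.5 * sign(W - mu)) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    path <- "normal-approximation"
  }
  new_comparison("Wilcoxon signed-rank", W, p, n = n,
                 effect = median(d), effect_name = "median difference",
                 method_path = path, note = note)
}

# Null counts of the rank-sum of the first group (sizes m, n; untied ranks
# 1..m+n): number of m-subsets of {1..N} per rank-sum value.
rank_sum_null_counts <- function(m, n) {
  key <- paste0("mw:", m, ",", n)
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  N <- m + n
  max_sum <- sum((N - m + 1L):N)
  g <- matrix(0, nrow = m + 1L, ncol = max_sum + 1L)
  g[1L, 1L] <- 1
  for (val in seq_len(N)) {
    for (k in seq(min(m, val), 1L)) {
      cols <- seq_len(max_sum + 1L - val)
      g[k + 1L, cols + val] <- g[k + 1L, cols + val] + g[k, cols]
    }
  }
  counts <- g[m + 1L, ]
  .null_cache[[key]] <- counts
  counts
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided comparison of two independent samples. When the combined
#' sample has at most `exact_max` observations and no ties, the p-value is
#' exact over all rank assignments; otherwise a normal approximation with
#' tie and continuity correction is used.
#'
#' @param x,y independent numeric samples.
#' @param exact_max largest combined sample size for the exact path.
#' @return A `comparison_result` with statistic `U` (for the first
#'   sample).
#' @export
mann_whitney <- function(x, y, exact_max = 14L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop_quant("both groups must be non-empty")
  comb <- c(x, y)
  r <- rank(comb)
  has_ties <- anyDuplicated(comb) > 0L
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!has_ties && n1 + n2 <= exact_max) {
    counts <- rank_sum_null_counts(n1, n2)
    total <- sum(counts)
    offset <- n1 * (n1 + 1) / 2          # rank-sum = U + offset
    u_idx <- as.integer(round(U + offset)) + 1L
    p_le <- sum(counts[seq_len(u_idx)]) / total
    p_ge <- sum(counts[u_idx:length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    path <- "exact-enumeration"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(comb)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * (N + 1 - tie_term))
    if (sigma == 0) stop_quant("degenerate samples: all values identical")
    z <- (U - mu - 0.5 * sign(U - mu)) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    path <- if (has_ties) "normal-approximation (ties)"
            else "normal-approximation"
  }
  new_comparison("Mann-Whitney", U, p, n = n1 + n2, n_a = n1, n_b = n2,
                 effect = 2 * U / (n1 * n2) - 1,
                 effect_name = "rank-biserial",
                 method_path = path)
}
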