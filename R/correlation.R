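#' Spearman rank correlation with significance
#'
#' Computes Spearman's rank correlation coefficient R as the Pearson
#' correlation of mid-ranked data (average ranks for ties) together with a
#' two-sided p-value. The default p-value uses the t approximation
#' `t = R * sqrt((n - 2) / (1 - R^2))` on `n - 2` degrees of freedom, which is
#' adequate at the sample sizes co-occurrence studies use (tens of samples);
#' `p_method = "permutation"` gives a permutation p-value for very small n
#' (exhaustive for n <= 7, otherwise `n_perm` random permutations).
#'
#' @param x,y numeric vectors of equal length (n >= 4), not constant.
#' @param p_method `"t_approx"` (default) or `"permutation"`.
#' @param n_perm number of random permutations when the permutation p-value is
#'   not exhaustive.
#' @return A list with `r` and `p_value`. `r = +/-1` gives `p_value = 0` under
#'   the t approximation.
#' @examples
#' spearman_with_p(1:5, c(2, 4, 6, 8, 10))$r        # 1
#' spearman_with_p(1:5, c(10, 8, 6, 4, 2))$r        # -1
#' @export
spearman_with_p <- function(x, y, p_method = c("t_approx", "permutation"),
                            n_perm = 10000L) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("constant vector: Spearman correlation undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  r <- cor(rx, ry)
  p <- switch(p_method,
    t_approx = spearman_p_t(r, n),
    permutation = spearman_p_perm(rx, ry, r, n_perm))
  list(r = r, p_value = p)
}

spearman_p_t <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tval), df = n - 2)
}

spearman_p_perm <- function(rx, ry, r_obs, n_perm) {
  n <- length(rx)
  if (n <= 7L) {
    perms <- permutations_of(n)
    rs <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    mean(abs(rs) >= abs(r_obs) - 1e-12)
  } else {
    rs <- replicate(n_perm, cor(rx, sample(ry)))
    (1 + sum(abs(rs) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  }
}

# All permutations of 1..n as rows (n! x n); used only for tiny n.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' All-pairs Spearman correlations for an OTU table
#'
#' Ranks each OTU's counts across samples (mid-ranks for ties) and computes
#' the Pearson correlation matrix of the rank vectors, plus two-sided
#' t-approximation p-values. OTUs with constant counts across all samples have
#' no defined correlation: they are skipped with a warning and returned in
#' `skipped`.
#'
#' @param table an [otu_table()] (OTUs x samples).
#' @return A list with `r` (p x p correlation matrix), `p_value` (p x p, NA on
#'   the diagonal), `n` (number of samples) and `skipped` (labels of constant
#'   OTUs, excluded from the matrices).
#' @export
spearman_matrix <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  m <- unclass(table)
  constant <- apply(m, 1L, function(v) length(unique(v)) == 1L)
  skipped <- rownames(m)[constant]
  if (length(skipped)) {
    warning(length(skipped), " constant OTU vector(s) skipped: correlation undefined")
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("fewer than 2 usable OTUs")
  n <- ncol(m)
  ranks <- t(apply(m, 1L, rank))
  r <- cor(t(ranks))
  p <- matrix(spearman_p_t_vec(r, n), nrow = nrow(r), dimnames = dimnames(r))
  diag(p) <- NA_real_
  list(r = r, p_value = p, n = n, skipped = skipped)
}

spearman_p_t_vec <- function(r, n) {
  r2 <- pmin(abs(r), 1)
  p <- ifelse(r2 >= 1, 0, 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2))
  p
}
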