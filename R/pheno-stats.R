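#' Lipid-partition arithmetic for dry-weight sets
#'
#' For batches of flies weighed dry (`dw`) and again after ether extraction
#' of lipids (`lfree_dw`), the lipid weight is `lw = dw - lfree_dw` and the
#' lipid percentage of dry weight is `lw / dw`.
#'
#' @param weights Data frame with numeric columns `dw` and `lfree_dw`
#'   (milligrams); any other columns are carried through.
#' @return The input as a tibble with added columns `lw` and `pct_lipid`.
#' @examples
#' lipid_metrics(data.frame(dw = 1.0, lfree_dw = 0.8))
#' @export
lipid_metrics <- function(weights) {
  weights <- as_tibble(weights)
  stopifnot(all(c("dw", "lfree_dw") %in% names(weights)))
  if (any(weights$lfree_dw > weights$dw)) {
    abort("lipid-free dry weight exceeds dry weight")
  }
  mutate(weights, lw = .data$dw - .data$lfree_dw,
         pct_lipid = .data$lw / .data$dw)
}

# Mann-Whitney U (group a "wins" over b) with midranks for ties
mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact two-sided p by enumerating all group labellings; handles ties
mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_obs <- mw_u(a, b)
  mu <- na * nb / 2
  sets <- combn(na + nb, na)
  us <- apply(sets, 2L, function(idx) mw_u(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Two-group contrast: percent difference and Mann-Whitney test
#'
#' The percent difference is `100 * (mean(b) - mean(a)) / mean(a)`, i.e.
#' relative to the first (reference/control) group. The Mann-Whitney U uses
#' midranks for ties; the two-sided p-value is exact (full enumeration of
#' group labellings) when `length(a) + length(b) <= exact_limit`, otherwise
#' the normal approximation with tie and continuity corrections is used.
#'
#' @param data Data frame in long form with a value column and a group
#'   column, or a numeric vector (reference group `a`) when `b` is given.
#' @param value,group Column names (strings) when `data` is a data frame.
#' @param ref Level of `group` to treat as the reference; default the first
#'   level encountered.
#' @param b Second group's values when `data` is a numeric vector.
#' @param exact_limit Total sample size at or below which the exact
#'   enumeration p-value is computed.
#' @return A one-row tibble of class `muc_contrast`: `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `pct_difference`, `U`, `p_value`, `method`.
#' @examples
#' group_contrast(c(1, 2, 3), b = c(4, 5, 6))
#' @export
group_contrast <- function(data, value = NULL, group = NULL, ref = NULL,
                           b = NULL, exact_limit = 12L) {
  if (is.data.frame(data)) {
    stopifnot(!is.null(value), !is.null(group))
    g <- data[[group]]
    ref <- ref %||% as.character(g[[1]])
    a <- data[[value]][g == ref]
    bb <- data[[value]][g != ref]
  } else {
    a <- data; bb <- b
  }
  if (length(a) == 0L || length(bb) == 0L) abort("empty group")
  u <- mw_u(a, bb)
  if (length(a) + length(bb) <= exact_limit) {
    p <- mw_exact_p(a, bb)
    method <- "exact"
  } else {
    p <- suppressWarnings(
      wilcox.test(a, bb, exact = FALSE, correct = TRUE))$p.value
    method <- "normal-approximation"
  }
  out <- tibble(n_a = length(a), n_b = length(bb),
                mean_a = mean(a), mean_b = mean(bb),
                pct_difference = 100 * (mean(bb) - mean(a)) / mean(a),
                U = u, p_value = p, method = method)
  class(out) <- c("muc_contrast", class(out))
  out
}

#' @method tidy muc_contrast
#' @export
tidy.muc_contrast <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "muc_contrast")
  out
}

#' @method glance muc_contrast
#' @export
glance.muc_contrast <- function(x, ...) {
  tibble(pct_difference = x$pct_difference, p_value = x$p_value,
         method = x$method)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass definition: the sum of hypergeometric
#' probabilities (margins fixed) of all tables at most as probable as the
#' observed one. The odds ratio reported is the sample odds ratio `ad / bc`
#' (`Inf` when `bc == 0`), not the conditional MLE.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @return A one-row tibble: `odds_ratio`, `p_value`, `defined` (FALSE when
#'   a zero margin makes the odds ratio undefined; then `p_value = 1`).
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("counts must be non-negative integers")
  }
  if (sum(tab) == 0) abort("empty table")
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(tibble(odds_ratio = NA_real_, p_value = 1, defined = FALSE))
  }
  p <- fisher.test(tab)$p.value   # R implements the probability-mass rule
  or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
  tibble(odds_ratio = or, p_value = p, defined = TRUE)
}

#' Pearson and Spearman correlations with t-based p-values
#'
#' Product-moment r and rank rho (midranks for ties); both p-values come
#' from the t distribution with `n - 2` degrees of freedom.
#'
#' @param data Data frame, or numeric vector `x` when `y` is given.
#' @param x,y Column names (strings) when `data` is a data frame, else `y`
#'   is the paired numeric vector.
#' @return A one-row tibble: `n`, `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `defined` (FALSE when either vector has zero variance).
#' @examples
#' correlations(c(1, 2, 3, 4), y = c(1, 3, 2, 4))
#' @export
correlations <- function(data, x = NULL, y = NULL) {
  if (is.data.frame(data)) {
    xx <- data[[x]]; yy <- data[[y]]
  } else {
    xx <- data; yy <- y
  }
  ok <- stats::complete.cases(xx, yy)
  xx <- xx[ok]; yy <- yy[ok]
  n <- length(xx)
  if (n < 3L) abort("need at least 3 paired observations")
  if (sd(xx) == 0 || sd(yy) == 0) {
    return(tibble(n = n, pearson_r = NA_real_, pearson_p = NA_real_,
                  spearman_rho = NA_real_, spearman_p = NA_real_,
                  defined = FALSE))
  }
  t_p <- function(r) {
    if (abs(r) >= 1) return(0)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  r <- cor(xx, yy)
  rho <- cor(rank(xx), rank(yy))
  tibble(n = n, pearson_r = r, pearson_p = t_p(r),
         spearman_rho = rho, spearman_p = t_p(rho), defined = TRUE)
}

#' Summaries of death times and survival at checkpoints
#'
#' Deaths observed at interval checks (every 12 h for starvation, every
#' other day for lifespan) are assigned to the right endpoint of the
#' interval, i.e. the checkpoint at which death was first observed.
#'
#' @param times Per-individual death times (all positive).
#' @param checkpoints Optional numeric vector of times at which to report
#'   the fraction still alive (`t > checkpoint`).
#' @return A list with `n`, `mean`, `sd`, and `alive`, a tibble
#'   (`checkpoint`, `fraction_alive`).
#' @examples
#' survival_summary(c(10, 20, 30), checkpoints = 25)
#' @export
survival_summary <- function(times, checkpoints = NULL) {
  if (length(times) == 0L) abort("no death times")
  if (any(times <= 0)) abort("death times must be positive")
  alive <- if (is.null(checkpoints)) {
    tibble(checkpoint = numeric(), fraction_alive = numeric())
  } else {
    tibble(checkpoint = checkpoints,
           fraction_alive = vapply(checkpoints,
                                   function(cp) mean(times > cp), numeric(1)))
  }
  list(n = length(times), mean = mean(times), sd = sd(times), alive = alive)
}
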