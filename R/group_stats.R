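# Per-energy-term group statistics: significance of proper-vs-mirror
# differences, NMT normalization across domains, correlations, and per-domain
# structural summaries.

#' Normalize a domain x term matrix of means (NMT)
#'
#' Each term column is divided by the maximum absolute mean of that term over
#' all domains, so every entry lies in \[-1, 1\] and at least one domain per
#' term attains +/-1.
#'
#' @param means numeric matrix (domains x terms), with dimnames.
#' @return matrix of the same shape with entries in \[-1, 1\].
#' @export
nmt_normalize <- function(means) {
  means <- as.matrix(means)
  out <- means
  for (j in seq_len(ncol(means))) {
    mx <- max(abs(means[, j]))
    if (mx == 0)
      stop("all-zero term column: ",
           if (!is.null(colnames(means))) colnames(means)[j] else j)
    out[, j] <- means[, j] / mx
  }
  out
}

# Mann-Whitney U statistic with 0.5 credit for ties
.mwu_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# exact two-sided permutation p-value of U by enumeration over all
# choose(n1+n2, n1) group splits (distribution computed from rank sums)
.mwu_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# tie-corrected normal approximation with continuity correction
.mwu_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  nn <- n1 + n2
  u <- .mwu_u(x, y)
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(u - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact permutation p-value (two-sided, by |U - n1 n2 / 2|) when both groups
#' have at most `exact_max` observations; otherwise a tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max enumerate exactly when both sizes are <= this (default 8).
#' @return list with `u` and `p_value`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (length(x) < 1L || length(y) < 1L) stop("empty group")
  p <- if (length(x) <= exact_max && length(y) <= exact_max)
    .mwu_exact_p(x, y) else .mwu_normal_p(x, y)
  list(u = .mwu_u(x, y), p_value = p)
}

#' Significance of one energy term between proper and mirror groups
#'
#' @param values_proper,values_mirror numeric vectors of per-model term
#'   values, each of length >= 3.
#' @param alpha significance level (default 0.05).
#' @param method `"mwu"` (default, two-sided Mann-Whitney U) or `"welch"`
#'   (Welch t-test, for sensitivity analysis).
#' @return one-row data.frame: means, sds, `p_value`, `significant`,
#'   `mean_ratio` = mean(proper)/mean(mirror).
#' @export
term_significance <- function(values_proper, values_mirror, alpha = 0.05,
                              method = c("mwu", "welch")) {
  method <- match.arg(method)
  if (length(values_proper) < 3L || length(values_mirror) < 3L)
    stop("each group needs at least 3 values")
  p <- if (method == "mwu") {
    mann_whitney_u(values_proper, values_mirror)$p_value
  } else {
    if (stats::var(values_proper) + stats::var(values_mirror) == 0) 1
    else stats::t.test(values_proper, values_mirror)$p.value
  }
  mp <- mean(values_proper); mm <- mean(values_mirror)
  data.frame(
    mean_proper = mp, sd_proper = stats::sd(values_proper),
    mean_mirror = mm, sd_mirror = stats::sd(values_mirror),
    p_value = p, significant = p < alpha,
    mean_ratio = if (mm != 0) mp / mm else NA_real_)
}

#' Per-domain, per-term significance matrix
#'
#' For each domain, tests every term column between the proper and mirror
#' groups. This is the machine version of a domain x term dot matrix: a cell
#' is `TRUE` when that term separates the two orientations at level `alpha`.
#'
#' @param domain_tables named list (one element per domain) of data.frames
#'   with a `label` column (`"proper"`/`"mirror"`) and numeric term columns.
#' @param alpha significance level.
#' @param method passed to [term_significance()].
#' @return list with logical matrix `significant` and numeric matrix
#'   `p_value` (domains x terms).
#' @export
significance_matrix <- function(domain_tables, alpha = 0.05,
                                method = c("mwu", "welch")) {
  method <- match.arg(method)
  stopifnot(length(domain_tables) >= 1L)
  terms <- setdiff(names(domain_tables[[1L]]),
                   c("label", "model_id", "true_label", "domain",
                     "rmsd_to_ref", "rmsd_to_mirror_ref"))
  terms <- terms[vapply(domain_tables[[1L]][terms], is.numeric, TRUE)]
  nd <- length(domain_tables)
  pm <- matrix(NA_real_, nd, length(terms),
               dimnames = list(names(domain_tables), terms))
  for (d in seq_len(nd)) {
    tab <- domain_tables[[d]]
    vp <- tab[tab$label == "proper", , drop = FALSE]
    vm <- tab[tab$label == "mirror", , drop = FALSE]
    if (nrow(vp) < 3L || nrow(vm) < 3L)
      stop("domain ", names(domain_tables)[d],
           ": need >= 3 proper and >= 3 mirror models")
    for (t in seq_along(terms)) {
      x <- vp[[terms[t]]]; y <- vm[[terms[t]]]
      pm[d, t] <- if (length(unique(c(x, y))) == 1L) 1
                  else term_significance(x, y, alpha, method)$p_value
    }
  }
  list(significant = pm < alpha, p_value = pm)
}

#' Pearson correlation with two-sided t-test p-value
#'
#' Sample Pearson r; p from the t statistic r * sqrt((n-2)/(1-r^2)) with
#' n - 2 degrees of freedom (p = 0 at |r| = 1).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r` and `p_value`.
#' @export
pearson <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("length mismatch")
  if (n < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p)
}

#' Per-domain structural and chirality summaries
#'
#' Per domain: mean RMSD-to-reference of the proper and mirror groups, their
#' ratio (the structural difference — near 1 means RMSD cannot tell the
#' groups apart), group mean Phi+ ratios and their proper/mirror ratio, and
#' the number of significant terms from a significance matrix row.
#'
#' @param domain_tables as in [significance_matrix()], with columns
#'   `rmsd_to_ref` and `phi_plus_ratio`.
#' @param sig_matrix optional result of [significance_matrix()] on the same
#'   list; when supplied, `n_significant_terms` is its row sum.
#' @return data.frame, one row per domain.
#' @export
domain_summaries <- function(domain_tables, sig_matrix = NULL) {
  rows <- lapply(names(domain_tables), function(dn) {
    tab <- domain_tables[[dn]]
    p <- tab[tab$label == "proper", ]
    m <- tab[tab$label == "mirror", ]
    if (!nrow(p) || !nrow(m)) stop("domain ", dn, ": empty group")
    data.frame(
      domain = dn,
      mean_rmsd_proper = mean(p$rmsd_to_ref),
      mean_rmsd_mirror = mean(m$rmsd_to_ref),
      structural_difference = mean(p$rmsd_to_ref) / mean(m$rmsd_to_ref),
      phi_plus_ratio_proper = mean(p$phi_plus_ratio),
      phi_plus_ratio_mirror = mean(m$phi_plus_ratio),
      n_significant_terms = if (is.null(sig_matrix)) NA_integer_
                            else sum(sig_matrix$significant[dn, ]))
  })
  do.call(rbind, rows)
}
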