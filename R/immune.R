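#' Macrophage polarisation ratio
#'
#' Computes log2(M1/M2) per sample from an immune-fraction table
#' (CIBERSORT-style relative fractions). Fractions of exactly zero are
#' structural (cell type called absent), so samples with M1 = 0 or M2 = 0
#' are excluded rather than pseudo-counted, and the exclusions are counted
#' in the result.
#'
#' @param fractions data.frame with a `sample_id` column and the named
#'   fraction columns, including `m1_col` and `m2_col`.
#' @param m1_col,m2_col column names of the M1 and M2 macrophage fractions.
#' @return List with `ratios` (data.frame `sample_id`, `log2_m1_m2`) and
#'   `n_excluded`.
#' @export
m1_m2_log_ratio <- function(fractions, m1_col = "Macrophages.M1",
                            m2_col = "Macrophages.M2") {
  for (col in c(m1_col, m2_col))
    if (!col %in% names(fractions)) stop("missing fraction column: ", col)
  m1 <- fractions[[m1_col]]
  m2 <- fractions[[m2_col]]
  ok <- is.finite(m1) & is.finite(m2) & m1 > 0 & m2 > 0
  list(
    ratios = data.frame(sample_id = fractions$sample_id[ok],
                        log2_m1_m2 = log2(m1[ok] / m2[ok]),
                        stringsAsFactors = FALSE),
    n_excluded = sum(!ok)
  )
}

#' Pairwise Spearman correlation matrix with p-values
#'
#' Correlates every column of `x` with every column of `y` (default: `x`
#' against itself) using Spearman's rank correlation with pairwise-complete
#' observations. P-values are exact (no-ties null) for n <= 10 and use the
#' asymptotic t approximation otherwise. Cells with fewer than `min_n`
#' complete pairs are set to `NA`. P-values are reported raw, without
#' multiplicity adjustment.
#'
#' @param x,y numeric data.frames or matrices with sample rows.
#' @param min_n minimum complete pairs per cell (default 4).
#' @return List of matrices `rho`, `p`, `n`.
#' @export
spearman_matrix <- function(x, y = x, min_n = 4) {
  x <- as.data.frame(x); y <- as.data.frame(y)
  rho <- p <- n <- matrix(NA_real_, ncol(x), ncol(y),
                          dimnames = list(names(x), names(y)))
  for (i in seq_len(ncol(x))) {
    for (j in seq_len(ncol(y))) {
      xi <- x[[i]]; yj <- y[[j]]
      ok <- is.finite(xi) & is.finite(yj)
      n[i, j] <- sum(ok)
      if (n[i, j] < min_n) next
      ct <- suppressWarnings(
        stats::cor.test(xi[ok], yj[ok], method = "spearman",
                        exact = n[i, j] <= 10 && !anyDuplicated(xi[ok]) &&
                          !anyDuplicated(yj[ok]))
      )
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(rho = rho, p = p, n = n)
}

#' Two-group comparison (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test. When both groups have at most 8
#' observations the exact null distribution is enumerated over all group
#' assignments (average ranks for ties, two-sided via the symmetric
#' |U - n1 n2 / 2| tail); otherwise the tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param values numeric vector.
#' @param labels two-level factor/vector aligned with `values`.
#' @return List with `U` (statistic for the first level), `p`, `exact`.
#' @export
group_compare <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("group_compare needs exactly two groups, got ", nlevels(labels))
  g1 <- values[labels == levels(labels)[1]]
  g2 <- values[labels == levels(labels)[2]]
  if (!length(g1) || !length(g2)) stop("both groups must be non-empty")
  n1 <- length(g1); n2 <- length(g2)
  r <- rank(c(g1, g2))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  exact <- n1 <= 8 && n2 <= 8
  if (exact) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(g1, g2, exact = FALSE, correct = TRUE)$p.value
    )
  }
  list(U = unname(u_obs), p = p, exact = exact)
}

#' One-way ANOVA across groups
#'
#' Classical one-way fixed-effects F test, as used for comparing a score
#' across cancer types.
#'
#' @param values numeric vector.
#' @param labels factor with k >= 2 levels, each with >= 2 observations.
#' @return List with `F`, `p`, `df`.
#' @export
anova_across_groups <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("ANOVA needs at least 2 groups")
  counts <- table(labels)
  if (any(counts < 2))
    stop("each group needs >= 2 observations; degenerate: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  fit <- stats::aov(values ~ labels)
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df = c(tab[1, "Df"], tab[2, "Df"]))
}

#' Filter a differential-expression/proteomics result table
#'
#' Retains features with |logFC| strictly greater than `fc_thresh` and
#' adjusted p strictly below `alpha` — the standard volcano-plot corner
#' rule. Boundary rows (|logFC| equal to the threshold, or adjusted p equal
#' to alpha) are excluded.
#'
#' @param rows data.frame with columns `logFC` and `adj_p` (feature id in
#'   any other column is carried through).
#' @param fc_thresh absolute log fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return The retained subset of `rows`.
#' @export
filter_differential <- function(rows, fc_thresh = 1, alpha = 0.05) {
  stopifnot(all(c("logFC", "adj_p") %in% names(rows)))
  if (any(rows$adj_p < 0 | rows$adj_p > 1, na.rm = TRUE))
    stop("adjusted p-values must lie in [0, 1]")
  keep <- (rows$logFC > fc_thresh | rows$logFC < -fc_thresh) & rows$adj_p < alpha
  keep[is.na(keep)] <- FALSE
  rows[keep, , drop = FALSE]
}
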