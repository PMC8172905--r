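#' Kernel-CDF expression statistic
#'
#' First stage of the single-sample enrichment score: each expression value
#' is replaced by its kernel-estimated cumulative density against the gene's
#' own cross-sample distribution (Gaussian kernel, bandwidth = per-gene
#' sd / `bw_divisor`). The statistic is monotone in expression within a gene
#' and invariant to shifting a gene's row by a constant, so downstream
#' scores depend only on relative expression.
#'
#' A gene that is constant across samples has no usable density; its
#' statistic is defined as 0.5 for every sample and a message is logged.
#'
#' @param m expression matrix (genes x samples), at least 3 samples.
#' @param bw_divisor bandwidth divisor (default 4: bandwidth sd/4).
#' @return Matrix of the same shape with values in (0, 1).
#' @export
kernel_expression_statistic <- function(m, bw_divisor = 4) {
  validate_expression(m)
  if (ncol(m) < 3)
    stop("kernel CDF estimation needs at least 3 samples")
  out <- m
  n <- ncol(m)
  constant <- character(0)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      out[i, ] <- 0.5
      constant <- c(constant, rownames(m)[i])
      next
    }
    h <- s / bw_divisor
    # z_ij = (1/n) sum_k Phi((x_ij - x_ik)/h)
    out[i, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
  }
  if (length(constant))
    message("constant genes given degenerate statistic 0.5: ",
            paste(utils::head(constant, 5), collapse = ", "),
            if (length(constant) > 5) " ..." else "")
  out
}

#' Single-sample gene-set enrichment score (weighted KS random walk)
#'
#' For each sample, genes are ordered by decreasing kernel-CDF statistic and
#' converted to centred rank statistics `|p/2 - rank|`. A weighted
#' Kolmogorov-Smirnov random walk then steps through the ordering: inside
#' the set the walk rises in proportion to the centred rank statistic raised
#' to `tau`, outside it falls uniformly. In `max_diff` mode the score is the
#' maximum positive deviation plus the minimum negative deviation of the
#' walk, so a set concentrated at the top of the ordering scores positive
#' and one at the bottom scores negative.
#'
#' @param stats_matrix output of [kernel_expression_statistic()].
#' @param gs a [gene_set()] or character vector of gene symbols; members
#'   absent from the matrix are dropped with a warning.
#' @param tau rank-weight exponent (default 1; 0 gives the unweighted KS walk).
#' @param mode scoring mode; only `"max_diff"` is implemented.
#' @return Named numeric vector of per-sample enrichment scores.
#' @export
gsva_score <- function(stats_matrix, gs, tau = 1, mode = "max_diff") {
  mode <- match.arg(mode, "max_diff")
  genes <- if (inherits(gs, "gene_set")) gs$genes else as.character(gs)
  present <- intersect(genes, rownames(stats_matrix))
  if (!length(present))
    stop("no gene of the set is present in the statistic matrix")
  if (length(present) < length(genes))
    warning("dropped ", length(genes) - length(present),
            " set genes absent from the matrix")
  p <- nrow(stats_matrix)
  k <- length(present)
  if (p <= k) stop("gene set covers the whole matrix; no background genes")
  in_set <- rownames(stats_matrix) %in% present
  es <- vapply(seq_len(ncol(stats_matrix)), function(j) {
    ord <- order(stats_matrix[, j], decreasing = TRUE)
    rnk <- integer(p); rnk[ord] <- seq_len(p)
    centred <- abs(p / 2 - rnk)
    w <- centred^tau
    inc <- ifelse(in_set, w, 0)
    dec <- ifelse(in_set, 0, 1)
    v <- cumsum(inc[ord]) / sum(w[in_set]) - cumsum(dec[ord]) / (p - k)
    max(c(v, 0)) + min(c(v, 0))
  }, numeric(1))
  stats::setNames(es, colnames(stats_matrix))
}

#' z-transform enrichment scores and call enrichment
#'
#' Cohort-wise z-scoring of the per-sample enrichment statistic (population
#' standard deviation, so the resulting z has mean exactly 0 and sd exactly
#' 1 over the cohort) followed by a threshold call: a sample is enriched
#' when its z exceeds `threshold`. The default 0.35 is the published
#' melanoma-derived cut-off for T-cell-inflamed enrichment; 0.32 also
#' appears in the same literature and can be passed instead.
#'
#' @param es named numeric vector of enrichment scores (>= 2 samples).
#' @param threshold z cut-off (default 0.35).
#' @return data.frame with `sample_id`, `es`, `z`, `enriched`, `threshold`.
#' @export
z_and_call <- function(es, threshold = 0.35) {
  if (length(es) < 2) stop("z-scoring needs at least 2 samples")
  sd_pop <- sqrt(mean((es - mean(es))^2))
  if (sd_pop == 0) stop("enrichment scores have zero variance; cannot z-score")
  z <- (es - mean(es)) / sd_pop
  data.frame(sample_id = names(es), es = unname(es), z = unname(z),
             enriched = unname(z > threshold), threshold = threshold,
             stringsAsFactors = FALSE)
}

#' Score T-cell-inflamed enrichment for a cohort
#'
#' End-to-end single-sample enrichment: kernel-CDF statistic, weighted KS
#' score for the gene set, cohort z-transform, threshold call.
#'
#' @param m expression matrix.
#' @param gs gene set (default the shipped 18-gene T-cell-inflamed list).
#' @param tau rank-weight exponent.
#' @param threshold z cut-off for the enrichment call.
#' @return The [z_and_call()] data.frame.
#' @export
tcia_enrichment <- function(m, gs = tcia_gene_set(), tau = 1, threshold = 0.35) {
  z_and_call(gsva_score(kernel_expression_statistic(m), gs, tau = tau),
             threshold = threshold)
}
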