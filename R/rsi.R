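#' Rank signature genes within each sample
#'
#' For each sample, the signature genes are ranked among themselves in
#' ascending order of expression: the gene with the highest expression gets
#' rank `n` (n = signature size), the lowest gets rank 1. Ties receive
#' average ranks, so the ranks always sum to `n(n+1)/2`.
#'
#' Ranking is confined to the signature genes; the rest of the matrix only
#' serves to locate them. This makes the downstream score invariant under
#' any strictly monotone per-sample transform of expression.
#'
#' @param m expression matrix (genes x samples).
#' @param sig a [weighted_signature()].
#' @return Matrix of ranks (signature genes x samples), rows in signature order.
#' @export
rank_transform <- function(m, sig) {
  validate_expression(m)
  missing_genes <- setdiff(sig$genes, rownames(m))
  if (length(missing_genes))
    stop("signature genes absent from matrix: ", paste(missing_genes, collapse = ", "))
  sub <- m[sig$genes, , drop = FALSE]
  na_cells <- which(is.na(sub), arr.ind = TRUE)
  if (nrow(na_cells))
    stop(sprintf("missing value for signature gene %s in sample %s",
                 rownames(sub)[na_cells[1, 1]], colnames(sub)[na_cells[1, 2]]))
  apply(sub, 2L, rank, ties.method = "average")
}

#' Compute weighted rank scores (RSI for the default signature)
#'
#' The score of a sample is the inner product of its within-signature ranks
#' with the signature coefficients. With the shipped [rsi_signature()] this
#' is the radiosensitivity index: a linear form over ranks 1..10 where a low
#' value indicates high radiosensitivity. The form is unbounded by design;
#' no clipping is applied.
#'
#' @param ranks rank matrix from [rank_transform()] (signature genes x samples).
#' @param sig the [weighted_signature()] used to produce `ranks`.
#' @return Named numeric vector of per-sample scores.
#' @export
compute_rsi <- function(ranks, sig) {
  if (!setequal(rownames(ranks), sig$genes))
    stop("rank matrix rows do not match signature genes")
  drop(sig$coefficients[rownames(ranks)] %*% ranks)
}

#' Score an expression matrix with a weighted rank signature
#'
#' Convenience wrapper: [rank_transform()] then [compute_rsi()] then
#' [stratify()].
#'
#' @param m expression matrix.
#' @param sig signature; defaults to [rsi_signature()].
#' @param threshold stratification cut-off (default 0.46, the published RSI
#'   cut-point).
#' @return A score table: data.frame with `sample_id`, `rsi`, `category`,
#'   `threshold`.
#' @examples
#' m <- matrix(rnorm(10 * 4), 10, 4,
#'             dimnames = list(rsi_signature()$genes, paste0("s", 1:4)))
#' rsi_score(m)
#' @export
rsi_score <- function(m, sig = rsi_signature(), threshold = 0.46) {
  scores <- compute_rsi(rank_transform(m, sig), sig)
  stratify(data.frame(sample_id = colnames(m), rsi = unname(scores),
                      stringsAsFactors = FALSE),
           threshold = threshold)
}

#' Stratify scores at a cut-off
#'
#' Labels samples `RSI-Low` when the score is strictly below the threshold
#' and `RSI-High` otherwise; the threshold used is recorded in the output.
#' The default 0.46 is the published cut-point; 0.3745 has also been used in
#' clinical cohorts and can be passed instead.
#'
#' @param scores data.frame with columns `sample_id` and `rsi` (or a named
#'   numeric vector of scores).
#' @param threshold stratification cut-off.
#' @return data.frame with `sample_id`, `rsi`, `category`, `threshold`.
#' @export
stratify <- function(scores, threshold = 0.46) {
  if (is.numeric(scores) && !is.data.frame(scores))
    scores <- data.frame(sample_id = names(scores), rsi = unname(scores),
                         stringsAsFactors = FALSE)
  if (any(!is.finite(scores$rsi))) stop("non-finite scores cannot be stratified")
  if (!is.finite(threshold)) stop("threshold must be finite")
  scores$category <- ifelse(scores$rsi < threshold, "RSI-Low", "RSI-High")
  scores$threshold <- threshold
  scores
}

#' Cross-platform signature quality-control report
#'
#' Summarises how a rank signature behaves in one or two datasets: per-gene
#' mean and sd of within-sample ranks, the gene-gene Spearman correlation
#' matrix, and the sd of the resulting scores. With two datasets the report
#' also carries the per-gene absolute difference of rank means, a simple
#' transferability diagnostic (rank behaviour should be stable across
#' platforms if the signature ports).
#'
#' @param m1 expression matrix (reference dataset).
#' @param m2 optional second dataset for comparison.
#' @param sig signature; defaults to [rsi_signature()].
#' @return List of class `signature_qc` with per-dataset summaries and, if
#'   `m2` is given, `rank_mean_delta`.
#' @export
qc_signature <- function(m1, m2 = NULL, sig = rsi_signature()) {
  one <- function(m) {
    r <- rank_transform(m, sig)
    scores <- compute_rsi(r, sig)
    list(rank_mean = rowMeans(r),
         rank_sd = apply(r, 1L, stats::sd),
         spearman = stats::cor(t(m[sig$genes, , drop = FALSE]), method = "spearman"),
         score_mean = mean(scores),
         score_sd = stats::sd(scores))
  }
  out <- list(dataset1 = one(m1))
  if (!is.null(m2)) {
    out$dataset2 <- one(m2)
    out$rank_mean_delta <- abs(out$dataset1$rank_mean - out$dataset2$rank_mean)
  }
  structure(out, class = "signature_qc")
}

#' @export
print.signature_qc <- function(x, ...) {
  cat("<signature_qc>\n  per-gene rank means (dataset 1):\n")
  print(round(x$dataset1$rank_mean, 3))
  cat(sprintf("  score sd: %.4f\n", x$dataset1$score_sd))
  if (!is.null(x$rank_mean_delta)) {
    cat("  max |rank-mean delta| across datasets:",
        format(max(x$rank_mean_delta), digits = 4), "\n")
  }
  invisible(x)
}
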