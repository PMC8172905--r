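#' Read an expression matrix
#'
#' Reads a genes-x-samples expression table. The first column holds gene or
#' probe identifiers; the remaining columns are samples. Values are expected
#' on a log-like continuous scale (e.g. log2(RSEM + 1)); non-numeric cells
#' become `NA`.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"csv"`, `"gct"`. `"auto"` picks by file
#'   extension (`.gct` -> gct, `.csv` -> csv, otherwise tsv).
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gct = "gct", csv = "csv", "tsv")
  }
  if (format == "gct") {
    hdr <- readLines(path, n = 2L)
    if (!grepl("^#1\\.2", hdr[1])) stop("not a GCT 1.2 file: ", path)
    dims <- as.integer(strsplit(hdr[2], "\t")[[1]][1:2])
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    # GCT carries Name + Description before the sample columns
    ids <- as.character(df[[1]])
    check_sample_ids(colnames(df)[-(1:2)])
    df <- df[, -(1:2), drop = FALSE]
    if (nrow(df) != dims[1] || ncol(df) != dims[2])
      stop("GCT size line disagrees with table: declared ",
           dims[1], "x", dims[2], ", found ", nrow(df), "x", ncol(df))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE,
                            quote = "\"")
    ids <- as.character(df[[1]])
    check_sample_ids(colnames(df)[-1])
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  suppressWarnings(storage.mode(m) <- "double")   # non-numeric cells become NA
  rownames(m) <- ids
  validate_expression(m)
  m
}

#' Write an expression matrix
#'
#' @param m numeric matrix (genes x samples) with dimnames.
#' @param path output path.
#' @param format `"tsv"`, `"csv"` or `"gct"` (GCT 1.2).
#' @param comment optional one-line provenance comment (tsv/csv only).
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("tsv", "csv", "gct"),
                             comment = NULL) {
  format <- match.arg(format)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    df <- data.frame(Name = rownames(m), Description = rownames(m),
                     m, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

check_sample_ids <- function(ids) {
  # data.frame subsetting silently repairs duplicated names, so the check
  # must run on the raw header
  if (anyDuplicated(ids))
    stop("duplicate sample identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  invisible(ids)
}

validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene rownames and sample colnames")
  all_na <- colSums(!is.na(m)) == 0L
  if (ncol(m) > 0 && any(all_na))
    stop("samples with all-missing values: ",
         paste(colnames(m)[all_na], collapse = ", "))
  invisible(m)
}

#' Collapse probe-level rows to gene level
#'
#' Multiple probes mapping to the same gene are collapsed to the per-sample
#' maximum expression value. Missing cells are excluded from the maxima; a
#' gene whose probes are all missing for a sample stays `NA` there.
#'
#' @param m numeric matrix with probe rownames.
#' @param probe_map named character vector: `names()` are probe ids, values
#'   are gene symbols (many-to-one).
#' @param on_missing what to do with probes absent from `probe_map`:
#'   `"error"` (default) or `"drop"`.
#' @return Gene-level matrix, rows ordered by first appearance of each gene.
#' @export
collapse_probes <- function(m, probe_map, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  probes <- rownames(m)
  unmapped <- setdiff(probes, names(probe_map))
  if (length(unmapped)) {
    if (on_missing == "error")
      stop("probes absent from probe map: ", paste(utils::head(unmapped, 5), collapse = ", "),
           if (length(unmapped) > 5) " ..." else "")
    m <- m[setdiff(probes, unmapped), , drop = FALSE]
    probes <- rownames(m)
  }
  genes <- unname(probe_map[probes])
  gene_order <- unique(genes)
  out <- matrix(NA_real_, nrow = length(gene_order), ncol = ncol(m),
                dimnames = list(gene_order, colnames(m)))
  for (g in gene_order) {
    rows <- m[genes == g, , drop = FALSE]
    out[g, ] <- apply(rows, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) max(v) else NA_real_
    })
  }
  out
}
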