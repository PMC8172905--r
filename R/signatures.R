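#' Weighted gene signature
#'
#' A weighted signature is an ordered set of gene symbols with one real
#' linear coefficient per gene. Scores are computed as the weighted sum of
#' within-sample ranks of the signature genes (see [compute_rsi()]).
#'
#' @param genes character vector of unique gene symbols.
#' @param coefficients numeric vector of per-gene weights, same length.
#' @param name optional signature name.
#' @return An object of class `weighted_signature`.
#' @export
weighted_signature <- function(genes, coefficients, name = "signature") {
  genes <- as.character(genes)
  coefficients <- as.numeric(coefficients)
  if (length(genes) != length(coefficients))
    stop("genes and coefficients must have equal length")
  if (anyDuplicated(genes))
    stop("signature genes must be unique")
  if (any(!is.finite(coefficients)))
    stop("coefficients must be finite")
  structure(
    list(name = name, genes = genes, coefficients = stats::setNames(coefficients, genes)),
    class = "weighted_signature"
  )
}

#' @export
print.weighted_signature <- function(x, ...) {
  cat(sprintf("<weighted_signature> %s: %d genes\n", x$name, length(x$genes)))
  print(x$coefficients)
  invisible(x)
}

#' The ten-gene radiosensitivity index (RSI) signature
#'
#' Returns the published rank-based RSI signature: ten genes with the
#' linear coefficients applied to within-sample ranks (1 = lowest
#' expression among the ten, 10 = highest). A low RSI corresponds to high
#' radiosensitivity (the score proxies the surviving fraction at 2 Gy).
#'
#' @return A [weighted_signature()] with the 10 RSI genes.
#' @examples
#' sig <- rsi_signature()
#' sum(sig$coefficients) * 5.5  # score of a fully tied sample
#' @export
rsi_signature <- function() {
  weighted_signature(
    genes = c("AR", "JUN", "STAT1", "PRKCB", "RELA",
              "ABL1", "SUMO1", "CDK1", "HDAC1", "IRF1"),
    coefficients = c(-0.0098009, 0.0128283, 0.0254552, -0.0017589, -0.0038171,
                     0.1070213, -0.0002509, -0.0092431, -0.0204469, -0.0441683),
    name = "RSI"
  )
}

#' Default legacy-symbol alias table
#'
#' Maps the legacy gene symbols used in the radiosensitivity literature to
#' canonical HGNC symbols. Only the aliases that actually occur around the
#' RSI signature are shipped; extend with your own named vector if needed.
#'
#' @return Named character vector: `names()` are legacy symbols, values are
#'   canonical symbols.
#' @export
default_alias_table <- function() {
  c("c-JUN" = "JUN",
    "PKC"   = "PRKCB",
    "Rel A" = "RELA",
    "RELA/p65" = "RELA",
    "cABL"  = "ABL1",
    "c-Abl" = "ABL1",
    "CD8"   = "CD8A",
    "PD1"   = "PDCD1",
    "PDL1"  = "CD274")
}

#' Replace legacy gene symbols with canonical ones
#'
#' Unknown symbols pass through unchanged with a warning; known aliases are
#' rewritten. The mapping must be a function (each legacy symbol maps to
#' exactly one canonical symbol).
#'
#' @param names character vector of gene symbols.
#' @param alias_table named character vector (legacy -> canonical); defaults
#'   to [default_alias_table()].
#' @param warn warn on symbols found neither as alias nor as canonical value.
#' @return Character vector of canonical symbols, same length and order.
#' @export
canonicalise_genes <- function(names, alias_table = default_alias_table(), warn = TRUE) {
  names <- as.character(names)
  hit <- names %in% base::names(alias_table)
  out <- names
  out[hit] <- unname(alias_table[names[hit]])
  if (warn) {
    known <- c(unname(alias_table), rsi_signature()$genes, tcia_gene_set()$genes)
    unknown <- setdiff(names[!hit], known)
    if (length(unknown))
      warning("symbols passed through unchanged: ", paste(unique(unknown), collapse = ", "))
  }
  out
}

#' The 18-gene T-cell-inflamed gene set
#'
#' Loads the T-cell-inflamed activity (TCIA) gene set shipped with the
#' package: the 18-gene T-cell-inflamed expression profile associated with
#' response to PD-1 blockade. It shares one gene (STAT1) with the RSI
#' signature. The list is configuration, not code: pass `path` to use an
#' alternative single-column text file.
#'
#' @param path optional path to a plain-text file, one gene symbol per line.
#' @return A `gene_set`: list with `name` and `genes`.
#' @export
tcia_gene_set <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tcia_genes.txt", package = "radsens", mustWork = TRUE)
  genes <- readLines(path)
  genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
  gene_set("TCIA", genes)
}

#' Construct a gene set
#'
#' @param name set name.
#' @param genes character vector of at least two unique gene symbols.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene set members must be unique")
  if (length(genes) < 2) stop("a gene set needs at least 2 genes")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 4) stop("malformed GMT line: ", substr(l, 1, 40))
    gene_set(f[1], unique(f[-(1:2)]))
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}
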