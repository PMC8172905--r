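#' LM22-style immune cell type names
#'
#' The 22 cell-type columns used by the synthetic immune-fraction table,
#' matching the naming of the standard 22-type leukocyte deconvolution
#' output (only `Macrophages.M1` / `Macrophages.M2` are consumed downstream).
#' @return Character vector of length 22.
#' @export
immune_cell_types <- function() {
  c("B.cells.naive", "B.cells.memory", "Plasma.cells",
    "T.cells.CD8", "T.cells.CD4.naive", "T.cells.CD4.memory.resting",
    "T.cells.CD4.memory.activated", "T.cells.follicular.helper",
    "T.cells.regulatory", "T.cells.gamma.delta",
    "NK.cells.resting", "NK.cells.activated",
    "Monocytes", "Macrophages.M0", "Macrophages.M1", "Macrophages.M2",
    "Dendritic.cells.resting", "Dendritic.cells.activated",
    "Mast.cells.resting", "Mast.cells.activated",
    "Eosinophils", "Neutrophils")
}

#' Default C2 shift pattern over the RSI genes
#'
#' Signed multipliers (in sd units, scaled by `delta_rsi`) applied to the
#' five classifier genes in IFN-gamma-dominant (C2) samples. JUN, STAT1,
#' CDK1 and IRF1 are shifted up — these are the genes reported higher in
#' radiosensitive (RSI-Low) tumours — while ABL1, which carries the dominant
#' positive rank coefficient, is shifted down. This calibration guarantees
#' that C2 samples have lower mean RSI, the direction the analysis assumes;
#' see `analysis/00_calibrate_direction.R` for the derivation.
#' @return Named numeric vector over the 10 RSI genes.
#' @export
default_c2_pattern <- function() {
  sig <- rsi_signature()
  pattern <- stats::setNames(numeric(length(sig$genes)), sig$genes)
  pattern[c("JUN", "STAT1", "CDK1", "IRF1")] <- 1
  pattern["ABL1"] <- -1
  pattern
}

#' Synthetic-cohort configuration
#'
#' Bundles and validates the generative parameters for [generate_cohort()].
#' Defaults emulate a mid-sized bulk-expression cohort: six immune subtypes
#' with C1/C2 dominant, a 1.5-sd expression shift on the five classifier
#' genes and on the T-cell-inflamed genes in C2 samples, Dirichlet immune
#' fractions whose M1 component grows as RSI falls below the 0.46 cut-off,
#' and exponential survival with a doubled hazard in the RSI-High group.
#'
#' @param n_samples cohort size.
#' @param n_background_genes uninformative genes added to the matrix.
#' @param subtype_props named proportions over C1..C6 (must sum to 1).
#' @param delta_rsi C2 shift magnitude (sd units) applied via `c2_pattern`.
#' @param c2_pattern signed per-RSI-gene multipliers (see
#'   [default_c2_pattern()]).
#' @param delta_tcia C2 shift (sd units) on the T-cell-inflamed genes.
#' @param noise_sd per-gene residual sd of log-expression.
#' @param dirichlet_alpha concentration vector for the 22 immune fractions.
#' @param beta_m1 M1-RSI coupling slope: mass added to the M1 fraction per
#'   unit of (theta_rsi - RSI) for samples below `theta_rsi`.
#' @param theta_rsi RSI stratification cut-off used by the coupling and the
#'   latent survival group.
#' @param baseline_rate exponential baseline event rate (per time unit).
#' @param hazard_ratio hazard multiplier for the RSI-High latent group.
#' @param censoring_rate exponential censoring rate.
#' @param seed RNG seed (mandatory; recorded in all outputs).
#' @return Validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 600,
                             n_background_genes = 500,
                             subtype_props = c(C1 = 0.35, C2 = 0.25, C3 = 0.15,
                                               C4 = 0.10, C5 = 0.05, C6 = 0.10),
                             delta_rsi = 1.5,
                             c2_pattern = default_c2_pattern(),
                             delta_tcia = 1.5,
                             noise_sd = 1,
                             dirichlet_alpha = stats::setNames(rep(2, 22),
                                                               immune_cell_types()),
                             beta_m1 = 0.5,
                             theta_rsi = 0.46,
                             baseline_rate = 0.1,
                             hazard_ratio = 2,
                             censoring_rate = 0.05,
                             seed) {
  if (missing(seed)) stop("a seed is required")
  if (abs(sum(subtype_props) - 1) > 1e-8) stop("subtype proportions must sum to 1")
  if (!setequal(names(subtype_props), paste0("C", 1:6)))
    stop("subtype proportions must be named C1..C6")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (length(dirichlet_alpha) != 22 || any(dirichlet_alpha <= 0))
    stop("dirichlet_alpha must be 22 positive concentrations")
  if (baseline_rate <= 0 || hazard_ratio <= 0 || censoring_rate < 0)
    stop("rates must be positive (censoring_rate may be 0)")
  if (beta_m1 < 0) stop("beta_m1 must be >= 0")
  sig_genes <- rsi_signature()$genes
  if (!all(names(c2_pattern) == sig_genes))
    stop("c2_pattern must be named by the 10 RSI genes, in signature order")
  structure(list(
    n_samples = n_samples, n_background_genes = n_background_genes,
    subtype_props = subtype_props[paste0("C", 1:6)],
    delta_rsi = delta_rsi, c2_pattern = c2_pattern, delta_tcia = delta_tcia,
    noise_sd = noise_sd, dirichlet_alpha = dirichlet_alpha,
    beta_m1 = beta_m1, theta_rsi = theta_rsi,
    baseline_rate = baseline_rate, hazard_ratio = hazard_ratio,
    censoring_rate = censoring_rate, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the model described in [synthetic_config()]:
#' \itemize{
#'   \item log-expression: per-gene baseline mean + Gaussian noise; C2
#'     samples receive `delta_rsi * c2_pattern` (sd units) on the RSI genes
#'     and `+delta_tcia` on the T-cell-inflamed genes;
#'   \item immune fractions: Dirichlet draws, then the M1 component gains
#'     `beta_m1 * max(0, theta_rsi - RSI)` mass and the vector is
#'     renormalised (stays on the simplex);
#'   \item survival: exponential with hazard `baseline_rate *
#'     hazard_ratio^(RSI >= theta_rsi)`, independent exponential censoring.
#' }
#' Regeneration from the same config (same seed) is bitwise identical.
#'
#' @param config a [synthetic_config()].
#' @return `synthetic_cohort` list: `expression` (matrix), `subtypes`,
#'   `fractions`, `survival` (data.frames keyed by `sample_id`), `rsi`
#'   (score table), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  sig <- rsi_signature()
  tcia <- tcia_gene_set()$genes
  genes <- unique(c(sig$genes, tcia,
                    sprintf("BG%04d", seq_len(config$n_background_genes))))
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  subtype <- sample(names(config$subtype_props), n, replace = TRUE,
                    prob = config$subtype_props)
  # signature genes share a common baseline mean so that within-sample ranks
  # are driven by per-sample noise and the subtype effect; a wide spread of
  # baseline means would freeze the rank ordering, collapsing score variance
  # and overriding the calibrated C2 direction. Background genes vary freely.
  mu <- stats::rnorm(length(genes), mean = 6, sd = 2)
  mu[seq_len(length(unique(c(sig$genes, tcia))))] <- 6
  m <- matrix(stats::rnorm(length(genes) * n, mean = mu, sd = config$noise_sd),
              nrow = length(genes), ncol = n,
              dimnames = list(genes, samples))
  is_c2 <- subtype == "C2"
  if (any(is_c2)) {
    shift_rsi <- config$delta_rsi * config$noise_sd * config$c2_pattern
    m[sig$genes, is_c2] <- m[sig$genes, is_c2] + shift_rsi
    m[tcia, is_c2] <- m[tcia, is_c2] + config$delta_tcia * config$noise_sd
  }

  rsi <- rsi_score(m, sig, threshold = config$theta_rsi)

  # Dirichlet via normalised gamma draws
  g <- matrix(stats::rgamma(n * 22, shape = config$dirichlet_alpha, rate = 1),
              nrow = 22, ncol = n)
  frac <- t(g) / colSums(g)
  colnames(frac) <- names(config$dirichlet_alpha)
  m1_boost <- config$beta_m1 * pmax(0, config$theta_rsi - rsi$rsi)
  frac[, "Macrophages.M1"] <- frac[, "Macrophages.M1"] + m1_boost
  frac <- frac / rowSums(frac)
  fractions <- data.frame(sample_id = samples, frac, check.names = FALSE,
                          stringsAsFactors = FALSE)

  high <- rsi$rsi >= config$theta_rsi
  hazard <- config$baseline_rate * config$hazard_ratio^high
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- if (config$censoring_rate > 0)
    stats::rexp(n, rate = config$censoring_rate) else rep(Inf, n)
  survival_tab <- data.frame(
    sample_id = samples,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )

  structure(list(
    expression = m,
    subtypes = data.frame(sample_id = samples, subtype = subtype,
                          stringsAsFactors = FALSE),
    fractions = fractions,
    survival = survival_tab,
    rsi = rsi,
    config = config
  ), class = "synthetic_cohort")
}

#' Ground-truth table for a synthetic cohort
#'
#' One row per sample with the latent generating quantities, for joining
#' against pipeline outputs when scoring recovery.
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame `sample_id`, `subtype`, `is_c2`, `rsi`, `latent_group`,
#'   `hazard`, `seed`.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$config
  high <- cohort$rsi$rsi >= cfg$theta_rsi
  data.frame(
    sample_id = cohort$subtypes$sample_id,
    subtype = cohort$subtypes$subtype,
    is_c2 = cohort$subtypes$subtype == "C2",
    rsi = cohort$rsi$rsi,
    latent_group = ifelse(high, "RSI-High", "RSI-Low"),
    hazard = cfg$baseline_rate * cfg$hazard_ratio^high,
    seed = cfg$seed,
    stringsAsFactors = FALSE
  )
}

#' Split gene rows into synthetic probes
#'
#' Testing aid for probe collapsing: each gene row is expanded into
#' `n_probes` probe rows where one probe carries the original value and the
#' others are shifted down by positive noise, so collapsing by per-sample
#' maximum recovers the original matrix exactly.
#'
#' @param m gene-level expression matrix.
#' @param n_probes probes per gene.
#' @param seed RNG seed.
#' @return List with `matrix` (probe-level) and `probe_map` (named vector
#'   probe -> gene).
#' @export
split_probes <- function(m, n_probes = 2, seed = 1) {
  set.seed(seed)
  probe_ids <- as.vector(t(outer(rownames(m), seq_len(n_probes),
                                 function(g, k) paste0(g, "_p", k))))
  pm <- matrix(NA_real_, nrow = length(probe_ids), ncol = ncol(m),
               dimnames = list(probe_ids, colnames(m)))
  for (i in seq_len(nrow(m))) {
    base_row <- (i - 1L) * n_probes
    pm[base_row + 1L, ] <- m[i, ]
    for (k in seq_len(n_probes - 1L))
      pm[base_row + 1L + k, ] <- m[i, ] - abs(stats::rnorm(ncol(m)))
  }
  list(matrix = pm,
       probe_map = stats::setNames(rep(rownames(m), each = n_probes), probe_ids))
}
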