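#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain in one validated object. All
#' thresholds are surfaced here — nothing is hard-coded downstream — because
#' the two headline cut-offs are empirical and alternatives circulate in the
#' literature (RSI 0.46 vs 0.3745; enrichment z 0.35 vs 0.32).
#'
#' @param theta_rsi RSI stratification cut-off (default 0.46).
#' @param theta_z enrichment z cut-off (default 0.35).
#' @param tau enrichment rank-weight exponent.
#' @param n_trees forest size for the C2 classifier.
#' @param folds cross-validation folds.
#' @param minprop minimum group proportion for the survival cutpoint scan.
#' @param seed RNG seed for the stochastic stages (mandatory).
#' @param outdir optional output directory; when set, each stage writes its
#'   TSV/JSON artifact there.
#' @param stages subset of `c("score", "enrich", "associate", "classify",
#'   "survival")` to run.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(theta_rsi = 0.46, theta_z = 0.35, tau = 1,
                            n_trees = 500, folds = 5, minprop = 0.1,
                            seed, outdir = NULL,
                            stages = c("score", "enrich", "associate",
                                       "classify", "survival")) {
  if (missing(seed)) stop("a seed is required")
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(is.finite(theta_rsi), is.finite(theta_z))
  structure(list(theta_rsi = theta_rsi, theta_z = theta_z, tau = tau,
                 n_trees = n_trees, folds = folds, minprop = minprop,
                 seed = as.integer(seed), outdir = outdir, stages = stages),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on one cohort:
#' \enumerate{
#'   \item \strong{score}: rank-based RSI per sample, stratified at
#'     `theta_rsi`;
#'   \item \strong{enrich}: single-sample T-cell-inflamed enrichment,
#'     z-transformed and called at `theta_z`; when both stages run, the
#'     enrichment-by-RSI contingency table is produced;
#'   \item \strong{associate}: log2(M1/M2) polarisation, Spearman matrix of
#'     RSI against enrichment and polarisation, and RSI group comparisons
#'     across immune subtypes;
#'   \item \strong{classify}: Gini importance of the RSI genes for C2 vs
#'     non-C2, above-mean feature selection, cross-validated forest
#'     classifier, and the Youden cutpoint of RSI for C2;
#'   \item \strong{survival}: log-rank between RSI strata, univariate Cox
#'     hazard ratio, and the maximally selected survival cutpoint.
#' }
#' A stage whose inputs are absent is skipped with a note in the manifest.
#'
#' @param inputs a `synthetic_cohort`, or a list with elements `expression`
#'   (matrix), and optionally `fractions`, `subtypes`, `survival`
#'   (data.frames keyed by `sample_id`).
#' @param config a [pipeline_config()].
#' @return `pipeline_run` list: one element per executed stage plus
#'   `manifest` (config snapshot, seed, stage status, output files and
#'   checksums).
#' @export
run_pipeline <- function(inputs, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(inputs, "synthetic_cohort"))
    inputs <- list(expression = inputs$expression, fractions = inputs$fractions,
                   subtypes = inputs$subtypes, survival = inputs$survival)
  m <- inputs$expression
  validate_expression(m)
  out <- list()
  status <- list()
  files <- character(0)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(df, name) {
    if (is.null(outdir)) return(invisible(NULL))
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
    invisible(path)
  }

  # scoring underlies every later stage, so it is computed whenever needed;
  # it only becomes an output when the score stage itself is enabled
  score_tab <- NULL
  if (length(intersect(c("score", "associate", "classify", "survival"),
                       config$stages)))
    score_tab <- rsi_score(m, threshold = config$theta_rsi)
  if ("score" %in% config$stages) {
    out$score <- score_tab
    emit(out$score, "rsi_scores.tsv")
    status$score <- "ok"
  }

  if ("enrich" %in% config$stages) {
    out$enrich <- tcia_enrichment(m, tau = config$tau,
                                  threshold = config$theta_z)
    emit(out$enrich, "tcia_enrichment.tsv")
    status$enrich <- "ok"
    if (!is.null(score_tab)) {
      out$contingency <- table(
        enrichment = ifelse(out$enrich$enriched, "E", "NE"),
        rsi = score_tab$category
      )
      emit(as.data.frame(out$contingency), "enrichment_by_rsi.tsv")
    }
  }

  if ("associate" %in% config$stages) {
    if (is.null(inputs$fractions)) {
      status$associate <- "skipped: no immune fractions"
    } else {
      pol <- m1_m2_log_ratio(inputs$fractions)
      assoc_tab <- data.frame(sample_id = score_tab$sample_id,
                              rsi = score_tab$rsi,
                              stringsAsFactors = FALSE)
      if (!is.null(out$enrich)) assoc_tab$tcia_z <- out$enrich$z
      assoc_tab <- merge(assoc_tab, pol$ratios, by = "sample_id",
                         all.x = TRUE, sort = FALSE)
      sp <- spearman_matrix(assoc_tab[, "rsi", drop = FALSE],
                            assoc_tab[, setdiff(names(assoc_tab),
                                                c("sample_id", "rsi")),
                                      drop = FALSE])
      out$associate <- list(polarisation = pol, spearman = sp,
                            table = assoc_tab)
      if (!is.null(inputs$subtypes)) {
        st <- inputs$subtypes$subtype[match(score_tab$sample_id,
                                            inputs$subtypes$sample_id)]
        out$associate$c2_vs_rest <- group_compare(
          score_tab$rsi, factor(ifelse(st == "C2", "C2", "non-C2")))
        if (length(unique(st)) >= 2 && all(table(st) >= 2))
          out$associate$anova_subtypes <- anova_across_groups(score_tab$rsi, st)
      }
      emit(assoc_tab, "association_table.tsv")
      status$associate <- sprintf("ok (%d samples excluded from M1/M2 ratio)",
                                  pol$n_excluded)
    }
  }

  if ("classify" %in% config$stages) {
    if (is.null(inputs$subtypes)) {
      status$classify <- "skipped: no subtype labels"
    } else {
      sig <- rsi_signature()
      st <- inputs$subtypes$subtype[match(colnames(m),
                                          inputs$subtypes$sample_id)]
      y <- factor(ifelse(st == "C2", "C2", "nonC2"),
                  levels = c("nonC2", "C2"))
      X <- t(m[sig$genes, , drop = FALSE])
      fi <- gini_importance(X, y, n_trees = config$n_trees,
                            seed = config$seed)
      sel <- select_features(fi)
      if (length(sel) < 1) sel <- fi$gene[order(-fi$mdg)][1:2]
      rep_ <- train_eval(X[, sel, drop = FALSE], y, k = config$folds,
                         n_trees = config$n_trees, seed = config$seed)
      cut <- youden_cutpoint(score_tab$rsi, y)
      out$classify <- list(importance = fi, selected = sel, report = rep_,
                           rsi_cutpoint = cut)
      emit(fi, "gini_importance.tsv")
      emit(rep_$roc, "roc_points.tsv")
      if (!is.null(outdir)) {
        path <- file.path(outdir, "classifier_report.json")
        jsonlite::write_json(list(
          selected = sel, accuracy = rep_$accuracy,
          accuracy_ci = rep_$accuracy_ci, auc = rep_$auc,
          seed = rep_$seed, scheme = rep_$scheme,
          rsi_cutpoint = cut$value, cut_direction = cut$direction
        ), path, auto_unbox = TRUE, digits = NA)
        files <- c(files, path)
      }
      status$classify <- "ok"
    }
  }

  if ("survival" %in% config$stages) {
    if (is.null(inputs$survival)) {
      status$survival <- "skipped: no survival records"
    } else {
      sv <- inputs$survival[match(score_tab$sample_id,
                                  inputs$survival$sample_id), ]
      sv$group <- score_tab$category
      out$survival <- list(
        km = lapply(split(sv, sv$group), km_fit),
        logrank = logrank_test(sv),
        cox = cox_univariate(sv, as.integer(sv$group == "RSI-High")),
        cutpoint = surv_cutpoint(sv, score_tab$rsi,
                                 minprop = config$minprop)
      )
      emit(sv, "survival_groups.tsv")
      status$survival <- "ok"
    }
  }

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    version = as.character(utils::packageVersion("radsens")),
    stages = status,
    files = files,
    checksums = if (length(files)) as.list(tools::md5sum(files)) else list()
  )
  out$manifest <- manifest
  structure(out, class = "pipeline_run")
}

#' Human-readable pipeline report
#'
#' Renders a completed [run_pipeline()] result as markdown: score
#' distribution, enrichment fraction, contingency table, classifier and
#' survival summaries, and exclusion counts.
#'
#' @param run a `pipeline_run`.
#' @return Character vector of markdown lines.
#' @export
pipeline_report <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  ln <- c("# Pipeline report", "",
          sprintf("Seed: %d. Stages: %s.", run$manifest$seed,
                  paste(names(run$manifest$stages), collapse = ", ")))
  if (!is.null(run$score)) {
    q <- stats::quantile(run$score$rsi, c(0.25, 0.5, 0.75))
    ln <- c(ln, "", "## RSI scores",
            sprintf("n = %d; median %.4f (IQR %.4f-%.4f); %d RSI-Low / %d RSI-High at threshold %.4g.",
                    nrow(run$score), q[2], q[1], q[3],
                    sum(run$score$category == "RSI-Low"),
                    sum(run$score$category == "RSI-High"),
                    run$score$threshold[1]))
  }
  if (!is.null(run$enrich)) {
    ln <- c(ln, "", "## T-cell-inflamed enrichment",
            sprintf("%.1f%% of samples enriched at z > %.3g.",
                    100 * mean(run$enrich$enriched), run$enrich$threshold[1]))
    if (!is.null(run$contingency)) {
      ct <- run$contingency
      ln <- c(ln, "", "Enrichment by RSI stratum:",
              paste0("  ", paste(colnames(ct), collapse = " / "), ":"),
              paste0("  E: ", paste(ct["E", ], collapse = " / ")),
              paste0("  NE: ", paste(ct["NE", ], collapse = " / ")))
    }
  }
  if (!is.null(run$associate)) {
    sp <- run$associate$spearman
    for (cn in colnames(sp$rho))
      ln <- c(ln, sprintf("Spearman rho(RSI, %s) = %.3f (p = %.3g, n = %d).",
                          cn, sp$rho["rsi", cn], sp$p["rsi", cn],
                          sp$n["rsi", cn]))
    ln <- c(ln, sprintf("Samples excluded from the M1/M2 ratio: %d.",
                        run$associate$polarisation$n_excluded))
  }
  if (!is.null(run$classify)) {
    r <- run$classify$report
    ln <- c(ln, "", "## C2 classifier",
            sprintf("Selected genes: %s.", paste(run$classify$selected,
                                                 collapse = ", ")),
            sprintf("Accuracy %.3f (95%% CI %.3f-%.3f); AUC %.4f (%s).",
                    r$accuracy, r$accuracy_ci[1], r$accuracy_ci[2], r$auc,
                    r$scheme),
            sprintf("Youden RSI cutpoint for C2: %.4f (direction %s).",
                    run$classify$rsi_cutpoint$value,
                    run$classify$rsi_cutpoint$direction))
  }
  if (!is.null(run$survival)) {
    cx <- run$survival$cox
    ln <- c(ln, "", "## Survival",
            sprintf("Log-rank chi-square %.2f (p = %.3g).",
                    run$survival$logrank$chisq, run$survival$logrank$p),
            sprintf("Cox HR (RSI-High vs RSI-Low) %.3f (95%% CI %.3f-%.3f).",
                    cx$hr, cx$ci[1], cx$ci[2]),
            sprintf("Optimal survival cutpoint %.4f.",
                    run$survival$cutpoint$value))
  }
  incomplete <- names(run$manifest$stages)[
    !vapply(run$manifest$stages, function(s) identical(substr(s, 1, 2), "ok"),
            logical(1))]
  if (length(incomplete))
    ln <- c(ln, "", sprintf("Partial run: stage(s) %s did not complete.",
                            paste(incomplete, collapse = ", ")))
  ln
}
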