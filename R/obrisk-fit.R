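# The end-to-end model fit: greedy SNP selection -> genetic risk score
# -> gene-expression feature selection -> integrated linear model (and
# optionally the cross-validated weight-status classifier).

#' Fit the integrated obesity-risk model on a cohort
#'
#' Runs the full framework on an aligned cohort:
#' 1. greedy backward SNP exclusion maximizing the GRS-BMI correlation
#'    ([greedy_exclude()]);
#' 2. the genetic risk score over the retained SNPs ([compute_grs()]);
#' 3. the genome-wide BMI-association scan with BH correction and the
#'    greedy independence filter ([scan_genes()], [select_independent()]);
#' 4. ordinary least squares models of BMI on the admitted genes, with
#'    and without the risk score ([fit_bmi_model()]), plus the pairwise
#'    interaction scan;
#' 5. optionally, the cross-validated SVM for binary weight status
#'    ([cv_classify_weight_status()]).
#'
#' The expression layer may be absent, in which case only the SNP path
#' (trace + risk score) is fitted.
#'
#' @param cohort An aligned `cohort` (see [align_samples()]).
#' @param method Correlation method used for both selection stages.
#' @param adj_p_threshold,inter_gene_p_threshold Gene-selection cutoffs
#'   (see [select_independent()]).
#' @param tol,min_included Greedy-exclusion controls (see
#'   [greedy_exclude()]).
#' @param with_grs Include the risk score as a model predictor.
#' @param prune_insignificant Backward-prune insignificant predictors in
#'   the linear model (default `FALSE`).
#' @param classify Also fit the cross-validated classifier.
#' @param n_folds,kernel,seed Classifier controls.
#' @param bmi_threshold Overweight cutoff for the classifier.
#' @return An object of class `obrisk_fit` with components `trace`,
#'   `grs`, `scan`, `features`, `model` (the integrated linear model),
#'   `model_no_grs`, `interactions`, `classification` (or `NULL`),
#'   `cohort_n`, and the call settings.
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 120, n_genes = 50,
#'                                   seed = 7))
#' fit <- obrisk_fit(sim$cohort, seed = 7)
#' print(fit)
#' @export
obrisk_fit <- function(cohort, method = c("pearson", "spearman"),
                       adj_p_threshold = 0.05,
                       inter_gene_p_threshold = 0.05,
                       tol = 0, min_included = 1L,
                       with_grs = TRUE, prune_insignificant = FALSE,
                       classify = TRUE, n_folds = 5L,
                       kernel = c("linear", "rbf", "polynomial"),
                       seed = 1L, bmi_threshold = 25) {
  stopifnot(inherits(cohort, "cohort"))
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  if (is.null(cohort$genotypes) || is.null(cohort$phenotype)) {
    stop("cohort needs genotype and phenotype layers", call. = FALSE)
  }
  bmi <- cohort$phenotype$bmi

  trace <- greedy_exclude(cohort$genotypes, bmi, method = method,
                          min_included = min_included, tol = tol)
  grs <- compute_grs(cohort$genotypes, trace$final_included)

  scan <- NULL
  features <- NULL
  model <- model_no_grs <- interactions <- classification <- NULL
  if (!is.null(cohort$expression)) {
    scan <- scan_genes(cohort$expression, bmi, method = method)
    features <- select_independent(scan, cohort$expression,
                                   adj_p_threshold = adj_p_threshold,
                                   inter_gene_p_threshold =
                                     inter_gene_p_threshold)
    if (length(features$gene_ids)) {
      model_no_grs <- fit_bmi_model(cohort, features,
                                    prune_insignificant =
                                      prune_insignificant)
      model <- if (with_grs) {
        fit_bmi_model(cohort, features, grs = grs,
                      prune_insignificant = prune_insignificant)
      } else {
        model_no_grs
      }
      n_preds <- length(model$terms) - 1L
      if (n_preds >= 2L) {
        interactions <- interaction_scan(
          cohort, setdiff(model$terms, c("(Intercept)", "grs")),
          grs = if ("grs" %in% model$terms) grs)
      }
      if (classify) {
        classification <- cv_classify_weight_status(
          cohort, features, grs = if (with_grs) grs,
          n_folds = n_folds, kernel = kernel, seed = seed,
          bmi_threshold = bmi_threshold)
      }
    } else {
      warning("no genes admitted; expression models skipped",
              call. = FALSE)
    }
  }

  structure(
    list(trace = trace, grs = grs, scan = scan, features = features,
         model = model, model_no_grs = model_no_grs,
         interactions = interactions, classification = classification,
         cohort_n = length(cohort$sample_ids),
         settings = list(method = method,
                         adj_p_threshold = adj_p_threshold,
                         inter_gene_p_threshold = inter_gene_p_threshold,
                         tol = tol, min_included = min_included,
                         with_grs = with_grs,
                         prune_insignificant = prune_insignificant,
                         n_folds = n_folds, kernel = kernel,
                         seed = seed, bmi_threshold = bmi_threshold)),
    class = "obrisk_fit"
  )
}

#' @export
print.obrisk_fit <- function(x, ...) {
  it <- x$trace$iterations
  cat("integrated obesity-risk fit (", x$settings$method, ", n = ",
      x$cohort_n, ")\n", sep = "")
  cat(sprintf(
    "  SNP selection : %d excluded, %d retained; GRS-BMI r %.3f -> %.3f\n",
    length(x$trace$final_excluded), length(x$trace$final_included),
    it$r[1L], it$r[nrow(it)]))
  if (!is.null(x$features)) {
    cat(sprintf("  genes admitted: %d (%s)\n",
                length(x$features$gene_ids),
                paste(utils::head(x$features$gene_ids, 6L),
                      collapse = ", ")))
  }
  if (!is.null(x$model)) {
    cat(sprintf("  BMI model     : adj R2 = %.3f (without GRS: %.3f)\n",
                x$model$adjusted_r2, x$model_no_grs$adjusted_r2))
  }
  if (!is.null(x$classification)) {
    cat(sprintf("  weight status : %d-fold CV accuracy %.1f%%\n",
                x$classification$n_folds,
                100 * x$classification$accuracy))
  }
  invisible(x)
}

#' @export
summary.obrisk_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$model)) {
    cat("\ncoefficients of the integrated linear model:\n")
    print(summary(object$model))
  }
  invisible(object)
}

#' @export
coef.obrisk_fit <- function(object, ...) {
  if (is.null(object$model)) stop("no linear model in this fit",
                                  call. = FALSE)
  coef(object$model)
}

#' @export
residuals.obrisk_fit <- function(object, ...) {
  if (is.null(object$model)) stop("no linear model in this fit",
                                  call. = FALSE)
  object$model$residuals
}

#' @export
predict.obrisk_fit <- function(object, newdata, ...) {
  if (is.null(object$model)) stop("no linear model in this fit",
                                  call. = FALSE)
  predict(object$model, newdata, ...)
}

#' @export
plot.obrisk_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, if (is.null(x$model)) 1 else 2))
  on.exit(graphics::par(old))
  it <- x$trace$iterations
  graphics::plot(it$n_excluded, it$r, type = "b", pch = 16,
                 xlab = "SNPs excluded",
                 ylab = sprintf("GRS-BMI %s r", x$settings$method),
                 main = "greedy SNP exclusion")
  if (!is.null(x$model)) {
    graphics::plot(x$model$fitted,
                   x$model$fitted + x$model$residuals,
                   xlab = "fitted BMI", ylab = "observed BMI",
                   pch = 16, main = sprintf("adj R2 = %.3f",
                                            x$model$adjusted_r2))
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Run the full pipeline from files and write every artifact
#'
#' File-level front end: reads the SNP panel, genotypes, phenotype and
#' (optionally) expression, applies missingness QC and sample alignment,
#' fits [obrisk_fit()], and writes the intermediate tables (risk scores,
#' selection trace, gene scan, admission log, model summary) plus a
#' machine-readable JSON report to `out_dir`.
#'
#' @param panel_file,genotype_file,phenotype_file,expression_file Input
#'   paths (`expression_file` may be `NULL` for the SNP-only path).
#' @param out_dir Output directory (created if needed).
#' @param max_missing_fraction Genotype missingness QC threshold.
#' @param ... Passed to [obrisk_fit()].
#' @return The `obrisk_fit`, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(panel_file, genotype_file, phenotype_file,
                         expression_file = NULL, out_dir,
                         max_missing_fraction = 0.20, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- read_snp_panel(panel_file)
  geno <- read_genotypes(genotype_file, panel)
  phen <- read_phenotype(phenotype_file)
  expr <- if (!is.null(expression_file)) read_expression(expression_file)

  n_geno_raw <- nrow(geno$dosages)
  qc <- qc_missing_genotypes(geno, max_missing_fraction)
  cohort <- align_samples(genotypes = qc$genotypes, expression = expr,
                          phenotype = phen)
  fit <- obrisk_fit(cohort, ...)

  write_grs(fit$grs, file.path(out_dir, "grs.tsv"))
  write_trace(fit$trace, file.path(out_dir, "selection_trace.tsv"))
  if (!is.null(fit$scan)) {
    write_scan(fit$scan, file.path(out_dir, "gene_scan.tsv"))
    utils::write.table(fit$features$admission_log,
                       file.path(out_dir, "admission_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$model)) {
    utils::write.table(summary(fit$model)$coefficients,
                       file.path(out_dir, "model_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$interactions)) {
    utils::write.table(fit$interactions,
                       file.path(out_dir, "interaction_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  it <- fit$trace$iterations
  report <- list(
    settings = fit$settings,
    samples = list(genotyped = n_geno_raw,
                   removed_by_missingness_qc = length(qc$removed),
                   aligned = fit$cohort_n),
    snp_selection = list(
      baseline_r = it$r[1L],
      optimal_r = it$r[nrow(it)],
      n_excluded = length(fit$trace$final_excluded),
      retained_snps = fit$trace$final_included),
    genes = if (!is.null(fit$features)) list(
      n_significant = nrow(fit$features$admission_log),
      admitted = fit$features$gene_ids),
    model = if (!is.null(fit$model)) list(
      adjusted_r2 = fit$model$adjusted_r2,
      adjusted_r2_without_grs = fit$model_no_grs$adjusted_r2,
      model_p = fit$model$model_p),
    classification = if (!is.null(fit$classification)) list(
      pooled_accuracy = fit$classification$accuracy,
      mean_fold_accuracy = fit$classification$mean_fold_accuracy,
      seed = fit$classification$seed)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}
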