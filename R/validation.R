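# Validation analyses: allele-specific-expression ANOVA (expression of a
# SNP's nearby gene across its genotype groups) and per-SNP BMI
# association by three approaches.

#' Allele-specific-expression scan
#'
#' For each SNP-gene pair in the map, runs a one-way ANOVA of the gene's
#' expression across the SNP's genotype dosage groups (0/1/2). Genotype
#' groups with fewer than two samples are dropped; a pair is testable
#' only if at least two groups remain and the mapped gene is present.
#' BH adjustment is applied across the testable pairs only.
#'
#' @param cohort Aligned `cohort` with genotypes and expression.
#' @param snp_gene_map Named character vector (names = rsIDs, values =
#'   gene IDs) or two-column data frame (rsid, gene).
#' @return Data frame sorted by raw p: `rsid`, `gene_id`, `f_stat`,
#'   `p_value`, `adjusted_p`, `testable`, `reason`.
#' @export
ase_scan <- function(cohort, snp_gene_map) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$expression)) {
    stop("cohort has no expression layer", call. = FALSE)
  }
  if (is.data.frame(snp_gene_map)) {
    snp_gene_map <- stats::setNames(as.character(snp_gene_map[[2L]]),
                                    as.character(snp_gene_map[[1L]]))
  }
  unknown <- setdiff(names(snp_gene_map), cohort$genotypes$panel$rsid)
  if (length(unknown)) {
    stop("rsID(s) not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- vector("list", length(snp_gene_map))
  for (i in seq_along(snp_gene_map)) {
    rsid <- names(snp_gene_map)[i]
    gid <- snp_gene_map[[i]]
    if (!gid %in% rownames(cohort$expression)) {
      rows[[i]] <- data.frame(rsid = rsid, gene_id = gid,
                              f_stat = NA_real_, p_value = NA_real_,
                              testable = FALSE,
                              reason = "gene not in expression matrix",
                              stringsAsFactors = FALSE)
      next
    }
    av <- one_way_anova(cohort$expression[gid, ],
                        cohort$genotypes$dosages[, rsid])
    rows[[i]] <- data.frame(rsid = rsid, gene_id = gid,
                            f_stat = av$f_stat, p_value = av$p_value,
                            testable = av$testable,
                            reason = if (av$testable) NA_character_ else
                              av$reason,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  out$adjusted_p[out$testable] <- bh_adjust(out$p_value[out$testable])
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("rsid", "gene_id", "f_stat", "p_value", "adjusted_p",
          "testable", "reason")]
}

#' Per-SNP BMI association by correlation, regression and ANOVA
#'
#' Tests each panel SNP's dosage against BMI three ways: a correlation
#' test (t-based p), a simple linear regression slope test (algebraically
#' the same p for a single predictor; both reported), and a one-way ANOVA
#' of BMI across genotype groups. Monomorphic SNPs (or SNPs left with
#' fewer than two eligible genotype groups) are untestable and excluded
#' from the BH families; adjustment is done within each approach's
#' family.
#'
#' @param cohort Aligned `cohort` with genotypes and phenotype.
#' @param method Correlation method for the first approach.
#' @return Data frame: `rsid`, `corr_r`, `corr_p`, `regression_p`,
#'   `anova_p`, the three BH-adjusted columns, and `testable`.
#' @export
per_snp_bmi_association <- function(cohort,
                                    method = c("pearson", "spearman")) {
  stopifnot(inherits(cohort, "cohort"))
  method <- match.arg(method)
  bmi <- cohort$phenotype$bmi
  d <- cohort$genotypes$dosages
  rows <- vector("list", ncol(d))
  for (j in seq_len(ncol(d))) {
    dos <- d[, j]
    ok <- !is.na(dos)
    testable <- sum(ok) >= 3L && stats::sd(dos[ok]) > 0
    corr_r <- corr_p <- reg_p <- anova_p <- NA_real_
    if (testable) {
      ct <- correlate(dos[ok], bmi[ok], method = method)
      corr_r <- ct$r
      corr_p <- ct$p_value
      fit <- summary(stats::lm(bmi[ok] ~ dos[ok]))
      reg_p <- fit$coefficients[2L, 4L]
      av <- one_way_anova(bmi[ok], dos[ok])
      anova_p <- if (av$testable) av$p_value else NA_real_
    }
    rows[[j]] <- data.frame(rsid = colnames(d)[j], corr_r = corr_r,
                            corr_p = corr_p, regression_p = reg_p,
                            anova_p = anova_p, testable = testable,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  for (col in c("corr_p", "regression_p", "anova_p")) {
    adj <- paste0(col, "_adjusted")
    out[[adj]] <- NA_real_
    fam <- !is.na(out[[col]])
    out[[adj]][fam] <- bh_adjust(out[[col]][fam])
  }
  rownames(out) <- NULL
  out
}
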