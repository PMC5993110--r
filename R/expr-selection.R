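# Two-stage gene-expression feature selection: a genome-wide scan for
# BMI association with BH correction, then a greedy independence filter
# that keeps only mutually uncorrelated significant genes.

#' Scan every gene for correlation with BMI
#'
#' Computes the chosen correlation coefficient and its t-based p-value
#' between each gene's expression profile and BMI, then Benjamini-
#' Hochberg-adjusts the p-values over the full family of testable genes.
#' Genes with zero expression variance are reported as untestable and
#' excluded from the BH family.
#'
#' @param e Genes x samples numeric matrix, columns aligned with `bmi`.
#' @param bmi Numeric BMI vector, one value per expression column.
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @return An object of class `gene_scan`: list with `results` (data
#'   frame `gene_id`, `r`, `p_value`, `adjusted_p`, ordered by increasing
#'   p, ties broken by gene ID), `untestable` (gene IDs), `method`,
#'   `n_samples`.
#' @export
scan_genes <- function(e, bmi, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  bmi <- as.numeric(bmi)
  if (ncol(e) != length(bmi)) {
    stop("bmi length must match expression column count", call. = FALSE)
  }
  if (ncol(e) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(bmi) == 0) stop("phenotype has zero variance",
                                call. = FALSE)
  n <- length(bmi)
  vals <- e
  if (method == "spearman") {
    vals <- t(apply(e, 1L, rank))
    y <- rank(bmi)
  } else {
    y <- bmi
  }
  sds <- apply(vals, 1L, stats::sd)
  testable <- sds > 0
  r <- rep(NA_real_, nrow(e))
  r[testable] <- as.numeric(stats::cor(t(vals[testable, , drop = FALSE]),
                                       y))
  p <- vapply(r, function(ri) if (is.na(ri)) NA_real_ else .cor_p(ri, n),
              numeric(1))
  adj <- rep(NA_real_, length(p))
  adj[testable] <- bh_adjust(p[testable])
  res <- data.frame(gene_id = rownames(e), r = r, p_value = p,
                    adjusted_p = adj, stringsAsFactors = FALSE)
  res <- res[testable, , drop = FALSE]
  res <- res[order(res$p_value, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(
    list(results = res, untestable = rownames(e)[!testable],
         method = method, n_samples = n),
    class = "gene_scan"
  )
}

#' @export
print.gene_scan <- function(x, ...) {
  cat(sprintf(
    "gene scan (%s, n = %d): %d genes tested, %d with adjusted p < 0.05\n",
    x$method, x$n_samples, nrow(x$results),
    sum(x$results$adjusted_p < 0.05)))
  invisible(x)
}

#' Greedy independence filter over BMI-significant genes
#'
#' Significant genes (scan adjusted p below `adj_p_threshold`) are walked
#' in order of increasing raw p-value (ties by gene ID). The lowest-p
#' gene seeds the feature set; each subsequent gene is admitted only if
#' its correlation with every already-admitted gene is non-significant at
#' `inter_gene_p_threshold` (raw p, same correlation method as the scan).
#' Otherwise it is blocked, and the first admitted gene that blocks it is
#' recorded.
#'
#' @param scan A `gene_scan` from [scan_genes()].
#' @param e The expression matrix the scan was computed on.
#' @param adj_p_threshold Adjusted-p cutoff for scan significance
#'   (default 0.05).
#' @param inter_gene_p_threshold Raw-p cutoff for the pairwise
#'   independence test (default 0.05).
#' @return An object of class `feature_set`: list with `gene_ids`
#'   (admission order), `admission_log` (data frame `gene_id`, `admitted`,
#'   `blocking_gene`, `p_value`), and the thresholds used.
#' @export
select_independent <- function(scan, e, adj_p_threshold = 0.05,
                               inter_gene_p_threshold = 0.05) {
  stopifnot(inherits(scan, "gene_scan"))
  res <- scan$results
  missing_genes <- setdiff(res$gene_id, rownames(e))
  if (length(missing_genes)) {
    stop("scanned gene(s) absent from expression matrix: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "),
         call. = FALSE)
  }
  sig <- res[!is.na(res$adjusted_p) &
               res$adjusted_p < adj_p_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    warning("no genes pass the adjusted-p threshold; empty feature set",
            call. = FALSE)
    return(structure(
      list(gene_ids = character(0),
           admission_log = data.frame(gene_id = character(0),
                                      admitted = logical(0),
                                      blocking_gene = character(0),
                                      p_value = numeric(0),
                                      stringsAsFactors = FALSE),
           adj_p_threshold = adj_p_threshold,
           inter_gene_p_threshold = inter_gene_p_threshold,
           method = scan$method),
      class = "feature_set"
    ))
  }
  admitted <- character(0)
  log_rows <- vector("list", nrow(sig))
  for (i in seq_len(nrow(sig))) {
    gid <- sig$gene_id[i]
    blocker <- NA_character_
    for (a in admitted) {
      ct <- correlate(e[gid, ], e[a, ], method = scan$method)
      if (ct$p_value < inter_gene_p_threshold) {
        blocker <- a
        break
      }
    }
    if (is.na(blocker)) admitted <- c(admitted, gid)
    log_rows[[i]] <- data.frame(gene_id = gid,
                                admitted = is.na(blocker),
                                blocking_gene = blocker,
                                p_value = sig$p_value[i],
                                stringsAsFactors = FALSE)
  }
  structure(
    list(gene_ids = admitted,
         admission_log = do.call(rbind, log_rows),
         adj_p_threshold = adj_p_threshold,
         inter_gene_p_threshold = inter_gene_p_threshold,
         method = scan$method),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(
    "feature set: %d of %d significant genes admitted (%s)\n",
    length(x$gene_ids), nrow(x$admission_log), x$method))
  if (length(x$gene_ids)) {
    cat("  ", paste(x$gene_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a gene scan to TSV
#' @param scan A `gene_scan`.
#' @param path Output path.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
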