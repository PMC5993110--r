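# The unweighted genetic risk score: per-sample mean effect-allele dosage
# over a chosen SNP subset.

#' Compute the genetic risk score
#'
#' The score of a sample is the sum of its effect-allele dosages over the
#' included SNPs divided by the number of included SNPs — a mean dosage on
#' \[0, 2\]. Missing calls are handled by the observed-denominator policy:
#' they are excluded from both the numerator and that sample's
#' denominator, so the score stays a mean over what was actually
#' genotyped. Alternatively (`missing = "impute"`) missing calls are
#' replaced by the SNP's mean observed dosage (twice its effect-allele
#' frequency in expectation) and the denominator stays the full subset
#' size. A sample with every included SNP missing gets `NA` and is
#' flagged.
#'
#' @param g A [genotype_matrix].
#' @param included Character vector of panel rsIDs to include (non-empty).
#' @param convention `"mean"` (default; the score definition used
#'   throughout) or `"sum"` (raw allele count, no denominator).
#' @param missing `"observed"` (default) or `"impute"`.
#' @return An object of class `grs_result`: list with `sample_ids`,
#'   `scores`, `included_snps`, `per_sample_n_used`, `undefined`
#'   (sample IDs with no usable call) and `convention`.
#' @examples
#' pan <- snp_panel(c("rs1", "rs2", "rs3"), c("A", "C", "G"),
#'                  c("G", "T", "A"))
#' dos <- matrix(c(2L, 1L, 0L), 1, 3,
#'               dimnames = list("s1", pan$rsid))
#' compute_grs(genotype_matrix(dos, pan), pan$rsid)$scores  # 1.0
#' @export
compute_grs <- function(g, included, convention = c("mean", "sum"),
                        missing = c("observed", "impute")) {
  stopifnot(inherits(g, "genotype_matrix"))
  convention <- match.arg(convention)
  missing <- match.arg(missing)
  if (length(included) == 0L) {
    stop("included SNP set must be non-empty", call. = FALSE)
  }
  unknown <- setdiff(included, g$panel$rsid)
  if (length(unknown)) {
    stop("rsID(s) not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # keep panel order regardless of the order 'included' was given in
  included <- g$panel$rsid[g$panel$rsid %in% included]
  d <- g$dosages[, included, drop = FALSE]
  n_used <- rowSums(!is.na(d))
  if (missing == "impute" && anyNA(d)) {
    col_means <- colMeans(d, na.rm = TRUE)
    for (j in seq_len(ncol(d))) {
      miss_j <- is.na(d[, j])
      if (any(miss_j) && is.finite(col_means[j])) {
        d[miss_j, j] <- col_means[j]
      }
    }
  }
  sums <- rowSums(d, na.rm = TRUE)
  denom <- if (missing == "impute") {
    rowSums(!is.na(d))  # post-imputation; full subset unless a SNP is all-NA
  } else {
    n_used
  }
  scores <- if (convention == "sum") sums else sums / denom
  scores[denom == 0L] <- NA_real_
  undefined <- rownames(g$dosages)[denom == 0L]
  if (length(undefined)) {
    warning("sample(s) with no usable call over the included SNPs: ",
            paste(undefined, collapse = ", "), call. = FALSE)
  }
  structure(
    list(sample_ids = rownames(g$dosages),
         scores = stats::setNames(as.numeric(scores),
                                  rownames(g$dosages)),
         included_snps = included,
         per_sample_n_used = stats::setNames(as.integer(n_used),
                                             rownames(g$dosages)),
         undefined = undefined,
         convention = convention),
    class = "grs_result"
  )
}

#' @export
print.grs_result <- function(x, ...) {
  cat(sprintf(
    "genetic risk score (%s over %d SNPs): %d samples, mean %.3f\n",
    x$convention, length(x$included_snps), length(x$scores),
    mean(x$scores, na.rm = TRUE)))
  invisible(x)
}

#' Write genetic risk scores to TSV
#' @param grs A `grs_result`.
#' @param path Output path.
#' @export
write_grs <- function(grs, path) {
  df <- data.frame(sample_id = grs$sample_ids,
                   grs = unname(grs$scores),
                   n_snps_used = unname(grs$per_sample_n_used),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
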