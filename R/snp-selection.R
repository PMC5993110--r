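# Greedy backward exclusion of SNPs from the genetic risk score:
# repeatedly drop the SNP whose removal most increases the GRS-BMI
# correlation, until no removal improves it.

# Fast correlation coefficient for the inner loop (no result object).
.fast_r <- function(x, y_centered, y_ss) {
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  if (sx == 0) return(NA_real_)
  sum(xc * y_centered) / (sx * y_ss)
}

#' Greedy backward SNP exclusion maximizing GRS-BMI correlation
#'
#' Starts from the full panel. At each iteration every currently included
#' SNP is evaluated: the genetic risk score is recomputed without it and
#' correlated with BMI. The SNP whose exclusion gives the largest strictly
#' positive increase (> `tol`) in the signed correlation coefficient is
#' dropped. Iteration stops when no exclusion improves the correlation or
#' when only `min_included` SNPs remain. The objective is the signed
#' coefficient r because effect alleles are the BMI-increasing alleles,
#' so the intended optimum is positive; set `objective = "absolute"` to
#' maximize |r| instead. Ties between candidate exclusions break to the
#' SNP earlier in panel order.
#'
#' @param g A [genotype_matrix], samples aligned with `bmi`.
#' @param bmi Numeric BMI vector, one value per genotype row.
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @param min_included Stop before the included set would shrink below
#'   this size (default 1).
#' @param tol Minimum improvement in r to accept an exclusion (default 0,
#'   i.e. strictly greater in exact float comparison).
#' @param objective `"signed"` (default) or `"absolute"`.
#' @return An object of class `selection_trace`: list with `iterations`
#'   (data frame: `n_excluded`, `excluded_rsid`, `r`, `p_value`; row 0 is
#'   the all-SNP baseline), `method`, `objective`, `final_included`,
#'   `final_excluded`.
#' @export
greedy_exclude <- function(g, bmi, method = c("pearson", "spearman"),
                           min_included = 1L, tol = 0,
                           objective = c("signed", "absolute")) {
  stopifnot(inherits(g, "genotype_matrix"))
  method <- match.arg(method)
  objective <- match.arg(objective)
  bmi <- as.numeric(bmi)
  d <- g$dosages
  if (nrow(d) != length(bmi)) {
    stop("bmi length must match genotype sample count", call. = FALSE)
  }
  if (ncol(d) < 2L) stop("panel must have at least 2 SNPs", call. = FALSE)
  if (stats::sd(bmi) == 0) {
    stop("phenotype has zero variance", call. = FALSE)
  }
  n <- nrow(d)
  obj <- if (objective == "signed") identity else abs

  y <- if (method == "spearman") rank(bmi) else bmi
  yc <- y - mean(y)
  yss <- sqrt(sum(yc^2))

  score_r <- function(scores) {
    if (anyNA(scores) || stats::sd(scores, na.rm = TRUE) == 0) {
      return(NA_real_)
    }
    s <- if (method == "spearman") rank(scores) else scores
    .fast_r(s, yc, yss)
  }

  obs <- !is.na(d)
  d0 <- d
  d0[!obs] <- 0L
  included <- rep(TRUE, ncol(d))
  names(included) <- colnames(d)

  row_sum <- rowSums(d0)
  row_cnt <- rowSums(obs)

  r0 <- score_r(row_sum / row_cnt)
  if (is.na(r0)) {
    stop("all-SNP genetic risk score is degenerate", call. = FALSE)
  }
  iterations <- data.frame(
    n_excluded = 0L, excluded_rsid = NA_character_, r = r0,
    p_value = .cor_p(r0, n), stringsAsFactors = FALSE
  )
  current <- r0

  while (sum(included) > min_included) {
    idx <- which(included)
    cand_r <- rep(NA_real_, length(idx))
    for (k in seq_along(idx)) {
      j <- idx[k]
      cnt <- row_cnt - obs[, j]
      if (any(cnt == 0L)) next  # some sample would lose every call
      cand_r[k] <- score_r((row_sum - d0[, j]) / cnt)
    }
    gains <- obj(cand_r) - obj(current)
    gains[is.na(gains)] <- -Inf  # degenerate candidates never improve
    best <- which.max(gains)     # first max = earliest in panel order
    if (gains[best] <= tol) break
    j <- idx[best]
    included[j] <- FALSE
    row_sum <- row_sum - d0[, j]
    row_cnt <- row_cnt - obs[, j]
    current <- cand_r[best]
    iterations <- rbind(iterations, data.frame(
      n_excluded = sum(!included),
      excluded_rsid = colnames(d)[j],
      r = current, p_value = .cor_p(current, n),
      stringsAsFactors = FALSE
    ))
  }

  structure(
    list(iterations = iterations, method = method, objective = objective,
         final_included = colnames(d)[included],
         final_excluded = iterations$excluded_rsid[-1L]),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  last <- x$iterations[nrow(x$iterations), ]
  cat(sprintf(
    "greedy SNP exclusion (%s): %d excluded, %d retained; r %.3f -> %.3f\n",
    x$method, length(x$final_excluded), length(x$final_included),
    x$iterations$r[1L], last$r))
  invisible(x)
}

#' Exhaustive best-subset search over the panel
#'
#' Evaluates the GRS-BMI correlation over every non-empty SNP subset and
#' returns the maximizer of the chosen objective. Feasible only for small
#' panels; intended as a correctness oracle for [greedy_exclude()], whose
#' final r it bounds from above. Ties break to the smaller subset, then
#' lexicographically on the sorted rsID list.
#'
#' @inheritParams greedy_exclude
#' @param max_panel Refuse panels larger than this (default 15).
#' @return List with `best_subset` (rsIDs in panel order) and `r`.
#' @export
exhaustive_best_subset <- function(g, bmi,
                                   method = c("pearson", "spearman"),
                                   max_panel = 15L,
                                   objective = c("signed", "absolute")) {
  stopifnot(inherits(g, "genotype_matrix"))
  method <- match.arg(method)
  objective <- match.arg(objective)
  d <- g$dosages
  p <- ncol(d)
  if (p > max_panel) {
    stop("panel of ", p, " SNPs exceeds max_panel = ", max_panel,
         "; use greedy_exclude", call. = FALSE)
  }
  bmi <- as.numeric(bmi)
  if (stats::sd(bmi) == 0) stop("phenotype has zero variance",
                                call. = FALSE)
  obj <- if (objective == "signed") identity else abs
  y <- if (method == "spearman") rank(bmi) else bmi
  yc <- y - mean(y)
  yss <- sqrt(sum(yc^2))
  obs <- !is.na(d)
  d0 <- d
  d0[!obs] <- 0L

  best_r <- -Inf
  best_subset <- NULL
  for (mask in seq_len(2^p - 1L)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    cnt <- rowSums(obs[, sel, drop = FALSE])
    if (any(cnt == 0L)) next
    scores <- rowSums(d0[, sel, drop = FALSE]) / cnt
    if (stats::sd(scores) == 0) next
    s <- if (method == "spearman") rank(scores) else scores
    r <- .fast_r(s, yc, yss)
    v <- obj(r)
    better <- v > best_r + 1e-12 ||
      (abs(v - best_r) <= 1e-12 && !is.null(best_subset) &&
         (length(sel) < length(best_subset) ||
            (length(sel) == length(best_subset) &&
               paste(sort(colnames(d)[sel]), collapse = ",") <
               paste(sort(colnames(d)[best_subset]), collapse = ","))))
    if (is.null(best_subset) || better) {
      best_r <- v
      best_subset <- sel
      best_signed <- r
    }
  }
  if (is.null(best_subset)) {
    stop("every subset gives a degenerate score", call. = FALSE)
  }
  list(best_subset = colnames(d)[best_subset], r = best_signed)
}

#' Write a selection trace to TSV
#' @param trace A `selection_trace`.
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  df <- trace$iterations
  df$method <- trace$method
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
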