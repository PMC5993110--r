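# Reading, validation, alignment and QC of the three data layers:
# genotypes over a fixed SNP panel, expression profiles, and BMI phenotype.

.MISSING_TOKENS <- c("", "NA", "./.", ".")

# Dispatch on file extension: TSV/CSV via read.table, XLSX via readxl
# (optional dependency).
.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the 'readxl' package", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character",
                            na.strings = NULL, quote = "\"",
                            comment.char = "")
  }
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  df
}

#' Construct a SNP panel
#'
#' A SNP panel is the ordered annotation of the genotyped variants: the
#' rsID, the BMI-increasing "effect" allele whose dosage is counted, and
#' the other allele. Panel order is stable and defines the column order of
#' every genotype matrix downstream.
#'
#' @param rsid Character vector of unique rsIDs.
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T); the
#'   two alleles of a SNP must differ.
#' @return An object of class `snp_panel` (a data frame).
#' @export
snp_panel <- function(rsid, effect_allele, other_allele) {
  rsid <- as.character(rsid)
  effect_allele <- toupper(as.character(effect_allele))
  other_allele <- toupper(as.character(other_allele))
  dup <- rsid[duplicated(rsid)]
  if (length(dup)) {
    stop("duplicate rsID in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- !(effect_allele %in% c("A", "C", "G", "T")) |
    !(other_allele %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop("non-ACGT allele for: ", paste(rsid[bad], collapse = ", "),
         call. = FALSE)
  }
  same <- effect_allele == other_allele
  if (any(same)) {
    stop("effect and other allele identical for: ",
         paste(rsid[same], collapse = ", "), call. = FALSE)
  }
  structure(
    data.frame(rsid = rsid, effect_allele = effect_allele,
               other_allele = other_allele, stringsAsFactors = FALSE),
    class = c("snp_panel", "data.frame")
  )
}

#' Read a SNP panel from a delimited file
#'
#' Expects columns `rsid`, `effect_allele`, `other_allele`; row order in
#' the file becomes panel order.
#'
#' @param path Path to a TSV/CSV (or XLSX, if readxl is installed) file.
#' @return A [snp_panel].
#' @export
read_snp_panel <- function(path) {
  df <- .read_table(path)
  need <- c("rsid", "effect_allele", "other_allele")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("panel file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  snp_panel(df$rsid, df$effect_allele, df$other_allele)
}

#' Construct a genotype matrix
#'
#' @param dosages Integer matrix, samples in rows (rownames = sample IDs),
#'   SNPs in columns (colnames = panel rsIDs, panel order); values 0/1/2
#'   effect-allele counts, `NA` for missing calls.
#' @param panel The [snp_panel] the columns refer to.
#' @return An object of class `genotype_matrix`: list with `dosages` and
#'   `panel`.
#' @export
genotype_matrix <- function(dosages, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (ncol(dosages) != nrow(panel)) {
    stop("dosage column count (", ncol(dosages),
         ") does not match panel size (", nrow(panel), ")", call. = FALSE)
  }
  if (is.null(colnames(dosages))) colnames(dosages) <- panel$rsid
  if (!identical(colnames(dosages), panel$rsid)) {
    stop("dosage columns must match panel rsIDs in panel order",
         call. = FALSE)
  }
  if (is.null(rownames(dosages)) || anyDuplicated(rownames(dosages))) {
    stop("dosage rows need unique sample IDs as rownames", call. = FALSE)
  }
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or missing", call. = FALSE)
  }
  structure(list(dosages = dosages, panel = panel),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype matrix: %d samples x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

# Convert one column of genotype calls to effect-allele dosage.
.calls_to_dosage <- function(calls, effect, other, rsid, sample_ids,
                             missing_tokens) {
  calls <- trimws(as.character(calls))
  out <- rep(NA_integer_, length(calls))
  is_missing <- is.na(calls) | calls %in% missing_tokens
  plain <- !is_missing & calls %in% c("0", "1", "2")
  out[plain] <- as.integer(calls[plain])
  rest <- which(!is_missing & !plain)
  for (i in rest) {
    alleles <- strsplit(gsub("[/|]", "", toupper(calls[i])), "")[[1]]
    if (length(alleles) != 2L || !all(alleles %in% c(effect, other))) {
      stop("invalid genotype call '", calls[i], "' for sample ",
           sample_ids[i], ", SNP ", rsid,
           " (expected alleles ", effect, "/", other, ")", call. = FALSE)
    }
    out[i] <- sum(alleles == effect)
  }
  out
}

#' Read per-sample genotypes for a SNP panel
#'
#' The file has one row per sample with a `sample_id` column and one
#' column per panel SNP. Cells may be allele-pair strings (`"AG"`,
#' `"A/G"`), integer dosages 0/1/2 (already coded as effect-allele
#' counts), or a missing token. Allele pairs are converted to the count
#' of the panel's effect allele; within-call allele order is irrelevant.
#'
#' @param path Input file (TSV/CSV/XLSX).
#' @param panel The [snp_panel]; every panel SNP must have a column.
#' @param missing_tokens Strings treated as a missing call.
#' @return A [genotype_matrix] with columns in panel order.
#' @export
read_genotypes <- function(path, panel,
                           missing_tokens = .MISSING_TOKENS) {
  stopifnot(inherits(panel, "snp_panel"))
  df <- .read_table(path)
  id_col <- intersect(c("sample_id", "sample", "id"), names(df))[1]
  if (is.na(id_col)) stop("genotype file needs a sample_id column",
                          call. = FALSE)
  sample_ids <- as.character(df[[id_col]])
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs in genotype file", call. = FALSE)
  }
  miss <- setdiff(panel$rsid, names(df))
  if (length(miss)) {
    stop("genotype file missing panel SNP(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dos <- matrix(NA_integer_, nrow = length(sample_ids),
                ncol = nrow(panel),
                dimnames = list(sample_ids, panel$rsid))
  for (j in seq_len(nrow(panel))) {
    dos[, j] <- .calls_to_dosage(df[[panel$rsid[j]]],
                                 panel$effect_allele[j],
                                 panel$other_allele[j],
                                 panel$rsid[j], sample_ids,
                                 missing_tokens)
  }
  genotype_matrix(dos, panel)
}

#' Read an expression matrix
#'
#' @param path Input file; first column holds IDs, remaining columns are
#'   numeric.
#' @param orientation `"genes_in_rows"` (default: rows = genes, columns =
#'   samples) or `"genes_in_columns"` (transposed on read).
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows",
                                            "genes_in_columns")) {
  orientation <- match.arg(orientation)
  df <- .read_table(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate ", if (orientation == "genes_in_rows") "gene" else
      "sample", " IDs in expression file", call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, names(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric expression value at row ", bad[1L], ", column '",
           names(vals)[j], "'", call. = FALSE)
    }
    m[, j] <- v
  }
  if (orientation == "genes_in_columns") m <- t(m)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("duplicate IDs in expression matrix", call. = FALSE)
  }
  m
}

#' Read a BMI phenotype table
#'
#' @param path Input file with columns `sample_id` and `bmi` (kg/m^2).
#' @return A data frame with unique sample IDs and finite positive BMI.
#' @export
read_phenotype <- function(path) {
  df <- .read_table(path)
  need <- c("sample_id", "bmi")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("phenotype file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    bmi = suppressWarnings(as.numeric(df$bmi)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample IDs in phenotype table", call. = FALSE)
  }
  if (any(!is.finite(out$bmi) | out$bmi <= 0)) {
    stop("BMI must be finite and positive", call. = FALSE)
  }
  out
}

#' Remove samples with excessive genotype missingness
#'
#' A sample is removed when its fraction of missing calls over the panel
#' is greater than or equal to `max_missing_fraction` (the threshold is
#' inclusive: "20% or more missing").
#'
#' @param g A [genotype_matrix].
#' @param max_missing_fraction Inclusive removal threshold in (0, 1\];
#'   default 0.20.
#' @return List with the filtered `genotypes` and `removed` sample IDs.
#' @export
qc_missing_genotypes <- function(g, max_missing_fraction = 0.20) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (max_missing_fraction <= 0 || max_missing_fraction > 1) {
    stop("max_missing_fraction must be in (0, 1]", call. = FALSE)
  }
  frac <- rowMeans(is.na(g$dosages))
  removed <- rownames(g$dosages)[frac >= max_missing_fraction]
  kept <- g$dosages[frac < max_missing_fraction, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("all samples removed by missingness QC", call. = FALSE)
  }
  list(genotypes = genotype_matrix(kept, g$panel), removed = removed)
}

#' Align data layers to their common samples
#'
#' Restricts every supplied layer to the intersection of sample IDs. The
#' canonical sample order is the phenotype table's row order (or genotype
#' row order if no phenotype layer is given).
#'
#' @param genotypes A [genotype_matrix], or `NULL`.
#' @param expression Genes x samples numeric matrix, or `NULL`.
#' @param phenotype Phenotype data frame (`sample_id`, `bmi`), or `NULL`.
#' @return An object of class `cohort`: list with the aligned layers and
#'   a `dropped` attribute giving per-layer counts of excluded samples.
#' @export
align_samples <- function(genotypes = NULL, expression = NULL,
                          phenotype = NULL) {
  layers <- list()
  if (!is.null(genotypes)) {
    stopifnot(inherits(genotypes, "genotype_matrix"))
    layers$genotypes <- rownames(genotypes$dosages)
  }
  if (!is.null(expression)) layers$expression <- colnames(expression)
  if (!is.null(phenotype)) layers$phenotype <- phenotype$sample_id
  if (length(layers) < 2L) {
    stop("align_samples needs at least two layers", call. = FALSE)
  }
  common <- Reduce(intersect, layers)
  if (length(common) == 0L) {
    stop("no samples shared across layers", call. = FALSE)
  }
  # canonical order: phenotype file order, else genotype order
  ref <- if (!is.null(phenotype)) phenotype$sample_id else
    rownames(genotypes$dosages)
  common <- ref[ref %in% common]
  dropped <- vapply(layers, function(ids) length(setdiff(ids, common)),
                    integer(1))
  out <- list(
    genotypes = if (!is.null(genotypes)) {
      genotype_matrix(genotypes$dosages[common, , drop = FALSE],
                      genotypes$panel)
    },
    expression = if (!is.null(expression)) {
      expression[, common, drop = FALSE]
    },
    phenotype = if (!is.null(phenotype)) {
      phenotype[match(common, phenotype$sample_id), , drop = FALSE]
    }
  )
  structure(c(out, list(sample_ids = common)),
            dropped = dropped, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort of", length(x$sample_ids), "aligned samples\n")
  if (!is.null(x$genotypes)) {
    cat("  genotypes :", ncol(x$genotypes$dosages), "SNPs\n")
  }
  if (!is.null(x$expression)) {
    cat("  expression:", nrow(x$expression), "genes\n")
  }
  if (!is.null(x$phenotype)) {
    cat(sprintf("  BMI       : mean %.2f (range %.2f-%.2f)\n",
                mean(x$phenotype$bmi), min(x$phenotype$bmi),
                max(x$phenotype$bmi)))
  }
  invisible(x)
}

#' Dichotomize BMI into weight status
#'
#' Overweight is BMI >= `threshold` (inclusive; WHO convention with the
#' default cutoff of 25 kg/m^2).
#'
#' @param phenotype Phenotype data frame (`sample_id`, `bmi`).
#' @param threshold Positive cutoff, default 25.
#' @return Named factor (`normal`/`overweight`) indexed by sample ID.
#' @export
dichotomize_bmi <- function(phenotype, threshold = 25) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  status <- factor(ifelse(phenotype$bmi >= threshold, "overweight",
                          "normal"),
                   levels = c("normal", "overweight"))
  stats::setNames(status, phenotype$sample_id)
}

#' Collapse probe sets to one row per gene
#'
#' For genes measured by several probe sets, keeps the probe set with the
#' highest mean expression across samples; ties break to the
#' lexicographically smaller probe ID.
#'
#' @param e Probes x samples numeric matrix.
#' @param probe_to_gene Named character vector (`names` = probe IDs,
#'   values = gene IDs) or a two-column data frame (probe, gene).
#' @return Genes x samples matrix indexed by gene ID.
#' @export
collapse_probesets <- function(e, probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    probe_to_gene <- stats::setNames(as.character(probe_to_gene[[2L]]),
                                     as.character(probe_to_gene[[1L]]))
  }
  probes <- names(probe_to_gene)
  absent <- setdiff(probes, rownames(e))
  if (length(absent)) {
    warning("probe set(s) absent from matrix, skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
    probe_to_gene <- probe_to_gene[setdiff(probes, absent)]
  }
  if (length(probe_to_gene) == 0L) stop("no mapped probes present",
                                        call. = FALSE)
  means <- rowMeans(e[names(probe_to_gene), , drop = FALSE])
  ord <- order(names(probe_to_gene))  # lexicographic tie-break
  pick <- tapply(names(probe_to_gene)[ord],
                 unname(probe_to_gene)[ord],
                 function(p) p[which.max(means[p])])
  out <- e[unname(pick), , drop = FALSE]
  rownames(out) <- names(pick)
  out[order(rownames(out)), , drop = FALSE]
}

# --- writers (TSV), inverse of the readers ---------------------------------

#' Write a SNP panel to TSV
#' @param panel A [snp_panel].
#' @param path Output path.
#' @export
write_snp_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotype dosages to TSV
#' @param g A [genotype_matrix].
#' @param path Output path. Missing calls are written as `NA`.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(sample_id = rownames(g$dosages), g$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix to TSV (genes in rows)
#' @param e Genes x samples matrix.
#' @param path Output path.
#' @export
write_expression <- function(e, path) {
  df <- data.frame(gene_id = rownames(e), e, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a phenotype table to TSV
#' @param phenotype Data frame with `sample_id` and `bmi`.
#' @param path Output path.
#' @export
write_phenotype <- function(phenotype, path) {
  utils::write.table(phenotype, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
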