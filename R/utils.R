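# Small internal helpers.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Extract the ordered gene IDs from a feature_set or character vector.
.gene_ids <- function(genes) {
  if (inherits(genes, "feature_set")) genes$gene_ids else
    as.character(genes)
}

# Build the model frame: BMI response, admitted gene expression columns,
# optional GRS column. Sample alignment is the cohort's.
.model_frame <- function(cohort, genes, grs = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  gids <- .gene_ids(genes)
  df <- data.frame(bmi = cohort$phenotype$bmi)
  if (length(gids)) {
    missing_genes <- setdiff(gids, rownames(cohort$expression))
    if (length(missing_genes)) {
      stop("gene(s) absent from cohort expression: ",
           paste(missing_genes, collapse = ", "), call. = FALSE)
    }
    for (gid in gids) df[[gid]] <- cohort$expression[gid, ]
  }
  if (!is.null(grs)) {
    stopifnot(inherits(grs, "grs_result"))
    s <- grs$scores[cohort$sample_ids]
    if (anyNA(s)) {
      stop("undefined genetic risk score for sample(s): ",
           paste(cohort$sample_ids[is.na(s)], collapse = ", "),
           call. = FALSE)
    }
    df$grs <- unname(s)
  }
  rownames(df) <- cohort$sample_ids
  df
}
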