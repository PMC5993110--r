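# Shared fixture builders and independent oracles for the test suite.
# Oracles are deliberately naive re-implementations, kept independent of
# the package's code paths.

# tiny 3-SNP panel used across the IO tests
tiny_panel <- function() {
  snp_panel(c("rs1", "rs2", "rs3"), c("A", "C", "G"), c("G", "T", "A"))
}

# genotype matrix from a plain integer matrix, panel auto-built
make_genotypes <- function(dos, panel = NULL) {
  if (is.null(rownames(dos))) {
    rownames(dos) <- sprintf("s%02d", seq_len(nrow(dos)))
  }
  if (is.null(panel)) {
    k <- ncol(dos)
    panel <- snp_panel(sprintf("rs%d", seq_len(k)),
                       rep_len(c("A", "C"), k), rep_len(c("G", "T"), k))
  }
  colnames(dos) <- panel$rsid
  genotype_matrix(dos, panel)
}

# aligned cohort from raw pieces (expression optional)
make_cohort <- function(dos, bmi, expr = NULL, panel = NULL) {
  g <- make_genotypes(dos, panel)
  ids <- rownames(g$dosages)
  if (!is.null(expr)) {
    colnames(expr) <- ids
    if (is.null(rownames(expr))) {
      rownames(expr) <- sprintf("gene%02d", seq_len(nrow(expr)))
    }
  }
  phen <- data.frame(sample_id = ids, bmi = bmi,
                     stringsAsFactors = FALSE)
  align_samples(genotypes = g, expression = expr, phenotype = phen)
}

# --- independent oracles ---------------------------------------------------

# Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[ord[i]] / i)
    adj[ord[i]] <- prev
  }
  pmin(adj, 1)
}

# OLS by the normal equations
ols_oracle <- function(X, y) {
  Xd <- cbind(1, X)
  solve(crossprod(Xd), crossprod(Xd, y))[, 1]
}

# naive greedy backward exclusion (mean GRS, observed denominator)
greedy_oracle <- function(d, bmi, method = "pearson") {
  rfun <- function(g) {
    if (anyNA(g) || sd(g) == 0) return(NA_real_)
    if (method == "spearman") cor(rank(g), rank(bmi)) else cor(g, bmi)
  }
  grs <- function(s) rowMeans(d[, s, drop = FALSE], na.rm = TRUE)
  inc <- colnames(d)
  cur <- rfun(grs(inc))
  repeat {
    if (length(inc) == 1) break
    cand <- sapply(inc, function(s) rfun(grs(setdiff(inc, s))))
    gains <- cand - cur
    gains[is.na(gains)] <- -Inf
    best <- which.max(gains)
    if (gains[best] <= 0) break
    cur <- unname(cand[best])
    inc <- setdiff(inc, names(cand)[best])
  }
  list(included = inc, r = unname(cur))
}
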