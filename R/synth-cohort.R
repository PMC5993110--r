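# Seeded generator of synthetic cohorts with the statistical structure
# the framework assumes: Hardy-Weinberg genotypes with a causal subset
# acting additively on BMI, expression profiles with a few BMI-linked
# genes embedded in correlated blocks, Gaussian phenotype noise, and
# genotype missingness.

#' Hardy-Weinberg genotype frequencies
#'
#' Genotype proportions `((1-f)^2, 2f(1-f), f^2)` for effect-allele
#' dosages 0, 1, 2 at effect-allele frequency `f` under random mating.
#'
#' @param freq Effect-allele frequency, strictly inside (0, 1).
#' @return Named numeric vector `p0`, `p1`, `p2` summing to 1.
#' @export
hw_genotype_frequencies <- function(freq) {
  if (freq <= 0 || freq >= 1) {
    stop("effect-allele frequency must lie strictly in (0, 1)",
         call. = FALSE)
  }
  c(p0 = (1 - freq)^2, p1 = 2 * freq * (1 - freq), p2 = freq^2)
}

#' Simulation configuration
#'
#' Defines the generative model of a synthetic cohort:
#' * genotypes: `n_snps` biallelic SNPs drawn from Hardy-Weinberg
#'   proportions at per-SNP effect-allele frequencies; the first
#'   `n_causal` SNPs carry an additive per-allele effect `beta` on BMI.
#' * expression: `n_genes` log-scale profiles; `n_blocks` planted blocks
#'   each contain one BMI-linked representative (coefficient `gamma`)
#'   plus `block_size - 1` collinear duplicates sharing a latent factor
#'   so that every within-block pair has correlation `block_rho`; the
#'   remaining genes are independent standard normal noise.
#' * phenotype: `BMI_i = bmi_mean + sum_j beta * dosage_ij +
#'   sum_k gamma * E_i,rep(k) + N(0, noise_sd^2)`.
#' * missingness: genotype calls are set missing independently at
#'   `missing_rate`.
#'
#' Defaults describe a cohort of 500 individuals genotyped on a 27-SNP
#' panel (10 causal SNPs at 0.5 BMI units per allele), with 1000
#' expression profiles containing 5 planted blocks of 4 mutually
#' correlated genes, BMI centred at 26 kg/m^2 with residual SD 3, and 2%
#' missing genotype calls.
#'
#' @param n_samples Cohort size.
#' @param n_snps Panel size.
#' @param n_causal Number of causal SNPs (first `n_causal` of the panel).
#' @param beta Per-effect-allele BMI increment (kg/m^2) of causal SNPs.
#' @param effect_allele_freq Per-SNP effect-allele frequencies, recycled
#'   to `n_snps`.
#' @param n_genes Total expression profiles.
#' @param n_blocks Number of planted BMI-linked gene blocks.
#' @param gamma BMI units per expression unit for block representatives.
#' @param block_size Genes per planted block (representative + duplicates).
#' @param block_rho Within-block pairwise correlation, in \[0, 1).
#' @param bmi_mean Baseline BMI (kg/m^2).
#' @param noise_sd Residual BMI standard deviation (> 0).
#' @param missing_rate Genotype missingness rate, in \[0, 1).
#' @param seed Integer seed (mandatory: cohorts are reproducible).
#' @return An object of class `sim_config` (a list of the above).
#' @export
sim_config <- function(n_samples = 500L, n_snps = 27L, n_causal = 10L,
                       beta = 0.5,
                       effect_allele_freq = c(0.2, 0.35, 0.5, 0.65, 0.8),
                       n_genes = 1000L, n_blocks = 5L, gamma = 1,
                       block_size = 4L, block_rho = 0.8,
                       bmi_mean = 26, noise_sd = 3,
                       missing_rate = 0.02, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  freq <- rep_len(effect_allele_freq, n_snps)
  if (any(freq <= 0 | freq >= 1)) {
    stop("effect-allele frequencies must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (block_rho < 0 || block_rho >= 1) {
    stop("block_rho must lie in [0, 1)", call. = FALSE)
  }
  if (n_causal > n_snps) stop("n_causal cannot exceed n_snps",
                              call. = FALSE)
  if (n_blocks * block_size > n_genes) {
    stop("planted blocks exceed n_genes", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
         n_causal = as.integer(n_causal), beta = beta,
         effect_allele_freq = freq, n_genes = as.integer(n_genes),
         n_blocks = as.integer(n_blocks), gamma = gamma,
         block_size = as.integer(block_size), block_rho = block_rho,
         bmi_mean = bmi_mean, noise_sd = noise_sd,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort under the generative model of a [sim_config()]. All
#' randomness flows from `cfg$seed` through per-stage sub-seeds
#' (genotypes, expression, phenotype noise, missingness), so the same
#' configuration and seed give bit-identical cohorts and individual
#' stages can be reproduced in isolation.
#'
#' @param cfg A `sim_config`.
#' @return List with `cohort` (an aligned `cohort`) and `truth`: the
#'   ground-truth record (`causal_snps`, `snp_betas`, `planted_genes`
#'   = block representatives, `blocks` = full block membership,
#'   `gene_gammas`, `config`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  rsids <- sprintf("rs%05d", seq_len(cfg$n_snps) + 10000L)
  # alternate allele pairs; the alleles themselves carry no signal
  alleles <- matrix(c("A", "G", "C", "T"), nrow = 2)
  eff <- alleles[1L, (seq_len(cfg$n_snps) - 1L) %% 2L + 1L]
  oth <- alleles[2L, (seq_len(cfg$n_snps) - 1L) %% 2L + 1L]
  panel <- snp_panel(rsids, eff, oth)

  # per-stage sub-seeds derived from the master seed
  sub <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 4L))

  dos <- with_seed(sub[1L], {
    m <- matrix(NA_integer_, n, cfg$n_snps,
                dimnames = list(sample_ids, rsids))
    for (j in seq_len(cfg$n_snps)) {
      pr <- hw_genotype_frequencies(cfg$effect_allele_freq[j])
      m[, j] <- sample(0:2, n, replace = TRUE, prob = pr)
    }
    m
  })

  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  blocks <- if (cfg$n_blocks > 0L) {
    lapply(seq_len(cfg$n_blocks), function(b) {
      gene_ids[(b - 1L) * cfg$block_size + seq_len(cfg$block_size)]
    })
  } else {
    list()
  }
  expr <- with_seed(sub[2L], {
    e <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n,
                dimnames = list(gene_ids, sample_ids))
    for (members in blocks) {
      z <- stats::rnorm(n)
      for (g in members) {
        e[g, ] <- sqrt(cfg$block_rho) * z +
          sqrt(1 - cfg$block_rho) * stats::rnorm(n)
      }
    }
    e
  })
  reps <- vapply(blocks, `[`, character(1), 1L)

  genetic <- if (cfg$n_causal > 0L) {
    cfg$beta * rowSums(dos[, seq_len(cfg$n_causal), drop = FALSE])
  } else 0
  expressed <- if (length(reps)) {
    cfg$gamma * colSums(expr[reps, , drop = FALSE])
  } else 0
  noise <- with_seed(sub[3L], stats::rnorm(n, 0, cfg$noise_sd))
  bmi <- cfg$bmi_mean + genetic + expressed + noise
  bmi <- pmax(bmi, 12)  # BMI must stay positive; floor far below range

  if (cfg$missing_rate > 0) {
    dos <- with_seed(sub[4L], {
      drop_mask <- matrix(stats::runif(length(dos)) < cfg$missing_rate,
                          nrow(dos), ncol(dos))
      dos[drop_mask] <- NA_integer_
      dos
    })
  }

  phen <- data.frame(sample_id = sample_ids, bmi = bmi,
                     stringsAsFactors = FALSE)
  cohort <- align_samples(genotypes = genotype_matrix(dos, panel),
                          expression = expr, phenotype = phen)
  truth <- list(
    causal_snps = rsids[seq_len(cfg$n_causal)],
    snp_betas = stats::setNames(
      c(rep(cfg$beta, cfg$n_causal),
        rep(0, cfg$n_snps - cfg$n_causal)), rsids),
    planted_genes = reps,
    blocks = blocks,
    gene_gammas = stats::setNames(rep(cfg$gamma, length(reps)), reps),
    config = cfg
  )
  list(cohort = cohort, truth = truth)
}
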