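# Reading, validation, QC and alignment of the three data layers.

test_that("snp panel round-trips through file and preserves order", {
  pan <- tiny_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snp_panel(pan, path)
  again <- read_snp_panel(path)
  expect_identical(again$rsid, c("rs1", "rs2", "rs3"))
  expect_identical(as.data.frame(again), as.data.frame(pan))
})

test_that("panel validation rejects duplicates and bad alleles", {
  expect_error(snp_panel(c("rs1", "rs1"), c("A", "C"), c("G", "T")),
               "rs1")
  expect_error(snp_panel("rs9", "X", "G"), "non-ACGT")
  expect_error(snp_panel("rs9", "A", "A"), "identical")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\teffect_allele\tother_allele",
               "rs1\tA\tG", "rs1\tC\tT"), path)
  expect_error(read_snp_panel(path), "rs1")
})

test_that("genotype calls convert to effect-allele dosage symmetrically", {
  pan <- snp_panel("rs1", "A", "G")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1", "s1\tAA", "s2\tAG", "s3\tGG",
               "s4\tGA", "s5\tNA", "s6\t1"), path)
  g <- read_genotypes(path, pan)
  expect_identical(unname(g$dosages[, "rs1"]),
                   c(2L, 1L, 0L, 1L, NA, 1L))
})

test_that("genotype calls with alleles foreign to the panel error", {
  pan <- snp_panel("rs1", "A", "G")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1", "s1\tAT"), path)
  err <- expect_error(read_genotypes(path, pan))
  expect_match(conditionMessage(err), "s1")
  expect_match(conditionMessage(err), "rs1")
  expect_match(conditionMessage(err), "AT")
})

test_that("expression reader validates shape, types and duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ta\tb\tc", "g1\t1\t2\t3", "g2\t4\t5\t6"), path)
  e <- read_expression(path)
  expect_equal(dim(e), c(2L, 3L))
  expect_equal(e["g2", "c"], 6)
  # transposed orientation
  et <- read_expression(path, orientation = "genes_in_columns")
  expect_equal(dim(et), c(3L, 2L))
  expect_equal(et["c", "g2"], 6)

  writeLines(c("gene_id\ta", "g1\t1", "g1\t2"), path)
  expect_error(read_expression(path), "duplicate")
  writeLines(c("gene_id\ta", "g1\tnot_a_number"), path)
  expect_error(read_expression(path), "non-numeric")
  writeLines("gene_id\ta", path)
  expect_error(read_expression(path), "no data rows")
})

test_that("missingness QC removes at the inclusive 20% threshold", {
  # 27-SNP panel mirrors the scale at which the rule is stated:
  # 6/27 = 22.2% missing is removed, 5/27 = 18.5% kept
  k <- 27L
  dos <- matrix(1L, nrow = 3, ncol = k)
  dos[1, 1:6] <- NA
  dos[2, 1:5] <- NA
  g <- make_genotypes(dos)
  out <- qc_missing_genotypes(g)
  expect_identical(out$removed, "s01")
  expect_identical(rownames(out$genotypes$dosages), c("s02", "s03"))

  # exactly 20% missing is removed (threshold inclusive)
  dos2 <- matrix(1L, nrow = 2, ncol = 10)
  dos2[1, 1:2] <- NA
  out2 <- qc_missing_genotypes(make_genotypes(dos2), 0.20)
  expect_identical(out2$removed, "s01")
})

test_that("missingness QC boundary thresholds behave as documented", {
  dos <- matrix(1L, nrow = 3, ncol = 4)
  dos[1, 1] <- NA      # 25% missing
  dos[2, ] <- NA       # 100% missing
  g <- make_genotypes(dos)
  expect_identical(qc_missing_genotypes(g, 1.0)$removed, "s02")
  expect_setequal(qc_missing_genotypes(g, 1e-9)$removed,
                  c("s01", "s02"))
  expect_error(qc_missing_genotypes(g, 0), "max_missing_fraction")
})

test_that("align_samples intersects layers in phenotype order and is idempotent", {
  dos <- matrix(1:0, nrow = 3, ncol = 2)
  rownames(dos) <- c("A", "B", "C")
  g <- make_genotypes(dos)
  e <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"),
                                              c("B", "C", "D")))
  phen <- data.frame(sample_id = c("D", "C", "B", "A"),
                     bmi = c(20, 25, 30, 22))
  co <- align_samples(genotypes = g, expression = e, phenotype = phen)
  expect_identical(co$sample_ids, c("C", "B"))  # phenotype order
  expect_identical(rownames(co$genotypes$dosages), c("C", "B"))
  expect_identical(colnames(co$expression), c("C", "B"))
  expect_identical(co$phenotype$sample_id, c("C", "B"))

  co2 <- align_samples(genotypes = co$genotypes,
                       expression = co$expression,
                       phenotype = co$phenotype)
  expect_identical(co2[c("genotypes", "expression", "phenotype",
                         "sample_ids")],
                   co[c("genotypes", "expression", "phenotype",
                        "sample_ids")])
})

test_that("align_samples errors on disjoint layers and <2 layers", {
  dos <- matrix(1L, 2, 2, dimnames = list(c("A", "B"), NULL))
  g <- make_genotypes(dos)
  phen <- data.frame(sample_id = c("X", "Y"), bmi = c(20, 30))
  expect_error(align_samples(genotypes = g, phenotype = phen),
               "no samples shared")
  expect_error(align_samples(genotypes = g), "at least two layers")
})

test_that("BMI dichotomization is inclusive at the threshold", {
  phen <- data.frame(sample_id = c("a", "b", "c"),
                     bmi = c(18.65, 25.0, 46.66))
  st <- dichotomize_bmi(phen)
  expect_identical(as.character(st),
                   c("normal", "overweight", "overweight"))
  expect_named(st, c("a", "b", "c"))
})

test_that("probe-set collapse keeps the highest-mean probe with lexicographic ties", {
  e <- rbind(P1 = c(5, 5, 5), P2 = c(7, 7, 7),
             Q2 = c(3, 3, 3), Q1 = c(3, 3, 3),
             R1 = c(1, 2, 3))
  colnames(e) <- c("s1", "s2", "s3")
  map <- c(P1 = "GENEA", P2 = "GENEA", Q1 = "GENEB", Q2 = "GENEB",
           R1 = "GENEC")
  out <- collapse_probesets(e, map)
  expect_identical(rownames(out), c("GENEA", "GENEB", "GENEC"))
  expect_equal(unname(out["GENEA", ]), c(7, 7, 7))  # argmax mean
  expect_equal(unname(out["GENEB", ]), c(3, 3, 3))  # tie -> Q1 row
  expect_equal(unname(out["GENEC", ]), c(1, 2, 3))  # single probe
  expect_warning(collapse_probesets(e, c(map, ZZ = "GENED")),
                 "ZZ")
})

test_that("genotype, expression and phenotype layers round-trip exactly", {
  sim <- simulate_cohort(sim_config(n_samples = 15, n_snps = 5,
                                    n_causal = 2, n_genes = 8,
                                    n_blocks = 1, block_size = 2,
                                    missing_rate = 0.1, seed = 11))
  co <- sim$cohort
  td <- withr::local_tempdir()
  write_genotypes(co$genotypes, file.path(td, "g.tsv"))
  write_snp_panel(co$genotypes$panel, file.path(td, "p.tsv"))
  write_expression(co$expression, file.path(td, "e.tsv"))
  write_phenotype(co$phenotype, file.path(td, "ph.tsv"))

  pan <- read_snp_panel(file.path(td, "p.tsv"))
  g <- read_genotypes(file.path(td, "g.tsv"), pan)
  expect_identical(g$dosages, co$genotypes$dosages)
  e <- read_expression(file.path(td, "e.tsv"))
  expect_equal(e, co$expression, tolerance = 1e-12)
  ph <- read_phenotype(file.path(td, "ph.tsv"))
  expect_identical(ph$sample_id, co$phenotype$sample_id)
  expect_equal(ph$bmi, co$phenotype$bmi, tolerance = 1e-12)
})
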