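# Linear BMI model, interaction scan, cross-validated classifier.

# small aligned cohort with planted linear structure
planted_cohort <- function(n = 40, seed = 1, noise_sd = 0) {
  with_truth <- with_seed(seed, {
    dos <- matrix(sample(0:2, n * 4, replace = TRUE,
                         prob = c(0.25, 0.5, 0.25)), n, 4)
    e1 <- rnorm(n)
    e2 <- rnorm(n)
    g <- rowMeans(dos)
    bmi <- 2 + 1.5 * e1 - 0.5 * g + 26 + noise_sd * rnorm(n)
    list(dos = dos, e = rbind(E1 = e1, E2 = e2), bmi = bmi)
  })
  co <- make_cohort(with_truth$dos, with_truth$bmi, with_truth$e)
  co
}

test_that("noiseless planted coefficients are recovered exactly", {
  co <- planted_cohort()
  grs <- compute_grs(co$genotypes, co$genotypes$panel$rsid)
  # noiseless design: lm warns that the fit is essentially perfect
  fit <- suppressWarnings(fit_bmi_model(co, c("E1"), grs = grs))
  expect_equal(unname(fit$estimates["E1"]), 1.5, tolerance = 1e-10)
  expect_equal(unname(fit$estimates["grs"]), -0.5, tolerance = 1e-10)
  expect_equal(unname(fit$estimates["(Intercept)"]), 28,
               tolerance = 1e-8)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-10)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-8)
})

test_that("OLS agrees with the normal-equations oracle on random designs", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(15:60, 1)
    p <- sample(1:5, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("E", seq_len(p))))
    y <- rnorm(n, 26, 3)
    e <- t(X)
    colnames(e) <- sprintf("s%03d", seq_len(n))
    co <- make_cohort(matrix(rep(0:2, length.out = n * 2), n, 2), y, e)
    fit <- fit_bmi_model(co, rownames(e))
    beta <- ols_oracle(X, y)
    expect_equal(unname(fit$estimates), unname(beta),
                 tolerance = 1e-8)
    # adjusted R2 matches the closed form from the fit's R2
    expect_equal(fit$adjusted_r2,
                 1 - (1 - fit$r2) * (n - 1) / (n - p - 1),
                 tolerance = 1e-12)
  }
})

test_that("null-design adjusted R2 is near zero on average", {
  set.seed(404)
  vals <- replicate(40, {
    n <- 75
    e <- matrix(rnorm(7 * n), 7, n,
                dimnames = list(paste0("E", 1:7), sprintf("s%03d", 1:n)))
    co <- make_cohort(matrix(rep(0:2, length.out = n * 2), n, 2),
                      rnorm(n, 26, 3), e)
    fit_bmi_model(co, rownames(e))$adjusted_r2
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("rank-deficient designs error naming the collinear term", {
  n <- 30
  e <- with_seed(9, {
    x <- rnorm(n)
    rbind(E1 = x, E2 = 2 * x, E3 = rnorm(n))
  })
  co <- make_cohort(matrix(rep(0:2, length.out = n * 2), n, 2),
                    rnorm(n, 26, 3), e)
  expect_error(fit_bmi_model(co, c("E1", "E2", "E3")),
               "collinear.*E2")
  e2 <- rbind(E1 = rnorm(n), Econst = rep(1, n))
  co2 <- make_cohort(matrix(rep(0:2, length.out = n * 2), n, 2),
                     rnorm(n, 26, 3), e2)
  expect_error(fit_bmi_model(co2, c("E1", "Econst")),
               "zero variance.*Econst")
})

test_that("backward pruning drops insignificant predictors only when asked", {
  set.seed(31)
  n <- 60
  e1 <- rnorm(n)
  e <- rbind(E1 = e1, Enoise = rnorm(n))
  bmi <- 26 + 3 * e1 + rnorm(n)
  co <- make_cohort(matrix(rep(0:2, length.out = n * 2), n, 2), bmi, e)
  full <- fit_bmi_model(co, c("E1", "Enoise"))
  expect_identical(full$dropped, character(0))
  pruned <- fit_bmi_model(co, c("E1", "Enoise"),
                          prune_insignificant = TRUE)
  expect_identical(pruned$dropped, "Enoise")
  expect_identical(setdiff(pruned$terms, "(Intercept)"), "E1")
})

test_that("prediction is the linear predictor and is consistent with the fit", {
  co <- planted_cohort(noise_sd = 1)
  fit <- fit_bmi_model(co, c("E1", "E2"))
  # all-zero features give the intercept
  expect_equal(unname(predict_bmi(fit, data.frame(E1 = 0, E2 = 0))),
               unname(fit$estimates["(Intercept)"]))
  # training data reproduce fitted values / residuals
  newd <- data.frame(E1 = co$expression["E1", ],
                     E2 = co$expression["E2", ])
  expect_equal(unname(predict_bmi(fit, newd)), unname(fit$fitted),
               tolerance = 1e-10)
  expect_equal(unname(co$phenotype$bmi - predict_bmi(fit, newd)),
               unname(fit$residuals), tolerance = 1e-10)
  # linearity: +1 in E1 shifts by the E1 coefficient
  shift <- predict_bmi(fit, data.frame(E1 = 1, E2 = 0)) -
    predict_bmi(fit, data.frame(E1 = 0, E2 = 0))
  expect_equal(unname(shift), unname(fit$estimates["E1"]),
               tolerance = 1e-12)
  expect_error(predict_bmi(fit, data.frame(E1 = 0)), "E2")
})

test_that("interaction scan flags a true product effect and nothing else", {
  set.seed(61)
  n <- 80
  e1 <- rnorm(n)
  e2 <- rnorm(n)
  e3 <- rnorm(n)
  bmi <- 26 + e1 + e2 + 0.5 * e3 + 3 * e1 * e2
  e <- rbind(E1 = e1, E2 = e2, E3 = e3)
  co <- make_cohort(matrix(rep(0:2, length.out = n * 2), n, 2), bmi, e)
  tab <- suppressWarnings(interaction_scan(co, c("E1", "E2", "E3")))
  expect_equal(nrow(tab), 3L)  # C(3,2)
  hit <- tab[tab$term_pair == "E1:E2", ]
  expect_equal(hit$interaction_p, min(tab$interaction_p))
  expect_lt(hit$adjusted_p, 0.05)
})

test_that("additive-only data yield no significant interactions", {
  set.seed(62)
  n <- 80
  e1 <- rnorm(n)
  e2 <- rnorm(n)
  bmi <- 26 + e1 + e2 + rnorm(n, sd = 2)
  e <- rbind(E1 = e1, E2 = e2, E3 = rnorm(n))
  co <- make_cohort(matrix(rep(0:2, length.out = n * 2), n, 2), bmi, e)
  tab <- interaction_scan(co, c("E1", "E2", "E3"))
  expect_true(all(tab$adjusted_p > 0.05 | !tab$testable))
})

test_that("products collinear with the main effects are untestable", {
  set.seed(63)
  n <- 24
  e1 <- rep(c(0, 1), each = n / 2)   # binary indicator
  z <- rnorm(n)
  e2 <- e1 * z                       # zero wherever E1 is zero
  # E1 * E2 = E1^2 * z = E1 * z = E2 exactly: the product duplicates E2
  e <- rbind(E1 = e1, E2 = e2, E3 = rnorm(n))
  bmi <- 26 + e1 + 0.5 * e2 + rnorm(n)
  co <- make_cohort(matrix(rep(0:2, length.out = n * 2), n, 2), bmi, e)
  tab <- interaction_scan(co, c("E1", "E2", "E3"))
  bad <- tab[tab$term_pair == "E1:E2", ]
  expect_false(bad$testable)
  expect_true(is.na(bad$adjusted_p))
  expect_true(all(tab$testable[tab$term_pair != "E1:E2"]))
})

test_that("separable classes are classified perfectly", {
  n <- 40
  bmi <- c(rnorm(n / 2, 20, 0.5), rnorm(n / 2, 32, 0.5))
  feat <- ifelse(bmi >= 25, 10, -10) + rnorm(n, sd = 0.5)
  e <- rbind(E1 = feat, E2 = rnorm(n))
  co <- make_cohort(matrix(rep(0:2, length.out = n * 2), n, 2), bmi, e)
  res <- cv_classify_weight_status(co, c("E1", "E2"), seed = 3)
  expect_equal(res$accuracy, 1.0)
  expect_equal(sum(res$confusion_counts), n)
})

test_that("classification is reproducible given a seed and sensitive to it", {
  sim <- simulate_cohort(sim_config(n_samples = 80, n_genes = 30,
                                    n_blocks = 2, seed = 5))
  co <- sim$cohort
  genes <- sim$truth$planted_genes
  r1 <- cv_classify_weight_status(co, genes, seed = 11)
  r2 <- cv_classify_weight_status(co, genes, seed = 11)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_equal(r1$accuracy,
               sum(diag(r1$confusion_counts)) / sum(r1$confusion_counts),
               tolerance = 1e-12)
})

test_that("a class too small for the folds raises the fold-count error", {
  n <- 20
  bmi <- c(rep(20, n - 1), 30)  # a single overweight sample
  e <- rbind(E1 = rnorm(n))
  co <- make_cohort(matrix(rep(0:2, length.out = n * 2), n, 2), bmi, e)
  expect_error(cv_classify_weight_status(co, "E1", n_folds = 5, seed = 1),
               "fewer folds")
})
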