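test_that("cytokine group scores average members symmetrically", {
  cyt <- tidyr::expand_grid(
    patient = "p1",
    tibble::tibble(cytokine = c("IFN-g", "TNF-a", "IL-7"),
                   group = c("inflammatory", "inflammatory", "homeostatic")),
    tibble::tibble(timepoint = "pre", days = 0)
  )
  cyt$concentration <- c(2, 4, 9)
  sc <- cytokine_group_scores(cyt)
  expect_equal(sc$score[sc$group == "inflammatory"], 3)
  expect_equal(sc$score[sc$group == "homeostatic"], 9)  # single member

  # Permutation of members within a group leaves the score unchanged
  cyt2 <- cyt[c(2, 1, 3), ]
  expect_equal(cytokine_group_scores(cyt2)$score, sc$score)

  # Log-scale option averages logs
  lsc <- cytokine_group_scores(cyt, log_scale = TRUE)
  expect_equal(lsc$score[lsc$group == "inflammatory"], mean(log(c(2, 4))))

  bad <- cyt; bad$group[1] <- NA
  expect_error(cytokine_group_scores(bad), "group")
})

test_that("timepoint deltas are later-minus-earlier and telescope", {
  scores <- tidyr::expand_grid(
    patient = c("p1", "p2"), group = "inflammatory",
    correlate_timepoints()
  )
  scores$score <- c(1, 5, 7, 6, 4, 2, 2, 3, 3, 8)[1:10]
  d <- timepoint_deltas(scores)
  w <- function(pt, ctr) d$delta[d$patient == pt & d$contrast == ctr]
  expect_equal(w("p1", "pre_to_wk1"), 6)
  # Telescoping: pre->wk4 = pre->wk1 + wk1->wk4
  for (p in c("p1", "p2")) {
    expect_equal(w(p, "pre_to_wk4"),
                 w(p, "pre_to_wk1") + w(p, "wk1_to_wk4"))
  }
  # Equal values give zero deltas
  flat <- scores; flat$score <- 3
  expect_true(all(timepoint_deltas(flat)$delta == 0))
  # Missing timepoint flagged NA
  expect_warning(
    dmiss <- timepoint_deltas(scores[scores$timepoint != "wk4", ]),
    "Missing"
  )
  expect_true(all(is.na(dmiss$delta[dmiss$contrast == "pre_to_wk4"])))
})

test_that("Spearman association matches the brute-force midrank formula", {
  withr::with_seed(59, {
    x <- rnorm(10)
    y <- x + rnorm(10, 0, 0.5)
    y[3] <- y[4]   # force a tie
  })
  metrics <- tibble::tibble(patient = paste0("p", 1:10), cluster_metric = x)
  deltas <- tibble::tibble(patient = paste0("p", 1:10),
                           group = "g", contrast = "pre_to_wk1", delta = y)
  got <- spearman_assoc(metrics, deltas)

  # Independent midrank oracle: Pearson correlation of rank vectors
  rho_brute <- cor(rank(x), rank(y))
  expect_equal(got$rho, rho_brute, tolerance = 1e-12)

  # Perfectly monotone and reversed pairs
  deltas$delta <- exp(x)
  expect_equal(spearman_assoc(metrics, deltas)$rho, 1)
  deltas$delta <- -exp(x)
  expect_equal(spearman_assoc(metrics, deltas)$rho, -1)

  # Invariance under strictly monotone transforms
  deltas$delta <- y
  base <- spearman_assoc(metrics, deltas)$rho
  metrics2 <- metrics; metrics2$cluster_metric <- exp(3 * x)
  expect_equal(spearman_assoc(metrics2, deltas)$rho, base)

  # Constant vector: undefined, flagged
  metrics3 <- metrics; metrics3$cluster_metric <- 1
  expect_warning(und <- spearman_assoc(metrics3, deltas), "undefined")
  expect_false(und$defined)

  # BH option adds adjusted p-values
  withbh <- spearman_assoc(metrics, deltas, adjust = "BH")
  expect_true("p_adjusted" %in% names(withbh))
  expect_identical(unique(got$analysis), "exploratory")
})

test_that("trapezoidal AUC matches closed forms and is additive", {
  expect_equal(persistence_auc(c(0, 28), c(3, 3)), 84, tolerance = 1e-9)
  expect_equal(persistence_auc(c(0, 10), c(0, 5)), 25, tolerance = 1e-9)

  # Piecewise-linear curve vs fine-grid numerical integral
  days <- c(0, 0.125, 7, 14, 28)
  lev <- c(0, 50, 900, 400, 100)
  fine_t <- seq(0, 28, length.out = 200001)
  fine_y <- stats::approx(days, lev, xout = fine_t)$y
  expect_equal(persistence_auc(days, lev),
               pracma::trapz(fine_t, fine_y), tolerance = 1e-9)

  # Additivity over adjacent intervals
  expect_equal(persistence_auc(days, lev),
               persistence_auc(days[1:3], lev[1:3]) +
                 persistence_auc(days[3:5], lev[3:5]), tolerance = 1e-12)

  expect_error(persistence_auc(c(0, 2, 1), c(1, 1, 1)), "increasing")
  expect_error(persistence_auc(1, 1), "two timepoints")
})

test_that("per-patient persistence AUCs integrate the generated curves", {
  cs <- simulate_correlates(cohort_config(n_donors = 3, seed = 2), noise_sd = 0)
  aucs <- persistence_auc_by_patient(cs)
  expect_equal(nrow(aucs), 3)
  one <- cs$persistence[cs$persistence$patient == "prod01", ]
  expect_equal(aucs$auc[aucs$patient == "prod01"],
               pracma::trapz(one$days, one$level))
})

test_that("Pearson regression reports r, CI, slope and significance", {
  x <- c(1, 2, 3, 4, 5)
  exact <- suppressWarnings(pearson_regression(x, 2 * x))
  expect_equal(exact$r, 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 0, tolerance = 1e-12)

  # Antisymmetry under y -> -y
  withr::with_seed(61, y <- x + rnorm(5))
  expect_equal(pearson_regression(x, -y)$r, -pearson_regression(x, y)$r)

  # Independent variables at n = 1000: small r, CI covers 0
  withr::with_seed(67, {
    xn <- rnorm(1000); yn <- rnorm(1000)
  })
  nullfit <- pearson_regression(xn, yn)
  expect_lt(abs(nullfit$r), 0.1)
  expect_lt(nullfit$r_conf_low, 0)
  expect_gt(nullfit$r_conf_high, 0)
  expect_false(nullfit$significant)

  expect_warning(flat <- pearson_regression(x, rep(1, 5)), "Zero variance")
  expect_false(flat$defined)
  expect_error(pearson_regression(1:2, 1:2), "3 paired")
})

test_that("planted latent factors are recovered as positive correlations", {
  hits <- 0
  for (i in 1:200) {
    cs <- simulate_correlates(cohort_config(n_donors = 10, seed = 1000 + i),
                              group_effects = c(inflammatory = 0.8,
                                                regulatory = -0.4,
                                                homeostatic = 0),
                              noise_sd = 0.1, seed = 1000 + i)
    d <- timepoint_deltas(cytokine_group_scores(cs))
    rho <- spearman_assoc(cs$metrics, d)
    r <- rho$rho[rho$group == "inflammatory" & rho$contrast == "pre_to_wk1"]
    if (!is.na(r) && r > 0) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})
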