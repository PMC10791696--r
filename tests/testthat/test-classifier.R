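test_that("a one-point grid is returned unchanged and votes break ties to low complexity", {
  tab <- make_labeled_sites(fixture_spec(seed = 1))
  g1 <- expand.grid(learning_rate = 0.1, min_samples_split = 4,
                    n_estimators = 50)
  hp <- tune_hyperparameters(tab, g1, seed = 1)
  expect_equal(hp$learning_rate, 0.1)
  expect_equal(hp$min_samples_split, 4)
  expect_equal(hp$n_estimators, 50)
  # 50/50 vote splits resolve toward lower complexity
  expect_equal(insrtr:::.majority_vote(c(0.01, 0.01, 0.2, 0.2),
                                       prefer_large = FALSE), 0.01)
  expect_equal(insrtr:::.majority_vote(c(2, 2, 8, 8), prefer_large = TRUE), 8)
  expect_equal(insrtr:::.majority_vote(c(50, 100, 100), prefer_large = FALSE),
               100)
})

test_that("tuning selects a clearly dominating grid point on separable data", {
  tab <- make_labeled_sites(fixture_spec(seed = 2))
  tab$oracle_feature <- tab$label + 0  # perfectly separating descriptor
  grid <- expand.grid(learning_rate = c(1e-4, 0.2),
                      min_samples_split = 2, n_estimators = 20)
  hp <- tune_hyperparameters(tab, grid, seed = 1)
  # at 20 rounds only the larger rate drives the log-loss down
  expect_equal(hp$learning_rate, 0.2)
  expect_error(tune_hyperparameters(tab[tab$label == 1, ], grid, seed = 1),
               "stratification|single class|both classes")
})

test_that("a perfect feature yields perfect LOOCV accuracy and AUC", {
  tab <- make_labeled_sites(fixture_spec(seed = 3))
  tab$oracle_feature <- tab$label + 0
  ev <- evaluate_loocv(tab, default_params())
  expect_equal(ev$loocv_accuracy, 1.0)
  expect_equal(ev$loocv_auc, 1.0)
  expect_error(evaluate_loocv(tab[1:2, ], default_params()),
               "insufficient")
})

test_that("planted two-feature signal is recovered with high LOOCV accuracy", {
  accs <- vapply(1:3, function(sd) {
    tab <- make_labeled_sites(fixture_spec(seed = sd))
    # the generator's signal is calibrated against a model-free oracle
    expect_gt(nn_loocv_accuracy(tab), 0.8)
    evaluate_loocv(tab, default_params())$loocv_accuracy
  }, numeric(1))
  expect_gte(median(accs), 0.9)
})

test_that("coin-flip labels give chance-level accuracy", {
  params <- list(learning_rate = 0.1, min_samples_split = 4,
                 n_estimators = 50)
  accs <- vapply(1:30, function(sd) {
    tab <- make_labeled_sites(fixture_spec(seed = 1000 + sd),
                              weights = c(loop_sasa = 0),
                              label_noise = "bernoulli")
    evaluate_loocv(tab, params)$loocv_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("LOOCV results are reproducible and row-order invariant", {
  tab <- make_labeled_sites(fixture_spec(seed = 4))
  ev1 <- evaluate_loocv(tab, default_params(), seed = 7)
  ev2 <- evaluate_loocv(tab, default_params(), seed = 7)
  expect_identical(ev1$predictions, ev2$predictions)
  perm <- sample(nrow(tab))
  ev3 <- evaluate_loocv(tab[perm, ], default_params(), seed = 7)
  expect_equal(ev3$loocv_accuracy, ev1$loocv_accuracy)
  expect_equal(sort(ev3$predictions$prob), sort(ev1$predictions$prob))
})

test_that("permutation importance ranks planted features first and zeroes constants", {
  tab <- make_labeled_sites(fixture_spec(seed = 5))
  tab$flatline <- 1.0
  model <- train_site_model(tab, default_params())
  imp <- permutation_importance(model, tab, n_repeats = 20, seed = 1)
  expect_setequal(imp$feature[1:2], c("loop_sasa", "dist_active_site_nm"))
  expect_equal(imp$importance_mean[imp$feature == "flatline"], 0)
  expect_true(imp$constant[imp$feature == "flatline"])
})

test_that("independent shuffles bound the joint shuffle on additive signal", {
  tab <- make_labeled_sites(fixture_spec(seed = 6))
  model <- train_site_model(tab, default_params())
  imp <- permutation_importance(model, tab, n_repeats = 20, seed = 2)
  indep_sum <- sum(imp$importance_mean[imp$feature %in%
                                         c("loop_sasa",
                                           "dist_active_site_nm")])
  # joint shuffle of both planted features
  set.seed(2)
  X <- tab
  base <- mean((predict(model, tab) > 0.5) == tab$label)
  drops <- vapply(1:20, function(r) {
    X$loop_sasa <- sample(X$loop_sasa)
    X$dist_active_site_nm <- sample(X$dist_active_site_nm)
    base - mean((predict(model, X) > 0.5) == tab$label)
  }, numeric(1))
  expect_gte(indep_sum + 0.05, mean(drops))
})

test_that("ranking is by probability with declared tie-breaks and schema checks", {
  tab <- make_labeled_sites(fixture_spec(seed = 7))
  model <- train_site_model(tab, list(learning_rate = 0.3,
                                      min_samples_split = 2,
                                      n_estimators = 400))
  # empty candidate list
  expect_equal(nrow(rank_sites(model, tab[0, ])), 0)
  # a duplicated positive training row ranks first under the overfit model
  pos <- tab[tab$label == 1, ][1, ]
  neg <- tab[tab$label == 0, ]
  cand <- rbind(pos, neg)
  ranked <- rank_sites(model, cand)
  expect_equal(ranked$site_id[1], pos$site_id)
  # identical vectors: stable order by increasing active-site distance
  twin <- rbind(pos, pos)
  twin$dist_active_site_nm <- c(3, 1)
  r2 <- rank_sites(model, twin)
  expect_equal(r2$dist_active_site_nm, c(1, 3))
  # schema mismatch is refused with a diff
  expect_error(rank_sites(model, tab[, 1:3]), "missing feature")
})

test_that("site tables round-trip through CSV", {
  tab <- make_labeled_sites(fixture_spec(seed = 8))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- read_site_table(f)
  expect_equal(back$label, tab$label)
  expect_equal(back$loop_sasa, tab$loop_sasa)
  bad <- tab; bad$label <- bad$label + 2
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  expect_error(read_site_table(f2), "0/1")
})
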