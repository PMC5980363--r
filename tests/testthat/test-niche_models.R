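families <- c("glm_stepwise", "mars", "brt", "rf", "maxent_like")

test_that("every family separates a separable table and stays in [0, 1]", {
  tab <- fixture_table(n1 = 80, n0 = 120, shift = 6, seed = 3)
  tr <- tab[tab$role == "train", ]
  for (fam in families) {
    m <- fit_model(fast_spec(fam, seed = 5), tab)
    s <- predict(m, tr[c("x1", "noise1", "noise2")])
    expect_true(all(s >= 0 & s <= 1), info = fam)
    expect_equal(roc_auc(s[tr$response == 1], s[tr$response == 0]), 1.0,
                 info = fam)
  }
})

test_that("shuffled labels give chance-level test AUC", {
  set.seed(44)
  aucs <- replicate(20, {
    tab <- fixture_table(n1 = 80, n0 = 120, shift = 0, seed = sample.int(1e6, 1))
    m <- fit_model(model_spec("glm_stepwise"), tab)
    evaluate_model(m, tab)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("stepwise selection retains an informative predictor among noise", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 300
    tab <- data.frame(signal = rnorm(n))
    for (i in 1:5) tab[[paste0("noise", i)]] <- rnorm(n)
    tab$response <- rbinom(n, 1, plogis(2 * tab$signal))
    tab$role <- "train"
    m <- fit_model(model_spec("glm_stepwise"), tab)
    if ("signal" %in% names(coef(m$fit))) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("suitability stays bounded on inputs far outside the training range", {
  tab <- fixture_table(seed = 6)
  wild <- data.frame(x1 = c(-1e3, 0, 1e3), noise1 = c(1e3, 0, -1e3),
                     noise2 = c(0, 1e4, 0))
  for (fam in families) {
    m <- fit_model(fast_spec(fam, seed = 2), tab)
    s <- predict(m, wild)
    expect_true(all(is.finite(s) & s >= 0 & s <= 1), info = fam)
  }
})

test_that("refitting with the same seed reproduces identical predictions", {
  tab <- fixture_table(seed = 8)
  newd <- tab[1:25, c("x1", "noise1", "noise2")]
  for (fam in c("rf", "brt", "maxent_like")) {
    m1 <- fit_model(fast_spec(fam, seed = 31), tab)
    m2 <- fit_model(fast_spec(fam, seed = 31), tab)
    expect_identical(predict(m1, newd), predict(m2, newd), info = fam)
  }
})

test_that("predictions rank-correlate with a monotone single-driver truth", {
  set.seed(19)
  n <- 600
  x <- rnorm(n)
  truth <- plogis(2.5 * x)
  tab <- data.frame(x1 = x, noise1 = rnorm(n),
                    response = rbinom(n, 1, truth),
                    role = ifelse(runif(n) < 0.7, "train", "test"))
  te <- tab$role == "test"
  for (fam in families) {
    m <- fit_model(fast_spec(fam, seed = 7), tab)
    s <- predict(m, tab[te, c("x1", "noise1")])
    expect_true(cor(s, truth[te], method = "spearman") > 0.7, info = fam)
  }
})

test_that("fit_model rejects degenerate tables", {
  tab <- fixture_table(seed = 1)
  tab1 <- tab; tab1$response <- 1
  expect_error(fit_model(model_spec("glm_stepwise"), tab1), "single class")
  tab2 <- tab; tab2$x1[which(tab2$role == "train")[3]] <- Inf
  expect_error(fit_model(model_spec("glm_stepwise"), tab2), "non-finite")
  tab3 <- tab[c("x1", "response", "role")]
  expect_error(fit_model(model_spec("rf"), tab3), "at least 2 predictors")
})

test_that("surface prediction matches the pointwise contract and propagates nodata", {
  land <- fixture_landscape(40, seed = 3)$land
  st <- raster_stack(list(land$climate$bio1, land$climate$bio18))
  set.seed(2)
  n <- 300
  b1 <- as.vector(st$bio1$values); b18 <- as.vector(st$bio18$values)
  rows <- sample(length(b1), n)
  tab <- data.frame(bio1 = b1[rows], bio18 = b18[rows],
                    response = rbinom(n, 1, plogis(-(b1[rows] + 8))),
                    role = "train")
  tab$response[1:2] <- c(0, 1)  # guarantee both classes
  m <- fit_model(model_spec("glm_stepwise"), tab)
  surf <- predict_surface(m, st, "present")
  expect_true(all(surf$values >= 0 & surf$values <= 1, na.rm = TRUE))
  # consistency with the vector contract at a few cells
  for (cell in list(c(3, 5), c(20, 11), c(37, 36))) {
    v <- data.frame(bio1 = st$bio1$values[cell[1], cell[2]],
                    bio18 = st$bio18$values[cell[1], cell[2]])
    expect_equal(surf$values[cell[1], cell[2]], predict(m, v))
  }
  # constant stack gives a constant surface
  cst <- raster_stack(list(
    raster_grid(matrix(-8, 10, 10), 0, 1, 0.1, name = "bio1"),
    raster_grid(matrix(80, 10, 10), 0, 1, 0.1, name = "bio18")))
  sc <- predict_surface(m, cst)
  expect_equal(max(sc$values) - min(sc$values), 0)
  # nodata propagation
  st2 <- st
  st2$bio1$values[5, 5] <- NA
  expect_true(is.na(predict_surface(m, st2)$values[5, 5]))
  # missing layer is named in the failure
  expect_error(predict_surface(m, raster_stack(list(land$climate$bio1))),
               "bio18")
})

test_that("warming depresses suitability for a cold-adapted model", {
  land <- fixture_landscape(40, seed = 3)$land
  st <- raster_stack(list(land$climate$bio1, land$climate$bio4))
  set.seed(6)
  b1 <- as.vector(st$bio1$values)
  rows <- sample(length(b1), 400)
  # presence concentrated at the cold end
  tab <- data.frame(bio1 = b1[rows], bio4 = as.vector(st$bio4$values)[rows],
                    response = rbinom(400, 1, plogis(-2 * (b1[rows] + 10))),
                    role = "train")
  tab$response[1:2] <- c(0, 1)
  m <- fit_model(fast_spec("maxent_like", seed = 3), tab)
  present <- predict_surface(m, st)
  fut <- apply_scenario(st, scenario_delta("w5", temp_offset = 5))
  future <- predict_surface(m, fut)
  expect_lt(mean(future$values, na.rm = TRUE),
            mean(present$values, na.rm = TRUE))
})

test_that("permutation importance isolates the driving predictor", {
  set.seed(27)
  n <- 800
  x <- rnorm(n)
  tab <- data.frame(driver = x, null1 = rnorm(n), null2 = rnorm(n),
                    response = rbinom(n, 1, plogis(3 * x)),
                    role = ifelse(runif(n) < 0.7, "train", "test"))
  m <- fit_model(model_spec("glm_stepwise"), tab)
  vi <- variable_importance(m, tab, n_permutations = 20, seed = 5)
  expect_equal(vi$predictor[1], "driver")
  nulls <- vi$importance[vi$predictor != "driver"]
  expect_lt(max(abs(nulls)), 0.05)
  expect_gt(vi$importance[1], max(abs(nulls)))
  expect_error(variable_importance(m, tab, n_permutations = 0), "n_permutations")
})
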