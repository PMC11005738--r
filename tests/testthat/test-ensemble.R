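test_that("rmse and pcc reproduce hand-derived worked examples", {
  expect_equal(rmse(c(0, 1, 2), c(0, 2, 2)), 0.577350, tolerance = 1e-6)
  expect_equal(pcc(c(0, 1, 2), c(0, 2, 2)), 0.866025, tolerance = 1e-6)
  expect_equal(rmse(c(5, -3, 7), c(5, -3, 7)), 0)
  expect_equal(rmse(3, 1), 2)
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pcc(c(1, 2, 3), -c(1, 2, 3)), -1)
})

test_that("metrics agree with spelled-out summation on random vectors", {
  rmse_sum <- function(ye, yp) {
    acc <- 0
    for (i in seq_along(ye)) acc <- acc + (ye[i] - yp[i])^2
    sqrt(acc / length(ye))
  }
  pcc_sum <- function(ye, yp) {
    n <- length(ye)
    me <- sum(ye) / n; mp <- sum(yp) / n
    num <- 0; de <- 0; dp <- 0
    for (i in seq_len(n)) {
      num <- num + (ye[i] - me) * (yp[i] - mp)
      de <- de + (ye[i] - me)^2
      dp <- dp + (yp[i] - mp)^2
    }
    num / sqrt(de * dp)
  }
  withr::with_seed(8, {
    for (rep in 1:25) {
      n <- sample(2:60, 1)
      ye <- rnorm(n, sd = 50); yp <- rnorm(n, sd = 50)
      expect_equal(rmse(ye, yp), rmse_sum(ye, yp), tolerance = 1e-10)
      expect_equal(pcc(ye, yp), pcc_sum(ye, yp), tolerance = 1e-10)
    }
  })
})

test_that("metric bounds hold on 1000 random vector pairs", {
  withr::with_seed(10, {
    for (rep in 1:1000) {
      n <- sample(2:20, 1)
      ye <- rnorm(n); yp <- rnorm(n)
      expect_gte(rmse(ye, yp), 0)
      r <- pcc(ye, yp)
      expect_true(r >= -1 && r <= 1)
    }
  })
})

test_that("degenerate metric inputs raise contract errors", {
  expect_error(rmse(1:3, 1:2), "lengths differ")
  expect_error(pcc(c(1, 1, 1), 1:3), "constant")
  expect_error(pcc(1:3, c(2, 2, 2)), "constant")
  expect_error(pcc(1, 1), "two observations")
})

test_that("pcc is invariant under positive affine transforms", {
  withr::with_seed(12, {
    ye <- rnorm(30); yp <- rnorm(30)
    expect_equal(pcc(ye, 3 * yp + 7), pcc(ye, yp), tolerance = 1e-12)
    expect_equal(pcc(10 * ye - 2, yp), pcc(ye, yp), tolerance = 1e-12)
  })
})

# hand-built ranked table mimicking cv_rank output
fake_ranked <- function(measured, preds) {
  ranked <- tibble::tibble(
    name = names(preds), family = names(preds),
    cv_rmse = vapply(preds, function(p) rmse(measured, p), numeric(1)),
    oof = unname(preds),
    spec_row = lapply(names(preds), function(nm) list(name = nm))
  )
  ranked <- ranked[order(ranked$cv_rmse), ]
  attr(ranked, "measured") <- measured
  ranked
}

test_that("greedy selection solves the three-candidate hand example", {
  # measured (0,0); A -> (1,1), B -> (-1,-1) average to the truth; C -> (3,3)
  ranked <- fake_ranked(c(0, 0), list(A = c(1, 1), B = c(-1, -1), C = c(3, 3)))
  model <- greedy_select(ranked)
  members <- vapply(model$members, function(m) m$name, character(1))
  expect_setequal(members, c("A", "B"))
  expect_equal(model$cv_rmse, 0)
  expect_false(model$trace$accepted[model$trace$candidate == "C"])
  # brute force over all subsets containing the top-ranked member confirms
  # {A,B} is the best achievable uniform average
  preds <- list(A = c(1, 1), B = c(-1, -1), C = c(3, 3))
  subset_rmse <- vapply(list("A", c("A", "B"), c("A", "C"), c("A", "B", "C")),
                        function(s) rmse(c(0, 0), Reduce(`+`, preds[s]) / length(s)),
                        numeric(1))
  expect_equal(model$cv_rmse, min(subset_rmse))
})

test_that("greedy selection trace is strictly decreasing and beats best single", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      n <- 40
      measured <- rnorm(n, 300, 100)
      preds <- lapply(1:8, function(i) measured + rnorm(n, 0, runif(1, 20, 200)))
      names(preds) <- paste0("e", 1:8)
      model <- greedy_select(fake_ranked(measured, preds))
      acc <- model$trace$ensemble_rmse[model$trace$accepted]
      expect_true(all(diff(acc) < 0))
      expect_lte(model$cv_rmse, min(vapply(preds, function(p) rmse(measured, p),
                                           numeric(1))))
      expect_equal(model$cv_rmse, min(model$trace$ensemble_rmse))
    }
  })
})

test_that("greedy keeps only the best single estimator when additions hurt", {
  measured <- c(0, 0, 0)
  ranked <- fake_ranked(measured, list(best = c(0.1, 0.1, 0.1),
                                       far1 = c(5, 5, 5), far2 = c(-9, 9, 9)))
  model <- greedy_select(ranked)
  expect_length(model$members, 1)
  expect_equal(model$members[[1]]$name, "best")
})

test_that("single-candidate ranking yields that candidate", {
  model <- greedy_select(fake_ranked(c(1, 2), list(only = c(1.5, 1.5))))
  expect_length(model$members, 1)
  expect_equal(model$members[[1]]$name, "only")
})

test_that("cv_rank sorts ascending, ties in roster order, reproducible folds", {
  spec <- tiny_spec(3)
  d <- simulate_screen(spec, quiet_params(noise_sd = 0.1), n = 60, seed = 31)
  r <- fast_roster()
  rk1 <- cv_rank(d, spec, r, cv_config(5, 7))
  rk2 <- cv_rank(d, spec, r, cv_config(5, 7))
  expect_identical(rk1$cv_rmse, rk2$cv_rmse)
  expect_identical(attr(rk1, "fold_id"), attr(rk2, "fold_id"))
  expect_true(!is.unsorted(rk1$cv_rmse))
  # constant titers: every estimator hits (near) zero error; stable sort keeps
  # roster order among exact ties
  dc <- d
  dc$titer <- rep(100, nrow(d))
  rkc <- cv_rank(dc, spec, r, cv_config(5, 7), target = "identity")
  expect_true(all(rkc$cv_rmse < 1e-6))
  expect_equal(rkc$name, r$name)
})

test_that("a planted linear target puts linear families at the top", {
  spec <- tiny_spec(3)
  sp <- enumerate_space(spec)
  x <- encode_one_hot(sp, spec)
  beta <- seq_len(ncol(x)) * 10
  d <- dplyr::mutate(sp, titer = as.numeric(x %*% beta))
  d <- d[withr::with_seed(3, sample(nrow(d), 70)), ]
  r <- default_roster(1)[c(1, 2, 3, 5), ] # ridge, lasso, k-neighbors, tree
  rk <- cv_rank(d, spec, r, cv_config(5, 1), target = "identity")
  expect_true(rk$family[1] %in% c("ridge", "lasso"))
  # lasso with light penalty recovers an additive target almost exactly
  expect_lt(rk$cv_rmse[1], 0.05 * sd(d$titer))
})

test_that("estimator failures downgrade to infinite RMSE with a warning", {
  spec <- tiny_spec(3)
  d <- simulate_screen(spec, quiet_params(), n = 40, seed = 33)
  r <- fast_roster()
  r$hyperparams[[which(r$family == "k-neighbors")]] <- list(k = -1) # invalid
  expect_warning(rk <- cv_rank(d, spec, r, cv_config(4, 1)), "k-neighbors")
  expect_true(is.infinite(rk$cv_rmse[rk$name == "k-neighbors"]))
  expect_true(all(is.finite(rk$cv_rmse[rk$name != "k-neighbors"])))
  # greedy selection ignores the failed estimator
  model <- greedy_select(rk)
  expect_false("k-neighbors" %in% vapply(model$members, `[[`, "", "name"))
})

test_that("ensemble prediction is the member mean and member-order invariant", {
  spec <- tiny_spec(3)
  d <- simulate_screen(spec, quiet_params(noise_sd = 0.1), n = 60, seed = 35)
  m <- fit_ensemble(d, spec, fast_roster(), cv_config(5, 1))
  newd <- enumerate_space(spec)[1:10, ]
  p <- predict(m, newd)
  back <- if (identical(m$target, "log")) exp else identity
  member_preds <- vapply(m$fits, function(f) {
    back(predict(f, encode_one_hot(newd, spec)))
  }, numeric(10))
  if (is.null(dim(member_preds))) member_preds <- matrix(member_preds, nrow = 10)
  expect_equal(p, rowMeans(member_preds), tolerance = 1e-12)
  m_rev <- m
  m_rev$fits <- rev(m$fits)
  expect_equal(predict(m_rev, newd), p, tolerance = 1e-12)
})

test_that("noise-free recoverable target gives near-perfect CV metrics", {
  spec <- tiny_spec(3)
  sp <- enumerate_space(spec)
  x <- encode_one_hot(sp, spec)
  d <- dplyr::mutate(sp, titer = as.numeric(x %*% seq(20, 240, length.out = ncol(x))) + 100)
  res <- evaluate_ensemble(d, spec, fast_roster(), cv_config(9, 2),
                           target = "identity")
  expect_lt(res$cv_rmse, 0.05 * sd(d$titer))
  expect_gt(res$cv_pcc, 0.99)
})

test_that("permuted titers give near-zero CV PCC across seeds", {
  spec <- tiny_spec(3)
  d <- simulate_screen(spec, quiet_params(noise_sd = 0.2), n = 150, seed = 40)
  r <- fast_roster()
  pccs <- vapply(1:20, function(s) {
    dp <- d
    dp$titer <- with_seed_local(s, sample(d$titer))
    res <- evaluate_ensemble(dp, spec, r, cv_config(5, s))
    res$cv_pcc
  }, numeric(1))
  expect_true(all(abs(pccs) < 0.3))
  expect_lt(abs(mean(pccs)), 0.12)
})

test_that("tidy, glance and plots expose the fitted model", {
  spec <- tiny_spec(3)
  d <- simulate_screen(spec, quiet_params(noise_sd = 0.1), n = 50, seed = 41)
  m <- fit_ensemble(d, spec, fast_roster(), cv_config(5, 1))
  tr <- tidy(m)
  expect_true(all(c("candidate", "rmse_if_added", "accepted", "ensemble_rmse") %in%
                    names(tr)))
  g <- glance(m)
  expect_equal(g$n_train, 50)
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(plot_selection_trace(m), "ggplot")
})
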