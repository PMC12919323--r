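test_that("candidate fitting covers all forms and records per-form failures", {
  profiles <- default_profiles()
  tab <- generate_species(profiles$Poplar, 300, seed = 42)
  fits <- suppressWarnings(fit_candidates(tab, species = "poplar",
                                          relation = "dbh_height"))
  expect_length(fits, 8)
  expect_true(all(vapply(fits, inherits, TRUE, "growth_fit")))
  # the s-curve generating form should win on its own data
  expect_identical(select_best(fits)$form$form_id, "s_curve")
  # degrees-of-freedom guard: cubic fails on 4 records, linear survives
  tiny <- tab[1:4, ]
  fits4 <- suppressWarnings(fit_candidates(tiny, relation = "dbh_height",
                                           forms = c("linear", "cubic")))
  expect_s3_class(fits4$cubic, "growth_fit_error")
  expect_s3_class(fits4$linear, "growth_fit")
  expect_error(fit_candidates(tab, species = "nosuch",
                              relation = "dbh_height"), "nosuch")
})

test_that("zero-noise linear data give r2 = 1 for all nested polynomials", {
  tab <- data.frame(species = "A", dbh = seq(5, 40, length.out = 30),
                    height = 2 + 0.4 * seq(5, 40, length.out = 30),
                    age = 1:30 + 0)
  fits <- fit_candidates(tab, relation = "dbh_height",
                         forms = c("linear", "quadratic", "cubic"))
  expect_true(all(vapply(fits, function(f) abs(f$r2 - 1) < 1e-12, TRUE)))
})

test_that("model selection maximizes fit and breaks ties toward parsimony", {
  mk <- function(id, r2, n = 200) {
    f <- growth_form(id)
    structure(list(form = f, r2 = r2,
                   adj_r2 = 1 - (1 - r2) * (n - 1) / (n - f$n_par),
                   converged = TRUE, n = n), class = "growth_fit")
  }
  # the published height-model comparison: S beats linear/logarithm/growth
  fits <- list(mk("linear", 0.519), mk("logarithmic", 0.569),
               mk("s_curve", 0.670), mk("growth", 0.502))
  expect_identical(select_best(fits)$form$form_id, "s_curve")
  expect_identical(select_best(fits, statistic = "r2")$form$form_id,
                   "s_curve")
  # exact r2 tie: fewer parameters win under plain-r2 ranking
  tie <- list(mk("quadratic", 0.8), mk("linear", 0.8))
  expect_identical(select_best(tie, statistic = "r2")$form$form_id, "linear")
  expect_identical(select_best(list(mk("growth", 0.3)))$form$form_id,
                   "growth")
  bad <- list(structure(list(form = growth_form("linear"), r2 = 0.9,
                             adj_r2 = 0.9, converged = FALSE),
                        class = "growth_fit"))
  expect_error(select_best(bad), "no converged")
})

test_that("multivariate extension appends covariates to the selected form", {
  x <- seq(5, 40, length.out = 60)
  best <- fit_closed_form("s_curve", x, exp(3.174 - 8.341 / x))
  ext <- extend_multivariate(best, c("dem", "p", "txn"))
  expect_identical(ext$form$form_id, "s_curve")
  expect_identical(ext$form$covariates, c("dem", "p", "txn"))
  expect_equal(unname(ext$init), c(3.174, -8.341, 0, 0, 0),
               tolerance = 1e-9)
  lin <- fit_closed_form("linear", x, 1 + 2 * x)
  expect_equal(extend_multivariate(lin, "dem")$form$n_par, 3L)
  expect_error(extend_multivariate(best, character()), "1-3")
})

test_that("multivariate fit with zero-effect covariates reproduces the basic fit", {
  set.seed(77)
  tab <- toy_inventory(120)
  tab$height <- exp(2.8 - 9 / tab$dbh) + rnorm(120, 0, 0.5)
  tab <- tab[tab$height > 0, ]
  m <- split_table(tab, c(0.7, 0.3), seed = 1)[[1]]
  best <- fit_closed_form("s_curve", m$dbh, m$height)
  zero <- m; zero$dem <- 0; zero$p <- 0; zero$txn <- 0
  multi <- fit_multivariate(zero, best, c("dem", "p", "txn"), "dbh_height")
  basic_nls <- fit_nls("s_curve", m$dbh, m$height)
  expect_equal(unname(multi$params[1:2]), unname(basic_nls$params),
               tolerance = 1e-6)
  expect_equal(unname(multi$params[3:5]), c(0, 0, 0))
})

test_that("multivariate modelling-set fit never loses to the basic fit on one scale", {
  profiles <- default_profiles()
  for (seed in 1:3) {
    tab <- generate_species(profiles$Poplar, 300, seed = seed)
    # inject a real covariate effect on the response
    tab$height <- tab$height * exp(0.002 * (tab$dem - mean(tab$dem)) / 100)
    m <- split_table(tab, c(0.7, 0.3), seed = seed)[[1]]
    basic <- fit_nls("s_curve", m$dbh, m$height)
    multi <- fit_multivariate(m, basic, c("dem", "p", "txn"), "dbh_height")
    if (multi$converged && basic$converged)
      expect_gte(multi$r2, basic$r2 - 1e-9)
  }
})

test_that("validation metrics reproduce the worked example and closed forms", {
  v <- validation_metrics(c(1, 2, 3), c(1, 2, 4), p = 1)
  expect_equal(v$me, 1 / 3)
  expect_equal(v$mre, 1 / 9)
  expect_equal(v$rmse, sqrt(1 / 2))
  expect_equal(v$r2, 0.5)
  # perfect prediction
  y <- c(2, 4, 7, 9)
  vp <- validation_metrics(y, y, 1)
  expect_equal(c(vp$me, vp$mre, vp$rmse), c(0, 0, 0))
  expect_equal(vp$r2, 1)
  # constant-shift closed form: me = c, rmse = |c| sqrt(n/(n-p))
  set.seed(3); y <- runif(25, 5, 20); cshift <- -1.7
  vs <- validation_metrics(y, y + cshift, p = 2)
  expect_equal(vs$me, cshift)
  expect_equal(vs$rmse, abs(cshift) * sqrt(25 / 23))
  # zero observations flag MRE as undefined
  v0 <- validation_metrics(c(0, 1, 2), c(1, 1, 2), p = 1)
  expect_true(is.na(v0$mre) && !v0$mre_defined)
  expect_error(validation_metrics(1:2, 1:2, p = 2), "n - p")
})

test_that("validation metrics agree with a brute-force recomputation", {
  set.seed(19)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    y <- runif(n, 1, 30); yhat <- y + rnorm(n)
    p <- sample(1:4, 1)
    if (n - p <= 0) next
    v <- validation_metrics(y, yhat, p)
    o <- metrics_oracle(y, yhat, p)
    expect_equal(v$me, o$me, tolerance = 1e-12)
    expect_equal(v$mre, o$mre, tolerance = 1e-12)
    expect_equal(v$rmse, o$rmse, tolerance = 1e-12)
    expect_equal(v$r2, o$r2, tolerance = 1e-12)
  }
})

test_that("hold-out validation uses the fitted form on the original scale", {
  profiles <- default_profiles()
  tab <- generate_species(profiles$Poplar, 200, seed = 6)
  parts <- split_table(tab, c(0.7, 0.3), seed = 6)
  fit <- fit_closed_form("s_curve", parts[[1]]$dbh, parts[[1]]$height)
  attr(fit, "relation") <- "dbh_height"
  v <- validate(fit, parts[[2]])
  manual <- validation_metrics(
    parts[[2]]$height, exp(fit$params[1] + fit$params[2] / parts[[2]]$dbh),
    p = 1)
  expect_equal(v$rmse, manual$rmse, tolerance = 1e-12)
  expect_gte(v$rmse, 0)
  expect_equal(v$p, 1L)
})

test_that("the full workflow runs end to end and reports all layouts", {
  profiles <- default_profiles()[c("Poplar", "SandJujube")]
  tab <- generate_inventory(profiles, n_per_species = 150, seed = 21)
  wf <- suppressWarnings(run_workflow(tab, seed = 2))
  expect_length(wf$reports, 4)
  expect_length(wf$selected, 3)
  expect_true(all(wf$vif >= 1))
  basic <- build_report(wf, "basic")
  expect_true(all(c("species", "equation", "r2", "f_value", "df1", "df2",
                    "p_value", "b0", "b1", "b2", "b3") %in% names(basic)))
  expect_equal(nrow(basic), 2 * 2 * 8)   # species x relations x forms
  val <- build_report(wf, "validation")
  expect_true(all(c("me", "mre", "rmse") %in% names(val)))
  expect_true(all(val$rmse >= 0))
  multi <- build_report(wf, "multivariate")
  expect_true(all(multi$equation != ""))
  # multivariate model of each report has the selected covariates
  for (rep in wf$reports)
    if (inherits(rep$multivariate, "growth_fit"))
      expect_identical(rep$multivariate$form$covariates, wf$selected)
})
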