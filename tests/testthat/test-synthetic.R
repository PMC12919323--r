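test_that("default profiles carry the published study conditions", {
  pr <- default_profiles()
  expect_setequal(names(pr), c("Spruce", "Poplar", "MixedWood", "SandJujube",
                               "PopulusEuphratica"))
  expect_equal(pr$Spruce$age_distribution$mean, 112.91)
  expect_equal(pr$Spruce$age_distribution$sd, 34.69)
  expect_equal(pr$Spruce$age_distribution[c("min", "max")],
               list(min = 16, max = 187))
  expect_identical(pr$SandJujube$true_age_dbh$form$form_id, "logistic")
  expect_equal(pr$SandJujube$true_age_dbh$params, c(19.835, 0.205, 16.246))
  expect_identical(pr$Poplar$true_dbh_height$form$form_id, "s_curve")
  expect_equal(pr$Poplar$true_dbh_height$params, c(3.174, -8.341))
  expect_identical(pr$Spruce$true_age_dbh$form$form_id, "growth")
  expect_equal(pr$Spruce$true_age_dbh$params, c(2.053, 0.008))
  for (p in pr) {
    expect_equal(p$covariate_targets[["dem"]], 0.52)
    expect_equal(p$covariate_targets[["p"]], 0.41)
    expect_equal(p$covariate_targets[["txn"]], 0.41)
    expect_true(all(abs(p$covariate_targets) < 1))
  }
  expect_error(species_profile("X", 10, 2, 1, 20,
                               age_dbh = list(form = "linear",
                                              params = c(1, 1)),
                               dbh_height = list(form = "linear",
                                                 params = c(1, 1)),
                               noise_sd_dbh = 1, noise_sd_height = 1,
                               covariate_targets = c(dem = 1.2),
                               covariate_ranges = list(dem = c(0, 1))),
               "\\(-1, 1\\)")
})

test_that("generation is seed-deterministic and positivity-guarded", {
  pr <- default_profiles()
  a <- generate_species(pr$SandJujube, 10, seed = 5)
  b <- generate_species(pr$SandJujube, 10, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_species(pr$SandJujube, 10, seed = 6)
  expect_false(identical(a$dbh, c2$dbh))
  big <- generate_species(pr$MixedWood, 2000, seed = 9)
  expect_true(all(big$dbh > 0 & big$height > 0 & big$age > 0))
  expect_true(all(big$age >= 11 & big$age <= 55))
})

test_that("zero-noise profiles fall exactly on the generating curves", {
  pr <- default_profiles()$Poplar
  pr$noise_sd_dbh <- 0; pr$noise_sd_height <- 0
  tab <- generate_species(pr, 50, seed = 2)
  expect_equal(tab$dbh, exp(3.536 - 17.461 / tab$age), tolerance = 1e-12)
  expect_equal(tab$height, exp(3.174 - 8.341 / tab$dbh), tolerance = 1e-12)
})

test_that("generated moments match the generating construction", {
  pr <- default_profiles()
  tab <- generate_species(pr$Spruce, 10000, seed = 1)
  # expected DBH under the construction: curve value integrated over the
  # truncated-normal age law (noise is mean-zero) -- quadrature oracle
  ad <- pr$Spruce$age_distribution
  dens <- function(a) dnorm(a, ad$mean, ad$sd) /
    (pnorm(ad$max, ad$mean, ad$sd) - pnorm(ad$min, ad$mean, ad$sd))
  expected <- integrate(function(a) exp(2.053 + 0.008 * a) * dens(a),
                        ad$min, ad$max)$value
  se <- sd(tab$dbh) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$dbh) - expected), 3 * se)
  # ages respect the truncation and target location
  expect_true(all(tab$age >= 16 & tab$age <= 187))
  expect_lt(abs(mean(tab$age) -
                  integrate(function(a) a * dens(a), ad$min, ad$max)$value),
            3 * sd(tab$age) / sqrt(nrow(tab)))
})

test_that("copula covariates hit their target correlations", {
  pr <- default_profiles()
  for (sp in names(pr)) {
    tab <- generate_species(pr[[sp]], 10000, seed = 12)
    for (nm in c("dem", "p", "txn")) {
      expect_lt(abs(cor(tab[[nm]], tab$dbh) -
                      pr[[sp]]$covariate_targets[[nm]]), 0.03,
                label = paste(sp, nm))
      rg <- pr[[sp]]$covariate_ranges[[nm]]
      expect_gt(mean(tab[[nm]] >= rg[1] & tab[[nm]] <= rg[2]), 0.99)
    }
  }
})

test_that("summaries report the inventory-table layout", {
  tab <- data.frame(species = "A", dbh = c(1, 2, 3), height = c(2, 2, 2),
                    age = c(5, 6, 7))
  s <- summarize_inventory(tab)
  d <- s[s$variable == "dbh", ]
  expect_equal(c(d$mean, d$sd, d$min, d$max), c(2, 1, 1, 3))
  one <- summarize_inventory(tab[1, ])
  expect_true(all(one$mean == one$min & one$min == one$max & one$sd == 0))
  # range guard: generated sizes stay near the profile's physical range
  pr <- default_profiles()
  big <- generate_species(pr$Spruce, 2193, seed = 1)
  sb <- summarize_inventory(big)
  expect_lte(sb$max[sb$variable == "dbh"], 40 + 3 * pr$Spruce$noise_sd_dbh)
})

test_that("fitting the generating form to zero-noise draws recovers the profile", {
  pr <- default_profiles()
  for (sp in c("Poplar", "SandJujube", "Spruce")) {
    p <- pr[[sp]]
    p$noise_sd_dbh <- 0; p$noise_sd_height <- 0
    p$dbh_height_mixture <- NULL
    tab <- generate_species(p, 500, seed = 3)
    fit <- suppressWarnings(fit_nls(p$true_age_dbh$form, tab$age, tab$dbh))
    expect_lt(max(abs(fit$params - p$true_age_dbh$params) /
                    abs(p$true_age_dbh$params)), 1e-6, label = sp)
  }
})

test_that("the pipeline closes over every default profile", {
  tab <- generate_inventory(n_per_species = 200, seed = 14)
  wf <- suppressWarnings(run_workflow(tab, seed = 3))
  expect_length(wf$reports, 10)
  for (rep in wf$reports) expect_s3_class(rep$best, "growth_fit")
  # elevation, the strongest simulated driver, survives screening
  hits <- vapply(1:10, function(i) {
    t2 <- generate_inventory(n_per_species = 200, seed = 300 + i)
    m <- split_table(t2, c(0.7, 0.3), seed = i,
                     stratify_by_species = TRUE)[[1]]
    "dem" %in% select_top(screen_covariates(m), 3)
  }, TRUE)
  expect_gte(sum(hits), 10 * 0.95 - 1e-9)
})
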