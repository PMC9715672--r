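test_that("coefficient files are validated on load", {
  coefs <- biodiversity_coefficients()
  expect_s3_class(coefs, "biodiversity_coefficients")
  expect_setequal(coefs$key, predicts_class_names())
  # qualitative SR ordering: primary >= secondary >= pasture >= cropland
  sr <- stats::setNames(coefs$sr_coef, coefs$key)
  expect_true(sr["primary"] >= sr["secondary"])
  expect_true(sr["secondary"] >= max(sr[c("pasture_light", "pasture_intense")]))
  crop_keys <- grep("^(annual|perennial|nfixing)_", coefs$key, value = TRUE)
  expect_true(min(sr[c("pasture_light", "pasture_intense")]) >=
                max(sr[crop_keys]))

  missing_cls <- write_temp_csv(c(
    "class,intensity,sr_coef,abundance_coef,similarity_coef",
    "primary,none,0,1.0,2.0"))
  expect_error(biodiversity_coefficients(missing_cls), "missing coefficients")

  uncoarsened <- write_temp_csv(c(
    "class,intensity,sr_coef,abundance_coef,similarity_coef",
    vapply(predicts_class_names(), function(k) {
      parts <- regmatches(k, regexec("^(annual|perennial|nfixing|pasture)_(.+)$", k))[[1]]
      if (length(parts)) sprintf("%s,%s,-0.2,0.8,%s", parts[2], parts[3],
                                 if (k == "annual_light") "1.5" else "1.0")
      else sprintf("%s,none,0,1.0,1.0", k)
    }, character(1))))
  expect_error(biodiversity_coefficients(uncoarsened), "coarsening")
})

test_that("species richness projection matches the Poisson-link arithmetic", {
  coefs <- biodiversity_coefficients()
  coefs$sr_coef[coefs$key == "annual_light"] <- -0.5

  expect_equal(project_relative_sr(
    uniform_predicts_layer(c(primary = 1)), coefs)[1, 1], 100)
  expect_equal(project_relative_sr(
    uniform_predicts_layer(c(annual_light = 1)), coefs)[1, 1],
    100 * exp(-0.5), tolerance = 1e-6)
  expect_equal(project_relative_sr(
    uniform_predicts_layer(c(primary = 0.5, annual_light = 0.5)), coefs)[1, 1],
    80.33, tolerance = 1e-4)
})

test_that("abundance projection squares the sqrt-scale ratio", {
  coefs <- biodiversity_coefficients()
  coefs$abundance_coef[coefs$key == "annual_light"] <- 0.8
  coefs$abundance_coef[coefs$key == "urban"] <- 0
  expect_equal(project_relative_abundance(
    uniform_predicts_layer(c(primary = 1)), coefs)[1, 1], 100)
  expect_equal(project_relative_abundance(
    uniform_predicts_layer(c(annual_light = 1)), coefs)[1, 1], 64)
  expect_equal(project_relative_abundance(
    uniform_predicts_layer(c(urban = 1)), coefs)[1, 1], 0)
  coefs$abundance_coef[coefs$key == "primary"] <- 0
  expect_error(project_relative_abundance(
    uniform_predicts_layer(c(primary = 1)), coefs), "positive")
})

test_that("similarity back-transform applies the 0.01 adjustment", {
  expect_equal(similarity_from_logit(0), (0.5 - 0.01) / 0.98)
  expect_equal(similarity_from_logit(0), 0.5)
  expect_equal(similarity_from_logit(50), 1)     # clipped at saturation
  expect_equal(similarity_from_logit(-50), 0)
  coefs <- biodiversity_coefficients()
  expect_equal(project_compositional_similarity(
    uniform_predicts_layer(c(primary = 1)), coefs)[1, 1], 100)
  coefs$similarity_coef[coefs$key == "primary"] <- -50
  expect_error(project_compositional_similarity(
    uniform_predicts_layer(c(primary = 1)), coefs), "zero")
})

test_that("BII is the exact product of abundance and similarity", {
  expect_equal(compute_bii(matrix(100), matrix(100))[1, 1], 100)
  expect_equal(compute_bii(matrix(0), matrix(80))[1, 1], 0)
  expect_error(compute_bii(matrix(1, 2, 2), matrix(1, 3, 3)), "grid")

  coefs <- biodiversity_coefficients()
  lay <- random_predicts_layer(tiny_grid(5, 5), seed = 4)
  maps <- project_biodiversity(lay, coefs)
  expect_equal(maps$bii, maps$abundance * maps$similarity / 100)
  # an all-primary map scores 100 on every indicator
  full <- project_biodiversity(
    uniform_predicts_layer(c(primary = 1), tiny_grid(2, 2)), coefs)
  for (ind in c("sr", "abundance", "similarity", "bii"))
    expect_equal(unique(as.vector(full[[ind]])), 100)
})

test_that("worked single-cell example: half primary, half degraded crop", {
  coefs <- biodiversity_coefficients()
  # relative abundance 0.6 and relative similarity 0.5 for the crop class
  coefs$abundance_coef[coefs$key == "annual_intense"] <- sqrt(0.6)
  s0 <- similarity_from_logit(coefs$similarity_coef[coefs$key == "primary"])
  target <- 0.5 * s0
  coefs$similarity_coef[coefs$key == "annual_intense"] <-
    stats::qlogis(target * 0.98 + 0.01)
  # coarsening: annual must stay intensity-invariant
  coefs$similarity_coef[coefs$class == "annual"] <-
    coefs$similarity_coef[coefs$key == "annual_intense"][1]
  lay <- uniform_predicts_layer(c(primary = 0.5, annual_intense = 0.5))
  ab <- project_relative_abundance(lay, coefs)
  sim <- project_compositional_similarity(lay, coefs)
  expect_equal(ab[1, 1], 80)
  expect_equal(sim[1, 1], 75)
  expect_equal(compute_bii(ab, sim)[1, 1], 60)
})

test_that("indicators are affine in the land-use fraction vector", {
  coefs <- biodiversity_coefficients()
  set.seed(7)
  classes <- predicts_class_names()
  for (rep in 1:5) {
    a <- stats::rgamma(length(classes), 1); a <- a / sum(a)
    b <- stats::rgamma(length(classes), 1); b <- b / sum(b)
    alpha <- stats::runif(1)
    mix <- alpha * a + (1 - alpha) * b
    for (fun in list(project_relative_sr, project_relative_abundance,
                     project_compositional_similarity)) {
      va <- fun(uniform_predicts_layer(stats::setNames(a, classes)), coefs)[1, 1]
      vb <- fun(uniform_predicts_layer(stats::setNames(b, classes)), coefs)[1, 1]
      vm <- fun(uniform_predicts_layer(stats::setNames(mix, classes)), coefs)[1, 1]
      expect_equal(vm, alpha * va + (1 - alpha) * vb, tolerance = 1e-9)
    }
  }
})

test_that("replacing pasture by lower-richness cropland decreases cell SR", {
  coefs <- biodiversity_coefficients()
  before <- project_relative_sr(
    uniform_predicts_layer(c(primary = 0.4, pasture_light = 0.5,
                             annual_light = 0.1)), coefs)[1, 1]
  after <- project_relative_sr(
    uniform_predicts_layer(c(primary = 0.4, pasture_light = 0.3,
                             annual_light = 0.3)), coefs)[1, 1]
  expect_lt(after, before)
})

test_that("class coefficients are recoverable from simulated sites", {
  truth <- biodiversity_coefficients()
  sites <- simulate_biodiversity_sites(truth, n_per_class = 400, seed = 21)
  fit <- fit_biodiversity_coefficients(sites)
  m <- match(truth$key, fit$key)
  expect_true(all(!is.na(m)))
  expect_lt(max(abs(fit$sr_coef[m] - truth$sr_coef)), 0.06)
  expect_lt(max(abs(fit$abundance_coef[m] - truth$abundance_coef)), 0.02)
  expect_lt(max(abs(fit$similarity_coef[m] - truth$similarity_coef)), 0.1)
})
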