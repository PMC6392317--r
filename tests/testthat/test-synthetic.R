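test_that("generation is bit-identical under a fixed seed", {
  cfg <- generator_config(seed = 7)
  g1 <- generate_panel(cfg)
  g2 <- generate_panel(cfg)
  expect_identical(g1$panel, g2$panel)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_panel(generator_config(seed = 8))
  expect_false(identical(g1$panel$level, g3$panel$level))
})

test_that("generated panels satisfy the panel invariants", {
  gen <- generate_panel(generator_config(seed = 19))
  p <- gen$panel
  expect_silent(validate_panel(p))
  expect_equal(nrow(p), 18 * 21)
  expect_true(all(p$level[!p$censored] >= 0))
  # zero policy: censored cells sit at 0 (< mdl), detections at >= mdl
  metals <- p[p$unit == "ug/L", ]
  expect_equal(metals$censored, metals$level < metals$mdl)
  # truth aligns one-to-one with the generated brands
  expect_setequal(unique(p$brand), gen$truth$classes$brand)
  expect_equal(nrow(gen$truth$levels), 18 * 20)
})

test_that("configuration errors are caught", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(seed = 1,
                                analytes = default_analyte_baselines()[0, ]),
               "empty analyte list")
  expect_error(generator_config(seed = 1, n_industrial = 0,
                                n_artisanal = 0, outlier = FALSE),
               "no brands")
})

test_that("boosted artisanal copper dominates the brand total", {
  shares <- purrr::map_dbl(1:10, function(s) {
    gen <- generate_panel(generator_config(seed = 1000 + s, cu_boost = 500))
    sh <- composition_shares(gen$panel)
    art <- gen$truth$classes$brand[gen$truth$classes$class == "artisanal"]
    min(sh$brand_share[sh$brand %in% art & sh$analyte == "Cu"])
  })
  expect_true(all(shares > 90))
})

test_that("without boosts the class labels carry no cluster signal", {
  hits <- purrr::map_lgl(1:20, function(s) {
    gen <- generate_panel(generator_config(
      seed = 2000 + s, cu_boost = 1, outlier = FALSE
    ))
    a <- assess_risk(gen$panel)
    cl <- cluster_thq(a, exclude = "ethanol", k = 2)
    art <- gen$truth$classes$brand[gen$truth$classes$class == "artisanal"]
    cl_of <- setNames(cl$cut$cluster, cl$cut$item)
    # planted recovery = one cut cluster exactly the artisanal set
    any(vapply(1:2, function(k) {
      setequal(names(cl_of)[cl_of == k], art)
    }, logical(1)))
  })
  expect_lte(sum(hits), 2)
})

test_that("the outlier brand tops the industrial hazard ranking", {
  top <- purrr::map_lgl(1:10, function(s) {
    gen <- generate_panel(generator_config(seed = 3000 + s))
    a <- assess_risk(gen$panel)
    ind <- gen$truth$classes$brand[
      gen$truth$classes$class %in% c("industrial", "outlier")
    ]
    hi_ind <- a$hi[a$hi$brand %in% ind, ]
    hi_ind$brand[which.max(hi_ind$hi)] == "OUT01"
  })
  expect_gte(mean(top), 0.9)
})

test_that("zero duplicate noise reproduces the pre-noise truth exactly", {
  gen <- generate_panel(generator_config(seed = 4, duplicate_cv = 0,
                                         include_ethanol = FALSE))
  joined <- dplyr::left_join(gen$panel, gen$truth$levels,
                             by = c("brand", "analyte"))
  clean <- joined[!joined$censored, ]
  expect_equal(clean$level, clean$true_level)
  expect_equal(unique(gen$panel$sd), 0)
})

test_that("censoring rises monotonically with the detection limit", {
  fracs <- purrr::map_dbl(c(0.5, 1, 2, 8), function(mult) {
    base <- default_analyte_baselines()
    base$mdl <- base$mdl * mult
    gen <- generate_panel(generator_config(seed = 6, analytes = base))
    mean(gen$panel$censored[gen$panel$unit == "ug/L"])
  })
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[4], fracs[1])
})

test_that("baseline log-locations are recovered without bias", {
  cfg <- generator_config(seed = 100, n_industrial = 30, n_artisanal = 0,
                          outlier = FALSE, include_ethanol = FALSE)
  cfg$analytes$mdl <- 0 # uncensored mechanism
  rec <- parameter_recovery_suite(cfg, n_reps = 30)
  expect_equal(nrow(rec), 20)
  expect_lt(median(abs(rec$bias / rec$se)), 2)
  expect_true(all(rec$coverage > 0.7))
})

test_that("censored cells are handled by the censored-likelihood estimator", {
  base <- default_analyte_baselines()[1:3, ]
  base$mdl <- base$median / 2 # substantial left-censoring
  cfg <- generator_config(seed = 55, n_industrial = 40, n_artisanal = 0,
                          outlier = FALSE, include_ethanol = FALSE,
                          analytes = base)
  rec <- parameter_recovery_suite(cfg, n_reps = 5)
  expect_true(all(rec$censored_frac > 0))
  expect_true(all(abs(rec$bias) < 0.5))
})

test_that("the in-text fixture matches the printed study inputs", {
  fx <- paper_fixture()
  expect_equal(nrow(fx$brands), 18)
  expect_equal(fx$profile$IR, 78.54)
  expect_equal(fx$profile$EF, 240)
  expect_equal(fx$profile$BW, 60)
  expect_equal(fx$profile$ATn, 21407)
  expect_equal(fx$brands$abv[fx$brands$brand == "REX"], 20)
  awe <- fx$brand_hi[fx$brand_hi$brand == "AWE", ]
  expect_equal(awe$metal_content, 4342)
  expect_equal(awe$cu_level, 4214)
  expect_equal(fx$reference$rfd[fx$reference$analyte == "ethanol"], 62)
  expect_equal(fx$reference$rfd[fx$reference$analyte == "Pb"], 1.5)
  expect_equal(fx$reference$csf[fx$reference$analyte %in%
                                  c("As", "Cr", "Pb")],
               c(1.5, 0.5, 0.0085))
})
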