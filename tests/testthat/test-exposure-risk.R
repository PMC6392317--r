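# Frozen oracle values, hand-evaluated from the intake equation with the
# adult profile (IR 78.54, EF 240, ED 43.65, BW 60, ATn 21407, CF 1e-3):
# ADI(As, Mc = 1.3e-3 mg/kg) = 1.3e-3 * 78.54e-3 * 240 * 43.65 / 1284420
ADI_AS_ORACLE <- 8.32767e-7
THQ_AS_ORACLE <- ADI_AS_ORACLE / 3e-4    # shipped As RfD
CR_AS_ORACLE <- ADI_AS_ORACLE * 1.5      # As slope factor

test_that("ethanol Mc and ingestion-rate conversions follow their definitions", {
  expect_equal(ethanol_mc(40), 4e5)
  expect_equal(ethanol_mc(0), 0)
  expect_equal(ethanol_mc(100), 1e6)
  expect_equal(ethanol_mc(40, "table2"), 4000)
  expect_error(ethanol_mc(101), "\\[0, 100\\]")

  expect_equal(ingestion_rate(2.5, 100, 40, 0.7854), 78.54)
  # one WHO standard 30-mL pour of pure ethanol
  expect_equal(ingestion_rate(1, 30, 100, 0.7854), 23.562)
  expect_equal(ingestion_rate(2.5, 100, 0), 0)
})

test_that("average daily intake reproduces hand-evaluated values", {
  prof <- acoli_exposure_profile()
  expect_equal(average_daily_intake(0, prof), 0)
  expect_equal(average_daily_intake(1.3e-3, prof), ADI_AS_ORACLE,
               tolerance = 1e-5)
  expect_error(average_daily_intake(-1, prof), "non-negative")
})

test_that("THQ distinguishes missing references from zero risk", {
  expect_equal(target_hazard_quotient(ADI_AS_ORACLE, 3e-4), THQ_AS_ORACLE,
               tolerance = 1e-6)
  expect_equal(target_hazard_quotient(0, 1), 0)
  expect_true(is.na(target_hazard_quotient(1, NA)))
  expect_error(target_hazard_quotient(1, 0), "RfD")
})

test_that("row-percent transform normalizes, is idempotent, flags zero rows", {
  expect_equal(as.numeric(row_percent_transform(matrix(c(1, 3), 1))),
               c(25, 75))
  m <- matrix(c(10, 90, 40, 60), 2, byrow = TRUE)
  once <- row_percent_transform(m)
  expect_equal(row_percent_transform(once), once)
  expect_equal(rowSums(once), c(100, 100))

  mz <- matrix(c(1, 1, 0, 0), 2, byrow = TRUE)
  rz <- row_percent_transform(mz)
  expect_true(all(is.na(rz[2, ])))

  byan <- row_percent_transform(m, margin = "analytes")
  expect_equal(colSums(byan), c(100, 100))
})

test_that("hazard indices aggregate THQs with ratio strings and categories", {
  h <- hazard_index(c(ethanol = 4.1))
  expect_equal(h$hi, 4.1)
  expect_equal(h$ratio, ">1")
  expect_equal(as.character(h$category), "concern")

  hm <- hazard_index(c(Cu = 0.05, As = 0.023, Zn = NA))
  expect_equal(hm$hi, 0.073)
  expect_equal(hm$excluded[[1]], "Zn")
  expect_equal(hm$ratio, "1/14")

  expect_error(hazard_index(numeric(0)), "empty inclusion set")
  expect_error(hazard_index(c(Cu = NA_real_)), "non-missing")
  expect_equal(hi_ratio(0), "0")
  expect_equal(as.character(hi_category(c(0.5, 1, 5))),
               c("safe", "concern", "high"))
})

test_that("carcinogenic risk pools slope-factor analytes and reports exclusions", {
  prof <- acoli_exposure_profile()
  as_only <- carcinogenic_risk(c(As = 1.3e-3), prof)
  expect_equal(as_only$cr, CR_AS_ORACLE, tolerance = 1e-5)

  mixed <- carcinogenic_risk(c(As = 1.3e-3, Zn = 5, Cu = 2), prof)
  expect_equal(mixed$cr, CR_AS_ORACLE, tolerance = 1e-5)
  expect_setequal(mixed$excluded[[1]], c("Zn", "Cu"))

  zero <- carcinogenic_risk(c(As = 0, Pb = 0, Cr = 0), prof)
  expect_equal(zero$cr, 0)
  expect_equal(zero$persons_per_case, Inf)

  expect_error(carcinogenic_risk(c(Zn = 1), prof), "slope factor")
  expect_equal(persons_per_case(9.8e-6) * 9.8e-6, 1, tolerance = 1e-4)
})

test_that("ADI, THQ and CR are homogeneous of degree 1 in exposure inputs", {
  prof <- acoli_exposure_profile()
  prof2 <- exposure_profile(IR = 2 * prof$IR, EF = prof$EF, ED = prof$ED,
                            BW = prof$BW, ATn = prof$ATn, CF = prof$CF)
  mc <- c(As = 1.3e-3, Pb = 2e-4)
  expect_equal(average_daily_intake(2 * mc, prof),
               2 * average_daily_intake(mc, prof))
  expect_equal(average_daily_intake(mc, prof2),
               2 * average_daily_intake(mc, prof))
  expect_equal(carcinogenic_risk(2 * mc, prof)$cr,
               2 * carcinogenic_risk(mc, prof)$cr)
})

test_that("brand HI is additive over any analyte partition", {
  gen <- generate_panel(generator_config(seed = 5))
  a <- assess_risk(gen$panel)
  thq_b1 <- a$thq |>
    dplyr::filter(brand == "IND01", analyte != "ethanol")
  thqs <- setNames(thq_b1$thq, thq_b1$analyte)
  total <- hazard_index(thqs)$hi
  expect_equal(a$hi$hi[a$hi$brand == "IND01"], total,
               tolerance = 1e-12)
  half <- sample(names(thqs), 10)
  split_sum <- hazard_index(thqs, include = half)$hi +
    hazard_index(thqs, include = setdiff(names(thqs), half))$hi
  expect_equal(split_sum, total, tolerance = 1e-12)
})

test_that("an all-zero panel carries zero risk in every summary", {
  zero_panel <- conc_panel(
    brand = rep(c("B1", "B2"), each = 3),
    analyte = rep(c("As", "Pb", "Cr"), 2),
    level = 0
  )
  a <- assess_risk(zero_panel)
  expect_equal(a$hi$hi, c(0, 0))
  expect_equal(as.character(a$hi$category), c("safe", "safe"))
  expect_equal(a$cancer_pooled$cr, 0)
  expect_equal(a$cancer_pooled$persons_per_case, Inf)
})

test_that("strict mode removes the ethanol double count", {
  panel <- conc_panel("B1", "ethanol", 40)
  paper <- assess_risk(panel, mode = "paper")
  strict <- assess_risk(panel, mode = "strict")
  expect_equal(strict$ethanol$thq / paper$ethanol$thq, 1 / 0.4,
               tolerance = 1e-12)
  # hand-evaluated: 1e6 * 78.54e-3 * 240 * 43.65 / (60 * 21407) = 640.59
  expect_equal(strict$adi$adi, 640.59, tolerance = 1e-4)
})

test_that("tidy and glance expose the assessment as tibbles", {
  gen <- generate_panel(generator_config(seed = 5))
  a <- assess_risk(gen$panel)
  td <- tidy(a)
  expect_true(all(c("brand", "analyte", "mc", "adi", "thq") %in% names(td)))
  expect_equal(nrow(td), nrow(a$adi))
  gl <- glance(a)
  expect_equal(gl$n_brands, 18)
  expect_equal(as.character(gl$max_hi_brand), a$hi$brand[1])
  expect_s3_class(autoplot(a), "ggplot")
})
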