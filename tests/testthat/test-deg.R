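sim_table <- function(...) simulate_expression_table(expression_sim_spec(...))

test_that("expressed calls follow the mean-FPKM rule", {
  fpkm <- matrix(0, 3, 32)
  units <- design_units_fixture()
  colnames(fpkm) <- units
  rownames(fpkm) <- c("zero", "one_unit", "low")
  fpkm["one_unit", grepl("^DZ_CTL_0.5h", units)] <- 5
  fpkm["low", ] <- 0.2
  tab <- expression_table(fpkm)
  ex <- call_expressed(tab)
  expect_false(ex[["zero"]])
  expect_true(ex[["one_unit"]])   # FPKM 5 in one unit suffices by default
  expect_false(ex[["low"]])
  expect_true(call_expressed(tab, min_fpkm = 0.1)[["low"]])
  expect_false(call_expressed(tab, min_units = 2)[["one_unit"]])
})

test_that("non-expressed genes get NOTEST status and never become DEGs", {
  tab <- sim_table(n_genes = 50, zone_effects = NULL,
                   stress_effects = NULL, seed = 3)
  tab$fpkm[1:5, ] <- 0
  rec <- differential_expression(tab, comparison = "EZvsDZ_CTL_0.5h")
  expect_true(all(rec$status[1:5] == "NOTEST"))
  expect_true(all(is.na(rec$p_value[1:5])))
  expect_false(any(rec$is_deg[1:5]))
  expect_true(all(rec$status[6:50] == "OK"))
})

test_that("q-values match a brute-force Benjamini-Hochberg step-up", {
  tab <- sim_table(n_genes = 500, seed = 17)
  rec <- differential_expression(tab, comparison = "PEGvsCTL_DZ_3h")
  ok <- rec$status == "OK"
  expect_equal(rec$q_value[ok], bh_stepup(rec$p_value[ok]), tolerance = 1e-12)
})

test_that("swapping numerator and denominator negates log2fc and keeps p and q", {
  tab <- sim_table(n_genes = 200, zone_effects = NULL,
                   stress_effects = NULL, seed = 8)
  a <- differential_expression(tab, "EZ_CTL_0.5h", "DZ_CTL_0.5h")
  b <- differential_expression(tab, "DZ_CTL_0.5h", "EZ_CTL_0.5h")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$q_value, b$q_value, tolerance = 1e-12)
  expect_error(differential_expression(tab, "DZ_CTL_0.5h", "DZ_CTL_0.5h"),
               "differ")
  expect_error(differential_expression(tab, "XX_CTL_0.5h", "DZ_CTL_0.5h"),
               "not present")
})

test_that("noiseless planted fold changes hit the three-part rule as designed", {
  tab <- sim_table(
    n_genes = 60, baseline_log2_mean = 6, baseline_log2_sd = 0.5,
    zone_effects = data.frame(zone = "DZ", n = 10, log2fc = 3),
    stress_effects = NULL, replicate_log2_sd = 0, seed = 5)
  # add minute replicate jitter so the t-test is defined but fc is intact
  set.seed(1); tab$fpkm <- tab$fpkm * 2^matrix(rnorm(length(tab$fpkm), 0, 0.01),
                                               nrow(tab$fpkm))
  rec <- differential_expression(tab, comparison = "EZvsDZ_CTL_0.5h")
  expect_equal(rec$log2fc[1:10], rep(-3, 10), tolerance = 0.06)
  expect_true(all(rec$is_deg[1:10]))
  expect_false(any(rec$is_deg[11:60]))

  # a planted |log2FC| of 1.9 fails the fold-change gate however significant
  tab19 <- sim_table(
    n_genes = 40, baseline_log2_mean = 6, baseline_log2_sd = 0.5,
    zone_effects = data.frame(zone = "DZ", n = 10, log2fc = 1.9),
    stress_effects = NULL, replicate_log2_sd = 0.05, seed = 6)
  rec19 <- differential_expression(tab19, comparison = "EZvsDZ_PEG_3h",
                                   pseudocount = 0)
  expect_false(any(rec19$is_deg[1:10]))
  expect_true(all(rec19$p_value[1:10] < 0.05))  # significant, gated out
})

test_that("a gene constant everywhere has log2fc 0, p 1, and is not a DEG", {
  fpkm <- matrix(8, 2, 32)
  colnames(fpkm) <- design_units_fixture()
  rownames(fpkm) <- c("g1", "g2")
  rec <- differential_expression(expression_table(fpkm), "EZ_CTL_0.5h",
                                 "DZ_CTL_0.5h")
  expect_equal(rec$log2fc, c(0, 0))
  expect_equal(rec$p_value, c(1, 1))
  expect_false(any(rec$is_deg))
})

test_that("the null false-discovery fraction stays below 1%", {
  tab <- sim_table(n_genes = 5000, zone_effects = NULL, stress_effects = NULL,
                   replicate_log2_sd = 0.5, seed = 23)
  cls <- deg_classification(tab)
  frac <- vapply(cls$records, function(r) mean(r$is_deg), numeric(1))
  expect_true(all(frac < 0.01))
})

test_that("planted zone preference is recovered without cross-assignment", {
  tab <- sim_table(
    n_genes = 1000,
    zone_effects = data.frame(zone = c("DZ", "EZ"), n = c(100, 100), log2fc = 3),
    stress_effects = NULL, replicate_log2_sd = 0.5, seed = 31)
  cls <- deg_classification(tab)
  planted_dz <- tab$truth$class == "DZ-preferred"
  planted_ez <- tab$truth$class == "EZ-preferred"
  expect_gte(sum(cls$zone$dz_all4[planted_dz]), 80)
  expect_gte(sum(cls$zone$ez_all4[planted_ez]), 80)
  expect_equal(sum(cls$zone$ez_all4[planted_dz]), 0)
  expect_equal(sum(cls$zone$dz_all4[planted_ez]), 0)
  # core and partition invariants
  expect_true(all(cls$zone$core_dz == cls$zone$dz_all4))
  expect_equal(cls$summary$dz_preferred + cls$summary$ez_preferred,
               cls$summary$zone_all_four)
  expect_lte(cls$summary$zone_all_four, cls$summary$zone_any_condition)
})

test_that("significance in three of four conditions is not all-four preference", {
  genes <- paste0("g", 1:3)
  mk <- function(fc, deg) {
    structure(data.frame(gene_id = genes, comparison = "c", log2fc = fc,
                         p_value = 0.001, q_value = 0.001, status = "OK",
                         is_deg = deg, stringsAsFactors = FALSE),
              class = c("deg_records", "data.frame"))
  }
  # gene 1: -3 significant everywhere; gene 2: -3 in three, -1 in the fourth;
  # gene 3: never
  recs <- list(mk(c(-3, -3, 0.1), c(TRUE, TRUE, FALSE)),
               mk(c(-3, -3, 0.1), c(TRUE, TRUE, FALSE)),
               mk(c(-3, -3, 0.1), c(TRUE, TRUE, FALSE)),
               mk(c(-3, -1, 0.1), c(TRUE, FALSE, FALSE)))
  z <- classify_zone_preference(recs)
  expect_true(z$dz_all4[1])
  expect_false(z$dz_all4[2])
  expect_true(z$dz_any[2])
  expect_equal(as.character(z$zone_class),
               c("DZ-preferred", "some-conditions", "none"))
  expect_error(classify_zone_preference(recs[1:3]), "four")
})

test_that("stress timing classes are recovered from planted responses", {
  tab <- sim_table(
    n_genes = 1200, zone_effects = NULL,
    stress_effects = data.frame(
      zone = c("DZ", "EZ", "EZ"),
      timing = c("early-only", "sustained", "late"),
      n = c(60, 60, 60), log2fc = 3),
    replicate_log2_sd = 0.5, seed = 41)
  cls <- deg_classification(tab)
  for (tim in c("early-only", "sustained", "late")) {
    planted <- which(tab$truth$timing == tim)
    got <- cls$stress$timing_global[planted]
    expect_gte(mean(got == tim, na.rm = TRUE) * mean(!is.na(got)), 0.75)
  }
  expect_error(classify_stress_response(cls$records[1:3]), "PEGvsCTL")
})

test_that("simple timing paths classify as the definitions say", {
  genes <- "g"
  mk <- function(deg, fc = 3) {
    structure(data.frame(gene_id = genes, comparison = "c", log2fc = fc,
                         p_value = 0.01, q_value = 0.01, status = "OK",
                         is_deg = deg, stringsAsFactors = FALSE),
              class = c("deg_records", "data.frame"))
  }
  nm <- paste0("PEGvsCTL_", rep(c("DZ", "EZ"), each = 2), "_", c("0.5h", "3h"))
  # DEG at DZ-0.5h only -> early-only in DZ
  r1 <- setNames(list(mk(TRUE), mk(FALSE), mk(FALSE), mk(FALSE)), nm)
  s1 <- classify_stress_response(r1)
  expect_equal(s1$dz_timing, "early-only")
  expect_true(s1$responsive)
  # DEG at both EZ times, same sign -> sustained in EZ
  r2 <- setNames(list(mk(FALSE), mk(FALSE), mk(TRUE), mk(TRUE)), nm)
  expect_equal(classify_stress_response(r2)$ez_timing, "sustained")
  r3 <- setNames(list(mk(FALSE), mk(FALSE), mk(TRUE), mk(TRUE, fc = -3)), nm)
  expect_equal(classify_stress_response(r3)$ez_timing, "mixed")
})

test_that("summary counts respect the planted design and empty input gives zeros", {
  tab <- sim_table(n_genes = 800, seed = 13)  # default planted design
  cls <- deg_classification(tab)
  s <- cls$summary
  # planted sizes: 100 DZ-, 150 EZ-preferred, 100 stress-responsive
  expect_gt(s$dz_preferred, 80); expect_lte(s$dz_preferred, 110)
  expect_gt(s$ez_preferred, 120); expect_lte(s$ez_preferred, 165)
  expect_gt(s$stress_responsive, 70); expect_lte(s$stress_responsive, 115)
  expect_equal(s$dz_preferred + s$ez_preferred, s$zone_all_four)
  expect_true(all(c(s$timing_early_only, s$timing_sustained, s$timing_late) >= 0))
  expect_equal(sum(vapply(cls$records[5:8], function(r) sum(r$is_deg), numeric(1))),
               sum(s$per_zone_time$n_deg))
  expect_equal(s$per_zone_time$n_deg, s$per_zone_time$up + s$per_zone_time$down)

  null_tab <- sim_table(n_genes = 100, zone_effects = NULL,
                        stress_effects = NULL, replicate_log2_sd = 0,
                        baseline_log2_sd = 0.5, seed = 2)
  cls0 <- deg_classification(null_tab)
  expect_equal(cls0$summary$zone_any_condition, 0)
  expect_equal(cls0$summary$stress_responsive, 0)
})

test_that("recall is monotone in the planted effect size", {
  recall <- vapply(c(2.5, 3, 4), function(fc) {
    tab <- sim_table(
      n_genes = 600,
      zone_effects = data.frame(zone = "DZ", n = 80, log2fc = fc),
      stress_effects = NULL, replicate_log2_sd = 0.5, seed = 55)
    cls <- deg_classification(tab)
    mean(cls$zone$dz_all4[tab$truth$class == "DZ-preferred"])
  }, numeric(1))
  expect_true(all(diff(recall) >= 0))
  expect_gte(recall[2], 0.8)
})
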