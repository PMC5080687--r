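fx <- ib_fixtures()

test_that("yields and productivities match the reported endpoints", {
  # 21.62 g/L glucose consumed in 16 h: Y_B 0.20 g/g, P_B 0.28 g/L/h
  g16 <- fx$reported[["glucose_16h"]]
  expect_equal(mass_yield(g16, "butanol"), 0.20, tolerance = 0.005 / 0.2)
  expect_equal(productivity(g16, "butanol"), 0.28, tolerance = 0.005 / 0.28)

  # pH 5.5: Y_B 0.20, Y_IB 0.30 g/g; P_B 0.29, P_IB 0.44 g/L/h
  p55 <- fx$reported[["ph5.5"]]
  expect_equal(mass_yield(p55, "butanol"), 0.2035, tolerance = 1e-3)
  expect_equal(mass_yield(p55, "ib"), 0.3003, tolerance = 1e-3)
  expect_equal(productivity(p55, "butanol"), 0.2947, tolerance = 1e-3)
  expect_equal(productivity(p55, "ib"), 0.435, tolerance = 1e-3)

  # glucose:glycerol 14:8: Y_B 5.38 / 20.36
  expect_equal(mass_yield(fx$table3[["14:8"]], "butanol"),
               0.264243614931, tolerance = 1e-9)

  # degenerate inputs
  none <- endpoint_record("none", 10, c(glucose = 5), c(butanol = 0))
  expect_identical(mass_yield(none, "butanol"), 0)
  expect_identical(productivity(none, "ib"), 0)
  zero <- endpoint_record("zero", 10, c(glucose = 0), c(butanol = 1))
  expect_error(mass_yield(zero, "butanol"), class = "ib_computation_error")
})

test_that("butanol/isopropanol ratio handles the undefined case", {
  expect_equal(bi_ratio(fx$table3[["14:8"]]), 5.38 / 1.57)
  eq <- endpoint_record("eq", 10, c(glucose = 10),
                        c(butanol = 2, isopropanol = 2))
  expect_identical(bi_ratio(eq), 1)
  expect_true(is.na(bi_ratio(fx$table2[["glycerol"]])))  # IPA = 0
})

test_that("NAD(P)H generation and requirement follow the stoichiometric coefficients", {
  expect_equal(nadph_generated(fx$table3[["20:2"]]), 259.97,
               tolerance = 0.2 / 260)
  expect_equal(nadph_required(fx$table3[["22:0"]]), 289.93636347,
               tolerance = 1e-9)

  empty <- endpoint_record("empty", 10, c(glucose = 0), c(butanol = 0))
  expect_identical(nadph_generated(empty), 0)
  expect_identical(nadph_required(empty), 0)

  xyl <- fx$table2[["xylose"]]
  expect_error(nadph_generated(xyl), class = "ib_computation_error")
  err <- tryCatch(nadph_generated(xyl), error = identity)
  expect_match(conditionMessage(err), "xylose")

  pdo <- fx$table2[["glycerol"]]  # produces 1,3-PDO
  expect_error(nadph_required(pdo), class = "ib_computation_error")
  expect_equal(nadph_required(pdo, allow_extrapolated = TRUE),
               2 * 2.20 / 88.11 * 1000 + 1 * 3.40 / 76.09 * 1000 +
                 4 * 3.91 / 74.12 * 1000)
})

test_that("random compositions agree with a brute-force term-by-term sum", {
  set.seed(42)
  for (i in 1:25) {
    rec <- random_record()
    hand_req <- sum(vapply(names(ref_req_coef), function(p) {
      conc <- if (p %in% names(rec$products)) rec$products[[p]] else 0
      ref_req_coef[[p]] * conc / ref_masses[[p]] * 1000
    }, numeric(1)))
    expect_equal(nadph_required(rec), hand_req, tolerance = 1e-12)
    hand_gen <- sum(vapply(names(rec$substrates_consumed), function(s)
      ref_gen_coef[[s]] * rec$substrates_consumed[[s]] / ref_masses[[s]] * 1000,
      numeric(1)))
    expect_equal(nadph_generated(rec), hand_gen, tolerance = 1e-12)
  }
})

test_that("NAD(P)H per carbon mole is pinned at 1/3 (glucose) and 2/3 (glycerol)", {
  glu <- endpoint_record("glu", 10, c(glucose = 17.3), c(butanol = 1))
  gly <- endpoint_record("gly", 10, c(glycerol = 9.1), c(butanol = 1))
  expect_equal(nadph_per_cmol(glu), 1 / 3, tolerance = 1e-12)
  expect_equal(nadph_per_cmol(gly), 2 / 3, tolerance = 1e-12)
  expect_equal(nadph_per_cmol(fx$table3[["14:8"]]), 0.45,
               tolerance = 0.005 / 0.45)
})

test_that("ferredoxin fraction is the clipped NAD(P)H shortfall", {
  # from the printed 22:0 values: (290.02 - 242.51) / 290.02 = 0.1638
  expect_lt(abs(fd_fraction(fx$table3[["22:0"]]) - 0.163816), 1e-3)
  # 9:13 generates more than it requires: clipped to exactly 0
  expect_identical(fd_fraction(fx$table3[["9:13"]]), 0)
  # generated == required boundary
  b <- endpoint_record("b", 10, c(glucose = 180.16 / 10),  # 100 mM -> 200 gen
                       c(isopropanol = 0.1 * 200 * 60.10 / 100))  # 200 req
  expect_equal(fd_fraction(b), 0, tolerance = 1e-12)
  noreq <- endpoint_record("noreq", 10, c(glucose = 10), c(acetone = 1))
  expect_error(fd_fraction(noreq), class = "ib_computation_error")
})

test_that("per-carbon-mole production matches direct arithmetic and declines for IPA", {
  pc <- per_cmol_production(fx$table3[["22:0"]])
  expect_equal(pc[["buoh_c"]], 0.0802801485047, tolerance = 1e-6)
  expect_equal(pc[["ib_c"]], pc[["buoh_c"]] + pc[["ipa_c"]])
  zero <- endpoint_record("z", 10, c(glucose = 10), c(butanol = 0))
  expect_true(all(per_cmol_production(zero) == 0))

  # IPA_C strictly decreases with the glycerol share across the ratio series
  ipa_c <- vapply(fx$table3, function(r)
    per_cmol_production(r)[["ipa_c"]], numeric(1))
  expect_true(all(diff(ipa_c) < 0))

  # carbon-mole unit variant scales each product by its carbon count
  pc_c <- per_cmol_production(fx$table3[["22:0"]], unit = "cmol")
  expect_equal(pc_c[["buoh_c"]], 4 * pc[["buoh_c"]])
  expect_equal(pc_c[["ipa_c"]], 3 * pc[["ipa_c"]])
})

test_that("carbon recovery reproduces the reported percentages and conserves carbon", {
  p55 <- fx$reported[["ph5.5"]]
  expect_equal(carbon_recovery(p55, "ib"), 47.5, tolerance = 0.1 / 47.5)
  expect_equal(carbon_recovery(p55, "butanol"), 33.0, tolerance = 0.1 / 33)
  # products carrying exactly the consumed carbon -> 100%
  cons_c <- carbon_millimolar(10, "glucose")
  but <- cons_c / 4 * 74.12 / 1000  # g/L butanol holding the same carbon
  full <- endpoint_record("full", 10, c(glucose = 10), c(butanol = but))
  expect_equal(carbon_recovery(full, "butanol"), 100, tolerance = 1e-12)
})

test_that("fermentation mode classification separates acid and solvent producers", {
  expect_identical(classify_mode(fx$table2[["xylose"]]), "acidogenic")
  expect_identical(classify_mode(fx$table2[["glucose"]]), "solventogenic")
  allzero <- endpoint_record("z", 10, c(glucose = 5),
                             c(butanol = 0, acetic_acid = 0))
  expect_warning(mode <- classify_mode(allzero), "tie")
  expect_identical(mode, "solventogenic")
})

test_that("aggregate analysis equals its component operations on random records", {
  set.seed(7)
  for (i in 1:100) {
    rec <- random_record(sprintf("r%03d", i))
    res <- analyze_endpoint(rec)
    expect_identical(res$y_b, mass_yield(rec, "butanol"))
    expect_identical(res$y_ib, mass_yield(rec, "ib"))
    expect_identical(res$p_b, productivity(rec, "butanol"))
    expect_identical(res$p_ib, productivity(rec, "ib"))
    expect_identical(res$bi_ratio, bi_ratio(rec))
    expect_identical(res$total_carbon_mM, total_carbon(rec))
    expect_identical(res$nadph_gen_mM, nadph_generated(rec))
    expect_identical(res$nadph_req_mM, nadph_required(rec))
    expect_identical(res$nadph_c, nadph_per_cmol(rec))
    if (res$nadph_req_mM > 0) {
      expect_identical(res$fd_fraction, fd_fraction(rec))
    }
    expect_identical(res$per_cmol, per_cmol_production(rec))
    expect_identical(res$carbon_recovery[["ib"]], carbon_recovery(rec, "ib"))
    expect_true(res$y_ib >= res$y_b)
  }
})

test_that("intensive metrics are scale-invariant; molar totals double with scale", {
  set.seed(21)
  for (i in 1:20) {
    rec <- random_record()
    doubled <- endpoint_record(rec$label, rec$duration_h,
                               2 * rec$substrates_consumed, 2 * rec$products)
    a <- analyze_endpoint(rec); b <- analyze_endpoint(doubled)
    expect_equal(b$y_b, a$y_b)
    expect_equal(b$y_ib, a$y_ib)
    expect_equal(b$bi_ratio, a$bi_ratio)
    expect_equal(b$nadph_c, a$nadph_c)
    expect_equal(b$fd_fraction, a$fd_fraction)
    expect_equal(b$per_cmol, a$per_cmol)
    expect_equal(b$carbon_recovery, a$carbon_recovery)
    expect_equal(b$total_carbon_mM, 2 * a$total_carbon_mM)
    expect_equal(b$nadph_gen_mM, 2 * a$nadph_gen_mM)
    expect_equal(b$nadph_req_mM, 2 * a$nadph_req_mM)
  }
})

test_that("requirement computed from g/L equals requirement from mM directly", {
  set.seed(5)
  for (i in 1:10) {
    rec <- random_record()
    via_mm <- sum(vapply(names(rec$products), function(p) {
      if (rec$products[[p]] == 0) return(0)
      get_species(p)$nadph_req_per_mol * to_millimolar(rec$products[[p]], p)
    }, numeric(1)))
    expect_equal(nadph_required(rec), via_mm, tolerance = 1e-12)
  }
})

test_that("empty-product records flag the ferredoxin fraction instead of failing", {
  rec <- endpoint_record("e", 10, c(glucose = 10),
                         c(butanol = 0, acetic_acid = 0))
  res <- suppressWarnings(analyze_endpoint(rec))
  expect_identical(res$y_b, 0)
  expect_identical(res$nadph_req_mM, 0)
  expect_true(is.na(res$fd_fraction))
  expect_true(all(res$per_cmol == 0))
})

test_that("time-course analysis equals manual endpoint extraction", {
  tc <- timecourse(c(0, 8, 16, 28),
                   list(glucose = c(20, 15, 6, 0.5),
                        butanol = c(0, 0.4, 2.1, 4.2),
                        isopropanol = c(0, 0.1, 1.0, 2.0),
                        acetic_acid = c(0, 0.5, 0.4, 0.3)))
  # at a sample point the interpolation is exact: compare to a hand-built record
  manual <- endpoint_record("m", 16, c(glucose = 20 - 6),
                            c(butanol = 2.1, isopropanol = 1.0,
                              acetic_acid = 0.4))
  got <- analyze_timecourse(tc, at_time = 16)
  want <- analyze_endpoint(manual)
  expect_equal(got$y_b, want$y_b)
  expect_equal(got$nadph_req_mM, want$nadph_req_mM)
  expect_equal(got$carbon_recovery, want$carbon_recovery)

  # between samples, consumption interpolates linearly
  mid <- analyze_timecourse(tc, at_time = 12)
  expect_equal(mid$total_carbon_mM, carbon_millimolar(20 - (15 + 6) / 2,
                                                      "glucose"))
  expect_error(analyze_timecourse(tc, at_time = 0),
               class = "ib_validation_error")
  expect_error(analyze_timecourse(tc, at_time = 40),
               class = "ib_validation_error")
})
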