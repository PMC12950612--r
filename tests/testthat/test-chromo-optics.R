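# Closed-form optics chain: intracellular, lysed-medium and whole-sample
# coefficients and refractive indices.

test_that("intracellular absorption reproduces reference values and limits", {
  part <- hemoglobin_partition(blood_state(SO2 = 0.68))
  ref <- intracellular_reference()
  for (i in seq_len(nrow(ref))) {
    rec <- chromophore_record(ref$lambda_nm[i])
    mua <- rbc_absorption(part[["c_hbo"]], part[["c_hb"]], rec)
    expect_lt(rel_err(mua, ref$mua_rbc[i]), 0.02)
  }
  # chromophore-free limit: only the water term survives
  rec <- chromophore_record(700)
  expect_equal(rbc_absorption(0, 0, rec), 0.66 * rec$mua_water)
  expect_error(chromophore_record(633), "no chromophore record")
})

test_that("cell refractive index follows the hemoglobin load and absorption", {
  ref <- intracellular_reference()
  for (i in seq_len(nrow(ref))) {
    rec <- chromophore_record(ref$lambda_nm[i])
    idx <- rbc_refractive_index(5.1e-3, rec, ref$mua_rbc[i], "PBS")
    expect_lt(abs(idx[["nr"]] - ref$nr_rbc[i]), 0.002)
    expect_lt(rel_err(idx[["ni"]], ref$ni_rbc_e5[i] * 1e-5), 0.01)
  }
  rec <- chromophore_record(905)
  expect_equal(rbc_refractive_index(0, rec, 0, "PBS")[["nr"]], rec$nr_pbs)
})

test_that("lysed-medium absorption matches the mixing rule and its limits", {
  rec700 <- chromophore_record(700)
  s6 <- blood_state(0.5, 0.06, 0.68, "PBS")
  expect_lt(rel_err(lysed_medium_absorption(s6, 9.070, rec700), 0.533), 0.005)
  rec905 <- chromophore_record(905)
  s14 <- blood_state(0.5, 0.14, 0.68, "PBS")
  expect_lt(rel_err(lysed_medium_absorption(s14, 12.563, rec905), 1.589), 0.005)
  # no lysis -> pure medium
  s0 <- blood_state(0.5, 0, 0.68, "PBS")
  expect_equal(lysed_medium_absorption(s0, 9.070, rec700), rec700$mua_pbs)
  # fully packed, unlysed sample has no extracellular volume
  expect_error(lysed_medium_absorption(blood_state(1, 0, 0.68), 9, rec700),
               "degenerate")
})

test_that("whole-sample absorption combines phases and is lysis-invariant", {
  rec <- chromophore_record(700)
  s30 <- blood_state(0.5, 0.30, 0.68, "PBS")
  mua_lm <- lysed_medium_absorption(s30, 9.070, rec)
  expect_lt(rel_err(whole_blood_absorption(s30, 9.070, mua_lm), 4.545), 0.005)
  # LL = 0 closed form
  s0 <- blood_state(0.5, 0, 0.68, "PBS")
  expect_equal(whole_blood_absorption(s0, 9.070, rec$mua_pbs),
               0.5 * 9.070 + 0.5 * rec$mua_pbs)
  # homogeneous limit: identical phases give back the common coefficient
  expect_equal(whole_blood_absorption(s30, 9.070, 9.070), 9.070)
  # hemoglobin conservation: mua_bs constant across the lysis series
  for (med in c("PBS", "PLS")) {
    for (lam in c(700, 905, 1000)) {
      r <- chromophore_record(lam)
      intra <- intracellular_reference()
      mua_rbc <- intra$mua_rbc[intra$lambda_nm == lam]
      vals <- vapply(c(0, 0.06, 0.14, 0.20, 0.30), function(ll) {
        st <- blood_state(0.5, ll, 0.68, med)
        whole_blood_absorption(st, mua_rbc,
                               lysed_medium_absorption(st, mua_rbc, r))
      }, numeric(1L))
      expect_lt(diff(range(vals)) / mean(vals), 1e-12)
    }
  }
})

test_that("lysed-medium optics table is reproduced cell by cell", {
  tab <- reproduce_table("lysed_medium")
  expect_equal(nrow(tab), 30L)
  expect_lt(max(tab$rel_mua_lm), 0.005)
  expect_lt(max(tab$rel_mua_bs), 0.005)
  expect_true(all(abs(tab$nr_lm_calc - tab$nr_lm) <= 0.0015))
  # imaginary index agrees to 1% or to the printed resolution (0.005e-5)
  ok <- abs(tab$ni_lm_e5_calc - tab$ni_lm_e5) <=
    pmax(0.01 * tab$ni_lm_e5, 0.005)
  expect_true(all(ok))
  # released hemoglobin makes the medium absorption strictly increase with LL
  for (med in c("PBS", "PLS")) {
    for (lam in c(700, 905, 1000)) {
      col <- tab$mua_lm_calc[tab$medium == med & tab$lambda_nm == lam]
      expect_true(all(diff(col) > 0))
    }
  }
})

test_that("refractive increment B is recovered by regression on the table", {
  # least-squares oracle: (nr_lm / nr_m - 1) = B * c_free row by row
  ref <- lysed_medium_reference()
  for (lam in c(700, 905, 1000)) {
    rows <- ref[ref$lambda_nm == lam, ]
    rec <- chromophore_record(lam)
    nr_m <- ifelse(rows$medium == "PBS", rec$nr_pbs, rec$nr_pls)
    h <- rows$h_pct[rows$ll_pct == 0][1L] / 100
    ll <- rows$ll_pct / 100
    c_free <- 0.5 * ll * 5.1e-3 / (1 - 0.5 + 0.5 * ll)
    y <- rows$nr_lm / nr_m - 1
    b_hat <- sum(c_free * y) / sum(c_free^2)
    expect_lt(abs(b_hat - rec$B), 0.25)
    # fit residuals stay below one unit of the printed index precision
    expect_lt(max(abs(nr_m * (1 + b_hat * c_free) - rows$nr_lm)), 0.001)
  }
})

test_that("bulk coefficients follow from single-cell efficiencies", {
  b <- bulk_from_efficiencies(0.50, 389.4e-5, 3.045, aeff = 2.79,
                              v_rbc = 91.52)
  expect_lt(rel_err(b[["mua"]], 5.203), 0.002)
  expect_lt(rel_err(b[["mus"]], 1017.2), 0.002)
  # dilute limit and degenerate packing
  b0 <- bulk_from_efficiencies(0, 389.4e-5, 3.045)
  expect_equal(unname(b0), c(0, 0))
  expect_error(bulk_from_efficiencies(1, 389.4e-5, 3.045), "hematocrit")
  # every tabulated cell reproduced from printed efficiencies at the
  # current (post-lysis) hematocrit
  tab <- reproduce_table("bulk_optics")
  expect_equal(nrow(tab), 30L)
  expect_lt(max(tab$rel_mua_bs), 0.002)
  expect_lt(max(tab$rel_mus_bs), 0.002)
})

test_that("blood state validates its invariants", {
  expect_error(blood_state(H0 = 1.2), "H0")
  expect_error(blood_state(LL = -0.1), "LL")
  expect_error(blood_state(SO2 = 2), "SO2")
  expect_error(blood_state(c_total = 0), "c_total")
  st <- blood_state(0.5, 0.3, 0.68)
  expect_equal(current_hematocrit(st), 0.35)
  part <- hemoglobin_partition(st)
  expect_equal(sum(part), st$c_total)
})

test_that("user-supplied chromophore tables are validated", {
  tmp <- tempfile(fileext = ".csv")
  tab <- chromophore_table()
  utils::write.csv(tab[, -2L], tmp, row.names = FALSE)
  expect_error(chromophore_table(tmp), "missing columns")
  bad <- as.data.frame(tab)
  bad$B[1L] <- -1
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(chromophore_table(tmp), "B must be positive")
})
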