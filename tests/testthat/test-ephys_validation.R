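step_win <- c(0.2, 0.8)

test_that("membrane conductance follows Ohm's law on the step window", {
  tt <- seq(0, 1, by = 0.001)
  vv <- ifelse(tt >= 0.1 & tt <= 0.9, 40, 0)
  rec <- cx_recording(tt, vv, ifelse(vv == 40, 400, 0), "control")
  expect_equal(membrane_conductance(rec, step_win), 10)  # 400 pA / 40 mV
  rec2 <- cx_recording(tt, vv, ifelse(vv == 40, 800, 0), "control")
  expect_equal(membrane_conductance(rec2, step_win), 20)  # linear in current
  # zero driving force and non-constant voltage are errors
  rec0 <- cx_recording(tt, rep(0, length(tt)), rep(0, length(tt)), "control")
  expect_error(membrane_conductance(rec0, step_win), "zero driving voltage")
  expect_error(membrane_conductance(rec, c(0.05, 0.5)), "not constant")
})

test_that("leak subtraction recovers the generator's channel conductance", {
  tr <- simulate_current_traces(g_control = 8, residual_fraction = 0.5,
                                g_leak = 3, noise_sd = 0, seed = 2)
  blocked <- simulate_current_traces(g_control = 0, residual_fraction = 1,
                                     g_leak = 3, noise_sd = 0, seed = 3)$pre
  g <- membrane_conductance(tr$pre, step_win, leak_rec = blocked)
  expect_equal(g, 8)
  g_post <- membrane_conductance(tr$post, step_win, leak_rec = blocked)
  expect_equal(g_post, 4)
})

test_that("residual conductance is 100% for identical recordings and scale-invariant", {
  tr <- simulate_current_traces(10, 1, noise_sd = 0, seed = 1)
  expect_equal(residual_conductance(tr$pre, tr$pre, step_win), 100)
  tr2 <- simulate_current_traces(10, 0.4, noise_sd = 0, seed = 1)
  r <- residual_conductance(tr2$pre, tr2$post, step_win)
  scaled_pre <- tr2$pre; scaled_pre$current <- scaled_pre$current * 7.3
  scaled_post <- tr2$post; scaled_post$current <- scaled_post$current * 7.3
  expect_equal(residual_conductance(scaled_pre, scaled_post, step_win), r)
  # protocol mismatch and non-positive control conductance are errors
  off <- tr2$post; off$voltage <- off$voltage * 2
  expect_error(residual_conductance(tr2$pre, off, step_win), "different voltage")
  dead <- simulate_current_traces(0, 1, noise_sd = 0, seed = 1)
  expect_error(residual_conductance(dead$pre, dead$post, step_win), "non-positive")
})

test_that("generator residual fractions are recovered within one percentage point", {
  for (frac in c(0.1, 0.25, 0.5, 0.9)) {
    tr <- simulate_current_traces(10, frac, seed = 7)
    r <- residual_conductance(tr$pre, tr$post, step_win)
    expect_lt(abs(r - 100 * frac), 1)
  }
  # noiseless recovery is exact
  tr0 <- simulate_current_traces(10, 0.37, noise_sd = 0, seed = 1)
  expect_equal(residual_conductance(tr0$pre, tr0$post, step_win), 37)
})

test_that("recordings round-trip through delimited text", {
  tr <- simulate_current_traces(10, 0.5, seed = 4)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(tr$pre), f, sep = "\t", quote = FALSE, row.names = FALSE)
  rd <- read_recording(f, "control")
  expect_equal(rd$current, tr$pre$current)
  expect_equal(membrane_conductance(rd, step_win),
               membrane_conductance(tr$pre, step_win))
})

test_that("predictions and measured inhibition agree for all ten measured isoforms", {
  st <- scan_family(family_fasta_path())
  cc <- concordance_report(st, cx_conductance_table(), aliases = cx_isoform_aliases())
  expect_equal(cc$n_joined, 10L)
  expect_equal(cc$n_concordant, 10L)
  expect_equal(cc$concordant_fraction, 1)
  expect_equal(length(cc$unjoined$records_only), 0L)
  # the ten unmeasured isoforms are listed, not dropped
  expect_equal(length(cc$unjoined$predictions_only), 10L)
  # any cutoff between the two bands gives the same classification
  for (ct in c(30, 50, 70)) {
    expect_equal(concordance_report(st, cx_conductance_table(), ct,
                                    cx_isoform_aliases())$n_concordant, 10L)
  }
})

test_that("concordance edge cases: zero cutoff and empty joins", {
  st <- scan_family(family_fasta_path())
  cc0 <- concordance_report(st, cx_conductance_table(), inhibition_cutoff = 0,
                            aliases = cx_isoform_aliases())
  expect_false(any(cc0$table$measured_inhibited))
  none <- data.frame(isoform = "hCxNowhere", residual_pct = 50,
                     stringsAsFactors = FALSE)
  cce <- concordance_report(st, none)
  expect_true(is.na(cce$concordant_fraction))
  expect_equal(cce$unjoined$records_only, "hCxNowhere")
})
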