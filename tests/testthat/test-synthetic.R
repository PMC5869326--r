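test_that("the packaged patient table is complete and spot-correct", {
  d <- table1_fixture()
  expect_equal(nrow(d), 21L)
  expect_equal(d$patlak_Ki[d$patient_id == 9], 0.0403)
  expect_equal(d$kma3p_Ki[d$patient_id == 21], 0.1450)
  expect_equal(max(d$kma3p_kb), 0.0056)          # patient 12
  expect_equal(d$patient_id[which.max(d$kma3p_kb)], 12L)
  expect_true(all(as.matrix(d[-1]) >= 0))
})

test_that("fixture column means and SDs match the printed summary rows", {
  d <- table1_fixture()
  s <- summarize_columns(d)
  printed_mean <- c(A0 = 16.00, alpha2 = 0.1574, alpha3 = 0.0145,
                    patlak_Ki = 0.0391, kma3p_Ki = 0.0414,
                    kma3p_kb = 0.0009, kma3p_Vb = 0.16, k1_5p = 0.1028,
                    k2_5p = 0.5995, k3_5p = 0.3817, k4_5p = 0.0473,
                    ki_5p = 0.0403, kb_5p = 0.0013, vb_5p = 0.05)
  printed_sd <- c(A0 = 9.82, alpha2 = 0.0426, alpha3 = 0.0022,
                  patlak_Ki = 0.0263, kma3p_Ki = 0.0288,
                  kma3p_kb = 0.0016, kma3p_Vb = 0.09, k1_5p = 0.0361,
                  k2_5p = 0.3454, k3_5p = 0.2247, k4_5p = 0.2091,
                  ki_5p = 0.0269, kb_5p = 0.0023, vb_5p = 0.03)
  decimals <- c(A0 = 2, alpha2 = 4, alpha3 = 4, patlak_Ki = 4,
                kma3p_Ki = 4, kma3p_kb = 4, kma3p_Vb = 2, k1_5p = 4,
                k2_5p = 4, k3_5p = 4, k4_5p = 4, ki_5p = 4, kb_5p = 4,
                vb_5p = 2)
  for (col in names(printed_mean)) {
    tol <- 10^(-decimals[[col]])  # one unit in the last printed digit
    expect_lt(abs(s["mean", col] - printed_mean[[col]]), tol + 1e-12,
              label = paste("mean", col))
    expect_lt(abs(s["sd", col] - printed_sd[[col]]), tol + 1e-12,
              label = paste("sd", col))
  }
})

test_that("generate_case is deterministic given the seed", {
  d <- table1_fixture()
  r <- d[9, ]
  nm <- noise_model("multiplicative-gaussian", 0.05, 42L)
  case <- synthetic_case(if_model(r$A0, r$alpha2, r$alpha3),
                         truth_3p = c(r$kma3p_Ki, r$kma3p_kb, r$kma3p_Vb),
                         noise = nm)
  g1 <- generate_case(case)
  g2 <- generate_case(case)
  expect_identical(g1$tissue_tac$activities, g2$tissue_tac$activities)
  case$noise$seed <- 43L
  g3 <- generate_case(case)
  expect_false(identical(g1$tissue_tac$activities,
                         g3$tissue_tac$activities))
  # caller RNG untouched
  set.seed(1); before <- .Random.seed
  generate_case(case)
  expect_identical(.Random.seed, before)
  # noise-free generation equals the model evaluation
  clean <- generate_case(synthetic_case(
    if_model(r$A0, r$alpha2, r$alpha3),
    truth_3p = c(r$kma3p_Ki, r$kma3p_kb, r$kma3p_Vb)))
  fs <- default_frame_scheme()
  expect_equal(clean$tissue_tac$activities,
               tissue_model_3p(fs$mid, r$kma3p_Ki, r$kma3p_kb,
                               r$kma3p_Vb,
                               if_model(r$A0, r$alpha2, r$alpha3), pc18f))
  expect_false(clean$if_tac$decay_corrected)
})

test_that("the noise model delivers its nominal fractional SD", {
  d <- table1_fixture()
  r <- d[9, ]
  m <- if_model(r$A0, r$alpha2, r$alpha3)
  truth <- c(r$kma3p_Ki, r$kma3p_kb, r$kma3p_Vb)
  true57 <- tissue_model_3p(57.5, truth[1], truth[2], truth[3], m, pc18f)
  vals <- vapply(1:200, function(s) {
    case <- synthetic_case(m, truth_3p = truth,
                           noise = noise_model("multiplicative-gaussian",
                                               0.05, s))
    generate_case(case)$tissue_tac$activities[11]
  }, numeric(1))
  expect_lt(abs(stats::sd(vals) - 0.05 * true57) / (0.05 * true57), 0.20)
})

test_that("cohort_from_fixture builds one 3P case per patient", {
  cohort <- cohort_from_fixture()
  expect_length(cohort, 21L)
  expect_equal(cohort[[12]]$truth_3p[2], 0.0056)
  for (case in cohort) {
    expect_equal(case$scheme$mid, default_frame_scheme()$mid)
    expect_null(case$truth_5p)
  }
  expect_error(synthetic_case(mean_if()), "exactly one")
  expect_error(synthetic_case(mean_if(), truth_3p = 1:3, truth_5p = 1:5),
               "exactly one")
})
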