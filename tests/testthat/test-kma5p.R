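test_that("macroparameters reproduce the printed 5P columns", {
  # patient 12
  expect_equal(ki_from_micro(0.0962, 0.610, 0.1871), 0.0226,
               tolerance = 5e-5 / 0.0226)
  expect_equal(kb_from_micro(0.610, 0.1871, 0.0099), 0.0076,
               tolerance = 5e-5 / 0.0076)
  # patient 19
  expect_equal(ki_from_micro(0.1329, 0.549, 0.2267), 0.0388,
               tolerance = 5e-5 / 0.0388)
  expect_equal(kb_from_micro(0.549, 0.2267, 0.0052), 0.0037,
               tolerance = 5e-5 / 0.0037)
  # degenerate reductions and the undefined case
  expect_equal(ki_from_micro(0.1, 0, 0.3), 0.1)    # no efflux: Ki = K1
  expect_equal(kb_from_micro(0.6, 0.2, 0), 0)      # irreversible
  expect_error(ki_from_micro(0.1, 0, 0), "undefined")
})

test_that("macro invariants hold across random draws", {
  set.seed(31)
  for (rep in 1:50) {
    K1 <- runif(1, 0.01, 0.3); k2 <- runif(1, 0, 1)
    k3 <- runif(1, 0.01, 1); k4 <- runif(1, 0, 0.1)
    expect_lte(ki_from_micro(K1, k2, k3), K1)
    expect_lte(kb_from_micro(k2, k3, k4), k4 + 1e-15)
  }
})

test_that("analytic bi-exponential solution matches the RK4 oracle", {
  m9 <- p9_if()
  tt <- c(1, 2, 5, 10, 30, 60)  # exact multiples of the RK step
  p12 <- c(0.0962, 0.610, 0.1871, 0.0099, 0.05)
  va <- tissue_model_5p(tt, p12[1], p12[2], p12[3], p12[4], p12[5], m9,
                        pc18f)
  vo <- ode_oracle_5p(tt, p12[1], p12[2], p12[3], p12[4], p12[5], m9,
                      pc18f)
  expect_equal(va, vo, tolerance = 1e-6)

  set.seed(17)
  for (rep in 1:3) {
    p <- c(runif(1, 0.03, 0.2), runif(1, 0.05, 1), runif(1, 0.05, 1),
           runif(1, 0, 0.05), runif(1, 0, 0.2))
    va <- tissue_model_5p(tt, p[1], p[2], p[3], p[4], p[5], m9, pc18f)
    vo <- ode_oracle_5p(tt, p[1], p[2], p[3], p[4], p[5], m9, pc18f)
    expect_equal(va, vo, tolerance = 1e-6)
  }

  # K1 = 0: pure blood signal, on both decay scales
  expect_equal(tissue_model_5p(tt, 0, 0.1, 0.1, 0, 0.08, m9, pc18f),
               0.08 * eval_if(m9, tt))
  mc <- if_decay_transform(m9, pc18f, TRUE)
  expect_equal(tissue_model_5p(tt, 0, 0.1, 0.1, 0, 0.08, m9, pc18f,
                               decay_corrected = TRUE),
               0.08 * eval_if(mc, tt))
})

test_that("fit_5p recovers a noise-free dense-scheme truth", {
  m9 <- p9_if()
  ds <- dense_frame_scheme()
  p12 <- c(0.0962, 0.610, 0.1871, 0.0099, 0.05)
  y <- tissue_model_5p(ds$mid, p12[1], p12[2], p12[3], p12[4], p12[5],
                       m9, pc18f)
  f <- fit_5p(tac(ds$mid, y, decay_corrected = FALSE), m9, pc18f)
  est <- c(f$K1, f$k2, f$k3, f$k4, f$V_b)
  expect_equal(est, p12, tolerance = 0.01)
  expect_equal(f$Ki_macro, ki_from_micro(p12[1], p12[2], p12[3]),
               tolerance = 1e-3)
  # macro identities are recomputed from the fitted microparameters
  expect_equal(f$Ki_macro, ki_from_micro(f$K1, f$k2, f$k3))
  expect_equal(f$kb_macro, kb_from_micro(f$k2, f$k3, f$k4))

  # irreversible truth: k4 lands on its lower bound, kb_macro = 0
  y0 <- tissue_model_5p(ds$mid, 0.1, 0.6, 0.3, 0, 0.05, m9, pc18f)
  f0 <- fit_5p(tac(ds$mid, y0, decay_corrected = FALSE), m9, pc18f)
  expect_equal(f0$k4, 0, tolerance = 1e-6)
  expect_equal(f0$kb_macro, 0, tolerance = 1e-6)

  expect_error(fit_5p(tac(1:5, 5:1, decay_corrected = FALSE), m9, pc18f),
               "at least 8")
})

test_that("distinct microparameter sets with equal macro Ki fit alike", {
  # both sets have Ki = K1 k3/(k2+k3) = 1/30
  m9 <- p9_if()
  ds <- dense_frame_scheme()
  sets <- list(c(0.10, 0.60, 0.30, 0, 0.05),
               c(0.08, 0.35, 0.25, 0, 0.05))
  ki <- vapply(sets, function(p) {
    y <- tissue_model_5p(ds$mid, p[1], p[2], p[3], p[4], p[5], m9, pc18f)
    fit_5p(tac(ds$mid, y, decay_corrected = FALSE), m9, pc18f)$Ki_macro
  }, numeric(1))
  expect_equal(ki[1], ki[2], tolerance = 0.01)
  expect_equal(ki[1], 0.1 * 0.3 / 0.9, tolerance = 0.01)
})

test_that("3P fit of a 5P-generated late-window TAC recovers macro Ki", {
  d <- table1_fixture()
  r <- d[d$patient_id == 12, ]
  m <- if_model(r$A0, r$alpha2, r$alpha3)
  fs <- default_frame_scheme()
  y <- tissue_model_5p(fs$mid, r$k1_5p, r$k2_5p, r$k3_5p, r$k4_5p,
                       r$vb_5p, m, pc18f)
  f3 <- fit_3p(tac(fs$mid, y, decay_corrected = FALSE), m, pc18f)
  expect_equal(f3$Ki, 0.0226, tolerance = 0.10)
})
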