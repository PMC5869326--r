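test_that("closed form matches the numerical convolution oracle", {
  m <- mean_if()
  # cohort-mean parameters at representative times
  v <- tissue_model_3p(c(10, 60, 120), 0.0414, 0.0009, 0.16, m, pc18f)
  o <- convolution_oracle_3p(c(10, 60, 120), 0.0414, 0.0009, 0.16, m,
                             pc18f)
  expect_equal(v, o, tolerance = 1e-8)

  # random valid parameter draws
  set.seed(11)
  for (rep in 1:100) {
    cs <- draw_case_3p()
    tt <- c(5, 30, 90)
    v <- tissue_model_3p(tt, cs$Ki, cs$k_b, cs$V_b, cs$model, pc18f)
    o <- convolution_oracle_3p(tt, cs$Ki, cs$k_b, cs$V_b, cs$model, pc18f)
    expect_equal(v, o, tolerance = 1e-8)
  }
})

test_that("removable singularity beta = alpha_i uses the limit form", {
  m <- mean_if()
  kb_sing <- 0.0145 - pc18f$lambda_decay  # beta collides with alpha3
  v <- tissue_model_3p(c(10, 60), 0.05, kb_sing, 0.1, m, pc18f)
  o <- convolution_oracle_3p(c(10, 60), 0.05, kb_sing, 0.1, m, pc18f)
  expect_equal(v, o, tolerance = 1e-7)
  # continuity across the guard
  near <- tissue_model_3p(60, 0.05, kb_sing + 1e-8, 0.1, m, pc18f)
  expect_equal(near, v[2], tolerance = 1e-6)
})

test_that("degenerate parameter values reduce the model as expected", {
  m <- mean_if()
  expect_equal(tissue_model_3p(0, 0.04, 0.001, 0.16, m, pc18f),
               0.16 * eval_if(m, 0))
  tt <- c(0, 7.5, 30)
  expect_equal(tissue_model_3p(tt, 0, 0.001, 0.16, m, pc18f),
               0.16 * eval_if(m, tt))
  expect_error(tissue_model_3p(10, 0.04, 0.001, 1.2, m, pc18f), "V_b")
})

test_that("fit_3p recovers noise-free truths, including the k_b boundary", {
  m9 <- p9_if()
  f <- fit_3p(make_tissue_3p(0.0446, 0.0018, 0.03, m9), m9, pc18f)
  expect_equal(c(f$Ki, f$k_b, f$V_b), c(0.0446, 0.0018, 0.03),
               tolerance = 1e-4)
  expect_true(f$converged)

  f0 <- fit_3p(make_tissue_3p(0.0446, 0, 0.03, m9), m9, pc18f)
  expect_identical(f0$k_b, 0)                 # active lower bound
  expect_equal(f0$Ki, 0.0446, tolerance = 1e-5)

  expect_error(fit_3p(tac(1:3, 3:1, decay_corrected = FALSE), m9, pc18f),
               "at least 4")
})

test_that("fit_3p recovers all 21 cohort truths, noise-free", {
  d <- table1_fixture()
  worst <- 0
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    m <- if_model(r$A0, r$alpha2, r$alpha3)
    f <- fit_3p(make_tissue_3p(r$kma3p_Ki, r$kma3p_kb, r$kma3p_Vb, m),
                m, pc18f)
    worst <- max(worst, abs(f$Ki - r$kma3p_Ki) / r$kma3p_Ki)
  }
  expect_lt(worst, 1e-3)
})

test_that("Ki estimate is unbiased under 5% noise at patient-9 truth", {
  m9 <- p9_if()
  fs <- default_frame_scheme()
  clean <- tissue_model_3p(fs$mid, 0.0446, 0.0018, 0.03, m9, pc18f)
  set.seed(99)
  ki <- replicate(500, {
    noisy <- pmax(0, clean * (1 + 0.05 * rnorm(11)))
    fit_3p(tac(fs$mid, noisy, decay_corrected = FALSE), m9, pc18f)$Ki
  })
  expect_lt(abs(stats::median(ki) - 0.0446) / 0.0446, 0.02)
})

test_that("3P-vs-Patlak Ki ratio grows with the generating k_b", {
  d <- table1_fixture()
  pos <- d[d$kma3p_kb > 0, ]
  ratio <- vapply(seq_len(nrow(pos)), function(i) {
    r <- pos[i, ]
    m <- if_model(r$A0, r$alpha2, r$alpha3)
    tt <- make_tissue_3p(r$kma3p_Ki, r$kma3p_kb, r$kma3p_Vb, m)
    fit_3p(tt, m, pc18f)$Ki / patlak_analysis(tt, m, pc18f)$Ki
  }, numeric(1))
  expect_gt(stats::cor(pos$kma3p_kb, ratio, method = "spearman"), 0)
})

test_that("decomposition splits the TAC into trapped plus free exactly", {
  m <- mean_if()
  dec <- decompose_3p(mean_3p, m, pc18f, t_grid = seq(0, 240, by = 1))
  expect_equal(dec$total, dec$trapped + dec$free, tolerance = 1e-12)
  # at injection everything is free tracer
  expect_identical(dec$trapped[1], 0)
  expect_equal(dec$free[1] / dec$total[1], 1)
  # by the end of acquisition the trapped part dominates
  i <- which(dec$t_grid == 57)
  expect_gt(dec$trapped[i], dec$free[i])
  # trapped component agrees with the convolution oracle (V_b = 0 run)
  o <- convolution_oracle_3p(c(30, 120), mean_3p$Ki, mean_3p$k_b, 0, m,
                             pc18f)
  j <- match(c(30, 120), dec$t_grid)
  expect_equal(dec$trapped[j], o, tolerance = 1e-8)
})

test_that("peak times sit near 84 (total) and 88 (trapped) minutes", {
  pk <- peak_times_3p(mean_3p, mean_if(), pc18f)
  expect_equal(unname(pk["total"]), 84, tolerance = 1 / 84)
  expect_equal(unname(pk["trapped"]), 88, tolerance = 1 / 88)
  expect_gt(pk["trapped"], pk["total"])
})

test_that("trapped peak always lags the total peak when V_b > 0", {
  set.seed(23)
  for (rep in 1:40) {
    cs <- draw_case_3p()
    pk <- peak_times_3p(list(Ki = cs$Ki, k_b = cs$k_b, V_b = cs$V_b),
                        cs$model, pc18f)
    expect_gt(pk["trapped"], pk["total"])
  }
  # V_b = 0: the two curves coincide
  pk0 <- peak_times_3p(list(Ki = 0.0414, k_b = 0.0009, V_b = 0),
                       mean_if(), pc18f)
  expect_equal(unname(pk0["total"]), unname(pk0["trapped"]),
               tolerance = 1e-4)
})
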