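test_that("lambert_w_exp solves w + log(w) = a across the full range", {
  for (a in c(-50, -5, -1, 0, 1, 10, 100, 700, 1e5, 1e8)) {
    w <- lambert_w_exp(a)
    expect_equal(w + log(w), a, tolerance = 1e-12)
  }
  expect_equal(lambert_w_exp(-Inf), 0)
  expect_error(lambert_w_exp(Inf), "non-finite")
})

test_that("the Michaelis-Menten response has its defining identities", {
  expect_equal(mm_rate(150, imax = 1, km = 150), 0.5)
  expect_equal(mm_rate(60, imax = 2, km = 50, cmin = 10), 1)
  expect_equal(mm_rate(10, imax = 1, km = 50, cmin = 10), 0)
  expect_equal(mm_rate(0, imax = 1, km = 50), 0)
  # saturation limit
  expect_equal(mm_rate(1e6 * 50, imax = 1, km = 50), 1, tolerance = 1e-4)
})

test_that("the closed-form depletion satisfies its implicit relation", {
  # hand-derived: Km ln(C0/C) + (C0 - C) = k t with C0=1000, Km=100, k=200
  # gives C = 500 at t = (100 log 2 + 500)/200
  t_half <- (100 * log(2) + 500) / 200
  imax <- 200 * 0.25 / 500 # k = Imax L / V = 200 uM/h
  expect_equal(
    mm_depletion_conc(t_half, 1000, imax, 100, root_length_cm = 500, volume_ml = 250),
    500, tolerance = 1e-9
  )
  # relation holds to 1e-9 relative wherever evaluated
  set.seed(11)
  for (i in 1:20) {
    km <- exp(runif(1, log(10), log(2000)))
    im <- exp(runif(1, log(0.002), log(0.05)))
    c0 <- sample(c(100, 1000), 1)
    tt <- runif(1, 0, 8)
    cc <- mm_depletion_conc(tt, c0, im, km, 500, 250)
    k <- im * 500 / 0.25
    lhs <- km * log(c0 / cc) + (c0 - cc)
    expect_equal(lhs, k * tt, tolerance = 1e-9)
  }
})

test_that("depletion trajectories hit the zero-order and first-order limits", {
  # Km -> 0: linear depletion at rate k; C0=100, k=10 uM/h, t=4 -> 60
  imax <- 10 * 0.25 / 500
  expect_equal(mm_depletion_conc(4, 100, imax, km = 1e-6, 500, 250), 60,
               tolerance = 1e-6)
  # Km >> C0: first-order decay, C = C0 exp(-k t / Km)
  imax2 <- 100 * 0.25 / 500
  expect_equal(mm_depletion_conc(1, 100, imax2, km = 1e6, 500, 250),
               100 * exp(-1e-4), tolerance = 1e-7)
})

test_that("trajectories are non-increasing and floored at cmin", {
  tt <- seq(0, 50, by = 0.5)
  cc <- mm_depletion_conc(tt, 500, 0.05, 50, 500, 250, cmin = 20)
  expect_true(all(diff(cc) <= 1e-12))
  expect_true(all(cc >= 20))
  expect_equal(cc[length(cc)], 20, tolerance = 1e-6)
})

test_that("closed form agrees with Runge-Kutta integration", {
  set.seed(2)
  maxerr <- 0
  for (i in 1:25) {
    imax <- exp(runif(1, log(0.002), log(0.1)))
    km <- exp(runif(1, log(10), log(5000)))
    c0 <- sample(c(100, 1000), 1)
    cf <- mm_depletion_conc(paper_schedule, c0, imax, km, 500, 250)
    oc <- rk_depletion(c0, imax, km, 500, 250, paper_schedule)
    maxerr <- max(maxerr, max(abs(cf - oc) / pmax(abs(oc), 1e-9)))
  }
  expect_lt(maxerr, 1e-6)
})

test_that("noiseless depletion fits recover the generating parameters", {
  s <- simulate_depletion(1000, 0.02, 150, 500, volume_ml = 250,
                          schedule_h = paper_schedule, noise_cv = 0)
  f <- fit_depletion(s, root_length_cm = 500, volume_ml = 250)
  est <- setNames(tidy(f)$estimate, tidy(f)$term)
  expect_equal(unname(est["imax"]), 0.02, tolerance = 0.01)
  expect_equal(unname(est["km"]), 150, tolerance = 0.01)
  expect_true(glance(f)$converged)
  expect_true(glance(f)$km_reliable)
})

test_that("depletion fits reject degenerate inputs", {
  const <- tibble::tibble(time_h = paper_schedule, conc_uM = 100)
  expect_error(fit_depletion(const, 500), "constant series")
  short <- tibble::tibble(time_h = 0:2, conc_uM = c(100, 90, 80))
  expect_error(fit_depletion(short, 500), "at least 4 timepoints")
  expect_error(
    fit_depletion(tibble::tibble(time_h = 0:3, conc_uM = c(100, 95, 91, 88)),
                  500, fix_cmin = FALSE),
    "at least 5 timepoints"
  )
})

test_that("freeing the concentration floor recovers a true cmin", {
  s <- tibble::tibble(
    time_h = c(paper_schedule, 12, 16, 24),
    conc_uM = mm_depletion_conc(c(paper_schedule, 12, 16, 24), 500, 0.04, 80,
                                500, 250, cmin = 30)
  )
  f <- fit_depletion(s, 500, 250, fix_cmin = FALSE)
  est <- setNames(tidy(f)$estimate, tidy(f)$term)
  expect_equal(unname(est["cmin"]), 30, tolerance = 0.05)
  expect_equal(unname(est["imax"]), 0.04, tolerance = 0.02)
})

test_that("rate fits recover exact Michaelis-Menten data to machine precision", {
  d <- tibble::tibble(conc_uM = c(10, 50, 250, 1250),
                      rate = mm_rate(c(10, 50, 250, 1250), 1, 50))
  f <- fit_rates(d)
  est <- setNames(tidy(f)$estimate, tidy(f)$term)
  expect_equal(unname(est["imax"]), 1, tolerance = 1e-8)
  expect_equal(unname(est["km"]), 50, tolerance = 1e-6)
})

test_that("saturating-only rate data flag Km as unidentifiable", {
  d <- tibble::tibble(conc_uM = c(1000, 2000, 4000), rate = c(1, 1, 1))
  f <- fit_rates(d)
  expect_false(glance(f)$km_reliable)
  expect_error(fit_rates(tibble::tibble(conc_uM = c(1, 2), rate = c(0.1, 0.2))),
               "at least 3")
})

test_that("depletion and rate routes agree on the same series", {
  # a series sweeping well below Km, sampled densely enough that interval
  # midpoint concentrations approximate instantaneous rates
  sched <- c(seq(0, 8, 0.5), seq(9, 32, 1))
  s <- simulate_depletion(1000, 0.02, 150, 500, schedule_h = sched,
                          noise_cv = 0)
  fd <- fit_depletion(s, 500, 250)
  fr <- fit_rates(depletion_to_rates(s, 500, 250))
  ed <- setNames(tidy(fd)$estimate, tidy(fd)$term)
  er <- setNames(tidy(fr)$estimate, tidy(fr)$term)
  expect_equal(unname(er["imax"]), unname(ed["imax"]), tolerance = 0.05)
  expect_equal(unname(er["km"]), unname(ed["km"]), tolerance = 0.05)
})
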