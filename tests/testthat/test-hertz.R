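test_that("noiseless curves are recovered to better than 1%", {
  for (E in c(1000, 4000, 10000)) {
    fit <- fit_hertz(generate_indentation_curve(E, 10, 3.5))
    expect_lt(abs(fit$E_eff_Pa / E - 1), 0.01)
    expect_gt(fit$r_squared, 0.999)
    expect_true(fit$accepted)
  }
})

test_that("force scaling, contact-point shift and errors behave", {
  cur <- generate_indentation_curve(4000, 10, 3.5)
  f0 <- fit_hertz(cur)
  cur2 <- cur; cur2$force_nN <- 3 * cur$force_nN
  attr(cur2, "tip_radius_um") <- 10
  expect_equal(fit_hertz(cur2)$E_eff_Pa, 3 * f0$E_eff_Pa, tolerance = 1e-6)
  # shifting the depth axis moves the contact point, not the modulus
  sh <- generate_indentation_curve(4000, 10, 3.5, contact_offset = 1)
  fs <- fit_hertz(sh)
  expect_lt(abs(fs$contact_point_um - 1), 0.02)
  expect_lt(abs(fs$E_eff_Pa / f0$E_eff_Pa - 1), 0.005)
  # all-zero force errors; short curves error
  zero <- cur; zero$force_nN <- 0
  expect_error(fit_hertz(zero), class = "drusenmorph_invalid")
  expect_error(fit_hertz(cur[1:5, ], tip_radius_um = 10),
               class = "drusenmorph_invalid")
})

test_that("the R2 > 0.95 filter rejects heavily noisy curves", {
  acc <- vapply(1:100, function(s) {
    cur <- generate_indentation_curve(4000, 10, 3.5, noise_sd = 0.2,
                                      noise_type = "multiplicative",
                                      seed = s)
    suppressWarnings(fit_hertz(cur)$accepted)
  }, logical(1))
  expect_lt(mean(acc), 0.5)
  # mild noise is accepted
  mild <- generate_indentation_curve(4000, 10, 3.5, noise_sd = 0.02,
                                     noise_type = "multiplicative", seed = 1)
  expect_true(fit_hertz(mild)$accepted)
})
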