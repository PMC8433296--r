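reference_params <- function(n = 3L, L_s = 220L) {
  system_parameters(n = n, S_D = 100000, S_h = 10, S_T = 2010,
                    L_s = L_s, L_p = 20L, a = 1 / 1.6, r_c = 0.34)
}

test_that("compression efficiency follows e_c = 1 - (r_c*S_o + S_T)/S_o", {
  expect_equal(compression_efficiency(0.34, 5e6, 0), 0.66) # ideal case
  expect_equal(compression_efficiency(0.5, 100, 50), 0)    # break-even boundary
  # direct arithmetic oracle on an arbitrary operand set
  r_c <- 0.34; S_o <- 4194304; S_T <- 1646592
  expect_equal(compression_efficiency(r_c, S_o, S_T),
               1 - (r_c * S_o + S_T) / S_o) # = 0.267421875
  expect_equal(compression_efficiency(r_c, S_o, S_T), 0.267421875)
  # negative-efficiency regime: S_T >= (1 - r_c) * S_o
  expect_lt(compression_efficiency(0.9, 1e6, 2e5), 0)
  expect_error(compression_efficiency(0.5, 0, 10), "domain error")
})

test_that("break-even size is the root of the efficiency curve", {
  expect_equal(breakeven_S_o(0.5, 50), 100)
  expect_equal(breakeven_S_o(0.34, 1646592), 2494836.3636, tolerance = 1e-8)
  withr::with_seed(15, {
    for (i in 1:20) {
      r_c <- runif(1, 0, 0.99)
      S_T <- runif(1, 1, 1e7)
      expect_equal(compression_efficiency(r_c, breakeven_S_o(r_c, S_T), S_T), 0,
                   tolerance = 1e-12)
    }
  })
  expect_error(breakeven_S_o(1, 10), "no break-even")
})

test_that("stored bits match hand arithmetic for the three methods", {
  p <- reference_params()
  # n = 3, S_D = 1e5, r_c = 0.34, S_h = 10, S_T = 2010
  expect_equal(stored_bits("1-1CS", p), 3 * 34000 + 3 * (10 + 2010)) # 108060
  expect_equal(stored_bits("M-1CI", p), 102000 + 3 * (10 + 40) + 2010) # 104160
  expect_equal(stored_bits("1-MCI", p), 102000 + 30 + 2010) # 104040
  # empty-sum limit
  p0 <- system_parameters(n = 0, S_D = 1, S_h = 10, S_T = 2010)
  expect_equal(stored_bits("1-1CS", p0), 0)
  expect_equal(stored_bits("M-1CI", p0), 2010)
  expect_equal(stored_bits("1-MCI", p0), 2010)
  # heterogeneous per-file sizes use the printed sum form
  ph <- system_parameters(n = 2, S_D = c(1000, 3000), r_c = 0.5, S_h = 10, S_T = 100)
  expect_equal(stored_bits("1-MCI", ph), 0.5 * 4000 + 20 + 100)
})

test_that("stored bases match term-by-term oracles of the base-count formulas", {
  p <- reference_params()
  a <- 1 / 1.6
  # ordinary fragments: a * Sb * (1 + 2*L_p/(L_s - 2*L_p)) = a * Sb * 11/9
  expect_equal(stored_bases("1-1CS", p), a * 108060 * (11 / 9)) # 82545.83...
  expect_equal(stored_bases("1-1CS", p), 82545.8333, tolerance = 1e-8)
  # two-term sum form before simplification equals the factored form
  sb <- stored_bits("M-1CI", p)
  expect_equal(stored_bases("M-1CI", p), sb * a + (sb * a / 180) * 40)
  # one-to-many: independent term-by-term evaluation
  term1 <- 104040 * a
  term2 <- ((102000 + 30) * a / 220) * 40
  term3 <- (2010 * a / (220 - 4 * 20)) * (4 * 20)
  expect_equal(stored_bases("1-MCI", p), term1 + term2 + term3)
  expect_equal(stored_bases("1-MCI", p), 77337.1753, tolerance = 1e-7)
  # zero-primer limit collapses to a * Sb
  pz <- system_parameters(n = 3, S_D = 100000, S_h = 10, S_T = 2010,
                          L_s = 220, L_p = 1e-9, a = a, r_c = 0.34)
  expect_equal(stored_bases("1-1CS", pz), a * stored_bits("1-1CS", pz),
               tolerance = 1e-6)
  expect_error(stored_bases("1-MCI", reference_params(n = 10, L_s = 220)),
               "capacity error")
})

test_that("separate storage never stores more bits than continuous storage", {
  withr::with_seed(44, {
    for (i in 1:50) {
      p <- system_parameters(n = sample(1:40, 1), S_D = runif(1, 1e3, 1e6),
                             S_h = runif(1, 0, 100), S_T = runif(1, 0, 1e6),
                             L_s = 220, L_p = 20, a = 1 / 1.6,
                             r_c = runif(1, 0.05, 0.99))
      sb1 <- stored_bits("1-1CS", p)
      sb2 <- stored_bits("M-1CI", p)
      sb3 <- stored_bits("1-MCI", p)
      expect_lte(sb3, sb2) # difference 2 * n * L_p
      expect_lte(sb3, sb1) # difference (n - 1) * S_T
      expect_equal(sb2 - sb3, 2 * p$n * p$L_p)
      expect_equal(sb1 - sb3, (p$n - 1) * p$S_T)
    }
  })
})

test_that("sweeps reproduce the decreasing, ordered base-count trends", {
  sweep <- overhead_sweep(reference_params(), L_s = seq(100, 400, by = 20))
  expect_equal(nrow(sweep), 16)
  # every row ordered 1-MCI <= M-1CI <= 1-1CS under this parameter set
  expect_true(all(sweep$Sd_1_MCI <= sweep$Sd_M_1CI))
  expect_true(all(sweep$Sd_M_1CI <= sweep$Sd_1_1CS))
  # monotone decreasing in L_s/L_p with slowing descent
  for (col in c("Sd_1_1CS", "Sd_M_1CI", "Sd_1_MCI")) {
    expect_true(all(diff(sweep[[col]]) < 0), info = col)
    expect_true(all(diff(diff(sweep[[col]])) > 0), info = col) # convex descent
  }
  # linear growth in n for the ordinary-fragment methods
  sw_n <- overhead_sweep(reference_params(), n = 1:8)
  expect_equal(diff(sw_n$Sd_1_1CS), rep(diff(sw_n$Sd_1_1CS)[1], 7))
  # a single-point sweep equals the direct calls
  one <- overhead_sweep(reference_params())
  expect_equal(one$Sb_1_MCI, stored_bits("1-MCI", reference_params()))
  expect_equal(one$Sd_1_1CS, stored_bases("1-1CS", reference_params()))
  # e_c increases monotonically with S_o at fixed r_c, S_T > 0
  e_c <- compression_efficiency(0.34, seq(1e5, 1e7, length.out = 50), 2010)
  expect_true(all(diff(e_c) > 0))
})

test_that("storage density is S_o / S_b, with 1/a as the bare-codec ceiling", {
  expect_equal(storage_density(2000, 1000), 2)
  expect_equal(storage_density(1600, 1600 / 1.6), 1.6)
  expect_error(storage_density(10, 0), "domain error")
})
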