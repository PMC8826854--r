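test_that("logistic time course matches closed-form evaluations", {
  p <- printed_params()
  # asymptote: large das approaches K from below
  expect_lt(abs(logistic_srl(1e6, 125.9, p) - 125.9), 1e-6)
  expect_true(all(logistic_srl(c(0, 7, 30), 125.9, p) < 125.9))
  # degenerate shape C -> 0 reduces to the constant K
  p0 <- growth_params(C = 1e-12, r = 0.235, a = 5.64, b = 4, c = 0.677)
  expect_equal(logistic_srl(3, 100, p0), 100, tolerance = 1e-9)
  # hand evaluation of the logistic form
  expect_equal(logistic_srl(7, 100, p),
               100 / (1 + 2.402 * exp(-0.235 * 7)), tolerance = 1e-12)
  expect_error(logistic_srl(-1, 100, p), "das")
  expect_error(logistic_srl(7, -5, p), "K")
})

test_that("dose-response asymptote K matches hand evaluations", {
  p <- printed_params()
  # the published optimum: 126 mm at 5.9% PEG
  expect_equal(round(full_length_K(4 / 0.677, p)), 126)
  expect_equal(full_length_K(0, p), 0)
  expect_equal(full_length_K(10, p), 5.64 * 10^4 * exp(-0.677 * 10),
               tolerance = 1e-12)
  expect_error(full_length_K(-1, p), "peg")
})

test_that("predict_srl composes asymptote and time course", {
  p <- printed_params()
  expect_equal(predict_srl(0, 12, p), 0)
  expect_equal(predict_srl(c(3, 9), c(10, 15), p),
               logistic_srl(c(10, 15), full_length_K(c(3, 9), p), p))
  k <- 5.64 * 5.908^4 * exp(-0.677 * 5.908)
  expect_equal(predict_srl(5.908, 20, p),
               k / (1 + 2.402 * exp(-0.235 * 20)), tolerance = 1e-12)
  expect_equal(round(predict_srl(5.908, 1e6, p)), 126)
})

test_that("analytic derivative agrees with the finite-difference oracle", {
  p <- printed_params()
  expect_equal(dK_dPEG(optimal_peg(p), p), 0, tolerance = 1e-12)
  expect_gt(dK_dPEG(3, p), 0)   # rising limb
  expect_lt(dK_dPEG(10, p), 0)  # falling limb
  pegs <- c(0.5, 1, 3, 5, 8, 10, 15, 20, 25)
  for (pd in list(p, growth_params(2, 0.3, 2, 2.5, 0.9, 1.3))) {
    for (x in pegs) {
      if (abs(x - optimal_peg(pd)) < 0.1) next  # fd loses digits at 0
      expect_equal(dK_dPEG(x, pd), fd_dK(x, pd), tolerance = 1e-6)
    }
  }
})

test_that("optimal_peg equals b/c - d and the grid-search argmax", {
  p <- printed_params()
  expect_equal(round(optimal_peg(p), 1), 5.9)
  expect_equal(optimal_peg(growth_params(1, 1, 1, b = 2, c = 2)), 1)
  pd <- growth_params(2.402, 0.235, 5.64, b = 4, c = 0.677, d = 1)
  expect_equal(optimal_peg(pd), 4 / 0.677 - 1, tolerance = 1e-12)
  for (pp in list(p, pd, growth_params(1, 0.5, 3, b = 1.5, c = 0.4))) {
    expect_lt(abs(optimal_peg(pp) - grid_argmax_K(pp)), 0.001 + 1e-9)
  }
  expect_error(optimal_peg(growth_params(1, 1, 1, b = 1, c = 1, d = 2)),
               "b/c")
})

test_that("max_full_length evaluates K at the optimum", {
  p <- printed_params()
  expect_equal(round(max_full_length(p)), 126)
  p2 <- growth_params(2.402, 0.235, a = 2 * 5.64, b = 4, c = 0.677)
  expect_equal(max_full_length(p2), 2 * max_full_length(p),
               tolerance = 1e-12)
  expect_equal(max_full_length(growth_params(1, 1, a = 1, b = 2, c = 1)),
               4 * exp(-2), tolerance = 1e-12)
})

test_that("growth is monotone in das and bounded by K", {
  p <- printed_params()
  for (peg in c(1, 5.9, 13, 25)) {
    das <- seq(0, 40, by = 0.5)
    srl <- predict_srl(peg, das, p)
    expect_true(all(diff(srl) > 0))
    expect_true(all(srl < full_length_K(peg, p)))
  }
})

test_that("K is unimodal: rising then falling about b/c - d", {
  for (pp in list(printed_params(),
                  growth_params(1.5, 0.3, 2, b = 2.2, c = 0.35, d = 0.5))) {
    opt <- optimal_peg(pp)
    lo <- seq(0.01, opt - 0.01, length.out = 400)
    hi <- seq(opt + 0.01, opt + 30, length.out = 400)
    expect_true(all(diff(full_length_K(lo, pp)) > 0))
    expect_true(all(diff(full_length_K(hi, pp)) < 0))
  }
})

test_that("30-DAS growth is within 3% of the asymptote K", {
  p <- printed_params()
  peg <- 1:25
  gap <- 1 - predict_srl(peg, 30, p) / full_length_K(peg, p)
  expect_true(all(gap < 0.03))
})

test_that("coefficient validation enforces sign constraints", {
  expect_error(growth_params(C = -1, r = 0.2, a = 1, b = 1, c = 1), "C > 0")
  expect_error(growth_params(C = 1, r = 0, a = 1, b = 1, c = 1), "r > 0")
  expect_error(growth_params(C = 1, r = 1, a = 1, b = 1, c = 1, d = -1),
               "d >= 0")
  expect_error(growth_params(C = 1, r = Inf, a = 1, b = 1, c = 1), "finite")
})

test_that("coefficients round-trip through flat JSON", {
  p <- growth_params(2.402, 0.235, 5.64, 4, 0.677, 0.25)
  js <- params_to_json(p)
  expect_true(jsonlite::validate(js))
  expect_equal(params_from_json(js), p)
  path <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, path)
  expect_equal(params_from_json(path), p)
  expect_error(params_from_json('{"C": 1, "r": 1}'), "keys")
})

test_that("osmotic lookup reproduces its anchors and stays monotone", {
  expect_identical(osmotic_equivalent(3), 0.01)
  expect_identical(osmotic_equivalent(11), 0.15)
  expect_identical(osmotic_equivalent(5.9), 0.04)
  expect_identical(osmotic_equivalent(0), 0)
  grid <- seq(0, 25, by = 0.01)
  v <- osmotic_equivalent(grid)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 0))
  expect_error(osmotic_equivalent(-0.1), "\\[0, 25\\]")
  expect_error(osmotic_equivalent(26), "\\[0, 25\\]")
})
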