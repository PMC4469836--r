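presets <- c("table1", "table3", "table5", "table6", "table8")
mirrored <- c("table1", "table3", "table6", "table8")  # h-components mirror

test_that("gain closed forms match their sigmoid definitions", {
  d1 <- gain_params(1, -5, 0, "tangent_sigmoid")
  expect_equal(evaluate_gain(d1, 0), 0)                 # bipolar midpoint
  expect_equal(evaluate_gain(d1, 1e6), 1)               # asymptote c1
  expect_equal(evaluate_gain(d1, -1e6), -1)
  hd1 <- gain_params(0.1, -25, -0.5, "log_sigmoid")
  expect_equal(evaluate_gain(hd1, 0.5), 0.05)           # unipolar midpoint
  expect_true(all(evaluate_gain(hd1, c(-1e3, 0, 1e3)) >= 0))
  lin <- gain_params(2, 0, 0, "linear")
  expect_equal(evaluate_gain(lin, c(-1, 0.5)), c(-2, 1))
})

test_that("gains are finite for extreme dopamine signals", {
  for (nm in presets) {
    gs <- gain_preset(nm)
    for (g in Filter(Negate(is.null), gs[c("d1", "d2", "hd1", "hd2")])) {
      expect_true(all(is.finite(evaluate_gain(g, c(-1e8, -1, 0, 1, 1e8)))))
    }
  }
})

test_that("D1 gains increase and D2 gains decrease in dopamine", {
  for (nm in presets) {
    gs <- gain_preset(nm)
    expect_lt(gs$d1$c2, 0)
    expect_true(gain_monotone(gs$d1, direction = 1),
                label = paste(nm, "d1 increasing"))
    if (!is.null(gs$d2)) {
      expect_gt(gs$d2$c2, 0)
      expect_true(gain_monotone(gs$d2, direction = -1),
                  label = paste(nm, "d2 decreasing"))
    }
  }
})

test_that("the co-expressing gain is U-shaped with an interior minimum", {
  for (nm in presets) {
    # table5's components transition near |delta| = 100; the others near 0
    half <- if (nm == "table5") 150 else 2
    delta <- seq(-half, half, length.out = 401)
    v <- d1d2_gain(gain_preset(nm), delta)
    k <- which.min(v)
    expect_gt(k, 1, label = paste(nm, "minimum not at left edge"))
    expect_lt(k, length(v), label = paste(nm, "minimum not at right edge"))
    expect_gt(v[1], min(v))
    expect_gt(v[length(v)], min(v))
  }
})

test_that("mirrored h-components make the co-expressing gain even", {
  for (nm in mirrored) {
    gs <- gain_preset(nm)
    expect_equal(gs$hd1$c1, gs$hd2$c1)
    expect_equal(gs$hd1$c2, -gs$hd2$c2)
    expect_equal(gs$hd1$c3, -gs$hd2$c3)
    delta <- seq(0.01, 2, by = 0.01)
    expect_equal(d1d2_gain(gs, delta), d1d2_gain(gs, -delta),
                 tolerance = 1e-12)
    # algebraic identity at the origin
    expect_equal(d1d2_gain(gs, 0),
                 evaluate_gain(gs$hd1, 0) + evaluate_gain(gs$hd2, 0))
  }
})

test_that("gain parameters are validated", {
  expect_error(gain_params(1, NA_real_, 0), "is.finite")
  expect_error(gain_params(1, -5, 0, form = "bogus"))
  expect_error(gain_set(d1 = "x", hd1 = gain_params(1, 1, 0),
                        hd2 = gain_params(1, 1, 0)))
})
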