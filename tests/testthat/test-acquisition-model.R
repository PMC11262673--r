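test_that("per-projection costs decompose exposure, movement and gating", {
  s <- micro_setup()
  pc <- projection_costs(s, micro_consecutive())
  # t_frame = 1 s + c_det = 1 s for every projection
  expect_true(all(pc$t_exp == 2))
  expect_equal(pc$d_exp, pc$t_exp)
  # consecutive on the 360/512 grid at 60 s/rotation: 0.1 + spacing/6 deg/s
  expect_equal(pc$t_move[2], 0.1 + (360 / 512) / 6)
  expect_equal(pc$t_move[1], 0.1) # initial positioning carries no travel
  # gated beam: movement contributes no dose, gating overhead does
  expect_true(all(pc$d_move == 0))
  expect_true(all(pc$d_gate == 0.1))

  zero <- setup_parameters("zero", 4, 360, 16, 16, t_frame = 1,
                           time_per_rotation = 0, c_det = 0, c_move = 0)
  pcz <- projection_costs(zero, acq_order_consecutive(setup_grid(zero)))
  expect_true(all(pcz$t_move == 0))

  wrong <- acq_order_consecutive(angle_grid(0, 360, 100))
  expect_error(projection_costs(s, wrong),
               class = "mtrecon_invalid_parameter")
})

test_that("preset totals reproduce the published consecutive-order times", {
  tot <- function(name) {
    s <- setup_preset(name)
    acquisition_totals(s, acq_order_consecutive(setup_grid(s)))
  }
  expect_equal(tot("micro")$t_total, 1.1e3, tolerance = 0.05)
  expect_equal(tot("medical")$t_total, 1, tolerance = 0.05)
  expect_equal(tot("cargo")$t_total, 60, tolerance = 0.05)
  # ebct: exact closed form n_proj * (t_frame + c_move); the published
  # figure carries one significant digit
  ebct <- tot("ebct")$t_total
  expect_equal(ebct, 400 * (7e-5 + 1e-5))
  expect_equal(signif(ebct, 1), 0.03)
  # single-projection partial sum is the first per-projection cost
  s <- micro_setup()
  pc <- projection_costs(s, micro_consecutive())
  expect_equal(acquisition_totals(s, micro_consecutive(), n = 1)$t_total,
               pc$t_exp[1] + pc$t_move[1] + pc$t_gate[1])
  expect_error(acquisition_totals(s, micro_consecutive(), n = 0),
               class = "mtrecon_invalid_parameter")
  expect_error(acquisition_totals(s, micro_consecutive(), n = 513),
               class = "mtrecon_invalid_parameter")
})

test_that("continuous-movement regime takes the per-projection maximum", {
  s <- setup_preset("medical")
  ord <- acq_order_consecutive(setup_grid(s))
  pc <- projection_costs(s, ord)
  tot <- acquisition_totals(s, ord)
  expect_equal(tot$t_total, sum(pmax(pc$t_exp + pc$t_gate, pc$t_move)))
  expect_identical(tot$regime, "continuous")
  # when movement is never the bottleneck it reduces to the exposure sum
  slow <- setup_parameters("slow", 10, 360, 8, 8, t_frame = 5,
                           time_per_rotation = 1, c_det = 0, c_move = 0,
                           continuous = TRUE)
  os <- acq_order_consecutive(setup_grid(slow))
  expect_equal(acquisition_totals(slow, os)$t_total, 10 * 5)
})

test_that("time and dose curves are non-decreasing for all presets and orders", {
  for (name in c("micro", "nano", "medical", "cargo", "ebct")) {
    s <- setup_preset(name)
    g <- setup_grid(s)
    orders <- list(acq_order_consecutive(g), acq_order_random(g, 1))
    curves <- acquisition_curves(s, orders)
    for (kind in unique(curves$order_kind)) {
      sub <- curves[curves$order_kind == kind, ]
      expect_true(all(diff(sub$t_total) >= 0))
      expect_true(all(diff(sub$d_total) >= 0))
    }
  }
})

test_that("gating removes the acquisition-order dependence of dose", {
  s <- micro_setup()
  g <- setup_grid(s)
  doses <- vapply(
    list(acq_order_consecutive(g), acq_order_random(g, 4),
         acq_order_logarithmic(g, 4)),
    function(o) acquisition_totals(s, o)$d_total, numeric(1))
  expect_equal(doses[2], doses[1])
  expect_equal(doses[3], doses[1])
})

test_that("without gating, quasi-stationary dose equals time", {
  s <- setup_preset("nano") # gate = 0, quasi-stationary
  for (o in list(acq_order_consecutive(setup_grid(s)),
                 acq_order_random(setup_grid(s), 8))) {
    tot <- acquisition_totals(s, o)
    expect_equal(tot$d_total, tot$t_total)
  }
})

test_that("random order slows the micro scan by several-fold", {
  s <- micro_setup()
  g <- setup_grid(s)
  ratio <- acquisition_totals(s, acq_order_random(g, 1))$t_total /
    acquisition_totals(s, acq_order_consecutive(g))$t_total
  expect_gt(ratio, 5)
})

test_that("logarithmic modeled total matches the validation-stand model row", {
  s <- micro_setup()
  ol <- acq_order_logarithmic(setup_grid(s), 4)
  expect_equal(acquisition_totals(s, ol)$t_total, 1.54e3, tolerance = 0.05)
})

test_that("setups round-trip through YAML configs and reject bad input", {
  path <- withr::local_tempfile(fileext = ".yaml")
  s <- setup_preset("cargo")
  write_setup(s, path)
  back <- read_setup(path)
  expect_equal(unclass(back), unclass(s))
  expect_identical(setup_preset(path)$name, "cargo")
  expect_error(setup_preset("sonar"), class = "mtrecon_lookup_error")
  expect_error(setup_parameters("bad", 10, 360, 8, 8, t_frame = -1,
                                time_per_rotation = 0, c_det = 0,
                                c_move = 0),
               class = "mtrecon_invalid_parameter")
  expect_error(setup_parameters("bad", 10, 400, 8, 8, t_frame = 1,
                                time_per_rotation = 0, c_det = 0,
                                c_move = 0),
               class = "mtrecon_invalid_parameter")
})
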