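test_that("phantom is deterministic, bounded and background-free", {
  p <- phantom_image(96)
  expect_identical(dim(p), c(96L, 96L))
  expect_identical(unclass(p), unclass(phantom_image(96)))
  expect_gte(min(p), 0)
  expect_lte(max(p), 1)
  expect_identical(p[1, 1], 0) # corner background
  expect_error(phantom_image(8), class = "mtrecon_invalid_parameter")
})

test_that("forward projection is linear and geometrically sane", {
  ang <- seq(0, 350, by = 10)
  zero <- matrix(0, 64, 64)
  expect_true(all(radon_project(zero, ang)$values == 0))

  # rotational symmetry of a centred disk (edge antialiased so the
  # object, not its pixelisation, is rotation-invariant)
  n <- 64
  os <- 4
  m <- n * os
  cm <- (m - 1) / 2
  d2 <- outer((seq_len(m) - 1 - cm)^2, (seq_len(m) - 1 - cm)^2, "+")
  big <- matrix(0, m, m)
  big[d2 <= (20 * os)^2] <- 1
  disk <- matrix(colMeans(matrix(
    aperm(array(big, c(os, n, os, n)), c(1, 3, 2, 4)), nrow = os^2)), n, n)
  sd <- radon_project(disk, ang)
  ref <- sd$values[1, ]
  for (r in 2:nrow(sd$values)) {
    expect_lt(sqrt(mean((sd$values[r, ] - ref)^2)) / sqrt(mean(ref^2)),
              0.01)
  }

  # a centred point feature peaks at the central detector bin
  pt <- matrix(0, 65, 65)
  pt[33, 33] <- 1
  sp <- radon_project(pt, 17)
  expect_identical(which.max(sp$values[1, ]), 33L)

  # linearity
  p1 <- phantom_image(64)
  s_both <- radon_project(unclass(p1) + disk, ang)
  expect_equal(s_both$values,
               radon_project(p1, ang)$values + sd$values,
               tolerance = 1e-10)
})

test_that("ramp filter kills DC, preserves zero and is linear", {
  expect_equal(filter_profile(numeric(32)), numeric(32))
  const <- filter_profile(rep(1, 64))
  # zero DC gain holds away from the support edges (a finite constant
  # profile is a rect, whose edges legitimately respond to the ramp)
  expect_lt(max(abs(const[17:48])), 0.01)
  a <- sin(seq_len(64) / 5)
  b <- cos(seq_len(64) / 3)
  expect_equal(filter_profile(a + b),
               filter_profile(a) + filter_profile(b), tolerance = 1e-12)
  expect_error(filter_profile(numeric(0)),
               class = "mtrecon_invalid_parameter")
  # whole-sinogram filtering matches row-wise filtering
  s <- sino64()
  fs <- filter_sinogram(s)
  expect_equal(fs$values[3, ], filter_profile(s$values[3, ]),
               tolerance = 1e-12)
  expect_true(fs$filtered)
})

test_that("full-data FBP reconstructs the phantom accurately", {
  rec <- fbp_reconstruct(sino128())
  expect_identical(rec$n, 128L)
  expect_lt(image_rmse(recon_image(rec), phantom128()), 0.2)
})

test_that("batch FBP with n = 1 equals the single filtered backprojection", {
  s <- sino64()
  one <- fbp_reconstruct(s, n = 1)
  upd <- fbp_update(fbp_partial_init(64), s, 1)
  expect_equal(one$acc, upd$acc, tolerance = 1e-14)
  expect_error(fbp_reconstruct(s, subset = integer(0)),
               class = "mtrecon_invalid_parameter")
  expect_error(fbp_reconstruct(s, subset = 999),
               class = "mtrecon_invalid_parameter")
})

test_that("incremental accumulation equals batch reconstruction (property)", {
  s <- sino128()
  set.seed(7)
  for (m in c(1, 2, 5, 17, 64)) {
    sub <- sample(length(s$angles), m)
    inc <- fbp_partial_init(128)
    for (i in sub) inc <- fbp_update(inc, s, i)
    batch <- fbp_reconstruct(s, subset = sub)
    expect_identical(inc$n, as.integer(m))
    expect_lt(max(abs(inc$acc - batch$acc)) / max(abs(batch$acc)), 1e-6)
  }
})

test_that("the accumulator is order-invariant: the set determines the image", {
  s <- sino128()
  sub <- c(3, 40, 90, 17, 120, 77)
  accs <- lapply(list(sub, rev(sub), sample(sub)), function(ix) {
    r <- fbp_partial_init(128)
    for (i in ix) r <- fbp_update(r, s, i)
    r$acc
  })
  expect_lt(max(abs(accs[[1]] - accs[[2]])) / max(abs(accs[[1]])), 1e-12)
  expect_lt(max(abs(accs[[1]] - accs[[3]])) / max(abs(accs[[1]])), 1e-12)
})

test_that("refeeding the same projection renormalises to the same image", {
  s <- sino64()
  once <- fbp_update(fbp_partial_init(64), s, 10)
  twice <- fbp_update(once, s, 10)
  expect_equal(twice$acc, once$acc, tolerance = 1e-14)
})

test_that("incremental update rejects mismatched detector geometry", {
  rec <- fbp_partial_init(64, n_det = 64)
  expect_error(fbp_update(rec, sino128(), 1),
               class = "mtrecon_invalid_parameter")
})

test_that("equidistant subsets beat consecutive wedges of equal size", {
  s <- sino128()
  ph <- phantom128()
  for (m in c(16, 32)) { # 45 and 90 degree wedges on the 360-deg grid
    wedge <- fbp_reconstruct(s, subset = seq_len(m))
    equi <- fbp_reconstruct(s, subset = seq.int(1, 128, by = 128 / m))
    expect_lt(image_rmse(recon_image(equi), ph),
              image_rmse(recon_image(wedge), ph))
  }
})

test_that("convergence report tracks order quality and full-data agreement", {
  s <- sino128()
  ph <- phantom128()
  g <- angle_grid(0, 360, 128)
  cps <- c(8, 16, 32, 128)
  co <- convergence_report(s, acq_order_consecutive(g), cps, ph)
  lo <- convergence_report(s, acq_order_logarithmic(g, 8), cps, ph)
  # logarithmic rotation checkpoints stay at or below consecutive error
  expect_true(all(lo$rmse[1:3] <= co$rmse[1:3]))
  # same full data set: identical error whatever the order
  expect_equal(lo$rmse[4], co$rmse[4], tolerance = 1e-6)
  # the average stabilises: one more projection changes the image by O(1/n)
  last <- convergence_report(s, acq_order_consecutive(g), c(127, 128))
  expect_lt(last$rel_change[2], 0.05)
  half <- convergence_report(s, acq_order_consecutive(g), c(63, 64))
  expect_gt(half$rel_change[2], last$rel_change[2]) # shrinks with n
  expect_error(convergence_report(s, acq_order_consecutive(g), c(16, 8)),
               class = "mtrecon_invalid_parameter")
})

test_that("FBP agrees with an independent inverse-radon implementation", {
  py <- Sys.which("python")
  expect_true(nzchar(py)) # scientific python stack with scikit-image
  n <- 129 # odd grid so both implementations share the rotation centre
  ph <- phantom_image(n)
  ang <- (0:359) * 0.5
  sino <- radon_project(ph, ang)
  mine <- recon_image(fbp_reconstruct(sino))
  td <- withr::local_tempdir()
  write.table(sino$values, file.path(td, "sino.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  writeLines(as.character(ang), file.path(td, "ang.txt"))
  script <- file.path(td, "oracle.py")
  writeLines(c(
    "import sys, numpy as np",
    "from skimage.transform import iradon",
    "d = sys.argv[1]",
    "s = np.loadtxt(d + '/sino.csv', delimiter=',')",
    "ang = np.loadtxt(d + '/ang.txt')",
    "rec = iradon(s.T, theta=ang, circle=True, filter_name='ramp',",
    "             output_size=s.shape[1])",
    "np.savetxt(d + '/oracle.csv', rec, delimiter=',')"), script)
  status <- system2(py, c(script, td))
  expect_identical(status, 0L)
  oracle <- as.matrix(read.csv(file.path(td, "oracle.csv"), header = FALSE))
  # orientation: the oracle's first image axis points the other way
  oracle <- oracle[rev(seq_len(n)), ]
  expect_lt(image_rmse(mine, oracle), 0.05)
})
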