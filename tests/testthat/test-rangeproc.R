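# Range processing: range FFT, clutter removal, accumulation, OS-CFAR, HDBS.

test_that("range FFT satisfies Parseval and localizes a static target", {
  cube <- array(0 + 0i, dim = c(32, 4, 2))
  expect_equal(max(Mod(range_fft(cube))), 0)

  cfg <- test_config()
  sc <- radar_scene(list(radar_target(0.9, 0, vital = NULL)),
                    snr_db = Inf, duration = 6.4, seed = 1)
  rc <- simulate_cube(sc, cfg)
  rmap <- range_fft(rc)
  # Parseval per chirp
  expect_equal(sum(Mod(rc[, 1, 1])^2), sum(Mod(rmap[, 1, 1])^2) / 200,
               tolerance = 1e-9)
  # peak at bin 21 in every chirp (static target: constant over slow time)
  peaks <- apply(Mod(rmap[1:100, , 1]), 2, which.max) - 1L
  expect_true(all(peaks == 21L))
  sd_peak <- sd(Mod(rmap[22, , 1]))
  expect_lt(sd_peak / mean(Mod(rmap[22, , 1])), 1e-9)
})

test_that("clutter removal zeroes the slow-time mean and is idempotent", {
  set.seed(4)
  m <- array(complex(real = rnorm(20 * 16 * 2), imaginary = rnorm(20 * 16 * 2)),
             dim = c(20, 16, 2))
  out <- remove_clutter(m)
  means <- apply(out, c(1, 3), mean)
  expect_lt(max(Mod(means)), 1e-12)
  expect_equal(remove_clutter(out), out, tolerance = 1e-12)

  # static-clutter-only scene: residual power negligible
  sc <- radar_scene(list(radar_target(1.1, 0, vital = NULL)),
                    snr_db = Inf, duration = 6.4, seed = 1)
  rmap <- range_fft(simulate_cube(sc, test_config()))
  resid <- remove_clutter(rmap)
  expect_lt(sum(Mod(resid)^2), 1e-10 * sum(Mod(rmap)^2))

  # a zero-mean oscillation passes through unchanged
  osc <- array(0 + 0i, dim = c(4, 8, 1))
  osc[1, , 1] <- exp(2i * pi * (0:7) / 4) # full periods -> zero mean
  expect_equal(remove_clutter(osc)[1, , 1], osc[1, , 1], tolerance = 1e-12)
})

test_that("two-stage accumulation has the documented shape and gain", {
  seg <- array(1 + 0i, dim = c(4, 128, 8))
  acc <- two_stage_accumulate(seg, P = 8)
  expect_equal(dim(acc), c(4L, 16L))
  expect_equal(Re(acc[1, 1]), 64)    # 8 channels x 8 columns
  expect_error(two_stage_accumulate(seg, P = 7), "divisible")

  # I = 1, P = 1 is the identity
  one <- array(complex(real = rnorm(40), imaginary = rnorm(40)),
               dim = c(5, 8, 1))
  expect_equal(unname(two_stage_accumulate(one, P = 1)[, ]),
               one[, , 1], ignore_attr = TRUE)

  # stage-1 coherent gain ~ 10 log10(8) = 9.03 dB over Monte-Carlo draws
  set.seed(11)
  gains <- replicate(200, {
    s <- exp(2i * pi * 0.2 * (0:63))           # identical in all channels
    seg <- array(0 + 0i, dim = c(1, 64, 8))
    for (i in 1:8) {
      noise <- complex(real = rnorm(64, sd = sqrt(0.5)),
                       imaginary = rnorm(64, sd = sqrt(0.5)))
      seg[1, , i] <- s + noise
    }
    st1 <- seg[1, , 1]
    for (i in 2:8) st1 <- st1 + seg[1, , i]
    snr_in <- mean(Mod(s)^2) / 1
    snr_out <- mean(Mod(8 * s)^2) / mean(Mod(st1 - 8 * s)^2)
    10 * log10(snr_out / snr_in)
  })
  expect_lt(abs(mean(gains) - 10 * log10(8)), 1)
})

test_that("OS-CFAR matches the order-statistic oracle and its design Pfa", {
  # flat unit column with one strong cell: direct threshold oracle
  col <- rep(1, 64)
  col[30] <- 10                                 # +20 dB in power
  alpha <- os_cfar_alpha(1e-3, 16, 12)
  # oracle: training cells all have power 1 -> threshold = alpha * 1
  expect_true(alpha < 100)
  expect_identical(os_cfar(col, alpha = alpha), 30L)

  # constant column, alpha > 1: nothing detected
  expect_length(os_cfar(rep(3, 50), alpha = alpha), 0)

  expect_error(os_cfar(col, n_train = 8, rank = 12), "rank")

  # Monte-Carlo false-alarm rate on Rayleigh noise
  set.seed(21)
  n_cells <- 0
  n_fa <- 0
  while (n_cells < 1e5) {
    col <- sqrt(stats::rexp(500))               # Rayleigh magnitudes
    det <- os_cfar(col, alpha = alpha)
    # count only interior cells with full training windows
    interior <- 11:490
    n_fa <- n_fa + sum(det %in% interior)
    n_cells <- n_cells + length(interior)
  }
  pfa_emp <- n_fa / n_cells
  expect_gt(pfa_emp, 0.5e-3)
  expect_lt(pfa_emp, 2e-3)
})

test_that("HDBS clusters candidates like the brute-force DBSCAN oracle", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(20:100, 1)
    pts <- cbind(sample(1:60, n, replace = TRUE),
                 sample(1:16, n, replace = TRUE))
    eps <- sample(3:8, 1)
    ms <- sample(3:6, 1)
    got <- dbscan_cluster(pts, eps, ms)
    want <- dbscan_oracle(pts, eps, ms)
    # same noise set and same partition of the non-noise points
    expect_identical(got == 0L, want == 0L)
    nz <- got != 0L
    if (any(nz)) {
      expect_identical(as.vector(table(got[nz])[as.character(got[nz])]) > 0,
                       rep(TRUE, sum(nz)))
      # identical partitions: cluster co-membership matrices agree on cores
      co_got <- outer(got[nz], got[nz], "==")
      co_want <- outer(want[nz], want[nz], "==")
      core <- rowSums(as.matrix(dist(pts)) <= eps) >= ms
      core_nz <- core[nz]
      expect_identical(co_got[core_nz, core_nz], co_want[core_nz, core_nz])
    }
  }
})

test_that("HDBS selects the highest-energy bin and drops sparse points", {
  # two dense clusters 20 bins apart -> exactly two targets
  cl1 <- cbind(rep(20:22, c(4, 3, 3)), c(1:4, 1:3, 2:4))
  cl2 <- cbind(rep(40:42, c(3, 4, 3)), c(1:3, 1:4, 2:4))
  cand <- rbind(cl1, cl2)
  energy <- rep(1, 64)
  energy[c(21, 41) + 1L] <- 10
  det <- hdbs(cand, energy, eps = 6, min_samples = 5, bin_width = 0.0428)
  expect_equal(nrow(det), 2L)
  expect_setequal(det$bin, c(21L, 41L))

  # fewer than min_samples isolated points -> all noise
  iso <- cbind(c(5, 25, 45, 60), c(1, 5, 9, 13))
  det0 <- hdbs(iso, energy, eps = 3, min_samples = 5, bin_width = 0.0428)
  expect_equal(nrow(det0), 0L)

  # energy argmax picks bin 21 out of {20, 21, 22}
  tri <- cbind(rep(c(20, 21, 22), each = 3), rep(1:3, 3))
  e3 <- rep(0, 64); e3[c(20, 21, 22) + 1L] <- c(1, 5, 2)
  det3 <- hdbs(tri, e3, eps = 6, min_samples = 5, bin_width = 1)
  expect_equal(det3$bin, 21L)
  expect_equal(det3$range, 21)

  # empty candidate set is not an error
  det_e <- hdbs(matrix(numeric(0), ncol = 2), energy, bin_width = 1)
  expect_equal(nrow(det_e), 0L)
})

test_that("noiseless two-target scenes are detected within one bin", {
  cfg <- test_config()
  sc <- occlusion_scene(seed = 3, snr_db = Inf, duration = 12.8)
  rmap <- remove_clutter(range_fft(simulate_cube(sc, cfg)))
  dets <- detect_ranges(rmap, K = 128, P = 8)
  bins_true <- round(c(0.8, 1.5) / cfg$range_bin_width)
  for (d in dets) {
    expect_equal(nrow(d), 2L)
    got <- sort(d$bin)
    expect_true(all(abs(got - bins_true) <= 1))
    rel_err <- abs(sort(d$range) - c(0.8, 1.5)) / c(0.8, 1.5)
    expect_lt(max(rel_err), 0.03)
  }
})
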