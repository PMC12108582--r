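test_that("tunnel volume is exactly voxel count times spacing cubed", {
  expect_equal(tunnel_volume(array(0L, c(3, 3, 3)), 1), 0)
  expect_equal(tunnel_volume(array(1L, c(10, 10, 10)), 1), 1000)
  expect_identical(tunnel_volume(array(1L, c(10, 10, 10)), 0.0607),
                   1000 * 0.0607^3)
  set.seed(19)
  for (i in 1:50) {
    m <- random_mask(c(5, 6, 7), p = runif(1))
    s <- runif(1, 0.01, 2)
    expect_identical(tunnel_volume(m, s), sum(m) * s^3)   # bit-exact
  }
  expect_error(tunnel_volume(array(1L, c(2, 2, 2)), 0), "bad spacing")
})

test_that("bone-in-tunnel thresholding recovers the phantom bone phase", {
  spec <- phantom_spec(shape = c(20L, 24L, 24L), spacing = 0.1, noise_sd = 0,
                       seed = 3)
  ph <- make_lattice_phantom(spec)
  tun <- label_mask(array(1L, dim(ph$grid)))
  bone <- bone_in_tunnel(ph$grid, tun, method = "otsu")
  expect_identical(unclass(bone), unclass(ph$bone_truth))
  # uniform bright interior: bone mask equals the tunnel mask
  g <- voxel_grid(array(200, c(2, 8, 8)), spacing = 0.1)
  t2 <- random_mask(c(2, 8, 8), p = 0.4)
  b2 <- bone_in_tunnel(g, t2, method = "fixed", threshold = 100)
  expect_identical(unclass(b2), unclass(t2))
  # containment contract under arbitrary thresholds
  set.seed(13)
  g3 <- voxel_grid(array(runif(2 * 8 * 8, 0, 255), c(2, 8, 8)), spacing = 0.1)
  b3 <- bone_in_tunnel(g3, t2, method = "otsu")
  expect_true(all(b3 <= t2))
  expect_error(bone_in_tunnel(g3, label_mask(array(0L, c(2, 8, 8)))),
               "empty tunnel")
})

test_that("local thickness matches analytic slabs and isolated voxels", {
  slab <- array(0L, c(11, 10, 10)); slab[4:8, , ] <- 1L   # 5-voxel slab
  tm <- local_thickness_map(slab, spacing = 0.1)
  expect_lte(abs(mean(tm[slab == 1]) - 5 * 0.1), 0.1)
  expect_true(all(tm[slab == 0] == 0))
  one <- array(0L, c(7, 7, 7)); one[4, 4, 4] <- 1L
  tm1 <- local_thickness_map(one, spacing = 0.1)
  expect_equal(tm1[4, 4, 4], 0.1)
  # dilating the structure never shrinks mean thickness
  set.seed(2)
  m <- array(as.integer(runif(12^3) < 0.4), c(12, 12, 12))
  base_mean <- mean(local_thickness_map(m, 1)[m == 1])
  md <- m
  sh <- function(a, d, k) {
    out <- array(0L, dim(a))
    src <- lapply(dim(a), seq_len)
    dst <- src
    src[[d]] <- src[[d]][src[[d]] + k >= 1 & src[[d]] + k <= dim(a)[d]]
    dst[[d]] <- src[[d]] + k
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (d in 1:3) for (k in c(-1, 1)) md <- pmax(md, sh(m, d, k))
  expect_gte(mean(local_thickness_map(md, 1)[m == 1]), base_mean)
})

test_that("local thickness equals the brute-force maximal-sphere oracle", {
  set.seed(7)
  cases <- list(
    array(as.integer(runif(14^3) < 0.45), c(14, 14, 14)),
    array(as.integer(runif(10 * 12 * 16) < 0.6), c(10, 12, 16)))
  # a structured case: slab plus a hole
  slab <- array(0L, c(12, 12, 12)); slab[5:8, , ] <- 1L; slab[5:8, 6:7, 6:7] <- 0L
  cases[[3]] <- slab
  for (m in cases) {
    oracle <- bf_local_thickness(m)
    fast <- unclass(local_thickness_map(m, 1))
    expect_lte(max(abs(fast - oracle)), 2)      # within one voxel diameter
    expect_lt(mean(abs(fast - oracle)), 1e-9)   # and in fact identical here
  }
})

test_that("morphometry recovers plate-lattice parameters inside a cylinder ROI", {
  case <- plate_recovery_case(0.3, 1.0, 0.05)
  res <- morphometry_report(case$phantom$grid, case$roi)
  exp <- expected_lattice_metrics(case$spec)
  expect_lte(abs(res$bvtv - exp$bvtv), 0.02)
  expect_lte(abs(res$tb_th - exp$tb_th), 0.05 + 1e-9)   # one voxel
  expect_lte(abs(res$tb_sp - exp$tb_sp), 0.05 + 1e-9)
  expect_equal(res$volume, sum(case$roi) * 0.05^3)
})

test_that("degenerate tunnels and units behave as documented", {
  g <- voxel_grid(array(200, c(4, 8, 8)), spacing = 0.0607)
  tun <- label_mask(array(1L, c(4, 8, 8)))
  res <- morphometry_report(g, tun, method = "fixed", threshold = 100)
  expect_equal(res$bvtv, 1)
  expect_equal(res$tb_sp, 0)
  expect_equal(res$volume, 4 * 8 * 8 * 0.0607^3)
  expect_equal(res$mgv, 200)
  expect_error(morphometry_report(g, label_mask(array(0L, c(4, 8, 8)))),
               "empty tunnel")
})

test_that("doubling the spacing rescales every index correctly", {
  spec <- phantom_spec(shape = c(22L, 20L, 20L), spacing = 0.1,
                       plate_thickness_t = 0.3, plate_period_p = 1.0,
                       noise_sd = 0, seed = 6)
  ph <- make_lattice_phantom(spec)
  tun <- label_mask(array(1L, dim(ph$grid)))
  r1 <- morphometry_report(ph$grid, tun, method = "fixed", threshold = 100)
  g2 <- voxel_grid(unclass(ph$grid), spacing = 0.2)
  r2 <- morphometry_report(g2, tun, method = "fixed", threshold = 100)
  expect_equal(r2$bvtv, r1$bvtv)
  expect_equal(r2$tb_th, 2 * r1$tb_th)
  expect_equal(r2$tb_sp, 2 * r1$tb_sp)
  expect_equal(r2$tb_n, r1$tb_n / 2)
  expect_equal(r2$volume, 8 * r1$volume)
})

test_that("alternative trabecular-number conventions are consistent", {
  case <- plate_recovery_case(0.3, 1.0, 0.1)
  direct <- morphometry_report(case$phantom$grid, case$roi)
  plate <- morphometry_report(case$phantom$grid, case$roi,
                              tb_n_method = "plate")
  invsp <- morphometry_report(case$phantom$grid, case$roi,
                              tb_n_method = "inverse_separation")
  expect_equal(direct$tb_n, 1 / (direct$tb_th + direct$tb_sp))
  expect_equal(plate$tb_n, plate$bvtv / plate$tb_th)
  expect_equal(invsp$tb_n, 1 / invsp$tb_sp)
})
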