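probe_s2 <- function(op, sim) {
  op$residues$S2[match(sim$probe_resids, op$residues$resid)]
}

test_that("superposition of identical or translated structures is exact", {
  set.seed(11)
  ref <- matrix(stats::rnorm(12), 4, 3)
  s <- superpose(ref, ref)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(s$rotation), 1, tolerance = 1e-8)
  mob <- sweep(ref, 2, c(5, -3, 12), "+")
  expect_equal(superpose(mob, ref)$rmsd, 0, tolerance = 1e-10)
})

test_that("a known rotation is recovered to 1e-6", {
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0,
                -sin(th), cos(th), 0,
                0, 0, 1), 3, 3)
  set.seed(12)
  ref <- matrix(stats::rnorm(12, sd = 4), 4, 3)
  mob <- sweep(ref %*% R, 2, c(1, 2, 3), "+")
  s <- superpose(mob, ref)
  expect_equal(s$rmsd, 0, tolerance = 1e-8)
  # applying the recovered transform must undo R
  expect_equal(s$rotation, t(R), tolerance = 1e-6)
  expect_equal(apply_superposition(mob, s), ref, tolerance = 1e-8)
})

test_that("collinear selections are rejected", {
  ref <- cbind(1:5, 0, 0)
  mob <- cbind(2 * (1:5), 0, 0)
  expect_error(superpose(mob, ref), "collinear")
})

test_that("order parameter closed forms: static, isotropic, cone", {
  expect_equal(order_parameter(matrix(rep(c(0.3, -0.5, 0.81), 10),
                                      ncol = 3, byrow = TRUE)), 1,
               tolerance = 1e-9)
  set.seed(77)
  n <- 1e5
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  expect_lt(order_parameter(v), 0.02)
  # wobble-in-cone closed form at 30 degrees
  expect_equal(cone_order_parameter(30), 0.6529, tolerance = 1e-3)
  sim <- gen_cone_trajectory(30, n_frames = 6000, seed = 3)
  op <- per_residue_order(sim$traj)
  expect_lt(abs(probe_s2(op, sim) - 0.6529), 0.01)
  expect_error(order_parameter(matrix(0, 5, 3)), "zero-length")
})

test_that("cone order parameter decreases monotonically with cone angle", {
  s2 <- cone_order_parameter(seq(5, 90, by = 5))
  expect_true(all(diff(s2) < 0))
  expect_equal(cone_order_parameter(90), 0)
})

test_that("a wide-cone (hemisphere) trajectory approaches full disorder", {
  sim <- gen_cone_trajectory(90, n_frames = 8000, seed = 8)
  op <- per_residue_order(sim$traj)
  expect_lt(probe_s2(op, sim), 0.02)
})

test_that("rigid-body-only motion yields order parameters of one after alignment", {
  sim <- gen_cone_trajectory(c(5, 10), n_frames = 2, seed = 1)
  # frozen internal geometry: replicate frame 1 under rotations+translations
  tr <- sim$traj
  xyz <- tr$coords[, , 1]
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  nf <- 6
  coords <- array(NA_real_, c(nrow(xyz), 3, nf))
  acc <- diag(3)
  for (f in seq_len(nf)) {
    coords[, , f] <- sweep(xyz %*% acc, 2, c(f, -f, 2 * f), "+")
    acc <- acc %*% R
  }
  tr2 <- trajectory(tr$atoms, coords, seq_len(nf))
  op <- per_residue_order(tr2)
  expect_equal(op$residues$S2, rep(1, nrow(op$residues)), tolerance = 1e-8)
})

test_that("global rotation leaves recovered cone order parameters unchanged", {
  ang <- c(10, 30, 60)
  plain <- gen_cone_trajectory(ang, 5000, seed = 21)
  rot <- gen_cone_trajectory(ang, 5000, seed = 21, global_rotation = TRUE)
  truth <- cone_order_parameter(ang)
  expect_true(all(abs(probe_s2(per_residue_order(plain$traj), plain) -
                        truth) < 0.02))
  expect_true(all(abs(probe_s2(per_residue_order(rot$traj), rot) -
                        truth) < 0.02))
})

test_that("per-residue values cover cones and region averages are arithmetic means", {
  ang <- c(10, 30, 60)
  sim <- gen_cone_trajectory(ang, n_frames = 5000, seed = 13)
  op <- per_residue_order(sim$traj)
  expect_true(all(abs(probe_s2(op, sim) - sim$s2_truth) < 0.02))
  expect_equal(op$averages$receptor, mean(op$residues$S2))
})

test_that("identical trajectories give an identically zero difference trace", {
  sim <- gen_cone_trajectory(c(20, 40), n_frames = 500, seed = 2)
  a <- per_residue_order(sim$traj)
  d <- order_param_difference(a, a)
  expect_equal(d$dS2, rep(0, nrow(d)))
})

test_that("residues without an attached hydrogen are skipped with a warning", {
  sim <- gen_cone_trajectory(c(20, 40), n_frames = 50, seed = 4)
  tr <- sim$traj
  drop <- !(tr$atoms$resid == 2 & tr$atoms$name == "HA")
  tr2 <- trajectory(tr$atoms[drop, ], tr$coords[drop, , , drop = FALSE],
                    tr$times)
  expect_warning(op <- per_residue_order(tr2), "skipped")
  expect_false(2L %in% op$residues$resid)
})

test_that("missing hydrogens can be reconstructed from backbone geometry", {
  # residue 1 carries N, C, CB but no HA; three rigid anchors provide the
  # alignment frame
  atoms <- rbind(
    data.frame(name = c("CA", "N", "C", "CB"), resid = 1L, resname = "ALA",
               segcat = "receptor", heavy = TRUE),
    do.call(rbind, lapply(2:4, function(r)
      data.frame(name = c("CA", "HA"), resid = r, resname = "ANC",
                 segcat = "receptor", heavy = c(TRUE, FALSE)))))
  xyz <- rbind(c(0, 0, 0), c(1.45, 0, 0), c(-0.7, 1.3, 0), c(-0.6, -1.2, 0.6),
               c(10, 0, 0), c(10, 1.09, 0),
               c(0, 10, 0), c(0, 10, 1.09),
               c(0, 0, 10), c(1.09, 0, 10))
  nf <- 3
  coords <- array(rep(xyz, nf), c(nrow(xyz), 3, nf))
  tr <- trajectory(atoms, coords, seq_len(nf))
  # without reconstruction the residue is skipped
  expect_warning(op0 <- per_residue_order(tr), "skipped")
  expect_false(1L %in% op0$residues$resid)
  # with reconstruction a static effective bond gives S2 = 1
  op1 <- per_residue_order(tr, reconstruct_h = TRUE)
  expect_true(1L %in% op1$residues$resid)
  expect_equal(op1$residues$S2[op1$residues$resid == 1L], 1,
               tolerance = 1e-9)
})

test_that("rmsd series is zero for translations and bounded by d/sqrt(n)", {
  sim <- gen_cone_trajectory(1e-6, n_frames = 2, seed = 6)
  tr <- sim$traj
  xyz <- tr$coords[, , 1]
  nf <- 4
  coords <- array(rep(xyz, nf), c(nrow(xyz), 3, nf))
  for (f in 2:nf) coords[, , f] <- sweep(xyz, 2, c(f, f, f), "+")
  tr2 <- trajectory(tr$atoms, coords, seq_len(nf))
  expect_equal(rmsd_series(tr2), rep(0, nf), tolerance = 1e-9)
  sel <- which(tr$atoms$name == "CA")
  n <- length(sel)
  d <- 2.0
  coords2 <- coords
  coords2[sel[1], 1, 2] <- coords2[sel[1], 1, 2] + d
  tr3 <- trajectory(tr$atoms, coords2, seq_len(nf))
  r <- rmsd_series(tr3, reference = 1L, selection = sel)
  # the post-fit RMSD can only fall below the unfitted value d/sqrt(n)
  expect_lte(r[2], d / sqrt(n) + 1e-9)
  expect_gt(r[2], 0)
})

test_that("order parameters are invariant under a rigid rotation applied before re-alignment", {
  sim <- gen_cone_trajectory(c(25, 45), n_frames = 800, seed = 31)
  tr <- sim$traj
  set.seed(99)
  th <- stats::runif(1, 0, pi)
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  coords <- tr$coords
  for (f in seq_len(dim(coords)[3])) coords[, , f] <- coords[, , f] %*% R
  tr2 <- trajectory(tr$atoms, coords, tr$times)
  a <- per_residue_order(tr)
  b <- per_residue_order(tr2)
  expect_equal(b$residues$S2, a$residues$S2, tolerance = 1e-8)
})
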