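# shared fixtures and small independent oracles used across test files

acq_default <- acquisition_params()

apo_params <- table1_presets()$apo$params
npy_params <- table1_presets()$npy$params
control_params <- table1_presets()$control_construct_bicelles$params

# independent scalar-arithmetic evaluation of the product model: one term
# at a time, no vectorization shared with the implementation
oracle_zvalue <- function(params, x_ppm, acq) {
  total <- 0
  for (r in params$resonances) {
    d_rad <- 2 * pi * (r$b - x_ppm) * acq$f_obs * 1e-6
    total <- total + r$B * r$a^2 / (r$a^2 + d_rad^2)
  }
  params$A * exp(-total)
}

# brute-force per-frame contact scan: plain triple loop over residues and
# atoms, no shared code with contacts_in_frame
oracle_contacts <- function(traj, frame, cutoff) {
  at <- traj$atoms
  xyz <- traj$coords[, , frame]
  xe <- which(at$segcat == "xenon")
  hits <- character(0)
  for (key in unique(paste(at$segcat, at$resid))) {
    rows <- which(paste(at$segcat, at$resid) == key)
    seg <- at$segcat[rows[1]]
    if (!seg %in% c("receptor", "ligand", "lipid")) next
    found <- FALSE
    for (i in rows) {
      if (!at$heavy[i]) next
      d <- sqrt(sum((xyz[i, ] - xyz[xe, ])^2))
      if (d < cutoff) found <- TRUE
    }
    if (found) hits <- c(hits, key)
  }
  sort(hits)
}

# power-iteration stationary distribution, independent of hop_model's
# eigen-decomposition route
oracle_stationary <- function(P, iters = 10000) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) v <- drop(v %*% P)
  v / sum(v)
}

# minimal hand-built trajectory: one xenon plus one single-atom residue at
# a controlled distance per frame
two_atom_traj <- function(distances, segcat = "receptor") {
  atoms <- data.frame(name = c("C1", "XE"), resid = c(1L, 99L),
                      resname = c("TOY", "XE"),
                      segcat = c(segcat, "xenon"), heavy = TRUE)
  nf <- length(distances)
  coords <- array(0, c(2, 3, nf))
  for (f in seq_len(nf)) coords[1, 1, f] <- distances[f]
  trajectory(atoms, coords, seq_len(nf) * 0.1)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
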