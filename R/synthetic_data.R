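# run code under a private, seeded RNG stream; the caller's RNG state is
# untouched and the output is a pure function of (inputs, seed)
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# ---- z-spectrum presets ----------------------------------------------------

#' Reference z-spectrum parameter sets
#'
#' The fitted multi-resonance parameter sets of the cryptophane-tagged Y2
#' receptor study conditions, used as generating ground truth for
#' synthetic spectra: the conjugate alone (\code{apo}, 5 resonances), the
#' conjugate in complex with neuropeptide Y (\code{npy}, 6 resonances),
#' the free construct incubated in bicelles (\code{control_construct_bicelles},
#' a single strong resonance), and, for completeness, the two
#' direct-detection lines of free CrA-COOH in lipid and aqueous phases
#' (\code{control_free_cra}; line positions and widths only, no CEST
#' amplitudes). Positions in ppm, amplitudes dimensionless, widths as
#' a/pi in Hz. Baselines are 1.
#'
#' @return named list of presets; each has \code{label}, \code{params}
#'   (an \code{xe_zspec_params}, or NULL for the direct-detection control)
#'   and, for the free-CrA control, \code{lines} (data frame position_ppm,
#'   fwhm_hz).
#' @export
table1_presets <- function() {
  mk <- function(label, tab) {
    res <- lapply(seq_len(nrow(tab)), function(i)
      resonance(tab[i, 1], tab[i, 2], tab[i, 3]))
    list(label = label, params = zspec_params(1, res))
  }
  apo <- matrix(c(103.3, 0.069,  820,
                   91.9, 0.077,  947,
                   77.5, 2.300,  573,
                   67.2, 0.163,  242,
                   58.8, 0.092, 1570), ncol = 3, byrow = TRUE)
  npy <- matrix(c(104.9, 0.089,  322,
                   92.4, 0.136,  704,
                   77.5, 2.120,  618,
                   70.0, 0.181,  466,
                   63.0, 0.182,  785,
                   49.5, 0.109,  417), ncol = 3, byrow = TRUE)
  ctrl <- matrix(c(77.9, 2.206, 497), ncol = 3)
  list(
    apo = mk("apo", apo),
    npy = mk("npy", npy),
    control_construct_bicelles = mk("control_construct_bicelles", ctrl),
    control_free_cra = list(
      label = "control_free_cra", params = NULL,
      lines = data.frame(position_ppm = c(77.3, 63.7),
                         fwhm_hz = c(320, 24),
                         environment = c("lipid", "aqueous")))
  )
}

.resolve_params <- function(x) {
  if (inherits(x, "xe_zspec_params")) return(x)
  if (is.character(x) && length(x) == 1L) x <- table1_presets()[[x]]
  if (is.list(x) && inherits(x$params, "xe_zspec_params")) return(x$params)
  stop("expected an xe_zspec_params, a preset object, or a preset name")
}

#' Generate a synthetic z-spectrum
#'
#' Evaluates the forward model on the acquisition grid and adds
#' independent Gaussian noise of standard deviation \code{noise_sigma}.
#' The output is fully determined by (parameters, acquisition, seed). The
#' generating parameters travel in \code{meta$truth}.
#'
#' @param params an \code{xe_zspec_params}, a preset from
#'   [table1_presets()], or a preset name like \code{"apo"}.
#' @param acq an \code{xe_acq}; its grid defines the offsets.
#' @param noise_sigma Gaussian noise SD in intensity units (>= 0).
#' @param seed integer seed; required for reproducibility when
#'   \code{noise_sigma > 0}.
#' @return an \code{xe_zspectrum} (with per-point \code{sigma} set to
#'   \code{noise_sigma} when positive).
#' @export
gen_zspectrum <- function(params, acq = acquisition_params(),
                          noise_sigma = 0, seed = NULL) {
  params <- .resolve_params(params)
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop("noise_sigma must be >= 0")
  offsets <- acq_grid_ppm(acq)
  s <- evaluate_zspectrum(params, offsets, acq)
  if (noise_sigma > 0)
    s <- s + .with_seed(seed, function() stats::rnorm(length(s), 0, noise_sigma))
  zspectrum(offsets, s,
            sigma = if (noise_sigma > 0) rep(noise_sigma, length(s)) else NULL,
            meta = list(truth = params, noise_sigma = noise_sigma,
                        seed = seed, acquisition = acq))
}

#' Generate a per-scan spectrum series for a z-spectrum
#'
#' Emulates the raw material behind a z-spectrum: one absorption-mode
#' 1-D spectrum per irradiation offset, whose free-xenon peak (a
#' Lorentzian at the free-xenon position) has an area proportional to the
#' forward-model saturation response at that offset. Integrating these
#' scans and assembling them reproduces the model z-spectrum shape up to
#' one global scale.
#'
#' @inheritParams gen_zspectrum
#' @param axis_ppm ppm axis of each scan (default: free-xenon position
#'   +/- 16 ppm in 0.05 ppm steps).
#' @param peak_fwhm_ppm full width at half maximum of the detection line,
#'   ppm.
#' @param area_scale global area scale factor.
#' @param noise_sigma Gaussian noise SD added to scan amplitudes.
#' @return list with \code{scans} (list of \code{xe_scan1d}),
#'   \code{truth} (the noise-free model z-spectrum), and
#'   \code{offsets_hz} (manifest offsets relative to the free-xenon line).
#' @export
gen_scan_set <- function(params, acq = acquisition_params(),
                         axis_ppm = NULL, peak_fwhm_ppm = 0.5,
                         area_scale = 1, noise_sigma = 0, seed = NULL) {
  params <- .resolve_params(params)
  ref <- acq$ref_free_xe_ppm
  if (is.null(axis_ppm)) axis_ppm <- seq(ref - 16, ref + 16, by = 0.05)
  offsets <- acq_grid_ppm(acq)
  z <- evaluate_zspectrum(params, offsets, acq)
  gam <- peak_fwhm_ppm / 2
  shape <- (1 / pi) * gam / ((axis_ppm - ref)^2 + gam^2)  # unit area
  scans <- .with_seed(seed, function() {
    lapply(seq_along(offsets), function(i) {
      amp <- area_scale * z[i] * shape
      if (noise_sigma > 0)
        amp <- amp + stats::rnorm(length(amp), 0, noise_sigma)
      scan1d(axis_ppm, amp, offsets[i])
    })
  })
  list(scans = scans,
       truth = zspectrum(offsets, z, meta = list(truth = params)),
       offsets_hz = ppm_to_hz(offsets - ref, acq))
}

#' Write a scan set to a directory with a manifest
#'
#' Writes one CSV per scan (columns \code{ppm}, \code{amplitude}) plus a
#' \code{manifest.csv} with columns \code{filename},
#' \code{irradiation_offset_hz}, the format read back by
#' [read_scan_set()].
#'
#' @param scans list of \code{xe_scan1d}.
#' @param dir output directory.
#' @param acq an \code{xe_acq} (for offset conversion into the manifest).
#' @return invisibly, the manifest path.
#' @export
write_scan_set <- function(scans, dir, acq = acquisition_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fns <- sprintf("scan_%03d.csv", seq_along(scans))
  for (i in seq_along(scans)) {
    utils::write.csv(data.frame(ppm = scans[[i]]$axis,
                                amplitude = scans[[i]]$amplitude),
                     file.path(dir, fns[i]), row.names = FALSE)
  }
  offs <- vapply(scans, `[[`, numeric(1), "irradiation_offset")
  mf <- data.frame(filename = fns,
                   irradiation_offset_hz =
                     ppm_to_hz(offs - acq$ref_free_xe_ppm, acq))
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

# ---- Markov site-hopping trajectories --------------------------------------

#' Define a site-hopping model for xenon contact statistics
#'
#' A discrete-state Markov chain over named sites. Each state carries the
#' residues (segment category + residue index) whose neighborhood the
#' xenon occupies while in that state; a state with no residues is bulk
#' solvent ("no contacts"). The chain must have a unique stationary
#' distribution (one closed communicating class; an absorbing state is
#' fine, disconnected components are not). A residue may belong to at most
#' one state, which keeps the implied per-residue contact probabilities
#' analytic.
#'
#' @param transition row-stochastic square matrix.
#' @param states list, one element per chain state: a list with
#'   \code{name} and \code{targets}, a data frame with columns
#'   \code{segcat} (\code{receptor}, \code{ligand} or \code{lipid}) and
#'   \code{resid}; \code{NULL} targets mean bulk.
#' @return An object of class \code{xe_hop_model} with the analytic
#'   \code{stationary} distribution and per-state \code{category} labels
#'   attached.
#' @export
hop_model <- function(transition, states) {
  P <- as.matrix(transition)
  n <- nrow(P)
  stopifnot(ncol(P) == n, length(states) == n)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-10))
    stop("transition matrix must be row-stochastic")
  ev <- eigen(t(P))
  near1 <- which(abs(ev$values - 1) < 1e-9)
  if (length(near1) != 1L)
    stop("transition chain has no unique stationary distribution ",
         "(reducible into several closed classes)")
  stat <- Re(ev$vectors[, near1])
  stat <- stat / sum(stat)
  if (any(stat < -1e-12)) stop("invalid stationary distribution")
  stat <- pmax(stat, 0)
  stat <- stat / sum(stat)
  seen <- character(0)
  category <- character(n)
  for (i in seq_len(n)) {
    tg <- states[[i]]$targets
    if (is.null(tg) || !nrow(tg)) {
      category[i] <- "no contacts"
      next
    }
    stopifnot(all(c("segcat", "resid") %in% names(tg)),
              all(tg$segcat %in% c("receptor", "ligand", "lipid")))
    key <- paste(tg$segcat, tg$resid)
    if (any(key %in% seen)) stop("a residue may belong to only one state")
    seen <- c(seen, key)
    lip <- any(tg$segcat == "lipid")
    prot <- any(tg$segcat %in% c("receptor", "ligand"))
    category[i] <- if (lip && prot) "lipid and protein"
      else if (lip) "just lipid" else "just protein"
  }
  structure(list(transition = P, states = states, stationary = stat,
                 category = category),
            class = "xe_hop_model")
}

#' Generate a xenon site-hopping trajectory with analytic truth
#'
#' Builds a toy topology in which each chain state owns a spatially
#' isolated site (sites are separated by ten cutoff lengths), simulates
#' the Markov chain from its stationary distribution, and places the
#' xenon atom inside the cutoff of the current state's residues (or far
#' from everything for bulk states). The returned object carries the
#' analytic stationary distribution and the implied environment-category
#' probabilities, so downstream contact statistics can be checked against
#' closed-form truth.
#'
#' @param model an \code{xe_hop_model}.
#' @param n_frames number of frames.
#' @param dt_ns time step between frames, ns.
#' @param seed integer seed.
#' @param cutoff contact cutoff the placement respects, Angstrom.
#' @return list with \code{traj} (an \code{xe_trajectory}), \code{chain}
#'   (integer state per frame), \code{stationary}, \code{category_truth}
#'   (named probabilities of the four environment categories), and
#'   \code{model}.
#' @export
gen_hop_trajectory <- function(model, n_frames, dt_ns = 0.1, seed = 1,
                               cutoff = 8.5) {
  stopifnot(inherits(model, "xe_hop_model"), n_frames >= 1)
  n <- nrow(model$transition)
  centers <- cbind(10 * cutoff * seq_len(n), 0, 0)
  atoms <- list(); pos <- list()
  for (i in seq_len(n)) {
    tg <- model$states[[i]]$targets
    if (is.null(tg) || !nrow(tg)) next
    for (j in seq_len(nrow(tg))) {
      # residue heavy atom close to the site center so that xenon placed at
      # the center touches every residue of the state and no other site
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = "C1", resid = tg$resid[j], resname = "TOY",
        segcat = tg$segcat[j], heavy = TRUE)
      ang <- 2 * pi * j / (nrow(tg) + 1)
      pos[[length(pos) + 1L]] <-
        centers[i, ] + 0.3 * cutoff * c(cos(ang), sin(ang), 0)
    }
  }
  atoms[[length(atoms) + 1L]] <- data.frame(
    name = "XE", resid = 9999L, resname = "XE", segcat = "xenon",
    heavy = TRUE)
  pos[[length(pos) + 1L]] <- c(0, 0, 0)   # overwritten per frame
  atoms <- do.call(rbind, atoms)
  base_xyz <- do.call(rbind, pos)
  xe_row <- nrow(atoms)
  bulk_pos <- c(0, 1e4, 1e4)

  out <- .with_seed(seed, function() {
    chain <- integer(n_frames)
    chain[1] <- sample.int(n, 1, prob = model$stationary)
    for (f in seq_len(n_frames - 1L))
      chain[f + 1L] <- sample.int(n, 1, prob = model$transition[chain[f], ])
    coords <- array(rep(base_xyz, n_frames), c(nrow(atoms), 3, n_frames))
    for (f in seq_len(n_frames)) {
      st <- chain[f]
      tg <- model$states[[st]]$targets
      jitter <- stats::runif(3, -0.1, 0.1) * cutoff
      coords[xe_row, , f] <- if (is.null(tg) || !nrow(tg))
        bulk_pos + jitter else centers[st, ] + jitter
    }
    list(chain = chain, coords = coords)
  })
  traj <- trajectory(atoms, out$coords, dt_ns * seq_len(n_frames))
  cat_truth <- vapply(
    c("just lipid", "just protein", "lipid and protein", "no contacts"),
    function(cc) sum(model$stationary[model$category == cc]), numeric(1))
  list(traj = traj, chain = out$chain, stationary = model$stationary,
       category_truth = cat_truth, model = model)
}

# ---- cone-wobble trajectories ----------------------------------------------

.unit_in_cone <- function(axis, theta_rad) {
  # uniform in solid angle within the cone about `axis`
  c_min <- cos(theta_rad)
  cphi <- stats::runif(1, c_min, 1)
  sphi <- sqrt(1 - cphi^2)
  psi <- stats::runif(1, 0, 2 * pi)
  # orthonormal basis around axis
  a <- .unit(axis)
  e1 <- if (abs(a[1]) < 0.9) .unit(.cross(a, c(1, 0, 0)))
    else .unit(.cross(a, c(0, 1, 0)))
  e2 <- .cross(a, e1)
  cphi * a + sphi * (cos(psi) * e1 + sin(psi) * e2)
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Generate a cone-wobble bond-vector trajectory
#'
#' One receptor residue per requested cone angle, each with a Calpha atom
#' on a rigid non-collinear scaffold and a hydrogen whose bond vector is
#' sampled uniformly within a cone of the given semi-angle about a fixed
#' per-residue axis. The closed-form order parameter
#' [cone_order_parameter()] is the analytic truth per residue. Optionally
#' a random global rigid rotation (plus translation) is applied per frame
#' to exercise the alignment step.
#'
#' @param angles_deg cone semi-angles in degrees, one per residue, each in
#'   (0, 90].
#' @param n_frames frames to generate.
#' @param seed integer seed.
#' @param global_rotation apply a random rigid rotation and translation to
#'   every frame.
#' @param bond_length Calpha-H bond length, Angstrom.
#' @return list with \code{traj} (an \code{xe_trajectory}),
#'   \code{angles_deg}, \code{probe_resids} (residue indices of the
#'   wobbling probes; the remaining residues are rigid anchors with
#'   S2 = 1), and \code{s2_truth}.
#' @export
gen_cone_trajectory <- function(angles_deg, n_frames = 1000, seed = 1,
                                global_rotation = FALSE, bond_length = 1.09) {
  stopifnot(all(angles_deg > 0), all(angles_deg <= 90), n_frames >= 2)
  nr <- length(angles_deg)
  # rigid, non-collinear Calpha scaffold; three rigid anchor residues
  # (static bond vectors, S2 = 1 by construction) keep the alignment
  # well-posed even with a single wobbling residue
  ca <- cbind(10 * seq_len(nr), 5 * (seq_len(nr) %% 2), 3 * (seq_len(nr) %% 3))
  anchors <- rbind(c(-10, 7, 0), c(-20, -5, 9), c(-5, -12, -6))
  atoms <- do.call(rbind, c(
    lapply(seq_len(nr), function(i) data.frame(
      name = c("CA", "HA"), resid = i, resname = "TOY", segcat = "receptor",
      heavy = c(TRUE, FALSE))),
    lapply(1:3, function(i) data.frame(
      name = c("CA", "HA"), resid = nr + i, resname = "ANC",
      segcat = "receptor", heavy = c(TRUE, FALSE)))))
  axes <- t(vapply(seq_len(nr), function(i) .unit(c(0.3 * i, 1, 0.2)),
                   numeric(3)))
  base <- matrix(NA_real_, nrow(atoms), 3)
  for (i in 1:3) {
    base[2 * nr + 2 * i - 1, ] <- anchors[i, ]
    base[2 * nr + 2 * i, ] <- anchors[i, ] + bond_length * .unit(anchors[i, ])
  }
  out <- .with_seed(seed, function() {
    coords <- array(NA_real_, c(nrow(atoms), 3, n_frames))
    for (f in seq_len(n_frames)) {
      xyz <- base
      for (i in seq_len(nr)) {
        u <- .unit_in_cone(axes[i, ], angles_deg[i] * pi / 180)
        xyz[2 * i - 1, ] <- ca[i, ]
        xyz[2 * i, ] <- ca[i, ] + bond_length * u
      }
      if (global_rotation) {
        R <- .random_rotation()
        xyz <- sweep(xyz %*% R, 2, stats::runif(3, -5, 5), "+")
      }
      coords[, , f] <- xyz
    }
    coords
  })
  traj <- trajectory(atoms, out, 0.1 * seq_len(n_frames))
  list(traj = traj, angles_deg = angles_deg, probe_resids = seq_len(nr),
       s2_truth = cone_order_parameter(angles_deg))
}
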