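# ---- rigid-body superposition ---------------------------------------------

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation that superpose the mobile
#' coordinates onto the reference in the least-squares sense, using the
#' SVD-based Kabsch algorithm with the determinant correction that
#' excludes reflections. The transform is computed on the selected atoms
#' and reported together with the post-fit RMSD over that selection.
#' Row-vector convention: \code{transformed = mobile \%*\% rotation +
#' translation}.
#'
#' @param mobile,reference \code{n x 3} coordinate matrices with matching
#'   rows.
#' @param selection optional integer or logical index of rows used to
#'   compute the transform (default: all rows). At least 3 non-collinear
#'   atoms are required.
#' @return An object of class \code{xe_superposition}: \code{rotation}
#'   (3 x 3, det +1), \code{translation} (length-3), \code{rmsd}
#'   (Angstrom, over the selection).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  if (nrow(P) < 3L) stop("need at least 3 selected atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinearity check: a well-posed rotation needs rank >= 2 point clouds
  if (svd(Pc)$d[2] < 1e-8 * max(svd(Pc)$d[1], 1) ||
      svd(Qc)$d[2] < 1e-8 * max(svd(Qc)$d[1], 1))
    stop("degenerate (collinear) atom selection")
  H <- crossprod(Pc, Qc)            # t(Pc) %*% Qc
  sv <- svd(H)
  s <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  tr <- cq - drop(cp %*% R)
  fitted <- sweep(Pc %*% R, 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "xe_superposition")
}

#' Apply a superposition transform to coordinates
#'
#' @param coords \code{n x 3} matrix.
#' @param sup an \code{xe_superposition}.
#' @return transformed \code{n x 3} matrix.
#' @export
apply_superposition <- function(coords, sup) {
  stopifnot(inherits(sup, "xe_superposition"))
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, "+")
}

# ---- order parameters ------------------------------------------------------

#' Generalized order parameter from a set of unit bond vectors
#'
#' Computes the model-free generalized order parameter from the
#' time-averaged second moments of the (aligned) unit bond vector:
#' \deqn{S^2 = \frac{3}{2} \sum_{\alpha,\beta \in \{x,y,z\}}
#'        \langle u_\alpha u_\beta \rangle^2 - \frac{1}{2}.}
#' This second-moment form does not assume averaging over rotation about
#' any axis (unlike a P2 autocorrelation plateau), which matters for large
#' membrane-embedded molecules whose overall rotation is slow on the NMR
#' time scale. A static vector gives 1, an isotropically moving one 0.
#' Values outside [0, 1] by more than 1e-6 (numerically impossible for
#' true unit vectors) trigger a warning before clipping.
#'
#' @param vectors \code{n_frames x 3} matrix of bond vectors; they are
#'   normalized internally, zero-length rows are an error.
#' @return S-squared, in [0, 1].
#' @export
order_parameter <- function(vectors) {
  v <- as.matrix(vectors)
  stopifnot(ncol(v) == 3L)
  if (nrow(v) < 2L) stop("need at least 2 frames")
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-12)) stop("zero-length bond vector")
  u <- v / len
  M <- crossprod(u) / nrow(u)       # <u_a u_b>, 3 x 3
  s2 <- 1.5 * sum(M^2) - 0.5
  if (s2 < -1e-6 || s2 > 1 + 1e-6)
    warning("order parameter outside [0, 1] by more than 1e-6; clipping")
  min(max(s2, 0), 1)
}

#' Closed-form order parameter of the wobble-in-cone model
#'
#' For a unit vector distributed uniformly within a cone of semi-angle
#' theta about a fixed axis, \eqn{S^2 = [\cos\theta (1+\cos\theta)/2]^2}.
#' Used as analytic ground truth for cone-wobble synthetic trajectories.
#'
#' @param theta_deg cone semi-angle in degrees, in (0, 90].
#' @return S-squared.
#' @export
cone_order_parameter <- function(theta_deg) {
  stopifnot(all(theta_deg > 0), all(theta_deg <= 90))
  ct <- cos(theta_deg * pi / 180)
  (ct * (1 + ct) / 2)^2
}

# Calpha / attached-H atom indices per residue; returns data.frame
# (resid, resname, segcat, ica, ih) for residues providing both atoms
.ca_h_index <- function(traj, reconstruct_h = FALSE) {
  at <- traj$atoms
  rows <- list()
  for (seg in c("receptor", "ligand")) {
    ids <- unique(at$resid[at$segcat == seg])
    for (r in ids) {
      sel <- which(at$resid == r & at$segcat == seg)
      ica <- sel[at$name[sel] == "CA"]
      ih <- sel[at$name[sel] %in% c("HA", "HA1")]
      if (length(ica) == 1L && length(ih) >= 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          resid = r, resname = at$resname[ica], segcat = seg,
          ica = ica, ih = ih[1], in1 = NA_integer_, ic = NA_integer_,
          icb = NA_integer_)
      } else if (reconstruct_h && length(ica) == 1L) {
        in1 <- sel[at$name[sel] == "N"]
        ic <- sel[at$name[sel] == "C"]
        icb <- sel[at$name[sel] == "CB"]
        if (length(in1) == 1L && length(ic) == 1L && length(icb) == 1L) {
          rows[[length(rows) + 1L]] <- data.frame(
            resid = r, resname = at$resname[ica], segcat = seg,
            ica = ica, ih = NA_integer_, in1 = in1, ic = ic, icb = icb)
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

.unit <- function(v) v / sqrt(sum(v^2))

# effective Calpha-H direction from tetrahedral backbone geometry
.reconstructed_h_dir <- function(xyz, idx) {
  ca <- xyz[idx$ica, ]
  -.unit(.unit(xyz[idx$in1, ] - ca) + .unit(xyz[idx$ic, ] - ca) +
           .unit(xyz[idx$icb, ] - ca))
}

#' Per-residue Calpha-H order parameters of a trajectory
#'
#' Each frame is first rigid-body aligned to the reference frame on the
#' receptor Calpha atoms, removing overall reorientation of the receptor
#' (the ligand is never part of the alignment selection). The Calpha-H
#' unit vector of every receptor and ligand residue is then accumulated
#' over frames and reduced to S-squared with [order_parameter()]. Residues
#' lacking a Calpha or its hydrogen are skipped with a warning and
#' excluded from the region averages; optionally an effective Calpha-H
#' direction is reconstructed from the N, C and CB positions (tetrahedral
#' geometry) when hydrogens are absent.
#'
#' @param traj an \code{xe_trajectory} whose topology provides \code{CA}
#'   and \code{HA} atoms per residue.
#' @param reference frame index used as alignment reference (default 1).
#' @param align logical; set \code{FALSE} only for pre-aligned input.
#' @param reconstruct_h reconstruct missing hydrogens from backbone
#'   geometry (off by default).
#' @return An object of class \code{xe_order_params}: \code{residues}
#'   (data frame resid/resname/segcat/S2) and \code{averages} (named list
#'   with \code{receptor} and, when ligand residues exist, \code{ligand}).
#' @export
per_residue_order <- function(traj, reference = 1L, align = TRUE,
                              reconstruct_h = FALSE) {
  stopifnot(inherits(traj, "xe_trajectory"))
  idx <- .ca_h_index(traj, reconstruct_h)
  if (is.null(idx)) stop("no residue provides both CA and HA atoms")
  n_named <- length(unique(paste(
    traj$atoms$segcat[traj$atoms$segcat %in% c("receptor", "ligand")],
    traj$atoms$resid[traj$atoms$segcat %in% c("receptor", "ligand")])))
  if (nrow(idx) < n_named)
    warning(n_named - nrow(idx), " residue(s) lack Calpha-H and were skipped")
  ca_sel <- which(traj$atoms$segcat == "receptor" & traj$atoms$name == "CA")
  if (align && length(ca_sel) < 3L)
    stop("alignment needs at least 3 receptor Calpha atoms")
  nf <- n_frames(traj)
  ref_xyz <- frame_coords(traj, reference)
  vecs <- array(NA_real_, c(nf, 3, nrow(idx)))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    if (align) {
      sup <- superpose(xyz, ref_xyz, ca_sel)
      xyz <- apply_superposition(xyz, sup)
    }
    for (k in seq_len(nrow(idx))) {
      vecs[f, , k] <- if (is.na(idx$ih[k]))
        .reconstructed_h_dir(xyz, idx[k, ])
      else
        xyz[idx$ih[k], ] - xyz[idx$ica[k], ]
    }
  }
  s2 <- vapply(seq_len(nrow(idx)), function(k) order_parameter(vecs[, , k]),
               numeric(1))
  residues <- data.frame(resid = idx$resid, resname = idx$resname,
                         segcat = idx$segcat, S2 = s2)
  averages <- list(receptor = mean(s2[idx$segcat == "receptor"]))
  if (any(idx$segcat == "ligand"))
    averages$ligand <- mean(s2[idx$segcat == "ligand"])
  structure(list(residues = residues, averages = averages),
            class = "xe_order_params")
}

#' @export
print.xe_order_params <- function(x, ...) {
  cat(sprintf("order parameters: %d residues; receptor mean %.3f",
              nrow(x$residues), x$averages$receptor))
  if (!is.null(x$averages$ligand))
    cat(sprintf(", ligand mean %.3f", x$averages$ligand))
  cat("\n")
  invisible(x)
}

#' Paired per-residue order-parameter difference
#'
#' Difference trace between two runs (e.g. with and without an attached
#' construct), paired by residue index and segment.
#'
#' @param a,b \code{xe_order_params} objects.
#' @return data frame \code{resid}, \code{segcat}, \code{dS2} (a minus b)
#'   over the residues present in both.
#' @export
order_param_difference <- function(a, b) {
  stopifnot(inherits(a, "xe_order_params"), inherits(b, "xe_order_params"))
  m <- merge(a$residues, b$residues, by = c("resid", "segcat"),
             suffixes = c("_a", "_b"))
  data.frame(resid = m$resid, segcat = m$segcat, dS2 = m$S2_a - m$S2_b)
}

#' Per-frame RMSD after superposition
#'
#' Aligns every frame to the reference coordinates on the given selection
#' and reports the post-fit RMSD over that selection, the standard
#' trajectory-quality trace.
#'
#' @param traj an \code{xe_trajectory}.
#' @param reference frame index or an \code{n x 3} matrix.
#' @param selection atom index used for both fit and RMSD (default:
#'   receptor Calpha atoms).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL) {
  stopifnot(inherits(traj, "xe_trajectory"))
  ref_xyz <- if (is.matrix(reference)) reference
    else frame_coords(traj, reference)
  if (is.null(selection))
    selection <- which(traj$atoms$segcat == "receptor" &
                         traj$atoms$name == "CA")
  vapply(seq_len(n_frames(traj)), function(f)
    superpose(frame_coords(traj, f), ref_xyz, selection)$rmsd, numeric(1))
}

#' Write order-parameter outputs
#'
#' @param op an \code{xe_order_params}.
#' @param csv_path per-residue CSV output path.
#' @param json_path optional path for the JSON region averages.
#' @return invisibly, the paths written.
#' @export
write_order_params <- function(op, csv_path, json_path = NULL) {
  stopifnot(inherits(op, "xe_order_params"))
  utils::write.csv(op$residues, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(op$averages, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
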