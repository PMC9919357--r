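# minimum-image displacement for an orthorhombic box; d is n x 3
.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Residues and molecules in xenon contact within one frame
#'
#' A residue (receptor or ligand) or a lipid molecule is in contact when
#' the minimum distance from the xenon atom to any of its heavy atoms is
#' below the cutoff (default 8.5 Angstrom). Solvent and the cage itself are
#' ignored: the xenon sits inside the cage permanently, and contact
#' statistics quantify what the caged xenon approaches outside. Minimum-
#' image distances are used when the trajectory carries box vectors.
#'
#' @param traj an \code{xe_trajectory} containing exactly one xenon atom.
#' @param frame frame index.
#' @param cutoff contact distance in Angstrom.
#' @return data frame with columns \code{resid}, \code{resname},
#'   \code{segcat}, \code{min_dist}: one row per contacted residue or lipid
#'   molecule (zero rows when nothing is in contact).
#' @export
contacts_in_frame <- function(traj, frame, cutoff = 8.5) {
  stopifnot(inherits(traj, "xe_trajectory"))
  xe <- which(traj$atoms$segcat == "xenon")
  if (length(xe) != 1L)
    stop("trajectory must contain exactly one xenon atom (found ",
         length(xe), ")")
  xyz <- frame_coords(traj, frame)
  keep <- traj$atoms$heavy & traj$atoms$segcat %in% c("receptor", "ligand", "lipid")
  if (!any(keep))
    return(data.frame(resid = integer(0), resname = character(0),
                      segcat = character(0), min_dist = numeric(0)))
  d <- .min_image(sweep(xyz[keep, , drop = FALSE], 2, xyz[xe, ], "-"),
                  if (!is.null(traj$box)) traj$box[frame, ] else NULL)
  dist <- sqrt(rowSums(d^2))
  at <- traj$atoms[keep, ]
  key <- paste(at$segcat, at$resid)
  mind <- tapply(dist, key, min)
  hit <- names(mind)[mind < cutoff]
  if (!length(hit))
    return(data.frame(resid = integer(0), resname = character(0),
                      segcat = character(0), min_dist = numeric(0)))
  first <- at[!duplicated(key), ]
  rownames(first) <- key[!duplicated(key)]
  out <- data.frame(resid = first[hit, "resid"],
                    resname = first[hit, "resname"],
                    segcat = first[hit, "segcat"],
                    min_dist = unname(mind[hit]))
  out[order(out$segcat, out$resid), , drop = FALSE]
}

#' Xenon contact statistics over a trajectory
#'
#' Applies [contacts_in_frame()] to every retained frame (after discarding
#' an initial equilibration period, default 100 ns) and accumulates
#' per-residue contact counts and per-frame environment categories. A
#' residue contacted in k frames contributes k contact instances. The
#' categories partition the retained frames:
#' \describe{
#'   \item{just lipid}{contact with lipid molecules only}
#'   \item{just protein}{contact with receptor and/or ligand residues only}
#'   \item{lipid and protein}{both simultaneously}
#'   \item{no contacts}{neither}
#' }
#'
#' @param traj an \code{xe_trajectory}.
#' @param cutoff contact distance, Angstrom.
#' @param discard_ns equilibration period to discard, ns.
#' @return An object of class \code{xe_contact_table}: \code{residues}
#'   (data frame resid/resname/segcat/count/probability over receptor and
#'   ligand residues, plus lipid molecules), \code{frame_category} (factor
#'   per retained frame), \code{n_frames}, \code{cutoff},
#'   \code{discard_ns}.
#' @export
build_contact_table <- function(traj, cutoff = 8.5, discard_ns = 100) {
  stopifnot(inherits(traj, "xe_trajectory"))
  keep <- which(traj$times > discard_ns)
  if (!length(keep))
    stop("all frames fall within the ", discard_ns, " ns equilibration discard")
  if (is.null(traj$box))
    warning("no box vectors: using plain (non-periodic) distances")
  cats <- c("just lipid", "just protein", "lipid and protein", "no contacts")
  frame_cat <- character(length(keep))
  acc <- new.env(parent = emptyenv())
  for (j in seq_along(keep)) {
    hits <- contacts_in_frame(traj, keep[j], cutoff)
    lip <- any(hits$segcat == "lipid")
    prot <- any(hits$segcat %in% c("receptor", "ligand"))
    frame_cat[j] <- if (lip && prot) "lipid and protein"
      else if (lip) "just lipid"
      else if (prot) "just protein"
      else "no contacts"
    if (nrow(hits)) {
      for (key in paste(hits$segcat, hits$resid, hits$resname, sep = "\r")) {
        acc[[key]] <- (if (is.null(acc[[key]])) 0L else acc[[key]]) + 1L
      }
    }
  }
  keys <- ls(acc)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    residues <- data.frame(resid = as.integer(parts[, 2]),
                           resname = parts[, 3], segcat = parts[, 1],
                           count = vapply(keys, function(k) acc[[k]], integer(1)))
  } else {
    residues <- data.frame(resid = integer(0), resname = character(0),
                           segcat = character(0), count = integer(0))
  }
  residues$probability <- residues$count / length(keep)
  residues <- residues[order(residues$segcat, residues$resid), , drop = FALSE]
  rownames(residues) <- NULL
  structure(list(residues = residues,
                 frame_category = factor(frame_cat, levels = cats),
                 n_frames = length(keep), cutoff = cutoff,
                 discard_ns = discard_ns),
            class = "xe_contact_table")
}

#' @export
print.xe_contact_table <- function(x, ...) {
  cat(sprintf("contact table: %d frames (cutoff %.1f A, %.4g ns discarded)\n",
              x$n_frames, x$cutoff, x$discard_ns))
  print(round(category_probabilities(x), 4))
  invisible(x)
}

#' Per-frame environment category probabilities
#'
#' Fraction of retained frames in each of the four xenon-environment
#' categories. The probabilities sum to one exactly.
#'
#' @param table an \code{xe_contact_table}.
#' @return named numeric vector over the four categories.
#' @export
category_probabilities <- function(table) {
  stopifnot(inherits(table, "xe_contact_table"))
  base::table(table$frame_category) / table$n_frames
}

# ---- site clusters ---------------------------------------------------------

#' Define a contact-site cluster
#'
#' A named group of residues forming one xenon contact site (an
#' extracellular loop segment, the receptor N-terminus, or a part of the
#' bound peptide). Residues may be given as integer indices or as
#' one-letter-code labels like \code{"L40"} (the letter is ignored for
#' matching).
#'
#' @param name cluster name.
#' @param residues residue indices or labels.
#' @param segment segment category the residues belong to
#'   (\code{"receptor"} or \code{"ligand"}).
#' @return An object of class \code{xe_site_cluster}.
#' @export
site_cluster <- function(name, residues, segment = "receptor") {
  if (is.character(residues))
    residues <- as.integer(sub("^[A-Za-z]+", "", residues))
  stopifnot(length(residues) >= 1L, !anyNA(residues))
  segment <- match.arg(segment, c("receptor", "ligand"))
  structure(list(name = name, residues = sort(unique(as.integer(residues))),
                 segment = segment),
            class = "xe_site_cluster")
}

#' Built-in xenon contact-site definitions for the tagged Y2 receptor
#'
#' Residue clusters of the detected xenon contact sites on the Y2
#' receptor and on bound neuropeptide Y: receptor N-terminus (NTER), ECL1,
#' two ECL2 segments, ECL3, and for the ligand-bound state the NPY
#' N-terminus and NPY helix. Shipped as a YAML data file and loaded per
#' state.
#'
#' @param state \code{"apo"} or \code{"npy"} (ligand-bound).
#' @return named list of \code{xe_site_cluster}.
#' @export
default_site_clusters <- function(state = c("apo", "npy")) {
  state <- match.arg(state)
  path <- system.file("extdata", "site_clusters_y2r.yaml", package = "xecest",
                      mustWork = TRUE)
  spec <- yaml::read_yaml(path)[[state]]
  out <- lapply(names(spec), function(nm)
    site_cluster(nm, spec[[nm]]$residues, spec[[nm]]$segment))
  names(out) <- names(spec)
  out
}

#' Contact probability of a site cluster
#'
#' The site-level contact probability is the mean of the per-residue
#' contact probabilities of the three residues most often in contact
#' within the cluster (all residues when the cluster lists exactly three,
#' the usual convention). Ties in the contact counts are broken by
#' ascending residue index. Residues of the cluster never seen in contact
#' contribute probability zero; if fewer than three cluster residues are
#' listed, the mean runs over the available ones with a warning.
#'
#' @param table an \code{xe_contact_table}.
#' @param cluster an \code{xe_site_cluster}.
#' @return probability in [0, 1].
#' @export
site_contact_probability <- function(table, cluster) {
  stopifnot(inherits(table, "xe_contact_table"),
            inherits(cluster, "xe_site_cluster"))
  if (length(cluster$residues) < 3L)
    warning("cluster '", cluster$name, "' lists fewer than 3 residues; ",
            "averaging over the available ones")
  res <- table$residues
  prob <- vapply(cluster$residues, function(r) {
    i <- which(res$resid == r & res$segcat == cluster$segment)
    if (length(i)) res$probability[i[1]] else 0
  }, numeric(1))
  # top 3 by probability, ties broken by residue index (ascending)
  ord <- order(-prob, cluster$residues)
  mean(prob[ord][seq_len(min(3L, length(prob)))])
}

#' Normalize per-residue contact counts for surface projection
#'
#' Divides each residue's contact count by the per-system maximum so the
#' values span [0, 1], the normalization used to color contact counts onto
#' a protein surface one system at a time (values are not comparable
#' across systems).
#'
#' @param table an \code{xe_contact_table}.
#' @return data frame \code{resid}, \code{resname}, \code{segcat},
#'   \code{value} with the maximum-count residue at 1.
#' @export
normalize_counts_for_projection <- function(table) {
  stopifnot(inherits(table, "xe_contact_table"))
  res <- table$residues
  res <- res[res$segcat %in% c("receptor", "ligand"), , drop = FALSE]
  if (!nrow(res) || all(res$count == 0))
    stop("no nonzero contact counts to normalize")
  data.frame(resid = res$resid, resname = res$resname, segcat = res$segcat,
             value = res$count / max(res$count))
}

#' Write contact-analysis outputs
#'
#' Writes the per-residue table as CSV and a JSON summary holding the
#' category probabilities and, when clusters are supplied, the site
#' contact probabilities.
#'
#' @param table an \code{xe_contact_table}.
#' @param dir output directory (created if needed).
#' @param clusters optional named list of \code{xe_site_cluster}.
#' @return invisibly, the paths written.
#' @export
write_contact_results <- function(table, dir, clusters = NULL) {
  stopifnot(inherits(table, "xe_contact_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "contacts.csv")
  utils::write.csv(table$residues, csv, row.names = FALSE)
  summ <- list(n_frames = table$n_frames, cutoff = table$cutoff,
               discard_ns = table$discard_ns,
               categories = as.list(category_probabilities(table)))
  if (!is.null(clusters))
    summ$sites <- lapply(clusters, site_contact_probability, table = table)
  js <- file.path(dir, "contacts_summary.json")
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
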