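test_that("contact boundary behaves as a strict cutoff", {
  tr <- two_atom_traj(c(8.4, 8.6))
  hits1 <- contacts_in_frame(tr, 1)
  expect_equal(hits1$resid, 1L)
  expect_equal(nrow(contacts_in_frame(tr, 2)), 0L)
})

test_that("isolated xenon reports no contacts and missing xenon errors", {
  tr <- two_atom_traj(100)
  expect_equal(nrow(contacts_in_frame(tr, 1)), 0L)
  atoms <- data.frame(name = "C1", resid = 1L, resname = "TOY",
                      segcat = "receptor", heavy = TRUE)
  tr2 <- trajectory(atoms, array(0, c(1, 3, 1)), 0.1)
  expect_error(contacts_in_frame(tr2, 1), "exactly one xenon")
})

test_that("hydrogens and solvent never count as contact partners", {
  atoms <- data.frame(
    name = c("H1", "OW", "XE"), resid = c(1L, 2L, 9L),
    resname = c("TOY", "SOL", "XE"),
    segcat = c("receptor", "solvent", "xenon"),
    heavy = c(FALSE, TRUE, TRUE))
  coords <- array(0, c(3, 3, 1))
  coords[1, 1, 1] <- 2; coords[2, 2, 1] <- 2
  tr <- trajectory(atoms, coords, 0.1)
  expect_equal(nrow(contacts_in_frame(tr, 1)), 0L)
})

test_that("contact sets equal a brute-force all-pairs scan on random toys", {
  set.seed(301)
  segpool <- c("receptor", "receptor", "ligand", "lipid", "cage", "solvent")
  for (rep in 1:3) {
    n_res <- 12
    atoms <- do.call(rbind, lapply(seq_len(n_res), function(r) {
      k <- sample(2:4, 1)
      data.frame(name = paste0("A", seq_len(k)), resid = r,
                 resname = "TOY", segcat = sample(segpool, 1),
                 heavy = sample(c(TRUE, TRUE, FALSE), k, replace = TRUE))
    }))
    atoms <- rbind(atoms, data.frame(name = "XE", resid = 999L,
                                     resname = "XE", segcat = "xenon",
                                     heavy = TRUE))
    nf <- 5
    coords <- array(stats::runif(nrow(atoms) * 3 * nf, 0, 25),
                    c(nrow(atoms), 3, nf))
    tr <- trajectory(atoms, coords, seq_len(nf))
    for (f in seq_len(nf)) {
      got <- contacts_in_frame(tr, f, cutoff = 8.5)
      expect_equal(sort(paste(got$segcat, got$resid)),
                   oracle_contacts(tr, f, 8.5))
    }
  }
})

test_that("periodic minimum-image distances fold contacts across the box", {
  atoms <- data.frame(name = c("C1", "XE"), resid = c(1L, 9L),
                      resname = c("TOY", "XE"),
                      segcat = c("receptor", "xenon"), heavy = TRUE)
  coords <- array(0, c(2, 3, 1))
  coords[1, 1, 1] <- 48  # 48 A apart directly, 2 A through a 50 A box
  tr <- trajectory(atoms, coords, 0.1, box = matrix(c(50, 50, 50), 1))
  expect_equal(contacts_in_frame(tr, 1)$resid, 1L)
  tr2 <- trajectory(atoms, coords, 0.1)
  expect_equal(nrow(contacts_in_frame(tr2, 1)), 0L)
})

test_that("frame categories partition retained frames and sum to one", {
  # alternating: lipid contact, receptor contact, both, none
  atoms <- data.frame(name = c("C1", "C1", "XE"), resid = c(1L, 501L, 9L),
                      resname = c("TOY", "LIP", "XE"),
                      segcat = c("receptor", "lipid", "xenon"), heavy = TRUE)
  nf <- 8
  coords <- array(0, c(3, 3, nf))
  coords[1, 1, ] <- c(2, 100, 2, 100, 2, 100, 2, 100)   # receptor distance
  coords[2, 2, ] <- c(100, 2, 2, 100, 100, 2, 2, 100)   # lipid distance
  tr <- trajectory(atoms, coords, seq_len(nf) * 0.1)
  tab <- suppressWarnings(build_contact_table(tr, discard_ns = 0))
  pr <- category_probabilities(tab)
  expect_equal(sum(pr), 1)
  expect_equal(as.numeric(pr[c("just protein", "just lipid",
                               "lipid and protein", "no contacts")]),
               c(0.25, 0.25, 0.25, 0.25))
  # simultaneous lipid+receptor contact is one frame, never double-counted
  expect_equal(length(tab$frame_category), nf)
})

test_that("equilibration discard removes early frames and can empty the trajectory", {
  tr <- two_atom_traj(rep(2, 10))  # times 0.1 .. 1.0 ns
  tab <- suppressWarnings(build_contact_table(tr, discard_ns = 0.5))
  expect_equal(tab$n_frames, 5L)
  expect_error(suppressWarnings(build_contact_table(tr, discard_ns = 100)),
               "equilibration discard")
})

test_that("raising the cutoff never decreases any contact count", {
  set.seed(17)
  tr <- two_atom_traj(stats::runif(60, 2, 20))
  prev <- 0L
  for (cut in c(4, 6, 8.5, 12, 18)) {
    tab <- suppressWarnings(build_contact_table(tr, cutoff = cut,
                                                discard_ns = 0))
    cnt <- if (nrow(tab$residues)) tab$residues$count else 0L
    expect_gte(cnt, prev)
    prev <- cnt
  }
})

test_that("markov-hopping category frequencies match the stationary distribution", {
  P <- matrix(c(0.8, 0.1, 0.1,
                0.2, 0.7, 0.1,
                0.3, 0.2, 0.5), 3, 3, byrow = TRUE)
  hm <- hop_model(P, list(
    list(name = "lipid", targets = data.frame(segcat = "lipid", resid = 501L)),
    list(name = "protein", targets = data.frame(segcat = "receptor", resid = 40L)),
    list(name = "bulk", targets = NULL)))
  expect_equal(hm$stationary, oracle_stationary(P), tolerance = 1e-8)
  sim <- gen_hop_trajectory(hm, n_frames = 10000, seed = 5)
  tab <- suppressWarnings(build_contact_table(sim$traj, discard_ns = 0))
  pr <- category_probabilities(tab)
  for (cc in names(sim$category_truth)) {
    p0 <- sim$category_truth[[cc]]
    se <- sqrt(p0 * (1 - p0) / 10000) *
      3  # iid bound; chain correlation is mild for these rows
    expect_lt(abs(pr[[cc]] - p0), max(3 * se, 0.02))
  }
})

test_that("site probabilities average the top three residues with index tie-breaks", {
  # residues with controlled Bernoulli contact probabilities: residues move
  # in/out of range of a static xenon independently
  probs <- c(0.6, 0.4, 0.2, 0.1)
  nf <- 2000
  set.seed(23)
  atoms <- rbind(
    do.call(rbind, lapply(1:4, function(r)
      data.frame(name = "C1", resid = r, resname = "TOY",
                 segcat = "receptor", heavy = TRUE))),
    data.frame(name = "XE", resid = 9L, resname = "XE", segcat = "xenon",
               heavy = TRUE))
  coords <- array(0, c(5, 3, nf))
  for (r in 1:4) {
    inrange <- stats::rbinom(nf, 1, probs[r]) == 1
    coords[r, 1, ] <- ifelse(inrange, 3, 300)
    coords[r, 2, ] <- ifelse(inrange, 0, 40 * r)  # keep residues apart
  }
  coords[1:4, 3, ] <- rep(c(1, 2, 3, 4), nf)  # avoid exact overlap
  tr <- trajectory(atoms, coords, seq_len(nf) * 0.1)
  tab <- suppressWarnings(build_contact_table(tr, discard_ns = 0))
  cl <- site_cluster("SITE", 1:4)
  got <- site_contact_probability(tab, cl)
  expect_lt(abs(got - mean(c(0.6, 0.4, 0.2))), 3 * 0.012)
  # never-contacted cluster and always-contacted cluster
  cl2 <- site_cluster("EMPTY", 11:13)
  expect_equal(site_contact_probability(tab, cl2), 0)
  expect_warning(site_contact_probability(tab, site_cluster("SMALL", 1:2)),
                 "fewer than 3")
})

test_that("projection normalization scales counts to the per-system maximum", {
  tab <- structure(list(
    residues = data.frame(resid = 1:3, resname = "TOY", segcat = "receptor",
                          count = c(2L, 4L, 8L),
                          probability = c(0.2, 0.4, 0.8)),
    frame_category = factor(rep("just protein", 10),
                            levels = c("just lipid", "just protein",
                                       "lipid and protein", "no contacts")),
    n_frames = 10L, cutoff = 8.5, discard_ns = 0), class = "xe_contact_table")
  v <- normalize_counts_for_projection(tab)
  expect_equal(v$value, c(0.25, 0.5, 1.0))
  tab2 <- tab
  tab2$residues$count <- tab$residues$count * 2L
  expect_equal(normalize_counts_for_projection(tab2)$value, v$value)
  tab0 <- tab
  tab0$residues$count <- rep(0L, 3)
  expect_error(normalize_counts_for_projection(tab0), "nonzero")
})

test_that("bundled site clusters load and stay disjoint within each state", {
  for (state in c("apo", "npy")) {
    cl <- default_site_clusters(state)
    expect_gte(length(cl), 5 - (state == "npy"))
    keys <- unlist(lapply(cl, function(x) paste(x$segment, x$residues)))
    expect_equal(anyDuplicated(keys), 0L)
    expect_true(all(vapply(cl, function(x) length(x$residues) >= 3, logical(1))))
  }
  apo <- default_site_clusters("apo")
  expect_equal(apo$NTER$residues, c(40L, 41L, 45L))
})

test_that("contact results round-trip to CSV and JSON", {
  dir <- withr::local_tempdir()
  tr <- two_atom_traj(c(2, 2, 100, 2))
  tab <- suppressWarnings(build_contact_table(tr, discard_ns = 0))
  expect_warning(
    write_contact_results(tab, dir,
                          clusters = list(S = site_cluster("S", c(1, 2, 3)))),
    NA)
  back <- jsonlite::read_json(file.path(dir, "contacts_summary.json"),
                              simplifyVector = TRUE)
  expect_equal(back$n_frames, 4)
  expect_equal(back$categories$`just protein`, 0.75)
  expect_equal(back$sites$S, 0.75 / 3)
  csv <- utils::read.csv(file.path(dir, "contacts.csv"))
  expect_equal(csv$count, 3L)
})
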