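#' Synthetic fixture generators
#'
#' Every generator is deterministic given its seed, records the seed,
#' and emits its planted quantities as machine-readable ground truth so
#' recovery tests never re-derive them from generator internals.
#' Fixtures are coarse-grained -- three atoms per residue (CA, CB,
#' backbone O) -- enough to exercise every selector and distance rule
#' without force-field realism.
#'
#' @name synthetic
NULL

res_atoms <- function(resnum, ca, cb, o, chain = "A", resname = "ALA") {
  tibble::tibble(
    name = c("CA", "CB", "O"), resname = resname,
    resnum = as.integer(resnum), chain = chain,
    x = c(ca[1], cb[1], o[1]), y = c(ca[2], cb[2], o[2]),
    z = c(ca[3], cb[3], o[3]))
}

#' Coarse self-avoiding random-walk chain
#'
#' One residue contributes CA, CB and backbone O (glycine, if requested
#' via `resnames`, contributes CA and O only). Consecutive CA-CA
#' distances are 3.8 Angstrom; the walk rejects steps bringing
#' non-consecutive CA atoms within 4.5 Angstrom.
#'
#' @param n_residues number of residues (>= 4)
#' @param seed RNG seed
#' @param chain chain id
#' @param resnames residue names, recycled (default ALA)
#' @return an `xstruct`
#' @export
make_toy_chain <- function(n_residues, seed = 1, chain = "A",
                           resnames = "ALA") {
  if (n_residues < 4) stop("a toy chain needs at least 4 residues")
  set.seed(seed)
  resnames <- rep_len(resnames, n_residues)
  ca <- matrix(0, n_residues, 3)
  dir_prev <- c(1, 0, 0)
  for (r in 2:n_residues) {
    for (try in 1:200) {
      # bias toward extended geometry: perturb the previous direction
      d <- dir_prev + stats::rnorm(3, sd = 0.6)
      d <- d / sqrt(sum(d^2))
      cand <- ca[r - 1, ] + 3.8 * d
      ok <- r == 2 || all(sqrt(colSums((t(ca[1:(r - 2), , drop = FALSE]) -
                                          cand)^2)) >= 4.5)
      if (ok) break
    }
    if (!ok) stop("self-avoiding walk failed at residue ", r)
    ca[r, ] <- cand
    dir_prev <- d
  }
  rows <- lapply(seq_len(n_residues), function(r) {
    perp <- stats::rnorm(3); perp <- perp / sqrt(sum(perp^2))
    at <- res_atoms(r, ca[r, ], ca[r, ] + 1.5 * perp,
                    ca[r, ] + 2.4 * rev(perp) * c(1, -1, 1),
                    chain = chain, resname = resnames[r])
    if (resnames[r] == "GLY") at <- at[at$name != "CB", ]
    at
  })
  at <- dplyr::bind_rows(rows)
  at$serial <- seq_len(nrow(at))
  s <- new_structure(at, label = sprintf("toy chain n=%d seed=%d",
                                         n_residues, seed))
  attr(s, "seed") <- seed
  s
}

place_pair_geometry <- function(pos, pair, contact_dist) {
  # Collinear triads: contact atoms (CA) face each other, CB and O point
  # away along the pair axis, so only the CA-CA pair can fall under 5 A.
  a <- pair[1]; b <- pair[2]
  u <- pos[b, ] - pos[a, ]
  u <- u / sqrt(sum(u^2))
  ca_a <- pos[a, ]
  ca_b <- pos[a, ] + contact_dist * u
  list(a = list(ca = ca_a, cb = ca_a - 1.6 * u, o = ca_a - 3.2 * u),
       b = list(ca = ca_b, cb = ca_b + 1.6 * u, o = ca_b + 3.2 * u),
       u = u)
}

#' Two-state reference ensembles with planted state-specific contacts
#'
#' Residues sit on a 12-Angstrom grid. Each planted contact is a CA-CA
#' pair brought to `close_dist` (default 4.5 A) in the state it is
#' specific for and left at the 12 A grid distance in the other state;
#' common contacts are closed in both states. Residue triads are
#' collinear along the pair axis so no second atom pair of a planted
#' residue pair falls within the 5 A candidate cutoff. Ensemble members
#' are the reference plus isotropic Gaussian coordinate noise.
#'
#' @param n_residues residues on the grid (default 12)
#' @param planted_inactive,planted_active,common lists of residue-index
#'   pairs (sequence separation >= 3, each residue in at most one pair);
#'   defaults plant 2 + 2 + 1 pairs
#' @param ensemble_size members per state (default 10, the number of
#'   independent equilibration runs emulated)
#' @param noise coordinate noise sd, Angstrom (default 0.15)
#' @param close_dist planted contact CA-CA distance (default 4.5)
#' @param seed RNG seed
#' @return list with `inactive_ensemble`, `active_ensemble`,
#'   `inactive_reference`, `active_reference`, and `truth` (tibble of
#'   planted atom pairs with their specificity), plus `seed`
#' @export
make_two_state_references <- function(n_residues = 12,
                                      planted_inactive = list(c(1, 4),
                                                              c(2, 6)),
                                      planted_active = list(c(3, 8),
                                                            c(5, 9)),
                                      common = list(c(7, 10)),
                                      ensemble_size = 10, noise = 0.15,
                                      close_dist = 4.5, seed = 1) {
  set.seed(seed)
  all_pairs <- c(planted_inactive, planted_active, common)
  used <- unlist(all_pairs)
  if (anyDuplicated(used)) {
    stop("infeasible geometry: a residue appears in more than one ",
         "planted pair")
  }
  if (any(used > n_residues)) stop("planted pair outside the chain")
  if (any(vapply(all_pairs, function(p) abs(diff(p)) < 3, logical(1)))) {
    stop("planted pairs need sequence separation >= 3")
  }
  # grid layout
  pos <- t(vapply(seq_len(n_residues) - 1, function(r) {
    12 * c(r %% 4, (r %/% 4) %% 4, r %/% 16)
  }, numeric(3)))

  build_state <- function(closed_pairs) {
    at <- vector("list", n_residues)
    for (pair in all_pairs) {
      closed <- any(vapply(closed_pairs, identical, logical(1), pair))
      g <- place_pair_geometry(pos, pair,
                               if (closed) close_dist else 12)
      at[[pair[1]]] <- res_atoms(pair[1], g$a$ca, g$a$cb, g$a$o)
      at[[pair[2]]] <- res_atoms(pair[2], g$b$ca, g$b$cb, g$b$o)
    }
    for (r in setdiff(seq_len(n_residues), used)) {
      at[[r]] <- res_atoms(r, pos[r, ], pos[r, ] + c(1.6, 0, 0),
                           pos[r, ] + c(0, 1.6, 0))
    }
    tab <- dplyr::bind_rows(at)
    tab$serial <- seq_len(nrow(tab))
    tab
  }
  in_tab <- build_state(c(planted_inactive, common))
  ac_tab <- build_state(c(planted_active, common))
  inactive_reference <- new_structure(in_tab, label = "inactive reference")
  active_reference <- new_structure(ac_tab, label = "active reference")
  jitter <- function(ref, k) {
    xyz <- coords(ref) + matrix(stats::rnorm(3 * nrow(ref$atoms),
                                             sd = noise),
                                ncol = 3)
    s <- set_coords(ref, xyz)
    s$label <- paste(ref$label, "member", k)
    s
  }
  inactive_ensemble <- lapply(seq_len(ensemble_size), function(k) {
    jitter(inactive_reference, k)
  })
  active_ensemble <- lapply(seq_len(ensemble_size), function(k) {
    jitter(active_reference, k)
  })
  truth_rows <- function(pairs, spec) {
    if (length(pairs) == 0) return(NULL)
    tibble::tibble(
      chain_a = "A", resnum_a = vapply(pairs, `[`, numeric(1), 1),
      atom_a = "CA",
      chain_b = "A", resnum_b = vapply(pairs, `[`, numeric(1), 2),
      atom_b = "CA", specificity = spec)
  }
  truth <- dplyr::bind_rows(
    truth_rows(planted_inactive, "inactive"),
    truth_rows(planted_active, "active"),
    truth_rows(common, "common"))
  truth$resnum_a <- as.integer(truth$resnum_a)
  truth$resnum_b <- as.integer(truth$resnum_b)
  list(inactive_ensemble = inactive_ensemble,
       active_ensemble = active_ensemble,
       inactive_reference = inactive_reference,
       active_reference = active_reference,
       truth = truth, seed = seed)
}

#' Metropolis sampler on an analytic CV-space landscape
#'
#' Boltzmann sampling of `(cv1, cv2)` with per-frame ground-truth basin
#' labels (nearest well centre). For equal well widths the occupancy
#' ratio of two wells converges to `exp(delta_F / kB T)`.
#'
#' @param potential a [model_potential()] of the Gaussian-wells family
#' @param n_frames frames returned (after burn-in)
#' @param temperature K
#' @param seed RNG seed
#' @param proposal_sd Metropolis step, CV units
#' @param burn_in discarded initial sweeps
#' @return tibble with `frame`, `cv1`, `cv2`, `basin` (1-based well
#'   index); attributes `seed`, `acceptance`
#' @export
sample_landscape_trajectory <- function(potential, n_frames,
                                        temperature = 300, seed = 1,
                                        proposal_sd = 0.08,
                                        burn_in = 500) {
  set.seed(seed)
  centers <- potential$parameters$centers
  kt <- KB_KCAL * temperature
  x <- centers[which.max(potential$parameters$depths), ]
  u <- model_value(potential, x)
  n_tot <- n_frames + burn_in
  out <- matrix(NA_real_, n_tot, 2)
  acc <- 0
  for (i in seq_len(n_tot)) {
    prop <- x + stats::rnorm(2, sd = proposal_sd)
    up <- model_value(potential, prop)
    if (log(stats::runif(1)) < -(up - u) / kt) {
      x <- prop; u <- up; acc <- acc + 1
    }
    out[i, ] <- x
  }
  out <- out[(burn_in + 1):n_tot, , drop = FALSE]
  d2 <- vapply(seq_len(nrow(centers)), function(k) {
    (out[, 1] - centers[k, 1])^2 + (out[, 2] - centers[k, 2])^2
  }, numeric(nrow(out)))
  basin <- max.col(-d2)
  res <- tibble::tibble(frame = seq_len(n_frames), cv1 = out[, 1],
                        cv2 = out[, 2], basin = basin)
  attr(res, "seed") <- seed
  attr(res, "acceptance") <- acc / n_tot
  res
}

#' Structures populating prescribed CV-space targets
#'
#' Frames interpolate between the inactive and active references (plus
#' coordinate noise) and are accepted when their computed CVs fall
#' within `tol` of the target; per-frame ground-truth labels are
#' recorded. Targets must be reachable along the interpolation path.
#'
#' @param two_state output of [make_two_state_references()]
#' @param contact_set the `contact_set` defining the CVs
#' @param cv_targets list of target `c(cv1, cv2)` points
#' @param frames_per_target frames per target
#' @param noise coordinate noise sd, Angstrom
#' @param tol CV acceptance radius (default 0.05)
#' @param seed RNG seed
#' @param max_attempts bounded rejection sampling per frame
#' @return list with `trajectory` (an `xtraj`), `labels` (target index
#'   per frame), `cv` (tibble of realised CVs), `seed`
#' @export
make_basin_structures <- function(two_state, contact_set, cv_targets,
                                  frames_per_target = 20, noise = 0.05,
                                  tol = 0.05, seed = 1,
                                  max_attempts = 200) {
  set.seed(seed)
  xin <- coords(two_state$inactive_reference)
  xac <- coords(two_state$active_reference)
  template <- two_state$inactive_reference
  lambda_grid <- seq(0, 1, length.out = 201)
  cv_of <- function(xyz) cv_pair(set_coords(template, xyz), contact_set)
  path_cv <- t(vapply(lambda_grid, function(l) {
    cv_of((1 - l) * xin + l * xac)
  }, numeric(2)))
  frames <- list(); labels <- integer(0); cvs <- list()
  for (ti in seq_along(cv_targets)) {
    tgt <- cv_targets[[ti]]
    d <- sqrt((path_cv[, 1] - tgt[1])^2 + (path_cv[, 2] - tgt[2])^2)
    if (min(d) > tol) {
      stop("unreachable CV target (", paste(signif(tgt, 3),
                                            collapse = ", "),
           "): closest approach ", signif(min(d), 3),
           " exceeds tol = ", tol)
    }
    l0 <- lambda_grid[which.min(d)]
    base <- (1 - l0) * xin + l0 * xac
    for (f in seq_len(frames_per_target)) {
      ok <- FALSE
      for (try in seq_len(max_attempts)) {
        xyz <- base + matrix(stats::rnorm(length(base), sd = noise),
                             ncol = 3)
        cv <- cv_of(xyz)
        if (sqrt(sum((cv - tgt)^2)) <= tol) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("sampling failed for target ", ti, " frame ", f,
             " after ", max_attempts, " attempts")
      }
      frames[[length(frames) + 1]] <- xyz
      labels <- c(labels, ti)
      cvs[[length(cvs) + 1]] <- cv
    }
  }
  traj <- new_trajectory(template, frames)
  list(trajectory = traj, labels = labels,
       cv = tibble::tibble(
         time = traj$times,
         cv1 = vapply(cvs, `[[`, numeric(1), "cv1"),
         cv2 = vapply(cvs, `[[`, numeric(1), "cv2"),
         label = labels),
       seed = seed)
}

#' Plant a salt-bridge occupancy into a trajectory
#'
#' Independently per frame, with probability `target_occupancy` the CB
#' atom of residue b is placed `contact_dist` from the CB of residue a
#' (default 3.2 A, i.e. in contact under a 3.5 A criterion), otherwise
#' `far_dist` away (default 7.5 A, i.e. not in contact under 6 A).
#'
#' @param traj an `xtraj`
#' @param residue_a,residue_b residues as `list(chain, resnum)`
#' @param target_occupancy fraction in `[0, 1]`
#' @param seed RNG seed
#' @param contact_dist,far_dist Angstrom
#' @return the modified `xtraj`, with attributes `truth` (logical
#'   per-frame contact vector) and `seed`
#' @export
plant_saltbridge_occupancy <- function(traj, residue_a, residue_b,
                                       target_occupancy, seed = 1,
                                       contact_dist = 3.2,
                                       far_dist = 7.5) {
  stopifnot(target_occupancy >= 0, target_occupancy <= 1)
  set.seed(seed)
  template <- traj$template
  cb_a <- intersect(residue_atom_rows(template, residue_a),
                    which(template$atoms$name == "CB"))
  cb_b <- intersect(residue_atom_rows(template, residue_b),
                    which(template$atoms$name == "CB"))
  if (length(cb_a) != 1 || length(cb_b) != 1) {
    stop("both residues need a CB atom")
  }
  contact <- stats::runif(length(traj$frames)) < target_occupancy
  u <- c(1, 0, 0)
  for (f in seq_along(traj$frames)) {
    xyz <- traj$frames[[f]]
    d <- if (contact[f]) contact_dist else far_dist
    xyz[cb_b, ] <- xyz[cb_a, ] + d * u
    traj$frames[[f]] <- xyz
  }
  attr(traj, "truth") <- contact
  attr(traj, "seed") <- seed
  traj
}

#' Toy crystal with planted inter-molecule contacts
#'
#' A compact asymmetric unit is centred in a cell large enough that no
#' symmetry image approaches within 6 Angstrom. Each planted pair
#' `list(asu_res, neighbor_res, op, shift)` then pulls residue
#' `asu_res` next to the image of residue `neighbor_res` under operator
#' `op` (1-based index into the space-group table) and lattice `shift`,
#' at `contact_dist` (< 4 A); the neighbour residue is first pushed out
#' of the cluster so no other inter-image residue distance drops under
#' 6 A. Infeasible plantings raise a constraint error.
#'
#' @param asu_size residues in the asymmetric unit (default 6)
#' @param spacegroup `"P1"`, `"P21"` or `"P212121"`
#' @param planted_contact_pairs list of `list(asu_res, neighbor_res,
#'   op, shift)` (may be empty)
#' @param cell unit cell (default scaled to the space group)
#' @param contact_dist planted CA-CA contact distance (default 3.5)
#' @param seed RNG seed
#' @return list with `structure` (an `xstruct` with cell + operators),
#'   `truth` (tibble of planted contacts), `seed`
#' @export
make_crystal_fixture <- function(asu_size = 6,
                                 spacegroup = c("P1", "P21", "P212121"),
                                 planted_contact_pairs = list(),
                                 cell = NULL, contact_dist = 3.5,
                                 seed = 1) {
  spacegroup <- match.arg(spacegroup)
  ops <- spacegroup_operators(spacegroup)
  if (is.null(cell)) cell <- c(50, 54, 58, 90, 90, 90)
  set.seed(seed)
  base <- make_toy_chain(asu_size, seed = seed)
  # centre the cluster at the middle of the cell
  f2o <- orthogonalization_matrix(cell)
  centre <- as.numeric(f2o %*% c(0.5, 0.5, 0.5))
  xyz <- coords(base)
  xyz <- sweep(xyz, 2, colMeans(xyz)) +
    matrix(centre, nrow(xyz), 3, byrow = TRUE)
  at <- base$atoms
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  asu <- new_structure(at, cell = cell, sym_ops = ops,
                       label = sprintf("toy crystal %s", spacegroup))
  move_residue <- function(asu, resnum, new_ca) {
    rows <- which(asu$atoms$resnum == resnum)
    old_ca <- as.numeric(asu$atoms[
      rows[asu$atoms$name[rows] == "CA"], c("x", "y", "z")])
    delta <- new_ca - old_ca
    asu$atoms$x[rows] <- asu$atoms$x[rows] + delta[1]
    asu$atoms$y[rows] <- asu$atoms$y[rows] + delta[2]
    asu$atoms$z[rows] <- asu$atoms$z[rows] + delta[3]
    asu
  }
  for (pp in planted_contact_pairs) {
    i <- pp[[1]]; j <- pp[[2]]
    op <- ops[[pp[[3]]]]
    shift <- pp[[4]]
    if (i == j) stop("infeasible planting: identical residues")
    # push the neighbour residue out of the cluster, toward its image
    ca_j <- as.numeric(asu$atoms[
      asu$atoms$resnum == j & asu$atoms$name == "CA", c("x", "y", "z")])
    xyz_now <- coords(asu)
    com <- colMeans(xyz_now)
    img_of <- function(p) {
      o2f <- solve(f2o)
      frac <- as.numeric(o2f %*% p)
      as.numeric(f2o %*% (op$R %*% frac + op$t + shift))
    }
    dir_out <- img_of(ca_j) - ca_j
    nd <- sqrt(sum(dir_out^2))
    if (nd < 1e-6) stop("infeasible planting: image coincides with residue")
    dir_out <- dir_out / nd
    radius <- max(sqrt(rowSums(sweep(xyz_now, 2, com)^2)))
    asu <- move_residue(asu, j, com + (radius + 16) * dir_out)
    # place the asu residue close to the displaced neighbour's image
    ca_j2 <- as.numeric(asu$atoms[
      asu$atoms$resnum == j & asu$atoms$name == "CA", c("x", "y", "z")])
    q <- img_of(ca_j2)
    back <- com - q; back <- back / sqrt(sum(back^2))
    asu <- move_residue(asu, i, q + contact_dist * back)
    # align the residue triad along the approach axis so the planted
    # CA is the closest atom to the image
    rows_i <- which(asu$atoms$resnum == i)
    ca_i <- q + contact_dist * back
    for (rr in rows_i) {
      off <- switch(asu$atoms$name[rr], CA = 0, CB = 1.6, O = 3.2)
      p <- ca_i + off * back
      asu$atoms$x[rr] <- p[1]; asu$atoms$y[rr] <- p[2]
      asu$atoms$z[rr] <- p[3]
    }
  }
  truth <- if (length(planted_contact_pairs) > 0) {
    tibble::tibble(
      asu_resnum = vapply(planted_contact_pairs, function(p)
        as.integer(p[[1]]), integer(1)),
      nb_resnum = vapply(planted_contact_pairs, function(p)
        as.integer(p[[2]]), integer(1)),
      operator = vapply(planted_contact_pairs, function(p)
        as.integer(p[[3]]), integer(1)))
  } else tibble::tibble(asu_resnum = integer(0), nb_resnum = integer(0),
                        operator = integer(0))
  # feasibility: planted residue pairs must be the only ones under 6 A
  cmap <- crystal_contact_map(asu, ops, criterion = 6)
  cm <- merge_contact_map(cmap)
  planted_key <- paste(truth$asu_resnum, truth$nb_resnum)
  extra <- cm[!(paste(cm$asu_resnum, cm$nb_resnum) %in% planted_key |
                  paste(cm$nb_resnum, cm$asu_resnum) %in% planted_key), ]
  if (nrow(extra) > 0) {
    stop("infeasible placement: unplanned inter-image contact between ",
         "residues ", extra$asu_resnum[1], " and ", extra$nb_resnum[1],
         " at ", signif(extra$min_distance[1], 3), " A")
  }
  list(structure = asu, truth = truth, seed = seed)
}

#' Harmonic-fluctuation trajectory with known per-atom RMSF
#'
#' Independent Gaussian displacements per atom and frame with
#' per-coordinate variance `kB T / k`; the analytic RMSF is
#' `sqrt(3 kB T / k)`.
#'
#' @param structure template `xstruct`
#' @param stiffness per-atom spring constant(s), kcal/mol/A^2
#'   (scalar or per-atom vector)
#' @param temperature K
#' @param n_frames frames generated
#' @param seed RNG seed
#' @return an `xtraj` with attributes `truth` (analytic per-atom RMSF)
#'   and `seed`
#' @export
make_harmonic_trajectory <- function(structure, stiffness = 5,
                                     temperature = 300, n_frames = 100,
                                     seed = 1) {
  if (any(stiffness <= 0)) stop("stiffness must be positive")
  set.seed(seed)
  n_at <- nrow(structure$atoms)
  k <- rep_len(stiffness, n_at)
  sdv <- sqrt(KB_KCAL * temperature / k)
  xyz0 <- coords(structure)
  frames <- lapply(seq_len(n_frames), function(f) {
    xyz0 + matrix(stats::rnorm(3 * n_at, sd = rep(sdv, 3)), n_at, 3)
  })
  traj <- new_trajectory(structure, frames)
  attr(traj, "truth") <- sqrt(3) * sdv
  attr(traj, "seed") <- seed
  traj
}

#' Write a fixture with its ground-truth manifest
#'
#' Writes the structure (or trajectory) in PDB format next to a YAML
#' sidecar manifest carrying the seed and every planted quantity, so
#' recovery tests can run closed-loop from files alone.
#'
#' @param fixture a generator result (list with `structure` or an
#'   `xtraj`/`xstruct` carrying `truth`/`seed` attributes)
#' @param dir output directory
#' @param name base file name
#' @return invisibly, the manifest path
#' @export
write_fixture <- function(fixture, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  if (inherits(fixture, "xtraj")) {
    write_trajectory(fixture, file.path(dir, paste0(name, ".pdb")))
    manifest$truth <- attr(fixture, "truth")
    manifest$seed <- attr(fixture, "seed")
  } else if (inherits(fixture, "xstruct")) {
    write_structure(fixture, file.path(dir, paste0(name, ".pdb")))
    manifest$seed <- attr(fixture, "seed")
  } else {
    obj <- if (!is.null(fixture$structure)) fixture$structure else
      fixture$trajectory
    if (inherits(obj, "xtraj")) {
      write_trajectory(obj, file.path(dir, paste0(name, ".pdb")))
    } else {
      write_structure(obj, file.path(dir, paste0(name, ".pdb")))
    }
    manifest$seed <- fixture$seed
    if (!is.null(fixture$truth)) {
      manifest$truth <- as.data.frame(fixture$truth)
    }
  }
  path <- file.path(dir, paste0(name, ".manifest.yaml"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}
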