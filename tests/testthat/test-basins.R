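test_that("frame assignment respects basin membership and the boundary tie rule", {
  pot <- potential_wells(rbind(c(0.3, 0.3), c(0.7, 0.7)),
                         depths = c(6, 4), widths = 0.06)
  fes <- fes_from_potential(pot)
  m <- find_minima(fes)
  b1 <- extract_basin(fes, m[1, ], 2)

  at_min <- tibble::tibble(cv1 = rep(m$cv1[1], 5), cv2 = rep(m$cv2[1], 5))
  expect_equal(assign_frames(at_min, b1), 1:5)

  # a CV exactly on the boundary between cells i and i+1 belongs to the
  # lower-index cell: probe just around a half-spacing boundary
  h <- mean(diff(fes$ax1))
  edge <- tibble::tibble(cv1 = m$cv1[1] + h / 2, cv2 = m$cv2[1])
  inner <- tibble::tibble(cv1 = m$cv1[1] + h / 2 + 1e-9, cv2 = m$cv2[1])
  cell_of <- function(df) {
    idx <- assign_frames(df, b1)
    length(idx) == 1
  }
  expect_true(cell_of(edge))   # tie -> lower cell, still inside the basin
  rect <- basin_rectangle(c(0.6, 0.8), c(0.6, 0.8))
  cvs <- tibble::tibble(cv1 = c(0.7, 0.1), cv2 = c(0.7, 0.1))
  expect_equal(assign_frames(cvs, rect), 1L)
})

test_that("a planted 70/30 basin mixture is recovered within binomial 3-sigma", {
  kt <- KB_KCAL * 300
  pot <- potential_wells(rbind(c(0.3, 0.3), c(0.7, 0.7)),
                         depths = c(6, 6), widths = 0.05)
  fes <- fes_from_potential(pot)
  m <- find_minima(fes)
  b1 <- extract_basin(fes, m[1, ], 5)
  b2 <- extract_basin(fes, m[2, ], 5)
  set.seed(70)
  n <- 1000
  lab <- stats::runif(n) < 0.7
  jit <- function(center, k) center + stats::rnorm(k, sd = 0.015)
  cvs <- tibble::tibble(
    cv1 = ifelse(lab, jit(0.3, n), jit(0.7, n)),
    cv2 = ifelse(lab, jit(0.3, n), jit(0.7, n)))
  n1 <- length(assign_frames(cvs, b1))
  n2 <- length(assign_frames(cvs, b2))
  expect_equal(n1 + n2, n)  # windows wide enough to capture the jitter
  expect_lt(abs(n1 - sum(lab)), 1e-9)
  sigma <- sqrt(n * 0.7 * 0.3)
  expect_lt(abs(n1 - 0.7 * n), 3 * sigma)
})

test_that("gromos clustering matches the brute-force max-neighbour oracle", {
  ch <- make_toy_chain(8, seed = 3)
  ca <- select_atoms(ch, "calpha")

  # all frames identical: one cluster
  same <- lapply(1:6, function(i) coords(ch))
  cl <- gromos_cluster(same, ca, cutoff = 2)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, 1:6)

  # two tight groups far apart: two clusters with exact membership
  grp <- clustered_frames(ch, n_centers = 2, per = 10, spread = 12,
                          noise = 0.2, seed = 5)
  d <- pairwise_rmsd(grp$frames, ca)
  cl2 <- gromos_cluster(grp$frames, ca, cutoff = 2, dist = d)
  expect_length(cl2, 2)
  expect_equal(lapply(cl2, `[[`, "members"),
               lapply(gromos_oracle(d, 2), `[[`, "members"))
  for (c in cl2) {
    expect_length(unique(grp$labels[c$members]), 1)
  }

  # a cutoff above every distance collapses to one cluster
  expect_length(gromos_cluster(grp$frames, ca, cutoff = 1e6, dist = d), 1)

  # partition property + determinism
  all_members <- sort(unlist(lapply(cl2, `[[`, "members")))
  expect_equal(all_members, seq_along(grp$frames))
  cl3 <- gromos_cluster(grp$frames, ca, cutoff = 2, dist = d)
  expect_identical(cl2, cl3)
})

test_that("medoid representatives match exhaustive search and tie to lowest index", {
  ch <- make_toy_chain(8, seed = 4)
  ca <- select_atoms(ch, "calpha")
  grp <- clustered_frames(ch, n_centers = 1, per = 9, noise = 0.8,
                          seed = 8)
  d <- pairwise_rmsd(grp$frames, ca)
  cl <- gromos_cluster(grp$frames, ca, cutoff = 1e6, dist = d)
  med <- representative(cl[[1]], grp$frames, ca, dist = d)
  expect_equal(med, medoid_oracle(cl[[1]]$members, d))

  expect_equal(representative(list(members = 4L), grp$frames, ca), 4L)

  # three frames in a symmetric configuration: equal sums, lowest wins
  sym <- list(coords(ch), coords(ch) + 1, coords(ch) + 2)
  expect_equal(representative(list(members = 1:3), sym, NULL,
                              dist = matrix(1, 3, 3) - diag(3)), 1L)
})

test_that("top-cluster coverage is simple arithmetic over sizes", {
  mk <- function(sizes) {
    start <- cumsum(c(1, utils::head(sizes, -1)))
    structure(Map(function(s, b) list(members = seq(b, b + s - 1),
                                      center = b),
                  sizes, start), class = "gromos_clusters")
  }
  expect_equal(top_clusters_coverage(mk(100), 5), 1)
  expect_equal(top_clusters_coverage(mk(c(50, 30, 10, 5, 3, 2)), 5), 0.98)
  expect_equal(top_clusters_coverage(mk(c(4, 3, 2)), 3), 1)
})

test_that("occupancies count planted contact frames and classify per the 75/60 rules", {
  fx <- two_state_fixture()
  base <- coords(fx$ts$inactive_reference)
  traj <- new_trajectory(fx$ts$inactive_reference,
                         lapply(1:100, function(i) base))
  pairs <- tibble::tibble(chain_a = "A", resnum_a = 1L, chain_b = "A",
                          resnum_b = 8L)
  always <- plant_saltbridge_occupancy(traj, list("A", 1), list("A", 8),
                                       1, seed = 2)
  occ <- contact_occupancy(always, pairs, cutoff = 4,
                           atom_filter = "name CB")
  expect_equal(occ$occupancy, 1)
  expect_equal(occ$class, "strong")

  # planted 80/100 and 65/100: the occupancy equals the planted count
  for (case in list(list(t = 0.80, class = "strong"),
                    list(t = 0.65, class = "weak"),
                    list(t = 0.20, class = "below"))) {
    tr <- plant_saltbridge_occupancy(traj, list("A", 1), list("A", 8),
                                     case$t, seed = 7)
    occ <- contact_occupancy(tr, pairs, cutoff = 4,
                             atom_filter = "name CB")
    expect_equal(occ$occupancy, mean(attr(tr, "truth")))
    sigma <- sqrt(case$t * (1 - case$t) / 100)
    expect_lt(abs(occ$occupancy - case$t), 3 * sigma)
  }

  # frame permutation leaves occupancies unchanged
  tr <- plant_saltbridge_occupancy(traj, list("A", 1), list("A", 8),
                                   0.65, seed = 9)
  perm <- tr; perm$frames <- perm$frames[sample(seq_along(perm$frames))]
  expect_equal(contact_occupancy(perm, pairs, 4, "name CB")$occupancy,
               contact_occupancy(tr, pairs, 4, "name CB")$occupancy)
  expect_error(contact_occupancy(tr, tibble::tibble(
    chain_a = "A", resnum_a = 1L, chain_b = "B", resnum_b = 2L),
    4, "name CB"), "not found")
})

test_that("the occupancy report drops sub-0.60 rows by default", {
  occ <- tibble::tibble(chain_a = "A", resnum_a = c(1L, 2L),
                        chain_b = "A", resnum_b = c(5L, 6L),
                        occupancy = c(0.9, 0.3),
                        class = c("strong", "below"))
  class(occ) <- c("occupancy_table", class(occ))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_occupancy(occ, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 1)
  write_occupancy(occ, f, include_below = TRUE)
  expect_equal(nrow(utils::read.table(f, header = TRUE, sep = "\t")), 2)
})

test_that("distance histograms bin, conserve counts, and report the mean", {
  ch <- make_toy_chain(8, seed = 6)
  base <- coords(ch)
  static <- new_trajectory(ch, lapply(1:20, function(i) base))
  dh <- distance_histogram(static, list("A", 1), list("A", 5),
                           bin_width = 0.2)
  expect_equal(sum(dh$counts > 0), 1)
  expect_equal(sum(dh$counts), 20)
  d0 <- min_residue_distance(ch, list("A", 1), list("A", 5))
  expect_equal(dh$mean, d0, tolerance = 1e-12)

  # planted normal distances: sample mean within 3 sigma of 6.0
  set.seed(15)
  n <- 5000
  dists <- stats::rnorm(n, 6, 0.5)
  frames <- lapply(dists, function(d) {
    xyz <- base
    rows <- which(ch$atoms$resnum == 5)
    ref <- base[which(ch$atoms$resnum == 1 & ch$atoms$name == "CA"), ]
    # put residue 5 exactly d away along x, collapsed to its CA
    for (r in rows) xyz[r, ] <- ref + c(d, 0, 0)
    xyz
  })
  tr <- new_trajectory(ch, frames)
  dh2 <- distance_histogram(tr, list("A", 1), list("A", 5), 0.5,
                            atom_filter = "name CA")
  expect_equal(sum(dh2$counts), n)
  expect_lt(abs(dh2$mean - 6), 3 * 0.5 / sqrt(n))
})
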