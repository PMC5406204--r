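test_that("switching function has the right limits, values and shape", {
  # removable singularity: limit n/m at r = r0
  expect_equal(switching_value(4, 4, weight = 1), 0.6)
  expect_equal(switching_value(4 + 1e-9, 4, weight = 1), 0.6,
               tolerance = 1e-7)
  # asymptotes
  expect_equal(switching_value(1e-9, 4, weight = 3), 3, tolerance = 1e-6)
  expect_lt(switching_value(1e4, 4, weight = 1), 1e-10)
  # closed form at r = 2 r0: (1 - 2^6) / (1 - 2^10) = 63/1023
  expect_equal(switching_value(8, 4, weight = 1), 63 / 1023,
               tolerance = 1e-12)
  # strictly decreasing, bounded in (0, weight]
  r <- seq(0.01, 20, by = 0.01)
  v <- switching_value(r, 4, weight = 3)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v <= 3))
  expect_error(switching_value(1, -1), "r0")
})

test_that("switching derivative matches finite differences through r = r0", {
  fd <- function(r) {
    h <- 1e-7
    (switching_value(r + h, 4, 2) - switching_value(r - h, 4, 2)) / (2 * h)
  }
  for (r in c(2, 3.9, 4 - 1e-8, 4, 4 + 1e-8, 4.1, 8)) {
    expect_equal(wtmetad:::switching_deriv_r(r, 4, 2), fd(r),
                 tolerance = 1e-5)
  }
})

test_that("contact-set selection follows the presence and discard rules", {
  fx <- two_state_fixture()
  got <- fx$cs$contacts[, c("resnum_a", "resnum_b", "specificity")]
  want <- fx$ts$truth[fx$ts$truth$specificity != "common",
                      c("resnum_a", "resnum_b", "specificity")]
  expect_equal(as.data.frame(got[order(got$resnum_a), ]),
               as.data.frame(want[order(want$resnum_a), ]),
               ignore_attr = TRUE)
  # the common pair never appears with either specificity
  common <- fx$ts$truth[fx$ts$truth$specificity == "common", ]
  expect_false(any(fx$cs$contacts$resnum_a %in% common$resnum_a &
                     fx$cs$contacts$resnum_b %in% common$resnum_b))

  # presence below the threshold in both states discards the pair:
  # perturb 6 of 10 inactive members to break one planted contact
  ts <- make_two_state_references(seed = 55)
  broken <- ts
  for (k in 1:6) {
    s <- broken$inactive_ensemble[[k]]
    rows <- which(s$atoms$resnum == 4)
    s$atoms$x[rows] <- s$atoms$x[rows] + 30
    broken$inactive_ensemble[[k]] <- s
  }
  cs2 <- build_contact_set(broken$inactive_ensemble, broken$active_ensemble,
                           broken$inactive_reference,
                           broken$active_reference)
  expect_false(any(cs2$contacts$resnum_a == 1 & cs2$contacts$resnum_b == 4))
})

test_that("contact-set selection is invariant under ensemble member order", {
  ts <- make_two_state_references(seed = 77)
  cs1 <- build_contact_set(ts$inactive_ensemble, ts$active_ensemble,
                           ts$inactive_reference, ts$active_reference)
  cs2 <- build_contact_set(rev(ts$inactive_ensemble),
                           rev(ts$active_ensemble),
                           ts$inactive_reference, ts$active_reference)
  expect_equal(cs1$contacts, cs2$contacts)
})

test_that("salt-bridge pairs join the set with weight 3", {
  ts <- make_two_state_references(seed = 12)
  sb <- tibble::tibble(chain_a = "A", resnum_a = 3L, atom_a = "CB",
                       chain_b = "A", resnum_b = 8L, atom_b = "CB",
                       specificity = "active")
  cs <- build_contact_set(ts$inactive_ensemble, ts$active_ensemble,
                          ts$inactive_reference, ts$active_reference,
                          salt_bridges = sb)
  row <- cs$contacts[cs$contacts$weight == 3, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$atom_a, "CB")
  expect_equal(cs$normalization, sum(cs$contacts$weight^2))
})

test_that("cv_pair vanishes on its reference and obeys the mirror identity", {
  fx <- two_state_fixture()
  cv_in <- cv_pair(fx$ts$inactive_reference, fx$cs)
  cv_ac <- cv_pair(fx$ts$active_reference, fx$cs)
  expect_identical(cv_in[["cv1"]], 0)
  expect_identical(cv_ac[["cv2"]], 0)
  expect_identical(cv_in[["cv2"]], cv_ac[["cv1"]])
})

test_that("cv_pair matches the worked two-contact example", {
  # two unit-weight contacts, r0 = 4, references at r0 (D_ref = 0.6);
  # structure with r1 = r0 and r2 = 2 r0
  at <- function(xs) {
    tibble::tibble(name = "CA", resname = "ALA",
                   resnum = seq_along(xs) * 4L, chain = "A",
                   x = xs, y = 0, z = 0)
  }
  # four CA atoms: contact 1 = atoms 1-2, contact 2 = atoms 3-4
  mk <- function(r1, r2) new_structure(at(c(0, r1, 100, 100 + r2)))
  contacts <- dplyr::bind_rows(
    contact_spec(list("A", 4, "CA"), list("A", 8, "CA"), r0 = 4),
    contact_spec(list("A", 12, "CA"), list("A", 16, "CA"), r0 = 4))
  ref <- mk(4, 4)
  cs <- new_contact_set(contacts, ref, ref)
  cv <- cv_pair(mk(4, 8), cs)
  expected <- (0 + (63 / 1023 - 0.6)^2) / 2
  expect_equal(cv[["cv1"]], expected, tolerance = 1e-12)
  expect_equal(cv[["cv2"]], expected, tolerance = 1e-12)
})

test_that("cv values stay in [0, 1] and match the naive reference on random structures", {
  fx <- two_state_fixture()
  set.seed(202)
  base <- coords(fx$ts$inactive_reference)
  for (k in 1:25) {
    xyz <- base + matrix(stats::rnorm(length(base), sd = stats::runif(1, 0, 3)),
                         ncol = 3)
    s <- set_coords(fx$ts$inactive_reference, xyz)
    cv <- cv_pair(s, fx$cs)
    expect_true(all(cv >= 0 & cv <= 1))
    expect_equal(cv, naive_cv_pair(s, fx$cs), tolerance = 1e-10)
  }
})

test_that("cv_gradient is analytic: zero at the reference, matches finite differences", {
  fx <- two_state_fixture()
  g0 <- cv_gradient(fx$ts$inactive_reference, fx$cs, "cv1")
  expect_equal(max(abs(g0)), 0, tolerance = 1e-12)

  for (which in c("cv1", "cv2")) {
    # evaluate away from the CV's own reference so the gradient is live
    s <- if (which == "cv1") fx$ts$active_reference else
      fx$ts$inactive_reference
    g <- cv_gradient(s, fx$cs, which)
    involved <- which(rowSums(abs(g)) > 0)
    expect_gt(length(involved), 0)
    # atoms in no contact get exactly zero rows
    in_contact <- unique(c(
      wtmetad:::atom_row_lookup(s, fx$cs$contacts$chain_a,
                                fx$cs$contacts$resnum_a,
                                fx$cs$contacts$atom_a),
      wtmetad:::atom_row_lookup(s, fx$cs$contacts$chain_b,
                                fx$cs$contacts$resnum_b,
                                fx$cs$contacts$atom_b)))
    expect_true(all(involved %in% in_contact))
    h <- 1e-5
    for (i in involved[1:2]) {
      for (k in 1:3) {
        xp <- coords(s); xm <- coords(s)
        xp[i, k] <- xp[i, k] + h
        xm[i, k] <- xm[i, k] - h
        fd <- (cv_pair(set_coords(s, xp), fx$cs)[[which]] -
                 cv_pair(set_coords(s, xm), fx$cs)[[which]]) / (2 * h)
        expect_equal(g[i, k], fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("cv_trajectory strides and composes with cv_pair", {
  fx <- two_state_fixture()
  base <- coords(fx$ts$inactive_reference)
  frames <- lapply(1:10, function(k) {
    set.seed(k)
    base + matrix(stats::rnorm(length(base), sd = 0.3), ncol = 3)
  })
  traj <- new_trajectory(fx$ts$inactive_reference, frames)
  recs <- cv_trajectory(traj, fx$cs)
  expect_equal(nrow(recs), 10)
  manual <- cv_pair(set_coords(traj$template, frames[[4]]), fx$cs)
  expect_equal(c(cv1 = recs$cv1[4], cv2 = recs$cv2[4]), manual)
  expect_equal(nrow(cv_trajectory(traj, fx$cs, stride = 2)), 5)

  static <- new_trajectory(fx$ts$inactive_reference,
                           lapply(1:3, function(i) base))
  expect_equal(cv_trajectory(static, fx$cs)$cv1, rep(0, 3))
})

test_that("frames near a reference classify to its side of CV space", {
  fx <- two_state_fixture()
  set.seed(33)
  for (k in 1:10) {
    near_in <- set_coords(fx$ts$inactive_reference,
                          coords(fx$ts$inactive_reference) +
                            matrix(stats::rnorm(
                              3 * nrow(fx$ts$inactive_reference$atoms),
                              sd = 0.2), ncol = 3))
    cv <- cv_pair(near_in, fx$cs)
    expect_lt(cv[["cv1"]], 0.2)
    expect_gt(cv[["cv2"]], cv[["cv1"]])
    near_ac <- set_coords(fx$ts$active_reference,
                          coords(fx$ts$active_reference) +
                            matrix(stats::rnorm(
                              3 * nrow(fx$ts$active_reference$atoms),
                              sd = 0.2), ncol = 3))
    cv2 <- cv_pair(near_ac, fx$cs)
    expect_lt(cv2[["cv2"]], 0.2)
    expect_gt(cv2[["cv1"]], cv2[["cv2"]])
  }
})

test_that("contact-set and COLVAR text formats round-trip", {
  fx <- two_state_fixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_set(fx$cs, f)
  cs2 <- read_contact_set(f, fx$ts$inactive_reference,
                          fx$ts$active_reference)
  expect_equal(fx$cs$contacts, cs2$contacts)
  expect_equal(fx$cs$d_ref_active, cs2$d_ref_active)

  cvdf <- tibble::tibble(time = c(0, 0.5, 1), cv1 = c(0.1, 0.2, 0.3),
                         cv2 = c(0.9, 0.8, 0.7))
  f2 <- withr::local_tempfile(fileext = ".colvar")
  write_colvar(cvdf, f2)
  back <- read_colvar(f2)
  expect_equal(as.data.frame(back), as.data.frame(cvdf),
               tolerance = 1e-9)
  expect_error(cv_pair(make_toy_chain(4), fx$cs), "not found")
})
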