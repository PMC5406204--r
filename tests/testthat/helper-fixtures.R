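# Shared fixtures and independent oracles. Fixtures are built in code,
# memoised per test run.

two_state_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ts <- make_two_state_references(seed = 101)
      cs <- build_contact_set(ts$inactive_ensemble, ts$active_ensemble,
                              ts$inactive_reference, ts$active_reference)
      cache <<- list(ts = ts, cs = cs)
    }
    cache
  }
})

# Independent CV reference: plain double loop over contacts with the
# switching function written out directly (no shared code path with
# cv_pair beyond the structure container).
naive_cv_pair <- function(structure, contact_set) {
  cs <- contact_set
  at <- structure$atoms
  key <- paste(at$chain, at$resnum, at$name)
  d <- numeric(nrow(cs$contacts))
  for (k in seq_len(nrow(cs$contacts))) {
    ro <- cs$contacts[k, ]
    ia <- which(key == paste(ro$chain_a, ro$resnum_a, ro$atom_a))
    ib <- which(key == paste(ro$chain_b, ro$resnum_b, ro$atom_b))
    r <- sqrt((at$x[ia] - at$x[ib])^2 + (at$y[ia] - at$y[ib])^2 +
                (at$z[ia] - at$z[ib])^2)
    u <- r / ro$r0
    d[k] <- if (abs(u - 1) < 1e-9) ro$weight * 0.6 else
      ro$weight * (1 - u^6) / (1 - u^10)
  }
  c(cv1 = sum((d - cs$d_ref_inactive)^2) / cs$normalization,
    cv2 = sum((d - cs$d_ref_active)^2) / cs$normalization)
}

# Quaternion-parameterised superposition oracle: numerical minimisation
# of the RMSD over unit quaternions with multiple restarts.
quaternion_rmsd_oracle <- function(mobile, reference) {
  mc <- colMeans(mobile); rc <- colMeans(reference)
  M <- sweep(mobile, 2, mc); R <- sweep(reference, 2, rc)
  rot_of <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
      3, 3, byrow = TRUE)
  }
  obj <- function(q) {
    rot <- rot_of(q)
    sqrt(mean(rowSums((M %*% t(rot) - R)^2)))
  }
  best <- Inf
  set.seed(7)
  for (rs in 1:24) {
    q0 <- stats::rnorm(4)
    o <- stats::optim(q0, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
    best <- min(best, o$value)
  }
  best
}

# Brute-force re-statement of the iterative max-neighbour clustering
# rule, written directly against the distance matrix.
gromos_oracle <- function(dist, cutoff) {
  n <- nrow(dist)
  pool <- seq_len(n)
  clusters <- list()
  while (length(pool) > 0) {
    best <- -1L; seed <- NA_integer_
    for (i in pool) {
      cnt <- sum(dist[i, pool] <= cutoff)
      if (cnt > best) { best <- cnt; seed <- i }
    }
    members <- pool[dist[seed, pool] <= cutoff]
    clusters[[length(clusters) + 1]] <- list(members = sort(members),
                                             center = seed)
    pool <- setdiff(pool, members)
  }
  clusters
}

medoid_oracle <- function(members, dist) {
  best <- Inf; who <- NA_integer_
  for (m in members) {
    s <- sum(dist[m, members])
    if (s < best - 1e-12) { best <- s; who <- m }
  }
  who
}

# A jittered-cluster frame set for clustering tests: `centers` distinct
# conformations, `per` noisy copies of each.
clustered_frames <- function(template, n_centers = 3, per = 20,
                             spread = 15, noise = 0.3, seed = 1) {
  set.seed(seed)
  xyz0 <- coords(template)
  centers <- lapply(seq_len(n_centers), function(k) {
    xyz0 + matrix(rep(c(spread * k, 0, 0), each = nrow(xyz0)), ncol = 3) +
      matrix(stats::rnorm(length(xyz0), sd = 2), ncol = 3)
  })
  frames <- list(); labels <- integer(0)
  for (k in seq_len(n_centers)) {
    for (f in seq_len(per)) {
      frames[[length(frames) + 1]] <-
        centers[[k]] + matrix(stats::rnorm(length(xyz0), sd = noise),
                              ncol = 3)
      labels <- c(labels, k)
    }
  }
  list(frames = frames, labels = labels)
}

# Random rigid transform applied to a coordinate matrix.
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  xyz %*% t(rot) + matrix(stats::rnorm(3, sd = 10), nrow(xyz), 3,
                          byrow = TRUE)
}
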