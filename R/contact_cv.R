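#' Sigmoidal degree of contact formation
#'
#' `D(r) = W * (1 - (r/r0)^n) / (1 - (r/r0)^m)` with `n < m`. The
#' removable singularity at \code{r = r0} is handled by a first-order series
#' around the analytic limit `n/m`, avoiding catastrophic cancellation.
#' The function is continuous and strictly decreasing for \code{r > 0},
#' tending to `W` as \code{r -> 0} and to `0` as \code{r -> Inf}.
#'
#' @param r distance, Angstrom (vectorised)
#' @param r0 reference contact distance, Angstrom
#' @param weight contact weight W (1 regular, 3 salt bridge)
#' @param n,m switching exponents, `n < m` (defaults 6 and 10)
#' @return degree of contact formation, in `(0, weight]` for finite r
#' @export
switching_value <- function(r, r0, weight = 1, n = 6L, m = 10L) {
  if (any(r0 <= 0)) stop("r0 must be positive")
  if (any(r < 0)) stop("r must be non-negative")
  if (any(n >= m)) stop("switching exponents require n < m")
  u <- r / r0
  near <- abs(u - 1) < 1e-6
  val <- numeric(length(u))
  if (any(!near)) {
    uu <- u[!near]
    val[!near] <- (1 - uu^n) / (1 - uu^m)
  }
  if (any(near)) {
    e <- u[near] - 1
    val[near] <- (n / m) * (1 + (n - m) / 2 * e)
  }
  weight * val
}

switching_deriv_r <- function(r, r0, weight = 1, n = 6L, m = 10L) {
  # d D / d r, with the same series treatment near r = r0
  u <- r / r0
  near <- abs(u - 1) < 1e-6
  d <- numeric(length(u))
  if (any(!near)) {
    uu <- u[!near]
    den <- (1 - uu^m)
    d[!near] <- (-n * uu^(n - 1) * den + m * uu^(m - 1) * (1 - uu^n)) / den^2
  }
  if (any(near)) {
    # f(u) ~ n/m (1 + (n-m)/2 (u-1) + ...) => f'(1) = n (n-m) / (2 m)
    d[near] <- n * (n - m) / (2 * m)
  }
  weight * d / r0
}

#' Create a single contact specification
#'
#' @param atom_a,atom_b atom identities as `list(chain, resnum, name)`
#' @param r0 contact distance in the reference conformation the contact
#'   is specific for, Angstrom
#' @param weight 1 for regular contacts, 3 for salt bridges
#' @param specificity `"inactive"` or `"active"`
#' @return one-row tibble
#' @export
contact_spec <- function(atom_a, atom_b, r0, weight = 1,
                         specificity = c("inactive", "active")) {
  specificity <- match.arg(specificity)
  if (r0 <= 0) stop("r0 must be positive")
  if (identical(atom_a, atom_b)) stop("contact atoms must differ")
  tibble::tibble(
    chain_a = atom_a[[1]], resnum_a = as.integer(atom_a[[2]]),
    atom_a = atom_a[[3]],
    chain_b = atom_b[[1]], resnum_b = as.integer(atom_b[[2]]),
    atom_b = atom_b[[3]],
    r0 = r0, weight = weight, specificity = specificity)
}

atom_row_lookup <- function(structure, chain, resnum, name) {
  a <- structure$atoms
  idx <- match(paste(chain, resnum, name),
               paste(a$chain, a$resnum, a$name))
  if (anyNA(idx)) {
    k <- which(is.na(idx))[1]
    stop("contact atom not found in structure: ",
         chain[k], ":", resnum[k], ":", name[k])
  }
  idx
}

contact_distances <- function(structure, contacts) {
  xyz <- coords(structure)
  ia <- atom_row_lookup(structure, contacts$chain_a, contacts$resnum_a,
                        contacts$atom_a)
  ib <- atom_row_lookup(structure, contacts$chain_b, contacts$resnum_b,
                        contacts$atom_b)
  sqrt(rowSums((xyz[ia, , drop = FALSE] - xyz[ib, , drop = FALSE])^2))
}

#' Assemble a contact set object
#'
#' Computes and stores the per-contact switching values on the two
#' reference structures (`d_ref_inactive`, `d_ref_active`) and the
#' normalization `N = sum(W^2)`, which bounds both collective variables
#' in `[0, 1]`.
#'
#' @param contacts tibble of contact rows (see [contact_spec()])
#' @param inactive_reference,active_reference `xstruct` reference
#'   conformations
#' @param n,m switching exponents
#' @return object of class `contact_set`
#' @export
new_contact_set <- function(contacts, inactive_reference, active_reference,
                            n = 6L, m = 10L) {
  if (nrow(contacts) == 0) stop("empty contact set")
  if (n >= m) stop("switching exponents require n < m")
  d_in <- switching_value(contact_distances(inactive_reference, contacts),
                          contacts$r0, contacts$weight, n, m)
  d_ac <- switching_value(contact_distances(active_reference, contacts),
                          contacts$r0, contacts$weight, n, m)
  structure(list(
    contacts = contacts, n_exponent = as.integer(n),
    m_exponent = as.integer(m),
    normalization = sum(contacts$weight^2),
    d_ref_inactive = d_in, d_ref_active = d_ac), class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat("<contact set>", nrow(x$contacts), "contacts (",
      sum(x$contacts$specificity == "inactive"), "inactive-specific,",
      sum(x$contacts$specificity == "active"), "active-specific;",
      sum(x$contacts$weight != 1), "salt bridge ),",
      "N =", x$normalization, "\n")
  invisible(x)
}

cv_eligible_indices <- function(structure) {
  a <- structure$atoms
  gly_cb <- a$name == "CB" & a$resname == "GLY"
  which(a$name %in% c("CA", "CB", "O") & !gly_cb)
}

pair_distance_table <- function(structure, idx) {
  xyz <- coords(structure)[idx, , drop = FALSE]
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  sqrt(pmax(d2, 0))
}

#' Build the contact set from two reference ensembles
#'
#' Candidate pairs are contact-map-eligible atoms (C-alpha, C-beta,
#' backbone O; glycine contributes CA and O only) within `cutoff` in
#' either reference structure, with sequence separation of at least 3
#' residues on the same chain. A pair is inactive-specific when it is
#' within the cutoff in at least `min_presence` inactive-ensemble
#' members and in fewer than `min_presence` active-ensemble members
#' (mirror for active-specific); pairs meeting the presence rule in both
#' ensembles are common and discarded. `r0` is measured on the single
#' reference structure of the pair's specificity state. Supplied
#' salt-bridge pairs are appended with weight 3.
#'
#' @param inactive_ensemble,active_ensemble lists of `xstruct`
#'   (equilibrated members; default study condition 10 each)
#' @param inactive_reference,active_reference `xstruct` references
#' @param cutoff candidate cutoff, Angstrom (default 5)
#' @param min_presence presence count threshold (default 5 of 10)
#' @param salt_bridges optional tibble of salt-bridge contact rows
#'   (columns as [contact_spec()] without `r0`/`weight`; `r0` measured on
#'   the specificity reference, `weight` forced to 3)
#' @param min_sequence_separation minimum residue separation for
#'   candidate pairs on the same chain (default 3)
#' @return a `contact_set`
#' @export
build_contact_set <- function(inactive_ensemble, active_ensemble,
                              inactive_reference, active_reference,
                              cutoff = 5, min_presence = 5,
                              salt_bridges = NULL,
                              min_sequence_separation = 3) {
  key_of <- function(s) paste(s$atoms$chain, s$atoms$resnum, s$atoms$name)
  ref_key <- key_of(inactive_reference)
  for (s in c(inactive_ensemble, active_ensemble,
              list(active_reference))) {
    if (!identical(key_of(s), ref_key)) {
      stop("atom identity mismatch between ensembles and references")
    }
  }
  idx <- cv_eligible_indices(inactive_reference)
  a <- inactive_reference$atoms[idx, ]
  n_el <- length(idx)
  same_chain <- outer(a$chain, a$chain, "==")
  sep <- abs(outer(a$resnum, a$resnum, "-"))
  eligible_pair <- upper.tri(matrix(TRUE, n_el, n_el)) &
    (!same_chain | sep >= min_sequence_separation)

  d_in_ref <- pair_distance_table(inactive_reference, idx)
  d_ac_ref <- pair_distance_table(active_reference, idx)
  candidate <- eligible_pair & (d_in_ref < cutoff | d_ac_ref < cutoff)
  if (!any(candidate)) stop("empty contact set: no candidate pairs")

  count_within <- function(ensemble) {
    cnt <- matrix(0L, n_el, n_el)
    for (s in ensemble) cnt <- cnt + (pair_distance_table(s, idx) < cutoff)
    cnt
  }
  cnt_in <- count_within(inactive_ensemble)
  cnt_ac <- count_within(active_ensemble)
  in_specific <- candidate & cnt_in >= min_presence & cnt_ac < min_presence
  ac_specific <- candidate & cnt_ac >= min_presence & cnt_in < min_presence

  pair_rows <- function(mask, spec, d_ref) {
    w <- which(mask, arr.ind = TRUE)
    if (nrow(w) == 0) return(NULL)
    tibble::tibble(
      chain_a = a$chain[w[, 1]], resnum_a = a$resnum[w[, 1]],
      atom_a = a$name[w[, 1]],
      chain_b = a$chain[w[, 2]], resnum_b = a$resnum[w[, 2]],
      atom_b = a$name[w[, 2]],
      r0 = d_ref[w], weight = 1, specificity = spec)
  }
  rows <- dplyr::bind_rows(
    pair_rows(in_specific, "inactive", d_in_ref),
    pair_rows(ac_specific, "active", d_ac_ref))
  if (!is.null(salt_bridges) && nrow(salt_bridges) > 0) {
    sb <- tibble::as_tibble(salt_bridges)
    sb$weight <- 3
    r0 <- numeric(nrow(sb))
    for (i in seq_len(nrow(sb))) {
      ref <- if (sb$specificity[i] == "inactive") inactive_reference
             else active_reference
      r0[i] <- contact_distances(ref, sb[i, ])
    }
    sb$r0 <- r0
    cols <- c("chain_a", "resnum_a", "atom_a", "chain_b", "resnum_b",
              "atom_b", "r0", "weight", "specificity")
    rows <- dplyr::bind_rows(rows, sb[, cols])
  }
  if (is.null(rows) || nrow(rows) == 0) {
    stop("empty contact set: no state-specific pairs found")
  }
  rows <- dplyr::arrange(rows, .data$chain_a, .data$resnum_a, .data$atom_a,
                         .data$chain_b, .data$resnum_b, .data$atom_b)
  new_contact_set(rows, inactive_reference, active_reference)
}

#' Evaluate the two contact-map collective variables
#'
#' `CV(R) = (1/N) * sum over contacts of (D(R) - D(R_ref))^2`, with
#' `R_ref` the inactive reference for CV1 and the active reference for
#' CV2; both sums run over the full contact set. With `N = sum(W^2)`
#' both CVs lie in `[0, 1]`, vanish on their own reference, and satisfy
#' the mirror identity `cv1(active ref) = cv2(inactive ref)`.
#'
#' @param structure an `xstruct` containing every contact atom
#' @param contact_set a `contact_set`
#' @return named numeric `c(cv1 = ..., cv2 = ...)`
#' @export
cv_pair <- function(structure, contact_set) {
  cs <- contact_set
  d <- switching_value(contact_distances(structure, cs$contacts),
                       cs$contacts$r0, cs$contacts$weight,
                       cs$n_exponent, cs$m_exponent)
  c(cv1 = sum((d - cs$d_ref_inactive)^2) / cs$normalization,
    cv2 = sum((d - cs$d_ref_active)^2) / cs$normalization)
}

#' Cartesian gradient of a contact-map collective variable
#'
#' Analytic chain-rule gradient with respect to every atom's
#' coordinates; atoms participating in no contact get a zero row.
#'
#' @param structure an `xstruct`
#' @param contact_set a `contact_set`
#' @param which `"cv1"` (inactive reference) or `"cv2"` (active)
#' @return n_atoms x 3 matrix, CV units per Angstrom
#' @export
cv_gradient <- function(structure, contact_set, which = c("cv1", "cv2")) {
  which <- match.arg(which)
  cs <- contact_set
  xyz <- coords(structure)
  ia <- atom_row_lookup(structure, cs$contacts$chain_a,
                        cs$contacts$resnum_a, cs$contacts$atom_a)
  ib <- atom_row_lookup(structure, cs$contacts$chain_b,
                        cs$contacts$resnum_b, cs$contacts$atom_b)
  dvec <- xyz[ia, , drop = FALSE] - xyz[ib, , drop = FALSE]
  r <- sqrt(rowSums(dvec^2))
  d <- switching_value(r, cs$contacts$r0, cs$contacts$weight,
                       cs$n_exponent, cs$m_exponent)
  dref <- if (which == "cv1") cs$d_ref_inactive else cs$d_ref_active
  dd_dr <- switching_deriv_r(r, cs$contacts$r0, cs$contacts$weight,
                             cs$n_exponent, cs$m_exponent)
  pref <- 2 * (d - dref) * dd_dr / cs$normalization / r
  grad <- matrix(0, nrow(xyz), 3)
  contrib <- dvec * pref
  for (k in seq_along(ia)) {
    grad[ia[k], ] <- grad[ia[k], ] + contrib[k, ]
    grad[ib[k], ] <- grad[ib[k], ] - contrib[k, ]
  }
  grad
}

#' Evaluate the CVs along a trajectory
#'
#' @param traj an `xtraj` whose template contains every contact atom
#' @param contact_set a `contact_set`
#' @param stride keep every `stride`-th frame (default 1)
#' @return tibble with columns `time`, `cv1`, `cv2` (one CV record per
#'   retained frame)
#' @export
cv_trajectory <- function(traj, contact_set, stride = 1L) {
  sel <- seq(1L, length(traj$frames), by = stride)
  recs <- purrr::map(sel, function(i) {
    cv_pair(set_coords(traj$template, traj$frames[[i]]), contact_set)
  })
  tibble::tibble(time = traj$times[sel],
                 cv1 = vapply(recs, `[[`, numeric(1), "cv1"),
                 cv2 = vapply(recs, `[[`, numeric(1), "cv2"))
}

# ---- text interchange -----------------------------------------------------

#' Write a contact set as delimited text
#'
#' One contact per row: chain_a resnum_a atom_a chain_b resnum_b atom_b
#' r0 weight specificity, with a header row. Round-trips bit-exactly.
#'
#' @param contact_set a `contact_set`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_contact_set <- function(contact_set, path) {
  df <- contact_set$contacts
  df$r0 <- sprintf("%.17g", df$r0)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a contact-set table written by [write_contact_set()]
#'
#' @param path input file
#' @param inactive_reference,active_reference the reference structures
#'   against which switching values are (re)evaluated
#' @return a `contact_set`
#' @export
read_contact_set <- function(path, inactive_reference, active_reference) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(
                            chain_a = "character", resnum_a = "integer",
                            atom_a = "character", chain_b = "character",
                            resnum_b = "integer", atom_b = "character",
                            r0 = "numeric", weight = "numeric",
                            specificity = "character"))
  new_contact_set(tibble::as_tibble(df), inactive_reference,
                  active_reference)
}

#' Write a COLVAR-style CV time series
#'
#' Header `#! FIELDS time cv1 cv2`, then whitespace-delimited rows.
#'
#' @param cv_series tibble with `time`, `cv1`, `cv2`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_colvar <- function(cv_series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv1 cv2", con)
  writeLines(sprintf("%.6f %.10g %.10g", cv_series$time,
                     cv_series$cv1, cv_series$cv2), con)
  invisible(path)
}

#' Read a COLVAR-style CV time series
#' @param path input file
#' @return tibble with `time`, `cv1`, `cv2`
#' @export
read_colvar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1]
  if (!grepl("^#! FIELDS", hdr)) stop("missing COLVAR FIELDS header")
  fields <- strsplit(trimws(sub("^#! FIELDS", "", hdr)), "\\s+")[[1]]
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, col.names = fields)
  tibble::as_tibble(df)
}
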