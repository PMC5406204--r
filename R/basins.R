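#' Assign trajectory frames to a free-energy basin
#'
#' A frame belongs to the basin when its `(cv1, cv2)` record falls in a
#' member cell (grid cells are centred on grid points; a value exactly
#' on a cell boundary goes to the lower-index cell) or inside the
#' rectangle. No reweighting is applied: biased frames are taken as
#' they come, matching the published procedure.
#'
#' @param cv_series tibble with `cv1`, `cv2` (one row per frame)
#' @param basin a `fes_basin` from [extract_basin()] or a
#'   [basin_rectangle()]
#' @return integer frame indices
#' @export
assign_frames <- function(cv_series, basin) {
  if (inherits(basin, "cv_rectangle")) {
    keep <- cv_series$cv1 >= basin$cv1_range[1] &
      cv_series$cv1 <= basin$cv1_range[2] &
      cv_series$cv2 >= basin$cv2_range[1] &
      cv_series$cv2 <= basin$cv2_range[2]
    return(which(keep))
  }
  stopifnot(inherits(basin, "fes_basin"))
  ax1 <- basin$ax1; ax2 <- basin$ax2
  h1 <- mean(diff(ax1)); h2 <- mean(diff(ax2))
  cell_of <- function(v, ax, h) {
    # boundary tie goes to the lower-index cell: strict comparison
    vapply(v, function(x) 1L + sum(ax + h / 2 < x), integer(1))
  }
  i <- cell_of(cv_series$cv1, ax1, h1)
  j <- cell_of(cv_series$cv2, ax2, h2)
  member <- matrix(FALSE, length(ax1), length(ax2))
  member[basin$cells] <- TRUE
  inside <- i >= 1 & i <= length(ax1) & j >= 1 & j <= length(ax2)
  out <- logical(nrow(cv_series))
  out[inside] <- member[cbind(i[inside], j[inside])]
  which(out)
}

frames_of <- function(frames) {
  if (inherits(frames, "xtraj")) frames$frames else frames
}

#' Pairwise C-alpha RMSD matrix with per-pair superposition
#'
#' Every pair of frames is superposed independently on `fit_indices`
#' (the behaviour of the clustering tool the procedure follows), and the
#' RMSD over the same indices is recorded.
#'
#' @param frames list of coordinate matrices or an `xtraj`
#' @param fit_indices atom indices (e.g. the C-alpha set)
#' @return symmetric matrix of RMSDs, Angstrom
#' @export
pairwise_rmsd <- function(frames, fit_indices = NULL) {
  fr <- frames_of(frames)
  n <- length(fr)
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- superpose(fr[[i]], fr[[j]], fit_indices)$rmsd
    }
  }
  D
}

#' gromos conformational clustering
#'
#' Iteratively finds the frame with the most neighbours within `cutoff`
#' (pairwise-fit C-alpha RMSD as the metric), forms a cluster from it
#' and its neighbours, removes them, and repeats until no frame
#' remains. Neighbour-count ties break to the lowest frame index. The
#' output partitions the input frames and is deterministic given frame
#' order.
#'
#' @param frames list of coordinate matrices or an `xtraj`
#' @param fit_indices atom indices used for the RMSD metric (e.g. the
#'   C-alpha set; default: all atoms)
#' @param cutoff RMSD cutoff, Angstrom (default 2)
#' @param dist optional precomputed distance matrix (overrides frames)
#' @return object of class `gromos_clusters`: list of clusters, each
#'   with `members` (frame indices) and `center` (the max-neighbour
#'   seed frame)
#' @export
gromos_cluster <- function(frames, fit_indices = NULL, cutoff = 2,
                           dist = NULL) {
  if (is.null(dist)) dist <- pairwise_rmsd(frames, fit_indices)
  n <- nrow(dist)
  if (n < 1) stop("at least one frame required")
  adj <- dist <= cutoff
  remaining <- rep(TRUE, n)
  clusters <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    counts <- rowSums(adj[idx, idx, drop = FALSE])
    seed_local <- which.max(counts)  # which.max takes the first maximum
    seed <- idx[seed_local]
    members <- idx[adj[seed, idx]]
    clusters[[length(clusters) + 1]] <- list(
      members = sort(members), center = seed)
    remaining[members] <- FALSE
  }
  structure(clusters, class = "gromos_clusters", cutoff = cutoff)
}

#' @export
print.gromos_clusters <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$members), integer(1))
  cat("<gromos clusters>", length(x), "clusters, sizes:",
      paste(sort(sizes, decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Medoid representative of a cluster
#'
#' The member with the smallest summed pairwise RMSD to all other
#' members; ties break to the lowest frame index.
#'
#' @param cluster one element of a `gromos_clusters` (list with
#'   `members`), or an integer vector of frame indices
#' @param frames list of coordinate matrices or `xtraj`
#' @param fit_indices atom indices for the RMSD metric
#' @param dist optional precomputed full distance matrix
#' @return frame index of the medoid
#' @export
representative <- function(cluster, frames, fit_indices = NULL,
                           dist = NULL) {
  members <- if (is.list(cluster)) cluster$members else as.integer(cluster)
  if (length(members) == 0) stop("empty cluster")
  if (length(members) == 1) return(members)
  if (is.null(dist)) {
    fr <- frames_of(frames)[members]
    sub <- pairwise_rmsd(fr, fit_indices)
  } else {
    sub <- dist[members, members, drop = FALSE]
  }
  sums <- rowSums(sub)
  members[which.min(sums)]  # first minimum = lowest index on ties
}

#' Fraction of frames inside the k most populated clusters
#'
#' @param clusters a `gromos_clusters`
#' @param k number of top clusters (default 5)
#' @return fraction in `[0, 1]`
#' @export
top_clusters_coverage <- function(clusters, k = 5) {
  stopifnot(k >= 1)
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  total <- sum(sizes)
  sum(sort(sizes, decreasing = TRUE)[seq_len(min(k, length(sizes)))]) / total
}

#' Interaction occupancy over a set of frames
#'
#' For each residue pair, the fraction of frames in which the minimal
#' filtered inter-residue distance is at or below `cutoff`. Occupancies
#' above 0.75 are classed `strong`, 0.60-0.75 `weak`, the rest `below`
#' (excluded from the default written report).
#'
#' @param traj an `xtraj` (or list of frames plus `template`)
#' @param pairs tibble with `chain_a`, `resnum_a`, `chain_b`, `resnum_b`
#' @param cutoff interaction distance, Angstrom (default 4)
#' @param atom_filter selector restricting the atoms considered;
#'   default: side-chain nitrogen/oxygen atoms (salt-bridge criterion)
#' @param template template structure when `traj` is a bare frame list
#' @return tibble of class `occupancy_table` with `occupancy` and
#'   `class` columns
#' @export
contact_occupancy <- function(traj, pairs, cutoff = 4,
                              atom_filter = paste(
                                "name NZ NH1 NH2 NE NE2 ND1 ND2 OD1 OD2",
                                "OE1 OE2 OG OG1 OH"),
                              template = NULL) {
  if (inherits(traj, "xtraj")) {
    template <- traj$template
    frames <- traj$frames
  } else frames <- traj
  keep <- if (is.null(atom_filter)) seq_len(nrow(template$atoms)) else
    select_atoms(template, atom_filter)
  rows_a <- rows_b <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    ra <- intersect(residue_atom_rows(template,
                                      list(pairs$chain_a[p],
                                           pairs$resnum_a[p])), keep)
    rb <- intersect(residue_atom_rows(template,
                                      list(pairs$chain_b[p],
                                           pairs$resnum_b[p])), keep)
    if (length(ra) == 0 || length(rb) == 0) {
      stop("pair ", pairs$chain_a[p], ":", pairs$resnum_a[p], " - ",
           pairs$chain_b[p], ":", pairs$resnum_b[p],
           " has no atoms passing the filter")
    }
    rows_a[[p]] <- ra; rows_b[[p]] <- rb
  }
  hits <- matrix(FALSE, length(frames), nrow(pairs))
  for (f in seq_along(frames)) {
    xyz <- frames[[f]]
    for (p in seq_len(nrow(pairs))) {
      d <- min_cross_dist(xyz[rows_a[[p]], , drop = FALSE],
                          xyz[rows_b[[p]], , drop = FALSE])
      hits[f, p] <- d <= cutoff
    }
  }
  occ <- colMeans(hits)
  out <- tibble::as_tibble(pairs[, c("chain_a", "resnum_a", "chain_b",
                                     "resnum_b")])
  out$occupancy <- occ
  out$class <- dplyr::case_when(occ > 0.75 ~ "strong",
                                occ >= 0.60 ~ "weak",
                                TRUE ~ "below")
  class(out) <- c("occupancy_table", class(out))
  out
}

#' Write an occupancy report (strong rows marked, `below` rows dropped
#' unless requested)
#' @param occupancy an `occupancy_table`
#' @param path output file
#' @param include_below keep sub-0.60 rows (default FALSE)
#' @return invisibly, `path`
#' @export
write_occupancy <- function(occupancy, path, include_below = FALSE) {
  df <- as.data.frame(occupancy)
  if (!include_below) df <- df[df$class != "below", ]
  df$mark <- ifelse(df$class == "strong", "*", "")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Histogram of a per-frame minimal distance
#'
#' Bins are aligned to multiples of `bin_width`; the mean of the
#' per-frame distances is reported alongside (the dashed "average"
#' line of the distance-distribution figures).
#'
#' @param traj an `xtraj`
#' @param residue_a,residue_b residues as `list(chain, resnum)`
#' @param bin_width Angstrom (e.g. 0.2 or 0.5)
#' @param atom_filter optional selector restricting atoms
#' @return object of class `dist_histogram`: list with `breaks`,
#'   `counts`, `mids`, `mean`, `distances`
#' @export
distance_histogram <- function(traj, residue_a, residue_b, bin_width,
                               atom_filter = NULL) {
  stopifnot(bin_width > 0)
  template <- traj$template
  ra <- residue_atom_rows(template, residue_a)
  rb <- residue_atom_rows(template, residue_b)
  if (!is.null(atom_filter)) {
    keep <- select_atoms(template, atom_filter)
    ra <- intersect(ra, keep); rb <- intersect(rb, keep)
  }
  d <- vapply(traj$frames, function(xyz) {
    min_cross_dist(xyz[ra, , drop = FALSE], xyz[rb, , drop = FALSE])
  }, numeric(1))
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 mean = mean(d), distances = d),
            class = "dist_histogram")
}

#' @export
print.dist_histogram <- function(x, ...) {
  cat("<distance histogram>", sum(x$counts), "frames, mean",
      signif(x$mean, 4), "A, bin", signif(diff(x$breaks)[1], 3), "A\n")
  invisible(x)
}
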