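#' Crystallographic symmetry operators
#'
#' Operators act on fractional coordinates: `x' = R x + t`. Operators
#' read from REMARK 290 SMTRY records are converted from the orthogonal
#' to this convention using the unit cell.
#'
#' @param rotation 3 x 3 matrix (fractional convention, det +/- 1)
#' @param translation fractional 3-vector
#' @param id operator id
#' @return object of class `sym_op`
#' @export
symmetry_operator <- function(rotation, translation = c(0, 0, 0), id = NA) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (abs(abs(det(rotation)) - 1) > 1e-6) {
    stop("symmetry rotation must have determinant +/- 1")
  }
  structure(list(R = rotation, t = as.numeric(translation), id = id),
            class = "sym_op")
}

#' Built-in space-group operator tables
#'
#' Small table of common space groups used when a structure carries no
#' SMTRY records: P1 (1 operator), P21 (2), P212121 (4).
#'
#' @param name `"P1"`, `"P21"` or `"P212121"`
#' @return list of `sym_op`
#' @export
spacegroup_operators <- function(name = c("P1", "P21", "P212121")) {
  name <- match.arg(name)
  I <- diag(3)
  ops <- switch(name,
    P1 = list(symmetry_operator(I, c(0, 0, 0), 1)),
    P21 = list(
      symmetry_operator(I, c(0, 0, 0), 1),
      symmetry_operator(diag(c(-1, 1, -1)), c(0, 0.5, 0), 2)),
    P212121 = list(
      symmetry_operator(I, c(0, 0, 0), 1),
      symmetry_operator(diag(c(-1, -1, 1)), c(0.5, 0, 0.5), 2),
      symmetry_operator(diag(c(-1, 1, -1)), c(0, 0.5, 0.5), 3),
      symmetry_operator(diag(c(1, -1, -1)), c(0.5, 0.5, 0), 4)))
  ops
}

#' Orthogonalization matrix of a unit cell
#'
#' Standard crystallographic convention: `a` along x, `b` in the
#' xy-plane. Multiplying a fractional column vector by this matrix
#' yields orthogonal Angstrom coordinates.
#'
#' @param cell `c(a, b, c, alpha, beta, gamma)` (Angstrom, degrees)
#' @return 3 x 3 matrix
#' @export
orthogonalization_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180
  ga <- cell[6] * pi / 180
  v2 <- 1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
    2 * cos(al) * cos(be) * cos(ga)
  if (v2 <= 0) stop("degenerate unit cell")
  matrix(c(
    a, b * cos(ga), cc * cos(be),
    0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0, cc * sqrt(v2) / sin(ga)), 3, 3, byrow = TRUE)
}

#' Fractional / orthogonal coordinate transform
#'
#' @param cell unit cell `c(a, b, c, alpha, beta, gamma)`
#' @param direction `"to_frac"` or `"to_orth"`
#' @return a function mapping an n x 3 coordinate matrix
#' @export
fractional_orthogonal <- function(cell, direction = c("to_frac",
                                                      "to_orth")) {
  direction <- match.arg(direction)
  M <- orthogonalization_matrix(cell)
  A <- if (direction == "to_orth") M else solve(M)
  function(xyz) {
    xyz <- matrix(xyz, ncol = 3)
    t(A %*% t(xyz))
  }
}

chain_id_pool <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n > length(pool)) {
    pool <- c(pool, as.vector(outer(pool, pool, paste0)))
  }
  pool[seq_len(n)]
}

apply_sym_image <- function(asu, op, shift) {
  f2o <- orthogonalization_matrix(asu$cell)
  o2f <- solve(f2o)
  xyz <- coords(asu)
  frac <- t(o2f %*% t(xyz))
  frac2 <- t(op$R %*% t(frac)) +
    matrix(op$t + shift, nrow(frac), 3, byrow = TRUE)
  t(f2o %*% t(frac2))
}

#' Expand an asymmetric unit by symmetry operators and lattice shifts
#'
#' One copy is produced per (operator, lattice shift) combination, with
#' chain ids remapped uniquely and atom serials renumbered. The
#' identity image (identity operator, zero shift) is included once when
#' present among the inputs.
#'
#' @param asu an `xstruct` with a unit cell
#' @param operators list of `sym_op` (default: the structure's own,
#'   else identity)
#' @param lattice_shifts integer matrix of unit-cell translations, one
#'   row per shift (default: the zero shift)
#' @return multi-chain `xstruct`
#' @export
expand_symmetry <- function(asu, operators = NULL, lattice_shifts = NULL) {
  if (is.null(asu$cell)) stop("symmetry expansion requires a unit cell")
  if (is.null(operators)) operators <- asu$sym_ops
  if (is.null(operators)) operators <- spacegroup_operators("P1")
  if (length(operators) == 0) stop("no symmetry operators supplied")
  if (is.null(lattice_shifts)) lattice_shifts <- matrix(0, 1, 3)
  lattice_shifts <- matrix(lattice_shifts, ncol = 3)
  old_chains <- unique(asu$atoms$chain)
  n_img <- length(operators) * nrow(lattice_shifts)
  ids <- chain_id_pool(n_img * length(old_chains))
  pieces <- list()
  k <- 0
  for (oi in seq_along(operators)) {
    for (si in seq_len(nrow(lattice_shifts))) {
      xyz <- apply_sym_image(asu, operators[[oi]], lattice_shifts[si, ])
      at <- asu$atoms
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
      at$chain <- ids[k * length(old_chains) +
                        match(at$chain, old_chains)]
      k <- k + 1
      pieces[[k]] <- at
    }
  }
  at <- dplyr::bind_rows(pieces)
  at$serial <- seq_len(nrow(at))
  new_structure(at, cell = asu$cell, label = paste0(asu$label, " expanded"))
}

#' Build a crystal supercell
#'
#' Expands the asymmetric unit over all operators and an
#' `na x nb x nc` block of unit cells; the recorded cell is scaled to
#' `(na a, nb b, nc c)`. Four operators with a 2 x 2 x 1 block give the
#' 16-molecule supercell used for crystal-environment simulation.
#'
#' @param asu an `xstruct` with cell
#' @param operators list of `sym_op` (default: structure's own)
#' @param na,nb,nc positive unit-cell multiplicities
#' @return multi-chain `xstruct` with the scaled cell
#' @export
build_supercell <- function(asu, operators = NULL, na = 2, nb = 2, nc = 1) {
  if (na < 1 || nb < 1 || nc < 1) stop("cell multiplicities must be >= 1")
  shifts <- as.matrix(expand.grid(a = 0:(na - 1), b = 0:(nb - 1),
                                  c = 0:(nc - 1)))
  out <- expand_symmetry(asu, operators, shifts)
  out$cell <- c(asu$cell[1] * na, asu$cell[2] * nb, asu$cell[3] * nc,
                asu$cell[4:6])
  out$label <- paste0(asu$label, sprintf(" supercell %dx%dx%d", na, nb, nc))
  out
}

#' Residue-level crystal-contact map
#'
#' For every non-identity symmetry image (including lattice-shifted
#' identity copies) approaching the asymmetric unit, lists all residue
#' pairs whose minimal inter-atomic distance is below `criterion`.
#' Image bounding boxes are pruned at `criterion + 2` Angstrom before
#' the atom-level scan.
#'
#' @param asu an `xstruct` with cell
#' @param operators list of `sym_op` (default: structure's own, else a
#'   built-in table is required)
#' @param criterion contact distance, Angstrom (default 4)
#' @param lattice_range lattice shifts scanned in each direction
#'   (default 1: -1..1)
#' @return tibble of class `crystal_contact_map` with columns
#'   `asu_chain`, `asu_resnum`, `nb_chain`, `nb_resnum`, `operator`,
#'   `shift_a`, `shift_b`, `shift_c`, `min_distance`
#' @export
crystal_contact_map <- function(asu, operators = NULL, criterion = 4,
                                lattice_range = 1) {
  if (is.null(asu$cell)) stop("contact map requires a unit cell")
  if (is.null(operators)) operators <- asu$sym_ops
  if (is.null(operators)) stop("no symmetry operators available")
  xyz0 <- coords(asu)
  a <- asu$atoms
  bb_lo <- apply(xyz0, 2, min) - (criterion + 2)
  bb_hi <- apply(xyz0, 2, max) + (criterion + 2)
  shifts <- as.matrix(expand.grid(a = -lattice_range:lattice_range,
                                  b = -lattice_range:lattice_range,
                                  c = -lattice_range:lattice_range))
  res_key <- paste(a$chain, a$resnum)
  res_levels <- unique(res_key)
  res_idx <- match(res_key, res_levels)
  out <- list()
  for (oi in seq_along(operators)) {
    op <- operators[[oi]]
    is_identity <- isTRUE(all.equal(op$R, diag(3))) &&
      isTRUE(all.equal(op$t %% 1, c(0, 0, 0)))
    for (si in seq_len(nrow(shifts))) {
      if (is_identity && all(shifts[si, ] == 0)) next
      xyz1 <- apply_sym_image(asu, op, shifts[si, ])
      if (any(apply(xyz1, 2, min) > bb_hi) ||
          any(apply(xyz1, 2, max) < bb_lo)) next
      d2 <- outer(rowSums(xyz0^2), rowSums(xyz1^2), "+") -
        2 * xyz0 %*% t(xyz1)
      hit <- which(d2 < criterion^2, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      df <- tibble::tibble(
        asu_chain = a$chain[hit[, 1]], asu_resnum = a$resnum[hit[, 1]],
        nb_chain = a$chain[hit[, 2]], nb_resnum = a$resnum[hit[, 2]],
        operator = if (!is.null(op$id) && !is.na(op$id)) op$id else oi,
        shift_a = shifts[si, 1], shift_b = shifts[si, 2],
        shift_c = shifts[si, 3],
        dist = sqrt(pmax(d2[hit], 0)))
      out[[length(out) + 1]] <- df |>
        dplyr::group_by(.data$asu_chain, .data$asu_resnum, .data$nb_chain,
                        .data$nb_resnum, .data$operator, .data$shift_a,
                        .data$shift_b, .data$shift_c) |>
        dplyr::summarise(min_distance = min(.data$dist), .groups = "drop")
    }
  }
  res <- if (length(out) > 0) dplyr::bind_rows(out) else tibble::tibble(
    asu_chain = character(0), asu_resnum = integer(0),
    nb_chain = character(0), nb_resnum = integer(0),
    operator = integer(0), shift_a = integer(0), shift_b = integer(0),
    shift_c = integer(0), min_distance = numeric(0))
  res <- dplyr::arrange(res, .data$asu_chain, .data$asu_resnum,
                        .data$operator, .data$shift_a, .data$shift_b,
                        .data$shift_c, .data$nb_resnum)
  class(res) <- c("crystal_contact_map", class(res))
  res
}

#' Merge a per-neighbour contact map into one residue-pair view
#' @param map a `crystal_contact_map`
#' @return tibble with one row per (asu residue, neighbour residue)
#'   keeping the smallest distance over all images
#' @export
merge_contact_map <- function(map) {
  if (nrow(map) == 0) {
    return(tibble::tibble(asu_chain = character(0),
                          asu_resnum = integer(0),
                          nb_chain = character(0),
                          nb_resnum = integer(0),
                          min_distance = numeric(0),
                          n_images = integer(0)))
  }
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(map), .data$asu_chain,
                    .data$asu_resnum, .data$nb_chain, .data$nb_resnum),
    min_distance = min(.data$min_distance), n_images = dplyr::n(),
    .groups = "drop")
}

#' Annotate crystal contacts with residue-range labels
#'
#' Each contact row is tagged with every annotation range it intersects
#' on either side (docked elements, loop regions, ...); rows outside
#' all ranges are retained untagged.
#'
#' @param map a `crystal_contact_map`
#' @param annotations tibble with `label`, `start`, `end` (residue
#'   numbers, inclusive)
#' @return the map with a `tags` column (comma-joined labels)
#' @export
annotate_contacts <- function(map, annotations) {
  tags <- vapply(seq_len(nrow(map)), function(i) {
    hit <- (map$asu_resnum[i] >= annotations$start &
              map$asu_resnum[i] <= annotations$end) |
      (map$nb_resnum[i] >= annotations$start &
         map$nb_resnum[i] <= annotations$end)
    paste(annotations$label[hit], collapse = ",")
  }, character(1))
  map$tags <- tags
  map
}

#' Write a crystal-contact map as delimited text
#' @param map a `crystal_contact_map`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_contact_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
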