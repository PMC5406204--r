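#' Create a molecular structure object
#'
#' A structure couples an atom table with optional crystallographic
#' metadata (unit cell and symmetry operators). Atom identity follows
#' author numbering verbatim: no renumbering, insertion codes carried.
#'
#' @param atoms a data frame with columns `serial`, `name`, `resname`,
#'   `resnum`, `icode`, `chain`, `x`, `y`, `z`, `occ`, `b`. Missing
#'   `icode`/`occ`/`b` columns are filled with `""`, `1`, `0`.
#' @param cell optional numeric vector `c(a, b, c, alpha, beta, gamma)`
#'   (Angstrom / degrees)
#' @param sym_ops optional list of symmetry operators as produced by
#'   [symmetry_operator()] (fractional-coordinate convention)
#' @param label free-text label
#' @return an object of class `xstruct`
#' @export
new_structure <- function(atoms, cell = NULL, sym_ops = NULL, label = "") {
  atoms <- tibble::as_tibble(atoms)
  if (!("icode" %in% names(atoms))) atoms$icode <- ""
  if (!("occ" %in% names(atoms))) atoms$occ <- 1
  if (!("b" %in% names(atoms))) atoms$b <- 0
  if (!("serial" %in% names(atoms))) atoms$serial <- seq_len(nrow(atoms))
  need <- c("serial", "name", "resname", "resnum", "icode", "chain",
            "x", "y", "z", "occ", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  }
  atoms <- atoms[, need]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (any(atoms$b < 0, na.rm = TRUE)) stop("negative B-factor")
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate atom identity: ", key[which(duplicated(key))[1]])
  }
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 6 || any(cell[1:3] <= 0) ||
        any(cell[4:6] <= 0) || any(cell[4:6] >= 180)) {
      stop("invalid unit cell")
    }
  }
  structure(
    list(atoms = atoms, cell = cell, sym_ops = sym_ops, label = label),
    class = "xstruct"
  )
}

#' @export
print.xstruct <- function(x, ...) {
  cat("<structure", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      ">", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)")
  if (!is.null(x$cell)) {
    cat(", cell", paste(signif(x$cell, 6), collapse = " "))
  }
  if (!is.null(x$sym_ops)) cat(",", length(x$sym_ops), "symmetry ops")
  cat("\n")
  print(x$atoms, n = 5)
  invisible(x)
}

#' Atom coordinates as an n x 3 matrix
#' @param structure an `xstruct`
#' @return numeric matrix with one row per atom
#' @export
coords <- function(structure) {
  unname(as.matrix(structure$atoms[, c("x", "y", "z")]))
}

#' Replace atom coordinates
#' @param structure an `xstruct`
#' @param xyz n x 3 matrix congruent with the atom table
#' @return the modified structure
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atoms), ncol(xyz) == 3)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Create a trajectory
#'
#' Frames are coordinate snapshots congruent with a template structure;
#' multi-model PDB is the interchange format, model order defining time
#' with a declared stride.
#'
#' @param template an `xstruct` giving atom identities
#' @param frames list of n x 3 coordinate matrices (or a 3-d array
#'   frames x atoms x 3)
#' @param times frame times in ps, strictly increasing; default
#'   `seq_along(frames)`
#' @return an object of class `xtraj`
#' @export
new_trajectory <- function(template, frames, times = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ])
  }
  n_at <- nrow(template$atoms)
  ok <- vapply(frames, function(f) nrow(f) == n_at && ncol(f) == 3, logical(1))
  if (!all(ok)) stop("frame ", which(!ok)[1], " incongruent with template")
  if (is.null(times)) times <- as.numeric(seq_along(frames))
  if (length(times) != length(frames) || any(diff(times) <= 0)) {
    stop("times must be strictly increasing, one per frame")
  }
  structure(list(template = template, frames = frames, times = times),
            class = "xtraj")
}

#' @export
print.xtraj <- function(x, ...) {
  cat("<trajectory>", length(x$frames), "frames x",
      nrow(x$template$atoms), "atoms, t =",
      x$times[1], "..", x$times[length(x$times)], "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `xtraj`
#' @return integer frame count
#' @export
n_frames <- function(traj) length(traj$frames)

# ---- PDB text format ------------------------------------------------------

fmt_atom_line <- function(a) {
  if (max(abs(c(a$x, a$y, a$z))) >= 10000) {
    stop("coordinate magnitude >= 10000 A not representable in PDB")
  }
  name <- a$name
  # PDB convention: 1-3 char names start in column 14
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          a$serial %% 100000, name_f, a$resname, a$chain, a$resnum,
          ifelse(nzchar(a$icode), a$icode, " "), a$x, a$y, a$z, a$occ, a$b)
}

parse_atom_lines <- function(lines, lineno) {
  sub_f <- function(s, i, j) substr(s, i, j)
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & !grepl("^\\s*$", s) | is.na(v) & what %in% c("x", "y", "z")
    if (any(bad)) {
      stop(sprintf("unparsable %s field in ATOM record at line %d",
                   what, ln[which(bad)[1]]))
    }
    v
  }
  serial <- num(sub_f(lines, 7, 11), "serial", lineno)
  name <- trimws(sub_f(lines, 13, 16))
  altloc <- sub_f(lines, 17, 17)
  resname <- trimws(sub_f(lines, 18, 20))
  chain <- sub_f(lines, 22, 22)
  resnum <- num(sub_f(lines, 23, 26), "resnum", lineno)
  icode <- trimws(sub_f(lines, 27, 27))
  x <- num(sub_f(lines, 31, 38), "x", lineno)
  y <- num(sub_f(lines, 39, 46), "y", lineno)
  z <- num(sub_f(lines, 47, 54), "z", lineno)
  occ <- num(sub_f(lines, 55, 60), "occupancy", lineno)
  b <- num(sub_f(lines, 61, 66), "b-factor", lineno)
  if (any(!nzchar(name))) {
    stop("unparsable ATOM record (empty atom name) at line ",
         lineno[which(!nzchar(name))[1]])
  }
  keep <- altloc %in% c(" ", "", "A")  # single-conformer convention
  tibble::tibble(serial = as.integer(serial), name = name,
                 resname = resname, resnum = as.integer(resnum),
                 icode = icode, chain = chain, x = x, y = y, z = z,
                 occ = ifelse(is.na(occ), 1, occ),
                 b = ifelse(is.na(b), 0, b))[keep, ]
}

parse_cryst1 <- function(line) {
  v <- suppressWarnings(as.numeric(c(
    substr(line, 7, 15), substr(line, 16, 24), substr(line, 25, 33),
    substr(line, 34, 40), substr(line, 41, 47), substr(line, 48, 54))))
  if (any(is.na(v))) stop("unparsable CRYST1 record")
  v
}

parse_smtry <- function(lines, cell) {
  # REMARK 290 SMTRYn opid r1 r2 r3 t -- orthogonal-coordinate convention;
  # stored internally in fractional convention via the cell.
  tok <- lapply(strsplit(trimws(sub("^REMARK 290", "", lines)), "\\s+"),
                function(x) x[nzchar(x)])
  rows <- lapply(tok, function(t) {
    list(axis = as.integer(sub("SMTRY", "", t[1])), op = as.integer(t[2]),
         v = as.numeric(t[3:6]))
  })
  ids <- sort(unique(vapply(rows, function(r) r$op, integer(1))))
  o2f <- solve(orthogonalization_matrix(cell))
  f2o <- orthogonalization_matrix(cell)
  lapply(ids, function(id) {
    sel <- Filter(function(r) r$op == id, rows)
    if (length(sel) != 3) stop("incomplete SMTRY operator ", id)
    R <- matrix(0, 3, 3); t <- numeric(3)
    for (r in sel) { R[r$axis, ] <- r$v[1:3]; t[r$axis] <- r$v[4] }
    symmetry_operator(o2f %*% R %*% f2o, as.numeric(o2f %*% t), id = id)
  })
}

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records (file order preserved), CRYST1 into the
#' unit cell, and REMARK 290 SMTRY rows into symmetry operators
#' (converted from the orthogonal to the fractional convention using the
#' cell). Alternate locations other than blank/'A' are dropped; missing
#' occupancy/B-factor default to 1/0.
#'
#' @param path file path
#' @param model_index optional 1-based model to read from a multi-model
#'   file (default: first)
#' @return an `xstruct`
#' @export
read_structure <- function(path, model_index = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("format error: no ATOM record in ", path)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 0) {
    mi <- if (is.null(model_index)) 1L else as.integer(model_index)
    if (mi < 1 || mi > length(model_starts)) {
      stop("model_index ", mi, " out of range (", length(model_starts),
           " models)")
    }
    ends <- c(model_starts[-1], length(lines) + 1L)
    in_model <- seq_len(length(lines)) > model_starts[mi] &
      seq_len(length(lines)) < ends[mi]
    sel <- which(is_atom & in_model)
  } else {
    if (!is.null(model_index) && model_index != 1) {
      stop("model_index ", model_index, " out of range (1 model)")
    }
    sel <- which(is_atom)
  }
  atoms <- parse_atom_lines(lines[sel], sel)
  cell <- NULL
  ci <- which(rec == "CRYST1")
  if (length(ci) > 0) cell <- parse_cryst1(lines[ci[1]])
  sym_ops <- NULL
  si <- which(grepl("^REMARK 290   SMTRY", lines))
  if (length(si) > 0) {
    if (is.null(cell)) stop("SMTRY records without CRYST1 cell")
    sym_ops <- parse_smtry(lines[si], cell)
  }
  new_structure(atoms, cell = cell, sym_ops = sym_ops,
                label = basename(path))
}

#' Write a structure as PDB text
#'
#' Emits CRYST1 when a cell is present, REMARK 290 SMTRY rows when
#' symmetry operators are present, then fixed-width ATOM records. The
#' write/read round trip preserves atom identities and coordinates to
#' 0.001 Angstrom, and ATOM records are byte-stable under a second
#' round trip.
#'
#' @param structure an `xstruct`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_structure <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_pdb(structure), con)
  invisible(path)
}

format_pdb <- function(structure, close_with_end = TRUE) {
  out <- character(0)
  if (!is.null(structure$cell)) {
    cl <- structure$cell
    out <- c(out, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      cl[1], cl[2], cl[3], cl[4], cl[5], cl[6]))
    if (!is.null(structure$sym_ops)) {
      f2o <- orthogonalization_matrix(cl)
      o2f <- solve(f2o)
      for (k in seq_along(structure$sym_ops)) {
        op <- structure$sym_ops[[k]]
        Ro <- round(f2o %*% op$R %*% o2f, 6) + 0  # kill negative zero
        to <- round(as.numeric(f2o %*% op$t), 5) + 0
        for (ax in 1:3) {
          out <- c(out, sprintf(
            "REMARK 290   SMTRY%d  %2d%10.6f%10.6f%10.6f%15.5f",
            ax, k, Ro[ax, 1], Ro[ax, 2], Ro[ax, 3], to[ax]))
        }
      }
    }
  }
  a <- structure$atoms
  for (i in seq_len(nrow(a))) out <- c(out, fmt_atom_line(a[i, ]))
  if (close_with_end) out <- c(out, "END")
  out
}

#' Read a multi-model PDB file as a trajectory
#' @param path file path
#' @param dt time stride between models, ps
#' @return an `xtraj`
#' @export
read_trajectory <- function(path, dt = 1) {
  lines <- readLines(path, warn = FALSE)
  n_mod <- max(1L, sum(substr(lines, 1, 6) == "MODEL "))
  template <- read_structure(path, model_index = 1)
  frames <- vector("list", n_mod)
  frames[[1]] <- coords(template)
  if (n_mod > 1) {
    for (m in 2:n_mod) {
      frames[[m]] <- coords(read_structure(path, model_index = m))
    }
  }
  new_trajectory(template, frames, times = dt * seq_len(n_mod))
}

#' Write a trajectory as a multi-model PDB file
#' @param traj an `xtraj`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- traj$template
  for (m in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL %8d", m), con)
    writeLines(format_pdb(set_coords(s, traj$frames[[m]]),
                          close_with_end = FALSE), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- selection mini-language ---------------------------------------------

#' Select atoms by a simple expression
#'
#' The selection mini-language supports clauses joined by `and`
#' (intersection):
#' \itemize{
#'   \item `name CA CB O` -- atom-name membership
#'   \item `chain A B` -- chain membership
#'   \item `resnum 5:10 12` -- residue numbers and ranges
#'   \item `backbone` -- atoms named N, CA, C, O
#'   \item `calpha` -- atoms named CA
#'   \item `cveligible` -- the contact-map-eligible set: C-alpha, C-beta
#'     and backbone O (glycine contributes CA and O only)
#' }
#'
#' @param structure an `xstruct`
#' @param selector selection expression (character)
#' @return integer atom indices, order preserving
#' @export
select_atoms <- function(structure, selector) {
  a <- structure$atoms
  clauses <- strsplit(trimws(selector), "\\s+and\\s+")[[1]]
  if (length(clauses) == 0 || !nzchar(trimws(selector))) {
    stop("malformed selector: empty expression")
  }
  keep <- rep(TRUE, nrow(a))
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(tok[1])
    args <- tok[-1]
    m <- switch(kw,
      name = {
        if (length(args) == 0) stop("malformed selector: 'name' needs arguments")
        a$name %in% args
      },
      chain = {
        if (length(args) == 0) stop("malformed selector: 'chain' needs arguments")
        a$chain %in% args
      },
      resnum = {
        if (length(args) == 0) stop("malformed selector: 'resnum' needs arguments")
        nums <- integer(0)
        for (s in args) {
          if (grepl("^-?\\d+:-?\\d+$", s)) {
            rng <- as.integer(strsplit(s, ":")[[1]])
            nums <- c(nums, seq(rng[1], rng[2]))
          } else if (grepl("^-?\\d+$", s)) {
            nums <- c(nums, as.integer(s))
          } else stop("malformed selector: bad resnum token '", s, "'")
        }
        a$resnum %in% nums
      },
      backbone = a$name %in% c("N", "CA", "C", "O"),
      calpha = a$name == "CA",
      cveligible = a$name %in% c("CA", "CB", "O"),
      stop("malformed selector: unknown keyword '", kw, "'")
    )
    keep <- keep & m
  }
  which(keep)
}

# ---- superposition and distances -----------------------------------------

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimising the
#' RMSD of `mobile[fit_indices, ]` onto `reference[fit_indices, ]`.
#'
#' @param mobile n x 3 coordinate matrix (or `xstruct`)
#' @param reference n x 3 coordinate matrix (or `xstruct`)
#' @param fit_indices atom indices used for the fit (default: all)
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), and `rmsd`
#'   (Angstrom, over the fit set after transformation)
#' @export
superpose <- function(mobile, reference, fit_indices = NULL) {
  if (inherits(mobile, "xstruct")) mobile <- coords(mobile)
  if (inherits(reference, "xstruct")) reference <- coords(reference)
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (length(fit_indices) < 3) stop("degenerate fit: fewer than 3 fit atoms")
  M <- mobile[fit_indices, , drop = FALSE]
  Rf <- reference[fit_indices, , drop = FALSE]
  mc <- colMeans(M); rc <- colMeans(Rf)
  M0 <- sweep(M, 2, mc); R0 <- sweep(Rf, 2, rc)
  if (qr(M0)$rank < 2) stop("degenerate fit: collinear fit atoms")
  H <- t(M0) %*% R0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)
  trans <- rc - as.numeric(rot %*% mc)
  fitted <- M %*% t(rot) + matrix(trans, nrow(M), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Rf)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#' @param xyz n x 3 matrix
#' @param fit result of [superpose()]
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(xyz, fit) {
  xyz %*% t(fit$rotation) +
    matrix(fit$translation, nrow(xyz), 3, byrow = TRUE)
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' Each frame is superposed on `fit_indices`; the RMSD is reported over
#' `measure_indices`, which may differ from the fit set (e.g. flexible
#' terminal tails excluded from the fit or the measure).
#'
#' @param traj an `xtraj`
#' @param reference an `xstruct` or coordinate matrix
#' @param fit_indices indices used for superposition
#' @param measure_indices indices over which RMSD is reported
#'   (default: the fit set)
#' @return tibble with columns `time`, `frame`, `rmsd`
#' @export
rmsd_series <- function(traj, reference, fit_indices = NULL,
                        measure_indices = NULL) {
  ref <- if (inherits(reference, "xstruct")) coords(reference) else reference
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(ref))
  if (is.null(measure_indices)) measure_indices <- fit_indices
  vals <- vapply(traj$frames, function(f) {
    fit <- superpose(f, ref, fit_indices)
    moved <- apply_transform(f, fit)
    sqrt(mean(rowSums((moved[measure_indices, , drop = FALSE] -
                         ref[measure_indices, , drop = FALSE])^2)))
  }, numeric(1))
  tibble::tibble(time = traj$times, frame = seq_along(traj$frames),
                 rmsd = vals)
}

residue_atom_rows <- function(structure, residue) {
  a <- structure$atoms
  rows <- which(a$chain == residue[[1]] & a$resnum == as.integer(residue[[2]]))
  if (length(rows) == 0) {
    stop("residue ", residue[[1]], ":", residue[[2]], " not found")
  }
  rows
}

#' Minimal inter-residue atom distance
#'
#' @param structure an `xstruct`
#' @param residue_a,residue_b `list(chain, resnum)` or `c(chain, resnum)`
#' @param atom_filter optional selector restricting the atoms considered
#'   (e.g. `"name CB"`)
#' @return minimal pairwise atom distance, Angstrom
#' @export
min_residue_distance <- function(structure, residue_a, residue_b,
                                 atom_filter = NULL) {
  ra <- residue_atom_rows(structure, residue_a)
  rb <- residue_atom_rows(structure, residue_b)
  if (!is.null(atom_filter)) {
    keep <- select_atoms(structure, atom_filter)
    ra <- intersect(ra, keep); rb <- intersect(rb, keep)
    if (length(ra) == 0 || length(rb) == 0) {
      stop("atom filter removed all atoms of a residue")
    }
  }
  xyz <- coords(structure)
  min_cross_dist(xyz[ra, , drop = FALSE], xyz[rb, , drop = FALSE])
}

min_cross_dist <- function(A, B) {
  # min over all pairs |a - b|
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}
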