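#' Free-energy surface reconstruction and basin analysis
#'
#' The estimator for a well-tempered run is
#' `F_hat(s) = -(f / (f - 1)) * V(s)` with `V` the accumulated bias,
#' shifted so the minimum over the grid is zero.
#'
#' @name fes
NULL

new_fes_grid <- function(ax1, ax2, values, temperature, bias_factor,
                         shifted = TRUE) {
  stopifnot(all(diff(ax1) > 0), all(diff(ax2) > 0),
            nrow(values) == length(ax1), ncol(values) == length(ax2))
  structure(list(ax1 = ax1, ax2 = ax2, values = values,
                 temperature = temperature, bias_factor = bias_factor,
                 shifted = shifted),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("<FES grid>", length(x$ax1), "x", length(x$ax2), "cells, F in [",
      signif(min(x$values), 4), ",", signif(max(x$values), 4),
      "] kcal/mol, T =", x$temperature, "K\n")
  invisible(x)
}

#' Reconstruct the free-energy surface from deposited hills
#'
#' Sums the deposited Gaussians on a regular grid (truncated at 6 sigma,
#' error below 1e-7 of each height) and applies the well-tempered
#' estimator `F_hat = -(f/(f-1)) V`, shifted to `min = 0`.
#'
#' @param hills hills tibble; all rows must share one bias factor
#' @param ax1,ax2 grid axes (default `seq(0, 1, by = 0.01)`)
#' @param temperature K (used by projections and basin free energies)
#' @return a `fes_grid`
#' @export
fes_from_hills <- function(hills, ax1 = seq(0, 1, by = 0.01),
                           ax2 = seq(0, 1, by = 0.01),
                           temperature = 300) {
  if (nrow(hills) > 0) {
    bf <- unique(hills$biasf)
    if (length(bf) > 1) stop("hills carry mixed bias factors")
  } else bf <- Inf
  V <- matrix(0, length(ax1), length(ax2))
  for (k in seq_len(nrow(hills))) {
    c1 <- hills$cv1[k]; c2 <- hills$cv2[k]
    s1 <- hills$sigma_cv1[k]; s2 <- hills$sigma_cv2[k]
    i <- which(abs(ax1 - c1) <= 6 * s1)
    j <- which(abs(ax2 - c2) <= 6 * s2)
    if (length(i) == 0 || length(j) == 0) next
    g1 <- exp(-(ax1[i] - c1)^2 / (2 * s1^2))
    g2 <- exp(-(ax2[j] - c2)^2 / (2 * s2^2))
    V[i, j] <- V[i, j] + hills$height[k] * outer(g1, g2)
  }
  Fhat <- if (nrow(hills) > 0) -(bf / (bf - 1)) * V else V
  Fhat <- Fhat - min(Fhat)
  new_fes_grid(ax1, ax2, Fhat, temperature, bf)
}

#' Build a `fes_grid` from an analytic potential (ground truth)
#' @param potential a [model_potential()]
#' @param ax1,ax2 grid axes
#' @param temperature K
#' @return a `fes_grid` with `F = U - min(U)`
#' @export
fes_from_potential <- function(potential, ax1 = seq(0, 1, by = 0.01),
                               ax2 = seq(0, 1, by = 0.01),
                               temperature = 300) {
  g <- as.matrix(expand.grid(s1 = ax1, s2 = ax2))
  U <- matrix(model_value(potential, g), length(ax1), length(ax2))
  new_fes_grid(ax1, ax2, U - min(U), temperature, Inf)
}

#' Project a 2-D free-energy surface onto one CV
#'
#' Boltzmann-weighted marginalisation:
#' `F1(a) = -kB T log( sum_b exp(-F(a, b) / kB T) * db )`, shifted to
#' min 0 (the shift convention commutes with the projection).
#'
#' @param fes a `fes_grid`
#' @param axis `"cv1"` or `"cv2"`
#' @return tibble with the axis value and `free` (kcal/mol)
#' @export
project_1d <- function(fes, axis = c("cv1", "cv2")) {
  axis <- match.arg(axis)
  kt <- KB_KCAL * fes$temperature
  M <- if (axis == "cv1") fes$values else t(fes$values)
  av <- if (axis == "cv1") fes$ax1 else fes$ax2
  bv <- if (axis == "cv1") fes$ax2 else fes$ax1
  db <- mean(diff(bv))
  # log-sum-exp, stabilised row-wise
  m <- apply(-M / kt, 1, max)
  f1 <- -kt * (m + log(rowSums(exp(-M / kt - m)) * db))
  tibble::tibble(!!axis := av, free = f1 - min(f1))
}

#' Compare an earlier and a later FES for convergence
#'
#' Both grids are aligned to min 0, and the maximum absolute change is
#' taken over cells whose later free energy does not exceed
#' `region_cap`. Convergence requires the change to stay within
#' `threshold` in the 2-D grid and in both 1-D projections -- the
#' trailing-window criterion used to stop the production runs (no more
#' than 2 kcal/mol change).
#'
#' @param fes_earlier,fes_later congruent `fes_grid`s
#' @param threshold kcal/mol (default 2)
#' @param region_cap restrict the comparison to cells with later
#'   F below this, kcal/mol (default 10)
#' @return list with `converged`, `max_change` (2-D), and
#'   `max_change_1d` (named, both projections)
#' @export
check_convergence <- function(fes_earlier, fes_later, threshold = 2,
                              region_cap = 10) {
  if (!identical(dim(fes_earlier$values), dim(fes_later$values))) {
    stop("incongruent FES grids")
  }
  a <- fes_earlier$values - min(fes_earlier$values)
  b <- fes_later$values - min(fes_later$values)
  mask <- b <= region_cap
  max2d <- if (any(mask)) max(abs(a - b)[mask]) else 0
  p1 <- function(axis) {
    pa <- project_1d(fes_earlier, axis)$free
    pb <- project_1d(fes_later, axis)$free
    m <- pb <= region_cap
    if (any(m)) max(abs(pa - pb)[m]) else 0
  }
  m1 <- c(cv1 = p1("cv1"), cv2 = p1("cv2"))
  list(converged = max2d <= threshold && all(m1 <= threshold),
       max_change = max2d, max_change_1d = m1)
}

#' Convergence check from the trailing fraction of a hills record
#'
#' Generalises the "last stretch of deposition time" criterion: the FES
#' built from all hills is compared against the FES built with the
#' trailing fraction removed.
#'
#' @param hills hills tibble
#' @param fraction trailing fraction of deposition time (default 0.1)
#' @param ... passed to [fes_from_hills()] and [check_convergence()]
#' @inheritParams check_convergence
#' @inheritParams fes_from_hills
#' @return as [check_convergence()]
#' @export
check_convergence_hills <- function(hills, fraction = 0.1, threshold = 2,
                                    region_cap = 10,
                                    ax1 = seq(0, 1, by = 0.01),
                                    ax2 = seq(0, 1, by = 0.01),
                                    temperature = 300) {
  t_cut <- max(hills$time) * (1 - fraction)
  early <- fes_from_hills(hills[hills$time <= t_cut, ], ax1, ax2,
                          temperature)
  late <- fes_from_hills(hills, ax1, ax2, temperature)
  check_convergence(early, late, threshold, region_cap)
}

#' Locate local minima of a free-energy surface
#'
#' A cell is a minimum when no 8-neighbour is lower and every
#' equal-valued plateau neighbour group is enclosed by higher cells;
#' plateau minima are resolved to the lowest-index cell. Results are
#' sorted by free energy, ascending.
#'
#' @param fes a `fes_grid`
#' @return tibble with `cv1`, `cv2`, `free`, `i`, `j` (grid indices)
#' @export
find_minima <- function(fes) {
  v <- fes$values
  n1 <- nrow(v); n2 <- ncol(v)
  pad <- matrix(Inf, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- v
  lower_nb <- matrix(FALSE, n1, n2)
  equal_nb <- matrix(FALSE, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[2:(n1 + 1) + di, 2:(n2 + 1) + dj]
    lower_nb <- lower_nb | (nb < v)
    equal_nb <- equal_nb | (nb == v)
  }
  cand <- which(!lower_nb)
  if (length(cand) == 0) return(tibble::tibble(
    cv1 = numeric(0), cv2 = numeric(0), free = numeric(0),
    i = integer(0), j = integer(0)))
  strict <- cand[!equal_nb[cand]]
  # plateau handling: group equal-valued candidate cells into connected
  # components (4-neighbourhood), keep lowest linear index per component
  plateau <- setdiff(cand, strict)
  reps <- integer(0)
  if (length(plateau) > 0) {
    is_cand <- matrix(FALSE, n1, n2); is_cand[cand] <- TRUE
    seen <- matrix(FALSE, n1, n2)
    for (p in sort(plateau)) {
      if (seen[p]) next
      # the full equal-valued connected region: a plateau is a minimum
      # only when no cell of it borders a lower cell
      comp <- flood_component(v == v[p], p, n1, n2)
      seen[comp] <- TRUE
      if (all(is_cand[comp])) reps <- c(reps, min(comp))
    }
  }
  all_min <- sort(c(strict, reps))
  ij <- arrayInd(all_min, dim(v))
  out <- tibble::tibble(cv1 = fes$ax1[ij[, 1]], cv2 = fes$ax2[ij[, 2]],
                        free = v[all_min], i = ij[, 1], j = ij[, 2])
  dplyr::arrange(out, .data$free)
}

flood_component <- function(mask, start, n1, n2) {
  # linear-index flood fill over TRUE cells, 4-neighbourhood
  comp <- integer(0)
  stack <- start
  visited <- logical(length(mask))
  while (length(stack) > 0) {
    p <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (visited[p] || !mask[p]) next
    visited[p] <- TRUE
    comp <- c(comp, p)
    i <- (p - 1) %% n1 + 1; j <- (p - 1) %/% n1 + 1
    if (i > 1) stack <- c(stack, p - 1)
    if (i < n1) stack <- c(stack, p + 1)
    if (j > 1) stack <- c(stack, p - n1)
    if (j < n2) stack <- c(stack, p + n1)
  }
  comp
}

#' Extract the basin around a free-energy minimum
#'
#' Flood fill of 4-connected cells with `F <= F_min + depth_window`.
#' Basins are grown for every minimum in ascending free-energy order;
#' cells already claimed by a deeper minimum's fill are not re-entered
#' (watershed ties go to the lower minimum).
#'
#' @param fes a `fes_grid`
#' @param minimum one row of [find_minima()] output (or a list with
#'   `i`, `j`)
#' @param depth_window kcal/mol above the minimum (default 2)
#' @return object of class `fes_basin`: list with `minimum`, `cells`
#'   (matrix of i, j), `depth_window`
#' @export
extract_basin <- function(fes, minimum, depth_window = 2) {
  minima <- find_minima(fes)
  v <- fes$values
  n1 <- nrow(v); n2 <- ncol(v)
  claimed <- matrix(FALSE, n1, n2)
  target_lin <- (minimum$j - 1) * n1 + minimum$i
  result <- NULL
  for (k in seq_len(nrow(minima))) {
    lin <- (minima$j[k] - 1) * n1 + minima$i[k]
    eligible <- (v <= minima$free[k] + depth_window) & !claimed
    if (!eligible[lin]) next
    comp <- flood_component(eligible, lin, n1, n2)
    claimed[comp] <- TRUE
    if (lin == target_lin) result <- comp
  }
  if (is.null(result)) {
    stop("minimum not found among this grid's minima (or claimed by a ",
         "deeper basin)")
  }
  structure(list(minimum = minima[
    (minima$j - 1) * n1 + minima$i == target_lin, ],
    cells = arrayInd(sort(result), dim(v)),
    depth_window = depth_window, dims = dim(v),
    ax1 = fes$ax1, ax2 = fes$ax2),
    class = "fes_basin")
}

#' @export
print.fes_basin <- function(x, ...) {
  cat("<FES basin>", nrow(x$cells), "cells around (",
      signif(x$minimum$cv1, 3), ",", signif(x$minimum$cv2, 3),
      "), window", x$depth_window, "kcal/mol\n")
  invisible(x)
}

#' Rectangular CV-space basin definition
#' @param cv1_range,cv2_range numeric length-2 ranges
#' @return object of class `cv_rectangle`
#' @export
basin_rectangle <- function(cv1_range, cv2_range) {
  structure(list(cv1_range = sort(cv1_range), cv2_range = sort(cv2_range)),
            class = "cv_rectangle")
}

basin_free_energy <- function(fes, basin) {
  kt <- KB_KCAL * fes$temperature
  f <- fes$values[basin$cells]
  if (length(f) == 0) stop("empty basin")
  -kt * log(sum(exp(-f / kt)))
}

#' Free-energy difference between two basins
#'
#' Each basin's free energy is `-kB T log` of its Boltzmann-weighted
#' cell sum; the difference `F(a) - F(b)` is returned (cell area cancels).
#'
#' @param fes a `fes_grid`
#' @param basin_a,basin_b `fes_basin`s on this grid
#' @return kcal/mol
#' @export
fes_difference <- function(fes, basin_a, basin_b) {
  basin_free_energy(fes, basin_a) - basin_free_energy(fes, basin_b)
}

# ---- text interchange -----------------------------------------------------

#' Write a FES grid as text (`#! FIELDS cv1 cv2 free`, row-major)
#' @param fes a `fes_grid`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature %.17g bias_factor %.17g",
                     fes$temperature, fes$bias_factor), con)
  writeLines("#! FIELDS cv1 cv2 free", con)
  g <- expand.grid(i = seq_along(fes$ax1), j = seq_along(fes$ax2))
  g <- g[order(g$i, g$j), ]
  writeLines(sprintf("%.10g %.10g %.17g", fes$ax1[g$i], fes$ax2[g$j],
                     fes$values[cbind(g$i, g$j)]), con)
  invisible(path)
}

#' Read a FES grid written by [write_fes()]
#' @param path input file
#' @return a `fes_grid`
#' @export
read_fes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- strsplit(lines[1], "\\s+")[[1]]
  temperature <- as.numeric(meta[3]); bias_factor <- as.numeric(meta[5])
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body,
                          col.names = c("cv1", "cv2", "free"))
  ax1 <- sort(unique(df$cv1)); ax2 <- sort(unique(df$cv2))
  v <- matrix(NA_real_, length(ax1), length(ax2))
  v[cbind(match(df$cv1, ax1), match(df$cv2, ax2))] <- df$free
  new_fes_grid(ax1, ax2, v, temperature, bias_factor)
}
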