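#' Root-mean-square fluctuations of a trajectory
#'
#' Two-pass mean-structure fitting: frames are aligned to the first
#' frame on `fit_indices`, averaged, then re-aligned to that mean;
#' `RMSF_i = sqrt(mean |r_i - <r_i>|^2)` is the 3-D displacement RMS
#' per atom. Rigid-body motion is removed by the fit, so a rigidly
#' rotating trajectory has zero RMSF.
#'
#' @param traj an `xtraj` with at least 2 frames
#' @param fit_indices atoms used for superposition (default: all)
#' @param measure_indices atoms reported (default: all)
#' @return tibble of class `rmsf_profile` with `chain`, `resnum`,
#'   `name`, `rmsf` (Angstrom)
#' @export
rmsf <- function(traj, fit_indices = NULL, measure_indices = NULL) {
  if (length(traj$frames) < 2) stop("RMSF requires at least 2 frames")
  n_at <- nrow(traj$template$atoms)
  if (is.null(fit_indices)) fit_indices <- seq_len(n_at)
  if (is.null(measure_indices)) measure_indices <- seq_len(n_at)
  align_all <- function(ref) {
    lapply(traj$frames, function(f) {
      apply_transform(f, superpose(f, ref, fit_indices))
    })
  }
  pass1 <- align_all(traj$frames[[1]])
  mean1 <- Reduce(`+`, pass1) / length(pass1)
  pass2 <- align_all(mean1)
  mean2 <- Reduce(`+`, pass2) / length(pass2)
  dev2 <- Reduce(`+`, lapply(pass2, function(f) rowSums((f - mean2)^2))) /
    length(pass2)
  a <- traj$template$atoms[measure_indices, ]
  out <- tibble::tibble(chain = a$chain, resnum = a$resnum, name = a$name,
                        rmsf = sqrt(dev2[measure_indices]))
  class(out) <- c("rmsf_profile", class(out))
  attr(out, "fit_reference") <- "mean structure (two-pass)"
  out
}

#' Convert RMSF to crystallographic B-factors
#'
#' `B = (8 pi^2 / 3) * RMSF^2` (isotropic displacement convention).
#'
#' @param profile an `rmsf_profile` (or numeric RMSF vector)
#' @return the profile with a `b` column added (Angstrom^2), or a
#'   numeric vector
#' @export
bfactor_from_rmsf <- function(profile) {
  if (is.numeric(profile)) return((8 * pi^2 / 3) * profile^2)
  profile$b <- (8 * pi^2 / 3) * profile$rmsf^2
  profile
}

#' Rank-based comparison of simulated fluctuations with reference
#' B-factors
#'
#' Absolute B-factor scales from simulation and refinement are not
#' commensurable, so the comparison is qualitative: a Spearman rank
#' correlation plus an aligned per-atom listing.
#'
#' @param simulated an `rmsf_profile`
#' @param reference_b numeric B-factors, Angstrom^2, congruent with the
#'   profile rows
#' @return list with `correlation` (Spearman rho) and `table` (aligned
#'   tibble)
#' @export
profile_compare <- function(simulated, reference_b) {
  if (length(reference_b) != nrow(simulated)) {
    stop("reference B-factor vector incongruent with the profile (",
         length(reference_b), " vs ", nrow(simulated), " atoms)")
  }
  sim_b <- (8 * pi^2 / 3) * simulated$rmsf^2
  rho <- stats::cor(sim_b, reference_b, method = "spearman")
  tab <- tibble::tibble(chain = simulated$chain,
                        resnum = simulated$resnum,
                        name = simulated$name,
                        rmsf = simulated$rmsf,
                        b_simulated = sim_b,
                        b_reference = reference_b)
  list(correlation = rho, table = tab)
}
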