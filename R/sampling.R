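#' @useDynLib wtmetad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

# ---- model potentials -----------------------------------------------------

#' Analytic model potentials over CV space
#'
#' Potentials are defined on the `(cv1, cv2)` plane in kcal/mol.
#' `model_potential()` is the low-level constructor; the helpers build
#' the common cases. Wells are negative Gaussians on a flat background
#' with a harmonic wall confining the dynamics to `[wall_lo, wall_hi]^2`,
#' so well depths and barriers are known analytically: with wells
#' separated by many widths, the free energy at well `i` is `-depth[i]`
#' and the barrier between wells is the depth of the starting well (up
#' to Gaussian tails).
#'
#' @param kind one of `"gaussian_wells"`, `"double_well_2d"`,
#'   `"triple_well_2d"`, `"harmonic"`, `"user_table"`
#' @param parameters named list of parameters
#' @return object of class `model_potential`
#' @export
model_potential <- function(kind, parameters) {
  structure(list(kind = kind, parameters = parameters),
            class = "model_potential")
}

#' @rdname model_potential
#' @param centers k x 2 matrix of well centers (CV units)
#' @param depths well depths, kcal/mol
#' @param widths Gaussian well widths (CV units, recycled)
#' @param wall_k confinement wall stiffness, kcal/mol per CV-unit^2
#' @param wall_lo,wall_hi confinement box edges
#' @export
potential_wells <- function(centers, depths, widths = 0.08, wall_k = 500,
                            wall_lo = 0.02, wall_hi = 0.98) {
  centers <- matrix(centers, ncol = 2)
  stopifnot(nrow(centers) == length(depths), all(depths >= 0))
  model_potential("gaussian_wells", list(
    centers = centers, depths = as.numeric(depths),
    widths = rep_len(as.numeric(widths), length(depths)),
    wall_k = wall_k, wall_lo = wall_lo, wall_hi = wall_hi))
}

#' @rdname model_potential
#' @param delta_f free-energy difference between the two wells, kcal/mol
#' @param barrier barrier height from the deeper well, kcal/mol
#' @export
potential_double_well <- function(delta_f = 3, barrier = 6,
                                  centers = rbind(c(0.25, 0.25),
                                                  c(0.75, 0.75)),
                                  widths = 0.08) {
  stopifnot(barrier > delta_f, delta_f >= 0)
  potential_wells(centers, depths = c(barrier, barrier - delta_f),
                  widths = widths)
}

#' @rdname model_potential
#' @export
potential_triple_well <- function(depths = c(6, 4, 3),
                                  centers = rbind(c(0.2, 0.2), c(0.5, 0.8),
                                                  c(0.8, 0.3)),
                                  widths = 0.07) {
  potential_wells(centers, depths = depths, widths = widths)
}

#' @rdname model_potential
#' @param center harmonic center (length 2)
#' @param stiffness per-CV stiffness, kcal/mol per CV-unit^2 (length 1 or 2)
#' @export
potential_harmonic <- function(center = c(0.5, 0.5), stiffness = 100) {
  model_potential("harmonic", list(center = as.numeric(center),
                                   stiffness = as.numeric(stiffness)))
}

#' @rdname model_potential
#' @param ax,ay strictly increasing axis grids
#' @param values matrix of potential values, `values[i, j]` at
#'   `(ax[i], ay[j])`
#' @export
potential_table <- function(ax, ay, values) {
  stopifnot(all(diff(ax) > 0), all(diff(ay) > 0),
            nrow(values) == length(ax), ncol(values) == length(ay))
  model_potential("user_table", list(ax = ax, ay = ay, values = values))
}

#' Evaluate a model potential
#' @param potential a `model_potential`
#' @param s CV point `c(s1, s2)` (or n x 2 matrix)
#' @return potential value(s), kcal/mol
#' @export
model_value <- function(potential, s) {
  s <- matrix(s, ncol = 2)
  p <- potential$parameters
  switch(potential$kind,
    gaussian_wells = , double_well_2d = , triple_well_2d = {
      U <- numeric(nrow(s))
      for (i in seq_along(p$depths)) {
        d2 <- (s[, 1] - p$centers[i, 1])^2 + (s[, 2] - p$centers[i, 2])^2
        U <- U - p$depths[i] * exp(-d2 / (2 * p$widths[i]^2))
      }
      for (k in 1:2) {
        U <- U + p$wall_k * pmax(0, p$wall_lo - s[, k])^2 +
          p$wall_k * pmax(0, s[, k] - p$wall_hi)^2
      }
      U
    },
    harmonic = {
      k <- rep_len(p$stiffness, 2)
      0.5 * k[1] * (s[, 1] - p$center[1])^2 +
        0.5 * k[2] * (s[, 2] - p$center[2])^2
    },
    user_table = {
      vapply(seq_len(nrow(s)), function(i) {
        bilinear_interp(p$ax, p$ay, p$values, s[i, 1], s[i, 2])
      }, numeric(1))
    },
    stop("unknown potential kind"))
}

#' Analytic gradient of a model potential
#' @param potential a `model_potential`
#' @param s CV point `c(s1, s2)`
#' @return gradient `c(dU/ds1, dU/ds2)`
#' @export
model_gradient <- function(potential, s) {
  p <- potential$parameters
  switch(potential$kind,
    gaussian_wells = , double_well_2d = , triple_well_2d = {
      g <- c(0, 0)
      for (i in seq_along(p$depths)) {
        dd <- s - p$centers[i, ]
        e <- exp(-sum(dd^2) / (2 * p$widths[i]^2))
        g <- g + p$depths[i] * e * dd / p$widths[i]^2
      }
      for (k in 1:2) {
        if (s[k] < p$wall_lo) g[k] <- g[k] - 2 * p$wall_k * (p$wall_lo - s[k])
        if (s[k] > p$wall_hi) g[k] <- g[k] + 2 * p$wall_k * (s[k] - p$wall_hi)
      }
      g
    },
    harmonic = {
      k <- rep_len(p$stiffness, 2)
      k * (s - p$center)
    },
    user_table = {
      h <- 1e-5
      c(
        (model_value(potential, c(s[1] + h, s[2])) -
           model_value(potential, c(s[1] - h, s[2]))) / (2 * h),
        (model_value(potential, c(s[1], s[2] + h)) -
           model_value(potential, c(s[1], s[2] - h))) / (2 * h))
    },
    stop("unknown potential kind"))
}

bilinear_interp <- function(ax, ay, values, x, y) {
  i <- min(max(findInterval(x, ax), 1), length(ax) - 1)
  j <- min(max(findInterval(y, ay), 1), length(ay) - 1)
  tx <- min(max((x - ax[i]) / (ax[i + 1] - ax[i]), 0), 1)
  ty <- min(max((y - ay[j]) / (ay[j + 1] - ay[j]), 0), 1)
  values[i, j] * (1 - tx) * (1 - ty) + values[i + 1, j] * tx * (1 - ty) +
    values[i, j + 1] * (1 - tx) * ty + values[i + 1, j + 1] * tx * ty
}

# ---- engine parameters ----------------------------------------------------

#' Engine parameters for PT-metadynamics
#'
#' Defaults reproduce the study conditions: a 10-replica ladder at 300,
#' 310, 320, 330, 341, 352, 363, 375, 387 and 400 K; Gaussian hills of
#' width 0.05 in both CVs deposited every 2 ps with initial height
#' 5 kJ/mol and bias factor 10.
#'
#' @param temperature_ladder strictly increasing temperatures, K
#' @param friction Langevin friction, 1/ps
#' @param timestep integration step, ps
#' @param deposition_stride steps between hill depositions (default:
#'   2 ps of toy time)
#' @param w0 initial hill height, kcal/mol (default 5 kJ/mol converted)
#' @param bias_factor well-tempered bias factor f (> 1)
#' @param sigma per-CV Gaussian widths (length 2)
#' @param exchange_stride steps between exchange attempts (default 1 ps)
#' @param seed root random seed; all replica streams derive from it
#' @return object of class `engine_params`
#' @export
engine_params <- function(temperature_ladder = c(300, 310, 320, 330, 341,
                                                 352, 363, 375, 387, 400),
                          friction = 500, timestep = 0.02,
                          deposition_stride = NULL,
                          w0 = kj_to_kcal(5), bias_factor = 10,
                          sigma = c(0.05, 0.05),
                          exchange_stride = NULL, seed = 1) {
  if (is.null(deposition_stride)) {
    deposition_stride <- round(2 / timestep)
  }
  if (is.null(exchange_stride)) exchange_stride <- round(1 / timestep)
  stopifnot(all(diff(temperature_ladder) > 0) ||
              length(temperature_ladder) == 1,
            friction > 0, timestep > 0, w0 > 0, bias_factor > 1,
            all(sigma > 0), deposition_stride >= 1)
  structure(list(
    temperature_ladder = temperature_ladder, friction = friction,
    timestep = timestep, deposition_stride = as.integer(deposition_stride),
    w0 = w0, bias_factor = bias_factor, sigma = rep_len(sigma, 2),
    exchange_stride = as.integer(exchange_stride), seed = as.integer(seed)),
    class = "engine_params")
}

#' Well-tempered hill height
#'
#' `W = W0 * exp(-V(s, t) / (kB * (f - 1) * T))`: the deposition height
#' decays exponentially with the bias already accumulated at the
#' deposition point, so revisited regions receive ever smaller hills and
#' the bias converges instead of growing without bound.
#'
#' @param v_at_s accumulated bias at the deposition point, kcal/mol
#' @param w0 initial height, kcal/mol
#' @param f bias factor (> 1)
#' @param temperature replica temperature, K
#' @return hill height, kcal/mol
#' @export
wt_hill_height <- function(v_at_s, w0, f, temperature) {
  if (any(f <= 1)) stop("bias factor must exceed 1")
  if (any(temperature <= 0)) stop("temperature must be positive")
  w0 * exp(-v_at_s / (KB_KCAL * (f - 1) * temperature))
}

#' Accumulated bias potential and its gradient at a CV point
#'
#' Exact analytic sum of the deposited Gaussians
#' `h * exp(-sum((s - c)^2 / (2 sigma^2)))`; hills farther than
#' 6 sigma from the point in either CV contribute less than 1e-7 of
#' their height and may be skipped.
#'
#' @param hills hills tibble (columns `cv1`, `cv2`, `sigma_cv1`,
#'   `sigma_cv2`, `height`)
#' @param point CV point `c(s1, s2)`
#' @param truncate skip hills beyond 6 sigma (default FALSE: full sum)
#' @return list with `value` (kcal/mol) and `gradient` (length 2)
#' @export
bias_potential_and_force <- function(hills, point, truncate = FALSE) {
  if (is.null(hills) || nrow(hills) == 0) {
    return(list(value = 0, gradient = c(0, 0)))
  }
  d1 <- point[1] - hills$cv1
  d2 <- point[2] - hills$cv2
  keep <- rep(TRUE, nrow(hills))
  if (truncate) {
    keep <- abs(d1) <= 6 * hills$sigma_cv1 & abs(d2) <= 6 * hills$sigma_cv2
  }
  if (!any(keep)) return(list(value = 0, gradient = c(0, 0)))
  d1 <- d1[keep]; d2 <- d2[keep]
  s1 <- hills$sigma_cv1[keep]; s2 <- hills$sigma_cv2[keep]
  g <- hills$height[keep] * exp(-d1^2 / (2 * s1^2) - d2^2 / (2 * s2^2))
  list(value = sum(g),
       gradient = c(sum(-g * d1 / s1^2), sum(-g * d2 / s2^2)))
}

#' One overdamped Langevin step in CV space
#'
#' `x <- x - (dt / gamma) * grad(U + V) + sqrt(2 kB T dt / gamma) * xi`
#' with `xi` standard normal from the current RNG stream. Exposed for
#' unit-level work; production runs use [run_pt_metad()].
#'
#' @param state list with `coordinates` (length 2) and `temperature` (K)
#' @param potential a `model_potential`
#' @param hills hills tibble (may be empty / NULL)
#' @param params an `engine_params`
#' @return updated state (with `potential_energy` refreshed)
#' @export
langevin_step <- function(state, potential, hills, params) {
  g <- model_gradient(potential, state$coordinates)
  b <- bias_potential_and_force(hills, state$coordinates)
  force <- g + b$gradient
  if (any(!is.finite(force))) {
    stop("non-finite force at ", paste(signif(state$coordinates, 6),
                                       collapse = ", "))
  }
  mob <- params$timestep / params$friction
  noise <- sqrt(2 * KB_KCAL * state$temperature * mob) * stats::rnorm(2)
  x <- state$coordinates - mob * force + noise
  state$coordinates <- x
  state$potential_energy <- model_value(potential, x)
  state
}

#' Metropolis exchange probability between two replicas
#'
#' `p = min(1, exp((beta_i - beta_j) * (U_i - U_j)))` where the energies
#' include any static bias terms.
#'
#' @param u_i,u_j biased potential energies, kcal/mol
#' @param t_i,t_j replica temperatures, K
#' @return acceptance probability
#' @export
exchange_probability <- function(u_i, u_j, t_i, t_j) {
  min(1, exp((1 / (KB_KCAL * t_i) - 1 / (KB_KCAL * t_j)) * (u_i - u_j)))
}

#' Attempt a replica exchange
#'
#' Draws against the Metropolis probability; on acceptance the
#' configurations (coordinates and energies) swap while temperatures
#' stay in place.
#'
#' @param replica_i,replica_j lists with `coordinates`,
#'   `potential_energy` (biased, kcal/mol) and `temperature` (K)
#' @return list with `accepted`, `probability`, and the two (possibly
#'   swapped) replicas
#' @export
attempt_exchange <- function(replica_i, replica_j) {
  p <- exchange_probability(replica_i$potential_energy,
                            replica_j$potential_energy,
                            replica_i$temperature, replica_j$temperature)
  accepted <- stats::runif(1) < p
  if (accepted) {
    tmp <- replica_i$coordinates
    replica_i$coordinates <- replica_j$coordinates
    replica_j$coordinates <- tmp
    tmp <- replica_i$potential_energy
    replica_i$potential_energy <- replica_j$potential_energy
    replica_j$potential_energy <- tmp
  }
  list(accepted = accepted, probability = p,
       replica_i = replica_i, replica_j = replica_j)
}

# ---- well-tempered-ensemble preliminary stage -----------------------------

#' Precompute a static potential-energy bias (well-tempered ensemble)
#'
#' Runs a preliminary metadynamics stage in which only the potential
#' energy is biased (1-D well-tempered hills along U), then freezes the
#' accumulated bias into a table applied additively -- never updated --
#' during production. Broadening the energy fluctuations this way raises
#' the replica-exchange acceptance; the `scale` knob lowers the frozen
#' bias to tune the production exchange rate downward.
#'
#' @param potential a `model_potential`
#' @param params an `engine_params`
#' @param n_steps preliminary-stage steps
#' @param energy_range range of potential energies gridded, kcal/mol
#'   (default: found from a short unbiased probe)
#' @param n_bins energy grid size
#' @param sigma_e hill width in energy, kcal/mol
#' @param scale multiplier applied when the table is used (0 disables)
#' @return object of class `wte_bias`: list with `energies`, `bias`,
#'   `scale`
#' @export
precompute_energy_bias <- function(potential, params, n_steps = 20000,
                                   energy_range = NULL, n_bins = 101,
                                   sigma_e = NULL, scale = 1) {
  temps <- params$temperature_ladder
  set.seed(params$seed)
  if (is.null(energy_range)) {
    probe <- run_pt_metad(potential, params, n_steps = 2000,
                          deposit_hills = FALSE, record_stride = 10)
    u <- model_value(potential,
                     as.matrix(probe$replica_traj[, c("s1", "s2")]))
    pad <- 3 * KB_KCAL * max(temps)
    energy_range <- range(u) + c(-pad, pad + 2)
  }
  egrid <- seq(energy_range[1], energy_range[2], length.out = n_bins)
  if (is.null(sigma_e)) sigma_e <- diff(energy_range) / 25
  bias <- numeric(n_bins)
  # one walker per replica temperature, unbiased CV dynamics, hills on U
  states <- lapply(temps, function(tt) {
    list(coordinates = stats::runif(2, 0.2, 0.8), temperature = tt)
  })
  dep <- params$deposition_stride
  for (step in seq_len(n_steps)) {
    for (r in seq_along(states)) {
      states[[r]] <- langevin_step(states[[r]], potential, NULL, params)
    }
    if (step %% dep == 0) {
      u0 <- states[[1]]$potential_energy
      b0 <- stats::approx(egrid, bias, xout = u0, rule = 2)$y
      h <- wt_hill_height(b0, params$w0, params$bias_factor, temps[1])
      bias <- bias + h * exp(-(egrid - u0)^2 / (2 * sigma_e^2))
    }
  }
  structure(list(energies = egrid, bias = bias, scale = scale),
            class = "wte_bias")
}

#' Write / read a frozen energy-bias table (bit-exact round trip)
#' @param wte a `wte_bias`
#' @param path file path
#' @return invisibly `path` (write); a `wte_bias` (read)
#' @export
write_energy_bias <- function(wte, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale %.17g", wte$scale), con)
  writeLines("#! FIELDS energy bias", con)
  writeLines(sprintf("%.17g %.17g", wte$energies, wte$bias), con)
  invisible(path)
}

#' @rdname write_energy_bias
#' @export
read_energy_bias <- function(path) {
  lines <- readLines(path, warn = FALSE)
  scale <- as.numeric(strsplit(lines[1], "\\s+")[[1]][3])
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, col.names = c("energy", "bias"))
  structure(list(energies = df$energy, bias = df$bias, scale = scale),
            class = "wte_bias")
}

# ---- production runs ------------------------------------------------------

#' Run well-tempered parallel-tempering metadynamics
#'
#' In CV-space mode (`system` is a [model_potential()]) the compiled
#' engine propagates one overdamped Langevin walker per ladder
#' temperature directly in `(cv1, cv2)`. Hills are deposited from the
#' lowest-temperature replica every `deposition_stride` steps with the
#' well-tempered height law, the single accumulated bias acts on all
#' replicas, and exchanges alternate even/odd neighbour pairs every
#' `exchange_stride` steps. In structure mode (`system` is an `xstruct`)
#' a coarse bead model with an elastic network moves under bias forces
#' obtained from the contact-map CV gradients by the chain rule.
#'
#' @param system a `model_potential` (CV mode) or `xstruct`
#'   (structure mode)
#' @param params an `engine_params`
#' @param n_steps number of integration steps
#' @param contact_set required in structure mode
#' @param x0 starting CV points, n_replica x 2 (CV mode; default: all
#'   walkers at the first well or at `c(0.5, 0.5)`)
#' @param wte optional `wte_bias` static energy bias (CV mode)
#' @param record_stride steps between recorded frames (default:
#'   deposition stride)
#' @param deposit_hills set `FALSE` for an unbiased PT run
#' @param elastic_cutoff,elastic_k elastic-network parameters
#'   (structure mode), Angstrom and kcal/mol/A^2
#' @param bias_weight scale applied to the CV bias force in structure
#'   mode
#' @return object of class `metad_run` with elements `hills`, `colvar`,
#'   `replica_traj`, `exchange`, `params`
#' @export
run_pt_metad <- function(system, params, n_steps, contact_set = NULL,
                         x0 = NULL, wte = NULL, record_stride = NULL,
                         deposit_hills = TRUE, elastic_cutoff = 8,
                         elastic_k = 2, bias_weight = 1) {
  if (inherits(system, "model_potential")) {
    run_metad_cv(system, params, n_steps, x0, wte, record_stride,
                 deposit_hills)
  } else if (inherits(system, "xstruct")) {
    if (is.null(contact_set)) {
      stop("structure mode requires a contact_set")
    }
    run_metad_structure(system, contact_set, params, n_steps,
                        record_stride, deposit_hills, elastic_cutoff,
                        elastic_k, bias_weight)
  } else stop("system must be a model_potential or an xstruct")
}

default_bias_grid <- function(lo = -0.25, hi = 1.25, spacing = 0.01) {
  n <- round((hi - lo) / spacing) + 1
  list(x0 = lo, dx = spacing, nx = as.integer(n),
       y0 = lo, dy = spacing, ny = as.integer(n))
}

run_metad_cv <- function(potential, params, n_steps, x0, wte,
                         record_stride, deposit_hills) {
  temps <- params$temperature_ladder
  n_rep <- length(temps)
  if (is.null(x0)) {
    start <- if (potential$kind %in% c("gaussian_wells", "double_well_2d",
                                       "triple_well_2d")) {
      potential$parameters$centers[1, ]
    } else c(0.5, 0.5)
    x0 <- matrix(rep(start, each = n_rep), n_rep, 2)
  }
  x0 <- matrix(x0, ncol = 2)
  if (is.null(record_stride)) record_stride <- params$deposition_stride
  wte_list <- if (is.null(wte)) list(bias = NULL) else unclass(wte)
  res <- cpp_metad_run(unclass(potential), x0, temps, params$timestep,
                       params$friction, as.integer(n_steps),
                       params$deposition_stride, params$w0,
                       params$bias_factor, params$sigma,
                       params$exchange_stride, as.integer(record_stride),
                       params$seed, default_bias_grid(), wte_list,
                       isTRUE(deposit_hills))
  hills <- tibble::as_tibble(as.data.frame(res$hills))
  names(hills) <- c("time", "cv1", "cv2", "sigma_cv1", "sigma_cv2",
                    "height", "biasf")
  n_rec <- length(res$rec_time)
  traj <- tibble::tibble(
    time = rep(res$rec_time, times = n_rep),
    replica = rep(seq_len(n_rep), each = n_rec),
    temperature = rep(temps, each = n_rec),
    s1 = as.numeric(res$traj[, , 1]),
    s2 = as.numeric(res$traj[, , 2]))
  colvar <- dplyr::transmute(dplyr::filter(traj, .data$replica == 1),
                             time = .data$time, cv1 = .data$s1,
                             cv2 = .data$s2)
  exch <- tibble::tibble(
    pair = paste(seq_len(max(n_rep - 1, 0)), seq_len(max(n_rep - 1, 0)) + 1,
                 sep = "-"),
    attempts = as.integer(res$exch_attempts),
    accepts = as.integer(res$exch_accepts)) |>
    dplyr::mutate(rate = ifelse(.data$attempts > 0,
                                .data$accepts / .data$attempts, NA_real_))
  structure(list(hills = hills, colvar = colvar, replica_traj = traj,
                 exchange = exch, params = params, mode = "cv",
                 seed = params$seed),
            class = "metad_run")
}

elastic_network <- function(xyz, cutoff) {
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  w <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
  list(i = w[, 1], j = w[, 2], r0 = sqrt(pmax(d2[w], 0)))
}

elastic_gradient <- function(xyz, net, k) {
  dvec <- xyz[net$i, , drop = FALSE] - xyz[net$j, , drop = FALSE]
  r <- sqrt(rowSums(dvec^2))
  pref <- k * (r - net$r0) / pmax(r, 1e-12)
  g <- matrix(0, nrow(xyz), 3)
  contrib <- dvec * pref
  for (m in seq_along(net$i)) {
    g[net$i[m], ] <- g[net$i[m], ] + contrib[m, ]
    g[net$j[m], ] <- g[net$j[m], ] - contrib[m, ]
  }
  g
}

run_metad_structure <- function(template, contact_set, params, n_steps,
                                record_stride, deposit_hills,
                                elastic_cutoff, elastic_k, bias_weight) {
  if (is.null(record_stride)) record_stride <- params$deposition_stride
  set.seed(params$seed)
  xyz <- coords(template)
  net <- elastic_network(xyz, elastic_cutoff)
  temps <- params$temperature_ladder[1]  # single walker at base T
  mob <- params$timestep / params$friction
  noise_pref <- sqrt(2 * KB_KCAL * temps * mob)
  hills <- tibble::tibble(time = numeric(0), cv1 = numeric(0),
                          cv2 = numeric(0), sigma_cv1 = numeric(0),
                          sigma_cv2 = numeric(0), height = numeric(0),
                          biasf = numeric(0))
  frames <- list(); rec_times <- numeric(0); cvrec <- list()
  s <- template
  for (step in seq_len(n_steps)) {
    s <- set_coords(s, xyz)
    cv <- cv_pair(s, contact_set)
    b <- bias_potential_and_force(hills, cv, truncate = TRUE)
    g_bias <- matrix(0, nrow(xyz), 3)
    if (bias_weight != 0 && nrow(hills) > 0 &&
        any(b$gradient != 0)) {
      g_bias <- bias_weight *
        (b$gradient[1] * cv_gradient(s, contact_set, "cv1") +
           b$gradient[2] * cv_gradient(s, contact_set, "cv2"))
    }
    g <- elastic_gradient(xyz, net, elastic_k) + g_bias
    xyz <- xyz - mob * g +
      noise_pref * matrix(stats::rnorm(length(xyz)), nrow(xyz), 3)
    if (deposit_hills && step %% params$deposition_stride == 0) {
      h <- wt_hill_height(b$value, params$w0, params$bias_factor, temps)
      hills <- dplyr::bind_rows(hills, tibble::tibble(
        time = step * params$timestep, cv1 = cv[["cv1"]],
        cv2 = cv[["cv2"]], sigma_cv1 = params$sigma[1],
        sigma_cv2 = params$sigma[2], height = h,
        biasf = params$bias_factor))
    }
    if (step %% record_stride == 0) {
      frames[[length(frames) + 1]] <- xyz
      rec_times <- c(rec_times, step * params$timestep)
      cvrec[[length(cvrec) + 1]] <- cv
    }
  }
  colvar <- tibble::tibble(
    time = rec_times,
    cv1 = vapply(cvrec, `[[`, numeric(1), "cv1"),
    cv2 = vapply(cvrec, `[[`, numeric(1), "cv2"))
  traj <- new_trajectory(template, frames, times = rec_times)
  structure(list(hills = hills, colvar = colvar, trajectory = traj,
                 exchange = NULL, params = params, mode = "structure",
                 seed = params$seed),
            class = "metad_run")
}

#' @export
print.metad_run <- function(x, ...) {
  cat("<PT-metaD run>", x$mode, "mode,", nrow(x$hills), "hills,",
      if (!is.null(x$exchange)) {
        paste0("mean exchange rate ",
               signif(mean(x$exchange$rate, na.rm = TRUE), 3))
      } else "", "\n")
  invisible(x)
}

#' Tune a temperature ladder to a target exchange rate
#'
#' Adjusts the geometric spacing of the ladder by short pilot runs until
#' the mean neighbour acceptance falls within `tol` of `target`.
#'
#' @param potential a `model_potential`
#' @param params starting `engine_params`
#' @param target target mean acceptance (default 0.30)
#' @param tol tolerance (default 0.05)
#' @param pilot_steps steps per pilot run
#' @param max_iter maximum bisection iterations
#' @return an `engine_params` with the tuned ladder
#' @export
tune_temperature_ladder <- function(potential, params, target = 0.30,
                                    tol = 0.05, pilot_steps = 20000,
                                    max_iter = 12) {
  t_min <- params$temperature_ladder[1]
  n_rep <- length(params$temperature_ladder)
  rate_for <- function(ratio) {
    ladder <- t_min * ratio^(seq_len(n_rep) - 1)
    p <- params; p$temperature_ladder <- ladder
    run <- run_pt_metad(potential, p, n_steps = pilot_steps,
                        deposit_hills = FALSE,
                        record_stride = pilot_steps)
    mean(run$exchange$rate, na.rm = TRUE)
  }
  lo <- 1.0005; hi <- 1.6
  ratio <- (params$temperature_ladder[n_rep] / t_min)^(1 / (n_rep - 1))
  for (it in seq_len(max_iter)) {
    r <- rate_for(ratio)
    if (abs(r - target) <= tol) break
    if (r > target) lo <- ratio else hi <- ratio  # wider spacing lowers rate
    ratio <- sqrt(lo * hi)
  }
  params$temperature_ladder <- t_min * ratio^(seq_len(n_rep) - 1)
  params
}

# ---- HILLS interchange ----------------------------------------------------

#' Write hills in a PLUMED-compatible layout
#'
#' Header `#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf`,
#' then whitespace-delimited rows.
#'
#' @param hills hills tibble
#' @param path output file
#' @return invisibly, `path`
#' @export
write_hills <- function(hills, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf", con)
  writeLines(sprintf("%.6f %.10g %.10g %.10g %.10g %.10g %.10g",
                     hills$time, hills$cv1, hills$cv2, hills$sigma_cv1,
                     hills$sigma_cv2, hills$height, hills$biasf), con)
  invisible(path)
}

#' Read a HILLS file written by [write_hills()] (or PLUMED, matching
#' column names)
#' @param path input file
#' @return hills tibble
#' @export
read_hills <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^#! FIELDS", lines[1])) stop("missing HILLS FIELDS header")
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[1])), "\\s+")[[1]]
  body <- lines[!grepl("^#", lines)]
  tibble::as_tibble(utils::read.table(text = body, col.names = fields))
}
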