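#' Harmonic spring energy and forces
#'
#' `E = 1/2 * k * (|r_ij| - r0)^2` with forces along the bead-bead axis,
#' equal and opposite.
#'
#' @param pos_i,pos_j 2-D coordinates of the two beads.
#' @param stiffness spring constant `k` (energy/length^2).
#' @param rest_length rest length `r0` (> 0).
#' @return A list with `energy`, `force_i`, `force_j`.
#' @examples
#' spring_energy_force(c(0, 0), c(2, 0), stiffness = 1, rest_length = 1)
#' @export
spring_energy_force <- function(pos_i, pos_j, stiffness, rest_length) {
  d <- pos_i - pos_j
  r <- sqrt(sum(d * d))
  if (r < 1e-12) stop("degenerate geometry: coincident beads", call. = FALSE)
  e <- 0.5 * stiffness * (r - rest_length)^2
  f <- -stiffness * (r - rest_length) / r * d
  list(energy = e, force_i = f, force_j = -f)
}

#' Discrete bending energy and forces
#'
#' `E = kappa00 * (1 - cos(theta - theta0))` where `theta` is the angle at
#' the middle bead `j` between the arms to `i` and `k`.  For straight
#' preferred angles (`theta0 = pi`, the default used on all rings and
#' filaments) the energy is orientation-independent.  The three forces sum to
#' zero and exert no net torque.
#'
#' @param pos_i,pos_j,pos_k 2-D coordinates; `j` is the vertex.
#' @param stiffness bending stiffness (energy units).
#' @param theta0 preferred angle in radians.
#' @return A list with `energy`, `force_i`, `force_j`, `force_k`, `theta`.
#' @export
bending_energy_force <- function(pos_i, pos_j, pos_k, stiffness, theta0 = pi) {
  u <- pos_i - pos_j
  v <- pos_k - pos_j
  u2 <- sum(u * u)
  v2 <- sum(v * v)
  if (u2 < 1e-24 || v2 < 1e-24)
    stop("degenerate geometry: coincident beads in angle", call. = FALSE)
  th <- atan2(u[1] * v[2] - u[2] * v[1], sum(u * v))
  e <- stiffness * (1 - cos(th - theta0))
  dEdth <- stiffness * sin(th - theta0)
  f_i <- dEdth * c(-u[2], u[1]) / u2
  f_k <- dEdth * c(v[2], -v[1]) / v2
  list(energy = e, force_i = f_i, force_j = -(f_i + f_k), force_k = f_k,
       theta = th)
}

#' Membrane-actin attraction energy and radial force
#'
#' The cortical-adhesion potential applied to membrane x actin bead pairs: a
#' WCA repulsive core (strength `eps_rep`, independent of `U3`) plus an
#' attractive tail of depth `U3` that is flat below the minimum at
#' `2^(1/6) sigma` and follows a Lennard-Jones profile out to `r_cut_attr`,
#' shifted so the energy is continuous (zero) at the cutoff.  The minimum
#' value is `-U3 * (1 - s)` with the small cutoff shift `s`; at `U3 = 0` only
#' the repulsive branch below `2^(1/6) sigma` remains.
#'
#' @param distance bead-bead distance (> 0); may be a vector.
#' @param U3 well depth (>= 0).
#' @param sigma bead diameter.
#' @param r_cut_attr cutoff distance.
#' @param eps_rep repulsive-core strength.
#' @return A list with `energy` and `force` (the radial force
#'   `-dE/d(distance)`, positive = repulsive), each the length of `distance`.
#' @export
attraction_energy_force <- function(distance, U3, sigma = 1, r_cut_attr = 2.5,
                                    eps_rep = 1) {
  if (any(distance <= 0))
    stop("degenerate geometry: non-positive distance", call. = FALSE)
  rep_part <- excluded_volume_energy_force(distance, sigma, eps_rep)
  rmin <- 2^(1 / 6) * sigma
  sc6 <- (sigma / r_cut_attr)^6
  vshift <- 4 * U3 * (sc6^2 - sc6)
  e <- numeric(length(distance))
  f <- numeric(length(distance))
  flat <- distance < rmin
  tail <- distance >= rmin & distance < r_cut_attr
  e[flat] <- -U3 - vshift
  if (any(tail)) {
    s6 <- (sigma / distance[tail])^6
    e[tail] <- 4 * U3 * (s6^2 - s6) - vshift
    f[tail] <- 24 * U3 * (2 * s6^2 - s6) / distance[tail]
  }
  list(energy = rep_part$energy + e, force = rep_part$force + f)
}

#' Excluded-volume (WCA) energy and radial force
#'
#' Purely repulsive truncated-shifted Lennard-Jones: zero at and beyond
#' `2^(1/6) sigma`, strictly repulsive below.
#'
#' @inheritParams attraction_energy_force
#' @param eps repulsion strength.
#' @return A list with `energy` and `force` (radial, `-dE/d(distance)`).
#' @export
excluded_volume_energy_force <- function(distance, sigma = 1, eps = 1) {
  if (any(distance <= 0))
    stop("degenerate geometry: non-positive distance", call. = FALSE)
  rmin <- 2^(1 / 6) * sigma
  e <- numeric(length(distance))
  f <- numeric(length(distance))
  in_ <- distance < rmin
  if (any(in_)) {
    s6 <- (sigma / distance[in_])^6
    e[in_] <- 4 * eps * (s6^2 - s6) + eps
    f[in_] <- 24 * eps * (2 * s6^2 - s6) / distance[in_]
  }
  list(energy = e, force = f)
}

state_pairpars <- function(params) {
  list(sigma = params$sigma, eps_rep = params$eps_rep, U3 = params$U3,
       r_cut_attr = params$r_cut_attr,
       attract_heads_only = params$attract_heads_only)
}

state_to_cpp <- function(state) {
  b <- state$bonds
  a <- state$angles
  list(
    roles = role_codes(state$roles),
    bonds = list(i = as.integer(b$i) - 1L, j = as.integer(b$j) - 1L,
                 rest_length = as.numeric(b$rest_length),
                 stiffness = as.numeric(b$stiffness),
                 kind = kind_codes(b$kind)),
    angles = list(i = as.integer(a$i) - 1L, j = as.integer(a$j) - 1L,
                  k = as.integer(a$k) - 1L, theta0 = as.numeric(a$theta0),
                  stiffness = as.numeric(a$stiffness))
  )
}

#' Total potential energy of a cell state
#'
#' Sums harmonic bond energies, discrete bending energies, membrane-actin
#' attraction (core + tail, over membrane x actin pairs within the cutoff)
#' and excluded-volume WCA repulsion (all other non-bonded pairs).  Directly
#' bonded pairs are excluded from non-bonded terms.
#'
#' @param state a `cell_state`.
#' @param params a [sim_params()] object.
#' @param method `"cell"` for the cell-list accelerated pair enumeration or
#'   `"brute"` for the O(n^2) path (identical results; useful for checking).
#' @return An object of class `energy_breakdown`: list with `spring`,
#'   `bending`, `attraction`, `excluded_volume`, `total`.
#' @export
total_energy <- function(state, params, method = c("cell", "brute")) {
  method <- match.arg(method)
  cs <- state_to_cpp(state)
  res <- forces_energy_cpp(state$positions, cs$roles, cs$bonds, cs$angles,
                           state_pairpars(params), method == "brute")
  out <- res[c("spring", "bending", "attraction", "excluded_volume", "total")]
  class(out) <- "energy_breakdown"
  out
}

#' Total forces on every bead
#'
#' @inheritParams total_energy
#' @return An `n x 2` matrix of forces (the negative gradient of
#'   [total_energy()] with respect to positions).
#' @export
total_forces <- function(state, params, method = c("cell", "brute")) {
  method <- match.arg(method)
  cs <- state_to_cpp(state)
  res <- forces_energy_cpp(state$positions, cs$roles, cs$bonds, cs$angles,
                           state_pairpars(params), method == "brute")
  res$forces
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy breakdown (kT):\n")
  for (f in c("spring", "bending", "attraction", "excluded_volume", "total"))
    cat(sprintf("  %-16s %.6g\n", f, x[[f]]))
  invisible(x)
}
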