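# Shared fixtures and independent oracles for the test suite.

# small, fast parameter set used throughout
small_params <- function(...) fixture_params("small", ...)

# a bare membrane-ring state (no nucleus, no filaments) whose radial profile
# is fully controlled by the caller: radii[i] is the distance of ring bead i
# from the origin, beads at equal angles.  Useful for morphometrics tests.
ring_state <- function(radii, stiffness = 100) {
  n <- length(radii)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(radii * cos(ang), radii * sin(ang))
  bonds <- data.frame(i = seq_len(n), j = c(2:n, 1L),
                      rest_length = 2 * mean(radii) * sin(pi / n),
                      stiffness = stiffness, kind = "membrane",
                      stringsAsFactors = FALSE)
  cell_state(pos, rep("membrane", n), bonds, empty_angles_df())
}

empty_angles_df <- function() {
  data.frame(i = integer(), j = integer(), k = integer(),
             theta0 = numeric(), stiffness = numeric(),
             stringsAsFactors = FALSE)
}

empty_bonds_df <- function() {
  data.frame(i = integer(), j = integer(), rest_length = numeric(),
             stiffness = numeric(), kind = character(),
             stringsAsFactors = FALSE)
}

# rotate/translate positions rigidly
rigid_motion <- function(pos, angle = 0, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(pos %*% t(R), 2, -shift)
}

# Independent O(n^2) oracle for the total energy breakdown: pure R, no
# neighbor lists, built from the exported per-term operations plus its own
# pair logic.  Deliberately mirrors the documented contracts, not the C++
# implementation.
oracle_energy <- function(state, params) {
  pos <- state$positions
  n <- nrow(pos)
  b <- state$bonds
  a <- state$angles
  e_spring <- 0
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      e_spring <- e_spring + spring_energy_force(
        pos[b$i[r], ], pos[b$j[r], ], b$stiffness[r], b$rest_length[r])$energy
    }
  }
  e_bend <- 0
  if (nrow(a) > 0) {
    for (r in seq_len(nrow(a))) {
      e_bend <- e_bend + bending_energy_force(
        pos[a$i[r], ], pos[a$j[r], ], pos[a$k[r], ], a$stiffness[r],
        a$theta0[r])$energy
    }
  }
  bonded <- matrix(FALSE, n, n)
  if (nrow(b) > 0) {
    bonded[cbind(b$i, b$j)] <- TRUE
    bonded[cbind(b$j, b$i)] <- TRUE
  }
  actin_roles <- if (params$attract_heads_only) "actin_head" else
    c("actin_shaft", "actin_head")
  e_attr <- 0
  e_excl <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bonded[i, j]) next
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      pair_roles <- c(state$roles[i], state$roles[j])
      is_attr <- ("membrane" %in% pair_roles) &&
        any(pair_roles %in% actin_roles)
      if (is_attr) {
        e_attr <- e_attr + attraction_energy_force(
          d, params$U3, params$sigma, params$r_cut_attr,
          params$eps_rep)$energy
      } else {
        e_excl <- e_excl + excluded_volume_energy_force(
          d, params$sigma, params$eps_rep)$energy
      }
    }
  }
  list(spring = e_spring, bending = e_bend, attraction = e_attr,
       excluded_volume = e_excl,
       total = e_spring + e_bend + e_attr + e_excl)
}

# Independent brute-force structural checker used against validate_state
oracle_ring_ok <- function(state, ring) {
  members <- which(state$roles == ring)
  b <- state$bonds[state$bonds$kind == ring, , drop = FALSE]
  deg <- table(factor(c(b$i, b$j), levels = members))
  if (!all(deg == 2)) return(FALSE)
  # breadth-first reachability: one cycle means all members connected
  adj <- split(c(b$j, b$i), c(b$i, b$j))
  seen <- members[1]
  frontier <- members[1]
  while (length(frontier) > 0) {
    nxt <- setdiff(unlist(adj[as.character(frontier)]), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(members)
}
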