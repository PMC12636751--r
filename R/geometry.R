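#' @useDynLib neuritesim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm runif sd setNames
#' @importFrom utils head packageVersion write.table read.table
NULL

ROLE_LEVELS <- c("membrane", "nuclear", "actin_shaft", "actin_head")
BOND_KINDS <- c("membrane", "nuclear", "filament", "anchor")

role_codes <- function(roles) match(roles, ROLE_LEVELS) - 1L
kind_codes <- function(kinds) match(kinds, BOND_KINDS) - 1L

#' Construct a cell state
#'
#' Low-level constructor used by [build_cell()] and by tests that need
#' hand-made states.  Positions are an `n x 2` matrix; `roles` one of
#' `"membrane"`, `"nuclear"`, `"actin_shaft"`, `"actin_head"` per bead;
#' `bonds`/`angles` are data frames with 1-based bead indices.
#'
#' @param positions numeric `n x 2` matrix of bead coordinates.
#' @param roles character vector of bead roles.
#' @param bonds data frame with columns `i`, `j`, `rest_length`, `stiffness`,
#'   `kind`.
#' @param angles data frame with columns `i`, `j`, `k`, `theta0`, `stiffness`.
#' @param filament_id integer filament membership (`NA` for ring beads).
#' @param time simulation time of the state.
#' @param rng_state serialized RNG state (opaque; may be `NULL`).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(positions, roles, bonds, angles,
                       filament_id = rep(NA_integer_, nrow(positions)),
                       time = 0, rng_state = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  stopifnot(ncol(positions) == 2L, nrow(positions) == length(roles))
  s <- list(positions = positions, roles = as.character(roles),
            filament_id = as.integer(filament_id),
            bonds = as.data.frame(bonds), angles = as.data.frame(angles),
            time = as.numeric(time), rng_state = rng_state)
  class(s) <- "cell_state"
  s
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), rest_length = numeric(),
             stiffness = numeric(), kind = character(),
             stringsAsFactors = FALSE)
}

empty_angles <- function() {
  data.frame(i = integer(), j = integer(), k = integer(), theta0 = numeric(),
             stiffness = numeric(), stringsAsFactors = FALSE)
}

ring_bonds <- function(idx, rest, stiffness, kind) {
  n <- length(idx)
  data.frame(i = idx, j = idx[c(2:n, 1L)], rest_length = rest,
             stiffness = stiffness, kind = kind, stringsAsFactors = FALSE)
}

ring_angles <- function(idx, theta0, stiffness) {
  n <- length(idx)
  data.frame(i = idx[c(n, 1:(n - 1L))], j = idx, k = idx[c(2:n, 1L)],
             theta0 = theta0, stiffness = stiffness, stringsAsFactors = FALSE)
}

#' Build the initial coarse-grained cell
#'
#' Places a regular membrane ring of `n_membrane` beads, a concentric nuclear
#' ring of `n_nuclear` beads, and `n_filaments` straight radial actin
#' filaments at equal angular spacing.  Each filament is anchored to its
#' nearest nuclear bead and ends in a head bead positioned at the
#' membrane-attraction minimum (`r_mem - 2^(1/6) sigma`), i.e. within
#' attraction range of the membrane, so that at t = 0 the nuclear envelope is
#' mechanically connected to the plasma membrane through the filaments.
#' Ring bond rest lengths equal the polygon chord (the rings are built
#' unstressed); all preferred bending angles are `pi` (straight), so bending
#' penalizes curvature and acts as an effective membrane tension.
#'
#' @param params a [sim_params()] object.
#' @return A `cell_state` at time 0.
#' @examples
#' cell <- build_cell(fixture_params("small"))
#' nrow(cell$positions)
#' @export
build_cell <- function(params) {
  validate_params(params)
  p <- params
  rr <- ring_radii(p)
  r_mem <- rr$r_mem
  r_nuc <- rr$r_nuc

  ang_m <- 2 * pi * (seq_len(p$n_membrane) - 1L) / p$n_membrane
  ang_n <- 2 * pi * (seq_len(p$n_nuclear) - 1L) / p$n_nuclear
  pos <- rbind(cbind(r_mem * cos(ang_m), r_mem * sin(ang_m)),
               cbind(r_nuc * cos(ang_n), r_nuc * sin(ang_n)))
  roles <- c(rep("membrane", p$n_membrane), rep("nuclear", p$n_nuclear))
  fil_id <- rep(NA_integer_, p$n_membrane + p$n_nuclear)

  chord_m <- 2 * r_mem * sin(pi / p$n_membrane) * (1 - p$membrane_prestrain)
  chord_n <- 2 * r_nuc * sin(pi / p$n_nuclear)
  mem_idx <- seq_len(p$n_membrane)
  nuc_idx <- p$n_membrane + seq_len(p$n_nuclear)
  bonds <- rbind(ring_bonds(mem_idx, chord_m, p$kappa, "membrane"),
                 ring_bonds(nuc_idx, chord_n, p$kappa, "nuclear"))
  angles <- rbind(ring_angles(mem_idx, pi, p$kappa00),
                  ring_angles(nuc_idx, pi, kappa_nuc_eff(p)))

  if (p$n_filaments > 0L) {
    n_mt <- round(p$mt_fraction * p$n_filaments)
    r_head <- r_mem - 2^(1 / 6) * p$sigma
    if (r_head <= r_nuc)
      stop("configuration error: no room for filaments between the rings",
           call. = FALSE)
    bpf <- p$beads_per_filament
    spacing <- (r_head - r_nuc) / bpf
    next_id <- p$n_membrane + p$n_nuclear
    for (f in seq_len(p$n_filaments)) {
      phi <- 2 * pi * (f - 1L) / p$n_filaments
      radii <- r_nuc + spacing * seq_len(bpf)
      fp <- cbind(radii * cos(phi), radii * sin(phi))
      ids <- next_id + seq_len(bpf)
      next_id <- next_id + bpf
      pos <- rbind(pos, fp)
      roles <- c(roles, rep("actin_shaft", bpf - 1L), "actin_head")
      fil_id <- c(fil_id, rep(f, bpf))
      # anchor to the angularly nearest nuclear bead
      danc <- (ang_n - phi + pi) %% (2 * pi) - pi
      anchor <- nuc_idx[which.min(abs(danc))]
      anc_rest <- sqrt(sum((pos[anchor, ] - fp[1L, ])^2))
      bonds <- rbind(bonds, data.frame(
        i = anchor, j = ids[1L], rest_length = anc_rest, stiffness = p$kappa,
        kind = "anchor", stringsAsFactors = FALSE))
      if (bpf >= 2L) {
        bonds <- rbind(bonds, data.frame(
          i = ids[-bpf], j = ids[-1L], rest_length = spacing,
          stiffness = p$kappa, kind = "filament", stringsAsFactors = FALSE))
      }
      if (bpf >= 3L) {
        kf <- p$kappa_fil * if (f <= n_mt) 20 else 1
        angles <- rbind(angles, data.frame(
          i = ids[1:(bpf - 2L)], j = ids[2:(bpf - 1L)], k = ids[3:bpf],
          theta0 = pi, stiffness = kf, stringsAsFactors = FALSE))
      }
    }
  }

  st <- cell_state(pos, roles, bonds, angles, fil_id, time = 0)
  viol <- validate_state(st)
  if (length(viol) > 0L)
    stop("configuration error: built cell fails validation: ",
         paste(viol, collapse = "; "), call. = FALSE)
  st
}

# walk one ring's bonds starting from its lowest-index bead; returns visited
# bead ids in ring order, or NULL if the walk does not close properly
walk_ring <- function(bsub, members) {
  adj <- lapply(setNames(vector("list", length(members)), members), function(x) integer())
  for (r in seq_len(nrow(bsub))) {
    i <- as.character(bsub$i[r]); j <- as.character(bsub$j[r])
    adj[[i]] <- c(adj[[i]], bsub$j[r])
    adj[[j]] <- c(adj[[j]], bsub$i[r])
  }
  if (any(vapply(adj, length, 1L) != 2L)) return(NULL)
  start <- min(members)
  path <- integer(length(members))
  path[1L] <- start
  prev <- -1L
  cur <- start
  for (s in seq_len(length(members) - 1L)) {
    nb <- adj[[as.character(cur)]]
    nxt <- if (nb[1L] == prev) nb[2L] else nb[1L]
    path[s + 1L] <- nxt
    prev <- cur
    cur <- nxt
  }
  nb <- adj[[as.character(cur)]]
  if (!(start %in% nb)) return(NULL)
  if (anyDuplicated(path)) return(NULL)
  path
}

#' Validate a cell state
#'
#' Diagnostic invariant checker: returns a character vector describing every
#' violated structural invariant (empty when the state is valid).  Checked:
#' index sanity of bonds and angles; positive rest lengths and stiffnesses;
#' membrane and nuclear rings each forming one closed cycle (every ring bead
#' in exactly two ring bonds); each filament being a simple anchored chain
#' ending in its head bead; and, for states at time 0, every actin head lying
#' within the attraction cutoff of at least one membrane bead.
#'
#' @param state a `cell_state`.
#' @param r_cut_attr attraction cutoff used for the t = 0 connectivity check.
#' @return Character vector of violations (length 0 if valid). Never mutates
#'   `state`.
#' @export
validate_state <- function(state, r_cut_attr = 2.5) {
  v <- character()
  n <- nrow(state$positions)
  b <- state$bonds
  a <- state$angles
  if (any(!is.finite(state$positions)))
    v <- c(v, "non-finite positions")
  if (nrow(b) > 0L) {
    if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n))
      v <- c(v, "bond index out of range")
    if (any(b$i == b$j)) v <- c(v, "bond connects a bead to itself")
    if (any(b$rest_length <= 0)) v <- c(v, "non-positive bond rest length")
    if (any(b$stiffness <= 0)) v <- c(v, "non-positive bond stiffness")
  }
  if (nrow(a) > 0L) {
    if (any(a$i == a$j | a$j == a$k | a$i == a$k))
      v <- c(v, "angle with repeated beads")
    if (any(a$theta0 <= 0 | a$theta0 >= 2 * pi))
      v <- c(v, "angle theta0 outside (0, 2*pi)")
  }
  for (ring in c("membrane", "nuclear")) {
    members <- which(state$roles == ring)
    bsub <- b[b$kind == ring, , drop = FALSE]
    if (length(members) == 0L) next
    deg <- tabulate(c(bsub$i, bsub$j), nbins = n)
    if (any(deg[members] != 2L) || any(deg[-members] != 0L)) {
      v <- c(v, paste0(ring, " ring: not every ", ring,
                       " bead is in exactly 2 ", ring, " bonds"))
    } else if (is.null(walk_ring(bsub, members))) {
      v <- c(v, paste0(ring, " ring: bonds do not form a single closed cycle"))
    }
  }
  fil_ids <- sort(unique(state$filament_id[!is.na(state$filament_id)]))
  n_heads <- sum(state$roles == "actin_head")
  if (n_heads != length(fil_ids))
    v <- c(v, "head-bead count does not match filament count")
  for (f in fil_ids) {
    members <- which(state$filament_id == f)
    bsub <- b[b$kind == "filament" &
                (b$i %in% members | b$j %in% members), , drop = FALSE]
    anc <- b[b$kind == "anchor" &
               (b$i %in% members | b$j %in% members), , drop = FALSE]
    deg <- tabulate(c(bsub$i, bsub$j), nbins = n)
    heads <- members[state$roles[members] == "actin_head"]
    ok <- length(heads) == 1L && nrow(anc) == 1L &&
      nrow(bsub) == length(members) - 1L
    if (ok && length(members) > 1L) {
      ends <- members[deg[members] == 1L]
      ok <- length(ends) == 2L && all(deg[members] <= 2L) &&
        (heads %in% ends)
    }
    if (!ok) v <- c(v, sprintf("filament %d is not a simple anchored chain ending in its head", f))
  }
  if (isTRUE(all.equal(state$time, 0)) && n_heads > 0L &&
      sum(state$roles == "membrane") > 0L) {
    mem <- state$positions[state$roles == "membrane", , drop = FALSE]
    hd <- state$positions[state$roles == "actin_head", , drop = FALSE]
    for (h in seq_len(nrow(hd))) {
      d2 <- (mem[, 1] - hd[h, 1])^2 + (mem[, 2] - hd[h, 2])^2
      if (min(d2) > r_cut_attr^2) {
        v <- c(v, "an actin head starts outside attraction range of the membrane")
        break
      }
    }
  }
  v
}

#' Perturb bead positions with isotropic Gaussian noise
#'
#' Displaces every coordinate by independent Gaussian noise of standard
#' deviation `magnitude`.  Used to break the perfect rotational symmetry of
#' the built cell so protrusions can nucleate anywhere.  Deterministic given
#' `seed`; topology is untouched.
#'
#' @param state a `cell_state`.
#' @param magnitude noise standard deviation (length units), >= 0.
#' @param seed integer seed.
#' @return A new `cell_state` with displaced positions.
#' @export
perturb_positions <- function(state, magnitude, seed) {
  if (magnitude < 0) stop("argument error: magnitude must be >= 0",
                          call. = FALSE)
  n <- nrow(state$positions)
  out <- state
  if (magnitude > 0) {
    noise <- withr_seed(seed, matrix(rnorm(2L * n, sd = magnitude), ncol = 2L))
    out$positions <- state$positions + noise
  }
  out
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' @export
print.cell_state <- function(x, ...) {
  tab <- table(factor(x$roles, levels = ROLE_LEVELS))
  cat(sprintf("cell_state: %d beads (%s) at t = %g\n", nrow(x$positions),
              paste(sprintf("%d %s", as.integer(tab), names(tab)),
                    collapse = ", "), x$time))
  cat(sprintf("  %d bonds, %d angles\n", nrow(x$bonds), nrow(x$angles)))
  invisible(x)
}
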