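#' Simulation parameters for the bead-spring cell model
#'
#' Collects every model constant into a validated parameter object.  The cell
#' is built from `n_membrane` plasma-membrane beads forming a closed ring,
#' `n_nuclear` nuclear-envelope beads forming a concentric inner ring, and
#' `n_filaments` radial actin filaments of `beads_per_filament` beads each
#' (shaft beads plus one tip "head" bead), so that
#' `n_membrane + n_nuclear + n_filaments * beads_per_filament == n_total`.
#' The defaults (240 + 110 + 14*25) give the canonical 700-bead cell.
#'
#' Reduced units are used throughout: the bead diameter `sigma` sets the
#' length scale, `kT` the energy scale and `gamma` (bead friction) the time
#' scale, so `U3` and `kappa00` are dimensionless well depths/stiffnesses.
#'
#' @param n_total total bead count.
#' @param n_membrane membrane-ring bead count.
#' @param n_nuclear nuclear-ring bead count.
#' @param n_filaments number of radial actin filaments.
#' @param beads_per_filament beads per filament, shaft beads plus one head.
#' @param U3 membrane-actin attraction well depth (cortical tension), >= 0.
#' @param kappa00 membrane bending stiffness (membrane tension/elasticity), >= 0.
#' @param kappa bond spring stiffness (energy/length^2), > 0.
#' @param sigma bead diameter (length unit).
#' @param r_cut_attr attraction cutoff; must exceed the well minimum
#'   `2^(1/6) * sigma`.
#' @param kT thermal energy.
#' @param gamma friction coefficient.
#' @param dt integration timestep (reduced time units).
#' @param n_steps number of integration steps.
#' @param record_every snapshot stride (steps between recorded frames).
#' @param growth_rate per-filament probability per step of a tip growth event.
#' @param growth_increment rest-length increment per growth event.
#' @param max_filament_length cap on a filament's total bond rest length.
#' @param mt_fraction fraction of filaments flagged stiff ("microtubule-like");
#'   flagged filaments have their bending stiffness multiplied by 20.
#' @param seed integer RNG seed.
#' @param kappa_fil filament bending stiffness (energy units).
#' @param kappa_nuc nuclear-ring bending stiffness; `NULL` means "use kappa00".
#' @param eps_rep excluded-volume (WCA) strength.
#' @param attract_heads_only if `TRUE`, only actin head beads (not shaft
#'   beads) feel the membrane attraction.
#' @param init_noise std. dev. of the initial Gaussian position perturbation
#'   applied by [run_simulation()] to break the rotational symmetry.
#' @param r_mem,r_nuc ring radii; `NULL` derives them from bead counts so
#'   neighbouring ring beads sit `~sigma` apart.
#' @param membrane_prestrain fractional shortening of membrane bond rest
#'   lengths relative to the built ring chord, putting the membrane under
#'   resting (cortical-cage) tension `~kappa * prestrain * sigma`.
#' @param verlet_skin neighbor-list skin width (length units).
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [build_cell()], [run_simulation()], [fixture_params()]
#' @examples
#' p <- sim_params(n_steps = 1000)
#' p$n_total
#' @export
sim_params <- function(n_total = 700L,
                       n_membrane = 240L,
                       n_nuclear = 110L,
                       n_filaments = 14L,
                       beads_per_filament = 25L,
                       U3 = 3,
                       kappa00 = 10,
                       kappa = 1000,
                       sigma = 1,
                       r_cut_attr = 2.5,
                       kT = 1,
                       gamma = 1,
                       dt = 1e-4,
                       n_steps = 150000L,
                       record_every = 5000L,
                       growth_rate = 0.0035,
                       growth_increment = 0.05,
                       max_filament_length = 36,
                       mt_fraction = 0,
                       seed = 1L,
                       kappa_fil = 5,
                       kappa_nuc = NULL,
                       eps_rep = 1,
                       attract_heads_only = TRUE,
                       init_noise = 0.05,
                       r_mem = NULL,
                       r_nuc = NULL,
                       membrane_prestrain = 0,
                       verlet_skin = 0.3) {
  p <- list(
    n_total = as.integer(n_total), n_membrane = as.integer(n_membrane),
    n_nuclear = as.integer(n_nuclear), n_filaments = as.integer(n_filaments),
    beads_per_filament = as.integer(beads_per_filament),
    U3 = as.numeric(U3), kappa00 = as.numeric(kappa00),
    kappa = as.numeric(kappa), sigma = as.numeric(sigma),
    r_cut_attr = as.numeric(r_cut_attr), kT = as.numeric(kT),
    gamma = as.numeric(gamma), dt = as.numeric(dt),
    n_steps = as.integer(n_steps), record_every = as.integer(record_every),
    growth_rate = as.numeric(growth_rate),
    growth_increment = as.numeric(growth_increment),
    max_filament_length = as.numeric(max_filament_length),
    mt_fraction = as.numeric(mt_fraction), seed = as.integer(seed),
    kappa_fil = as.numeric(kappa_fil),
    kappa_nuc = if (is.null(kappa_nuc)) NULL else as.numeric(kappa_nuc),
    eps_rep = as.numeric(eps_rep),
    attract_heads_only = isTRUE(attract_heads_only),
    init_noise = as.numeric(init_noise),
    r_mem = if (is.null(r_mem)) NULL else as.numeric(r_mem),
    r_nuc = if (is.null(r_nuc)) NULL else as.numeric(r_nuc),
    membrane_prestrain = as.numeric(membrane_prestrain),
    verlet_skin = as.numeric(verlet_skin)
  )
  class(p) <- "sim_params"
  validate_params(p)
  p
}

#' @rdname sim_params
#' @param p a `sim_params` object.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_membrane + p$n_nuclear + p$n_filaments * p$beads_per_filament !=
      p$n_total) {
    stop("configuration error: bead budget violated: ",
         "n_membrane + n_nuclear + n_filaments*beads_per_filament = ",
         p$n_membrane + p$n_nuclear + p$n_filaments * p$beads_per_filament,
         " but n_total = ", p$n_total, call. = FALSE)
  }
  if (p$n_membrane < 3L) stop("configuration error: need >= 3 membrane beads",
                              call. = FALSE)
  if (p$n_nuclear < 3L) stop("configuration error: need >= 3 nuclear beads",
                             call. = FALSE)
  if (p$n_filaments < 0L || (p$n_filaments > 0L && p$beads_per_filament < 2L))
    stop("configuration error: filaments need >= 2 beads each", call. = FALSE)
  num_nonneg <- c("U3", "kappa00", "kappa_fil", "eps_rep", "kT", "init_noise",
                  "growth_increment", "mt_fraction")
  for (f in num_nonneg)
    if (p[[f]] < 0) stop("configuration error: ", f, " must be >= 0",
                         call. = FALSE)
  if (p$kappa <= 0) stop("configuration error: kappa must be > 0", call. = FALSE)
  if (p$dt <= 0) stop("configuration error: dt must be > 0", call. = FALSE)
  if (p$sigma <= 0) stop("configuration error: sigma must be > 0", call. = FALSE)
  if (p$r_cut_attr <= 2^(1 / 6) * p$sigma)
    stop("configuration error: r_cut_attr must exceed 2^(1/6)*sigma",
         call. = FALSE)
  if (p$membrane_prestrain < 0 || p$membrane_prestrain >= 1)
    stop("configuration error: membrane_prestrain must be in [0, 1)",
         call. = FALSE)
  if (p$growth_rate < 0 || p$growth_rate > 1)
    stop("configuration error: growth_rate must be in [0, 1]", call. = FALSE)
  if (p$n_steps < 0L || p$record_every < 1L)
    stop("configuration error: bad schedule (n_steps, record_every)",
         call. = FALSE)
  rm_ <- if (is.null(p$r_mem)) p$n_membrane * p$sigma / (2 * pi) else p$r_mem
  rn_ <- if (is.null(p$r_nuc)) p$n_nuclear * p$sigma / (2 * pi) else p$r_nuc
  if (rn_ >= rm_)
    stop("configuration error: nuclear radius must be smaller than membrane radius",
         call. = FALSE)
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Bead-spring cell simulation parameters\n")
  cat(sprintf("  beads: %d total (%d membrane + %d nuclear + %d filaments x %d)\n",
              x$n_total, x$n_membrane, x$n_nuclear, x$n_filaments,
              x$beads_per_filament))
  cat(sprintf("  U3 = %g  kappa00 = %g  kappa = %g  kT = %g\n",
              x$U3, x$kappa00, x$kappa, x$kT))
  cat(sprintf("  schedule: %d steps, dt = %g (T = %g), record every %d\n",
              x$n_steps, x$dt, x$n_steps * x$dt, x$record_every))
  cat(sprintf("  growth: rate %g, increment %g, cap %g\n",
              x$growth_rate, x$growth_increment, x$max_filament_length))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# effective ring radii (auto-derived when not set explicitly)
ring_radii <- function(p) {
  list(
    r_mem = if (is.null(p$r_mem)) p$n_membrane * p$sigma / (2 * pi) else p$r_mem,
    r_nuc = if (is.null(p$r_nuc)) p$n_nuclear * p$sigma / (2 * pi) else p$r_nuc
  )
}

# nuclear bending stiffness resolves to kappa00 unless set explicitly
kappa_nuc_eff <- function(p) if (is.null(p$kappa_nuc)) p$kappa00 else p$kappa_nuc

#' Read simulation parameters from a YAML/JSON configuration file
#'
#' The file must contain a flat mapping whose keys mirror [sim_params()]
#' argument names exactly; unknown keys are rejected rather than ignored.
#'
#' @param path path to a YAML (or JSON, a YAML subset) configuration file.
#' @return A `sim_params` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: no such file: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration error: config must be a mapping",
                          call. = FALSE)
  known <- names(formals(sim_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("configuration error: unknown config keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(sim_params, cfg)
}

#' Canonical serialization and digest of parameters
#'
#' Serializes a `sim_params` object to canonical single-line JSON (used in
#' trajectory headers) and computes its MD5 digest for integrity checks.
#'
#' @param p a `sim_params` object.
#' @return `params_json()`: a JSON string; `params_digest()`: an MD5 hex string.
#' @keywords internal
#' @export
params_json <- function(p) {
  q <- unclass(p)
  q$kappa_nuc <- kappa_nuc_eff(p)
  rr <- ring_radii(p)
  q$r_mem <- rr$r_mem
  q$r_nuc <- rr$r_nuc
  as.character(jsonlite::toJSON(q, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' @rdname params_json
#' @export
params_digest <- function(p) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(params_json(p), tf)
  unname(tools::md5sum(tf))
}

params_from_json <- function(txt) {
  cfg <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  known <- names(formals(sim_params))
  do.call(sim_params, cfg[intersect(names(cfg), known)])
}

#' Fixture parameter sets for tests and examples
#'
#' `"small"` is a 60-bead cell (24 membrane + 12 nuclear + 4 filaments x 6)
#' that builds and simulates in well under a second; `"default"` is the
#' canonical 700-bead cell.
#'
#' @param scale `"small"` or `"default"`.
#' @param ... overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
fixture_params <- function(scale = c("small", "default"), ...) {
  scale <- match.arg(scale)
  over <- list(...)
  if (scale == "small") {
    # r_mem widened beyond the auto value so the 6-bead filaments fit
    # between the rings at ~1 sigma spacing
    args <- list(n_total = 60L, n_membrane = 24L, n_nuclear = 12L,
                 n_filaments = 4L, beads_per_filament = 6L, r_mem = 9,
                 n_steps = 2000L, record_every = 200L,
                 max_filament_length = 8)
    args[names(over)] <- over
    do.call(sim_params, args)
  } else {
    do.call(sim_params, over)
  }
}
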