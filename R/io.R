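# Trajectory persistence (native structured-text container), extended-XYZ
# export, and snapshot rendering.
#
# The native format is a versioned plain-text container: a header (bead
# counts, params digest, canonical params JSON, roles, topology), then one
# block per frame holding time, positions and bond rest lengths printed with
# %.17g (lossless double round trip).  Writes are byte-deterministic; the
# reader validates the version, the frame count, and per-frame cardinalities,
# and rejects rather than repairs malformed files.

TRAJ_FORMAT_VERSION <- 1L

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a trajectory in the native text format
#'
#' Lossless, byte-deterministic round trip of positions, roles, topology,
#' per-frame rest lengths, times and parameters.
#'
#' @param trajectory a `trajectory` object.
#' @param path file path.
#' @return `write_trajectory()`: `path`, invisibly. `read_trajectory()`: a
#'   `trajectory` object (per-frame energies are not persisted and read back
#'   as `NULL`).
#' @export
write_trajectory <- function(trajectory, path) {
  st0 <- trajectory$snapshots[[1]]
  n <- nrow(st0$positions)
  b <- st0$bonds
  a <- st0$angles
  con <- file(path, open = "wb")  # binary mode: fixed \n line endings
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con, sep = "\n")
  wl("#neuritesim-trajectory")
  wl(paste("format_version", TRAJ_FORMAT_VERSION))
  wl(paste("n_total", n))
  wl(paste("n_membrane", sum(st0$roles == "membrane")))
  wl(paste("n_nuclear", sum(st0$roles == "nuclear")))
  wl(paste("n_filaments", sum(st0$roles == "actin_head")))
  wl(paste("frame_count", length(trajectory$snapshots)))
  wl(paste("record_every", trajectory$record_every))
  wl(paste("seed", trajectory$wall_metadata$seed))
  wl(paste("package_version", trajectory$wall_metadata$package_version))
  wl(paste("params_digest", params_digest(trajectory$params)))
  wl(paste("params", params_json(trajectory$params)))
  wl(paste("roles", paste(role_codes(st0$roles), collapse = " ")))
  fid <- st0$filament_id
  fid[is.na(fid)] <- 0L
  wl(paste("filament_id", paste(fid, collapse = " ")))
  wl(paste("bonds", nrow(b)))
  wl(paste(b$i, b$j, kind_codes(b$kind), fmt17(b$stiffness)))
  wl(paste("angles", nrow(a)))
  if (nrow(a) > 0L)
    wl(paste(a$i, a$j, a$k, fmt17(a$theta0), fmt17(a$stiffness)))
  for (fr in seq_along(trajectory$snapshots)) {
    st <- trajectory$snapshots[[fr]]
    if (nrow(st$positions) != n)
      stop("corrupt trajectory: frame ", fr, " has ", nrow(st$positions),
           " beads, expected ", n, call. = FALSE)
    wl(paste("frame", fr, fmt17(st$time)))
    wl(paste(fmt17(st$positions[, 1]), fmt17(st$positions[, 2])))
    wl(paste("rest", paste(fmt17(st$bonds$rest_length), collapse = " ")))
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1L || lines[1] != "#neuritesim-trajectory")
    stop("unsupported format: not a neuritesim trajectory file", call. = FALSE)
  cur <- 2L
  hdr <- list()
  take <- function() {
    l <- lines[cur]
    cur <<- cur + 1L
    l
  }
  field <- function(name) {
    l <- take()
    parts <- sub(paste0("^", name, " "), "", l)
    if (identical(parts, l)) stop("corrupt trajectory: expected header field '",
                                  name, "'", call. = FALSE)
    parts
  }
  version <- as.integer(field("format_version"))
  if (version != TRAJ_FORMAT_VERSION)
    stop("unsupported format version ", version, " (reader supports ",
         TRAJ_FORMAT_VERSION, ")", call. = FALSE)
  n <- as.integer(field("n_total"))
  field("n_membrane"); field("n_nuclear"); field("n_filaments")
  frame_count <- as.integer(field("frame_count"))
  record_every <- as.integer(field("record_every"))
  seed <- as.integer(field("seed"))
  pkg_version <- field("package_version")
  digest <- field("params_digest")
  params <- params_from_json(field("params"))
  if (params_digest(params) != digest)
    stop("corrupt trajectory: params digest mismatch", call. = FALSE)
  roles <- ROLE_LEVELS[as.integer(strsplit(field("roles"), " ")[[1]]) + 1L]
  fid <- as.integer(strsplit(field("filament_id"), " ")[[1]])
  fid[fid == 0L] <- NA_integer_
  if (length(roles) != n || length(fid) != n)
    stop("corrupt trajectory: role/filament vectors do not match n_total",
         call. = FALSE)
  parse_rows <- function(count, width, what) {
    m <- matrix(NA_real_, count, width)
    for (r in seq_len(count)) {
      vals <- suppressWarnings(as.numeric(strsplit(take(), " ")[[1]]))
      if (length(vals) != width || anyNA(vals))
        stop("corrupt trajectory: malformed ", what, " record ", r,
             call. = FALSE)
      m[r, ] <- vals
    }
    m
  }
  n_bonds <- as.integer(field("bonds"))
  bm <- parse_rows(n_bonds, 4L, "bond")
  n_angles <- as.integer(field("angles"))
  am <- parse_rows(n_angles, 5L, "angle")
  bonds0 <- data.frame(i = as.integer(bm[, 1]), j = as.integer(bm[, 2]),
                       rest_length = 1, stiffness = bm[, 4],
                       kind = BOND_KINDS[as.integer(bm[, 3]) + 1L],
                       stringsAsFactors = FALSE)
  angles0 <- if (n_angles > 0L)
    data.frame(i = as.integer(am[, 1]), j = as.integer(am[, 2]),
               k = as.integer(am[, 3]), theta0 = am[, 4], stiffness = am[, 5],
               stringsAsFactors = FALSE)
  else empty_angles()
  snapshots <- vector("list", frame_count)
  times <- numeric(frame_count)
  for (fr in seq_len(frame_count)) {
    if (cur > length(lines))
      stop("corrupt trajectory: truncated at frame ", fr, call. = FALSE)
    head_parts <- strsplit(take(), " ")[[1]]
    if (length(head_parts) != 3L || head_parts[1] != "frame" ||
        as.integer(head_parts[2]) != fr)
      stop("corrupt trajectory: bad frame header at frame ", fr, call. = FALSE)
    t_fr <- as.numeric(head_parts[3])
    if (cur + n > length(lines) + 1L)
      stop("corrupt trajectory: truncated positions at frame ", fr,
           call. = FALSE)
    pos_lines <- lines[cur:(cur + n - 1L)]
    cur <- cur + n
    nums <- suppressWarnings(as.numeric(unlist(strsplit(pos_lines, " "))))
    if (length(nums) != 2L * n || anyNA(nums))
      stop("corrupt trajectory: bad bead count or positions at frame ", fr,
           call. = FALSE)
    pm <- matrix(nums, ncol = 2, byrow = TRUE)
    if (nrow(pm) != n || any(is.na(pm)))
      stop("corrupt trajectory: bad bead count or positions at frame ", fr,
           call. = FALSE)
    if (cur > length(lines))
      stop("corrupt trajectory: truncated rest lengths at frame ", fr,
           call. = FALSE)
    rest_line <- take()
    if (!startsWith(rest_line, "rest "))
      stop("corrupt trajectory: missing rest-length block at frame ", fr,
           call. = FALSE)
    rl <- as.numeric(strsplit(sub("^rest ", "", rest_line), " ")[[1]])
    if (length(rl) != n_bonds)
      stop("corrupt trajectory: rest-length count mismatch at frame ", fr,
           call. = FALSE)
    b_fr <- bonds0
    b_fr$rest_length <- rl
    snapshots[[fr]] <- cell_state(pm, roles, b_fr, angles0, fid, time = t_fr)
    times[fr] <- t_fr
  }
  traj <- list(snapshots = snapshots, times = times, energies = NULL,
               record_every = record_every, params = params,
               wall_metadata = list(seed = seed,
                                    package_version = pkg_version))
  class(traj) <- "trajectory"
  traj
}

#' Export a trajectory in extended-XYZ format
#'
#' Interoperability dump: per frame, a bead-count line, a comment line
#' (`Properties=species:S:1:pos:R:3 time=<t>`), then one record per bead
#' with a role label (`M`/`N`/`A`/`H`) and `x y 0` coordinates (z padded for
#' 2-D).  Lossy (positions only, to 1e-8 or better); use the native format
#' for round trips.
#'
#' @param trajectory a `trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_xyz <- function(trajectory, path) {
  labels <- c(membrane = "M", nuclear = "N", actin_shaft = "A",
              actin_head = "H")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (st in trajectory$snapshots) {
    n <- nrow(st$positions)
    writeLines(c(
      as.character(n),
      sprintf("Properties=species:S:1:pos:R:3 time=%s", fmt17(st$time)),
      sprintf("%s %.10f %.10f 0.0", labels[st$roles], st$positions[, 1],
              st$positions[, 2])
    ), con = con, sep = "\n")
  }
  invisible(path)
}

#' Export the per-frame energy breakdown as a delimited table
#'
#' One row per recorded frame: time plus the spring, bending, attraction,
#' excluded-volume and total potential energies (kT).
#'
#' @param trajectory a `trajectory` with recorded energies (as produced by
#'   [run_simulation()]).
#' @param path output path for a tab-separated table.
#' @return `path`, invisibly.
#' @export
write_energies <- function(trajectory, path) {
  if (is.null(trajectory$energies))
    stop("trajectory carries no recorded energies", call. = FALSE)
  tab <- data.frame(time = trajectory$times, trajectory$energies)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a snapshot of the cell
#'
#' Draws the closed membrane outline, the nuclear outline, and every
#' filament (anchor to head).  `.svg` paths are written by a deterministic
#' built-in writer (identical states give byte-identical files; the membrane
#' polyline repeats its first point so the outline closes explicitly); any
#' other extension is rendered through the corresponding grDevices bitmap
#' device (`.png` supported).
#'
#' @param state a `cell_state`.
#' @param path output path (`.svg` or `.png`).
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(state, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") return(render_svg(state, path))
  if (ext != "png") stop("argument error: unsupported image format: ", ext,
                         call. = FALSE)
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  plot_state(state)
  invisible(path)
}

plot_state <- function(state) {
  pos <- state$positions
  ring <- membrane_ring(state)
  graphics::plot(pos[ring, 1], pos[ring, 2], type = "n", asp = 1,
                 xlab = "x [sigma]", ylab = "y [sigma]", main = sprintf(
                   "t = %g", state$time))
  graphics::polygon(pos[ring, 1], pos[ring, 2], border = "black", lwd = 2)
  nuc <- which(state$roles == "nuclear")
  if (length(nuc) >= 3L) {
    nring <- walk_ring(state$bonds[state$bonds$kind == "nuclear", ,
                                   drop = FALSE], nuc)
    if (!is.null(nring))
      graphics::polygon(pos[nring, 1], pos[nring, 2], border = "blue")
  }
  for (f in sort(unique(state$filament_id[!is.na(state$filament_id)]))) {
    members <- which(state$filament_id == f)
    graphics::lines(pos[members, 1], pos[members, 2], col = "red")
    hd <- members[state$roles[members] == "actin_head"]
    graphics::points(pos[hd, 1], pos[hd, 2], pch = 16, col = "red")
  }
}

svg_points <- function(xy) paste(sprintf("%.6f,%.6f", xy[, 1], xy[, 2]),
                                 collapse = " ")

render_svg <- function(state, path) {
  pos <- state$positions
  ring <- membrane_ring(state)
  pad <- 3
  xr <- range(pos[, 1]) + c(-pad, pad)
  yr <- range(pos[, 2]) + c(-pad, pad)
  # SVG y axis points down; flip
  tr <- function(idx) cbind(pos[idx, 1], yr[2] - (pos[idx, 2] - yr[1]))
  lines_out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" viewBox=",
                   "\"%.4f %.4f %.4f %.4f\" width=\"800\" height=\"800\">"),
            xr[1], yr[1], diff(xr), diff(yr)),
    sprintf(paste0("<polyline id=\"membrane\" points=\"%s\" fill=\"none\" ",
                   "stroke=\"black\" stroke-width=\"0.3\"/>"),
            svg_points(tr(c(ring, ring[1L]))))
  )
  nuc <- which(state$roles == "nuclear")
  if (length(nuc) >= 3L) {
    nring <- walk_ring(state$bonds[state$bonds$kind == "nuclear", ,
                                   drop = FALSE], nuc)
    if (!is.null(nring))
      lines_out <- c(lines_out, sprintf(
        paste0("<polyline id=\"nucleus\" points=\"%s\" fill=\"none\" ",
               "stroke=\"blue\" stroke-width=\"0.2\"/>"),
        svg_points(tr(c(nring, nring[1L])))))
  }
  for (f in sort(unique(state$filament_id[!is.na(state$filament_id)]))) {
    members <- which(state$filament_id == f)
    lines_out <- c(lines_out, sprintf(
      paste0("<polyline id=\"filament%d\" points=\"%s\" fill=\"none\" ",
             "stroke=\"red\" stroke-width=\"0.2\"/>"),
      f, svg_points(tr(members))))
    hd <- members[state$roles[members] == "actin_head"]
    hxy <- tr(hd)
    lines_out <- c(lines_out, sprintf(
      "<circle cx=\"%.6f\" cy=\"%.6f\" r=\"0.5\" fill=\"red\"/>",
      hxy[1], hxy[2]))
  }
  lines_out <- c(lines_out, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines_out, con = con, sep = "\n")
  invisible(path)
}
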