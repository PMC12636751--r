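# Parameter-sweep experiments: U3 sweeps at fixed kappa00 and full
# (U3, kappa00) phase diagrams with seeded replicates.
#
# Replicate seeds are derived as seed0 + (condition_index-1)*1e4 + replicate
# (collision-free for any grid with fewer than 1e4 replicates), so every
# replicate owns an independent RNG stream and results do not depend on
# execution order.

SEED_STRIDE <- 10000L

replicate_seed <- function(seed0, cond_idx, rep_idx) {
  as.integer((seed0 + (cond_idx - 1L) * SEED_STRIDE + rep_idx) %% .Machine$integer.max)
}

run_one_condition <- function(base, U3, kappa00, n_replicates, seed0,
                              cond_idx, threshold, window) {
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    p <- base
    p$U3 <- as.numeric(U3)
    p$kappa00 <- as.numeric(kappa00)
    p$seed <- replicate_seed(seed0, cond_idx, r)
    validate_params(p)
    res <- tryCatch({
      traj <- run_simulation(p)
      m <- analyze_trajectory(traj, threshold = threshold, window = window)
      data.frame(U3 = p$U3, kappa00 = p$kappa00, replicate = r, seed = p$seed,
                 max_projection_length = m$max_projection_length,
                 stability = m$stability,
                 final_protrusion_count =
                   m$per_frame$protrusion_count[nrow(m$per_frame)],
                 failed = FALSE)
    }, error = function(e) {
      if (!grepl("numerical instability", conditionMessage(e)))
        stop(e)
      warning(sprintf("replicate %d of condition (U3=%g, kappa00=%g) failed: %s",
                      r, U3, kappa00, conditionMessage(e)), call. = FALSE)
      data.frame(U3 = as.numeric(U3), kappa00 = as.numeric(kappa00),
                 replicate = r, seed = p$seed,
                 max_projection_length = NA_real_, stability = NA_real_,
                 final_protrusion_count = NA_integer_, failed = TRUE)
    })
    reps[[r]] <- res
  }
  out <- do.call(rbind, reps)
  if (all(out$failed))
    stop(sprintf("all replicates failed for condition (U3=%g, kappa00=%g)",
                 U3, kappa00), call. = FALSE)
  out
}

new_sweep_result <- function(conditions, per_replicate) {
  out <- list(conditions = conditions, per_replicate = per_replicate,
              summary = summarize_sweep_table(per_replicate))
  class(out) <- "sweep_result"
  out
}

#' Sweep the membrane-actin attraction U3 at fixed kappa00
#'
#' Runs `n_replicates` independently seeded simulations for every value of
#' `U3` in `u3_values`, holding the membrane bending stiffness fixed at
#' `kappa00_fixed`, and collects per-replicate morphometrics.  Deterministic
#' given `seed0`.  Replicates aborting with a numerical-instability error are
#' recorded as failed (with a warning) and excluded from summaries; a
#' condition whose replicates all fail is an error.
#'
#' @param base a [sim_params()] object providing everything but U3/kappa00.
#' @param u3_values numeric vector of U3 values (non-empty).
#' @param kappa00_fixed the fixed membrane bending stiffness.
#' @param n_replicates replicates per condition (>= 1).
#' @param seed0 master seed.
#' @param threshold protrusion threshold passed to [analyze_trajectory()]
#'   (length units).  The default, 2 bead diameters of radial excess, detects
#'   neurite-scale protrusions without counting thermal roughness.
#' @param window stability window (frames); `NULL` = final 25% of frames.
#' @return A `sweep_result`: list with `conditions` (data frame of U3,
#'   kappa00), `per_replicate` (one row per replicate) and `summary`
#'   (per-condition mean/SD/SEM of max projection length, mean stability).
#' @export
sweep_u3 <- function(base, u3_values, kappa00_fixed, n_replicates = 10L,
                     seed0 = 1L, threshold = 2, window = NULL) {
  stopifnot(length(u3_values) >= 1L, n_replicates >= 1L)
  conditions <- data.frame(U3 = as.numeric(u3_values),
                           kappa00 = as.numeric(kappa00_fixed))
  per <- vector("list", nrow(conditions))
  for (ci in seq_len(nrow(conditions))) {
    per[[ci]] <- run_one_condition(base, conditions$U3[ci],
                                   conditions$kappa00[ci], n_replicates,
                                   seed0, ci, threshold, window)
  }
  new_sweep_result(conditions, do.call(rbind, per))
}

#' Two-parameter (U3, kappa00) phase diagram
#'
#' Full factorial sweep over `u3_grid` x `kappa00_grid` with the same
#' contracts as [sweep_u3()] (U3 varies fastest).  A 1x1 grid is identical to
#' [sweep_u3()] with a single value.
#'
#' @inheritParams sweep_u3
#' @param u3_grid,kappa00_grid non-empty numeric grids.
#' @return A `sweep_result`.
#' @export
phase_diagram <- function(base, u3_grid, kappa00_grid, n_replicates = 10L,
                          seed0 = 1L, threshold = 2, window = NULL) {
  stopifnot(length(u3_grid) >= 1L, length(kappa00_grid) >= 1L,
            n_replicates >= 1L)
  conditions <- expand.grid(U3 = as.numeric(u3_grid),
                            kappa00 = as.numeric(kappa00_grid),
                            KEEP.OUT.ATTRS = FALSE)
  per <- vector("list", nrow(conditions))
  for (ci in seq_len(nrow(conditions))) {
    per[[ci]] <- run_one_condition(base, conditions$U3[ci],
                                   conditions$kappa00[ci], n_replicates,
                                   seed0, ci, threshold, window)
  }
  new_sweep_result(conditions, do.call(rbind, per))
}

summarize_sweep_table <- function(per_replicate) {
  ok <- per_replicate[!per_replicate$failed, , drop = FALSE]
  split_by <- interaction(per_replicate$U3, per_replicate$kappa00,
                          drop = TRUE, lex.order = TRUE)
  keys <- unique(per_replicate[, c("U3", "kappa00")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    s <- ok[ok$U3 == keys$U3[i] & ok$kappa00 == keys$kappa00[i], ,
            drop = FALSE]
    x <- s$max_projection_length
    data.frame(U3 = keys$U3[i], kappa00 = keys$kappa00[i], n = nrow(s),
               mean_max_projection = mean(x),
               sd_max_projection = if (nrow(s) > 1L) sd(x) else NA_real_,
               sem_max_projection = if (nrow(s) > 1L) sd(x) / sqrt(nrow(s))
                                    else NA_real_,
               mean_stability = mean(s$stability),
               mean_final_protrusions = mean(s$final_protrusion_count))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-condition summary of a sweep
#'
#' Mean, SD, SEM (`SD/sqrt(n)`) and n of max projection length per condition,
#' plus mean stability and mean final protrusion count, over successful
#' replicates.
#'
#' @param result a `sweep_result`.
#' @return A data frame, one row per condition.
#' @export
summarize_sweep <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  if (any(tapply(result$per_replicate$failed,
                 interaction(result$per_replicate$U3,
                             result$per_replicate$kappa00), all)))
    stop("a condition has no successful replicates", call. = FALSE)
  summarize_sweep_table(result$per_replicate)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d condition(s) x %d replicate(s)\n",
              nrow(x$conditions),
              nrow(x$per_replicate) / nrow(x$conditions)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write sweep tables to disk
#'
#' Writes the tidy per-replicate table (one row per replicate) and the
#' per-condition summary as tab-separated files.
#'
#' @param result a `sweep_result`.
#' @param replicates_path,summary_path output paths.
#' @return `invisible(NULL)`.
#' @export
write_sweep <- function(result, replicates_path, summary_path) {
  write.table(result$per_replicate, replicates_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$summary, summary_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}
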