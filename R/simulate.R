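#' Simulation configuration
#'
#' Bundles the lattice, transport, depolymerization and kinetic parameters with
#' the run controls. The default run emulates a 50 x 50 um chamber (1 um sites)
#' observed for 20 h, in the low-density low-activity corner of the parameter
#' plane (`rho = 0.1` cells/um^2, `K_enz = 0.1` 1/h).
#'
#' @param spec a [lattice_spec()].
#' @param transport a [transport_params()].
#' @param depoly a [depoly_params()].
#' @param kinetics a [kinetic_params()].
#' @param rho initial cell density (cells/um^2).
#' @param duration total simulated time (h, > 0). Default 20 h.
#' @param dt macro time step (h, > 0). Default 0.01 h (see the methods
#'   vignette for the step-size convergence check).
#' @param seed integer seed for cell placement.
#' @param snapshot_times times (h) at which field snapshots are kept; must lie
#'   within `[0, duration]`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(spec = lattice_spec(), transport = transport_params(),
                       depoly = depoly_params(), kinetics = kinetic_params(),
                       rho = 0.1, duration = 20, dt = 0.01, seed = 1L,
                       snapshot_times = numeric(0)) {
  stopifnot(inherits(spec, "lattice_spec"),
            inherits(transport, "transport_params"),
            inherits(depoly, "depoly_params"),
            inherits(kinetics, "kinetic_params"))
  if (!is.finite(duration) || duration <= 0) stop("sim_config: duration must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("sim_config: dt must be > 0")
  if (length(snapshot_times) && (any(snapshot_times < 0) ||
                                 any(snapshot_times > duration)))
    stop("sim_config: snapshot times must lie within [0, duration]")
  structure(list(spec = spec, transport = transport, depoly = depoly,
                 kinetics = kinetics, rho = rho, duration = duration, dt = dt,
                 seed = as.integer(seed),
                 snapshot_times = sort(unique(snapshot_times))),
            class = "sim_config")
}

# Semi-implicit coupled stepper: one backward-Euler solve per field per step,
# with the linearized reaction sink (and secretion source) inside the system
# matrix, so the per-step solution sits on the correct quasi-steady allocation
# of each field between transport, boundary loss, and reaction at any dt.
# (Pure operator splitting misallocates by O(k_loss * dt), which is not small
# here; see the methods vignette.)
make_coupled_stepper <- function(spec, transport, dt) {
  parts <- laplacian_parts(spec)
  n <- nrow(parts$L)
  h2 <- spec$spacing^2
  mk <- function(D) {
    A <- Matrix::forceSymmetric(
      Matrix::Diagonal(n) + (D * dt / h2) * parts$L + Matrix::Diagonal(n, 1))
    # locate the diagonal entries inside the CSC slot once, so per-step sink
    # updates touch @x in place
    A <- methods::as(A, "CsparseMatrix")
    dp <- integer(n)
    p <- A@p; i <- A@i
    for (col in seq_len(n)) {
      idx <- (p[col] + 1L):p[col + 1L]
      dp[col] <- idx[which(i[idx] == col - 1L)]
    }
    base_x <- A@x
    base_x[dp] <- base_x[dp] - 1 # remove the probe diagonal
    A@x <- base_x
    list(A = A, diag_pos = dp, base_diag = A@x[dp],
         fac = Matrix::Cholesky(A, LDL = FALSE, perm = TRUE),
         alpha_b = (D * dt / h2) * parts$nb_dirichlet)
  }
  ops <- list()
  for (f in c("P", "E", "O"))
    ops[[f]] <- mk(transport[[paste0("D_", f)]] * transport$D_rel)
  list(parts = parts, ops = ops, dt = dt, h2 = h2, n = n)
}

# One coupled BE solve: (I + dt D L + dt diag(sink)) u = u_old + dt * source
# + boundary term. Returns the new interior field vector.
coupled_solve <- function(st, f, u_old, sink, source, bval) {
  op <- st$ops[[f]]
  if (any(sink != 0)) {
    A <- op$A
    A@x[op$diag_pos] <- op$base_diag + st$dt * sink
    fac <- Matrix::update(op$fac, A)
  } else fac <- op$fac
  rhs <- u_old + st$dt * source + op$alpha_b * bval
  as.numeric(Matrix::solve(fac, rhs, system = "A"))
}

#' Run one chamber simulation
#'
#' Time loop from `t = 0` to `duration`: per macro step, each field is
#' advanced by one backward-Euler solve coupling diffusion with its linearized
#' reaction term (enzyme secretion source; depolymerization sink on the
#' polymer, its product as the oligomer source; Monod uptake sink at occupied
#' sites), with rate coefficients frozen over the step. Biomass then grows by
#' the yield times the implicit uptake. This resolves the competition between
#' uptake and boundary washout at any step size (see the methods vignette for
#' why pure operator splitting does not). The run is deterministic for a fixed
#' seed.
#'
#' @param cfg a [sim_config()].
#' @param quiet suppress the end-of-run clipping note.
#' @return An object of class `chamber_run`: the final `fields`, requested
#'   `snapshots`, the cell population `pop`, per-cell instantaneous growth
#'   rates at the final step (`mu_final`), per-cell time-averaged rates
#'   (`mu_timeavg`, `log(B_T/B_0)/T`), the population-mean growth rate time
#'   series `mu_mean_ts`, the per-step depolymerized mass `depol_ts`, and the
#'   chamber-mean interior oligomer concentration at the end (`mean_O`).
#' @export
run_chamber <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  n_steps <- round(cfg$duration / cfg$dt)
  if (abs(n_steps * cfg$dt - cfg$duration) > 1e-9 * cfg$duration)
    n_steps <- ceiling(cfg$duration / cfg$dt)
  spec <- cfg$spec; kin <- cfg$kinetics; dp <- cfg$depoly; dt <- cfg$dt
  fields <- make_fields(spec)
  pop <- place_cells(spec, cfg$rho, cfg$seed)
  st <- make_coupled_stepper(spec, cfg$transport, dt)
  unknown <- st$parts$unknown
  full2int <- integer(spec$n_rows * spec$n_cols)
  full2int[which(unknown)] <- seq_len(st$n)
  cell_pos <- full2int[pop$sites]
  P <- fields$P[unknown]; E <- fields$E[unknown]; O <- fields$O[unknown]
  src_E <- numeric(st$n); zero <- numeric(st$n)
  u_cap <- (kin$mu_max / kin$Y) * kin$b_conv * dt # Monod ceiling per biomass
  mu_mean_ts <- numeric(n_steps)
  depol_ts <- numeric(n_steps)
  mu <- numeric(length(pop$sites))
  clip_dep <- 0; clip_upt <- 0
  snap_steps <- round(cfg$snapshot_times / dt)
  pack <- function() {
    f <- fields
    f$P[unknown] <- P; f$E[unknown] <- E; f$O[unknown] <- O
    f
  }
  snapshots <- list()
  if (any(snap_steps == 0)) snapshots[[sprintf("t%0.4g", 0)]] <- pack()
  for (s in seq_len(n_steps)) {
    # enzyme: diffusion with the secretion source
    if (length(cell_pos)) src_E[cell_pos] <- kin$K_enz * pop$B
    E <- coupled_solve(st, "E", E, zero, src_E, spec$boundary[["E"]])
    # polymer: diffusion with the linearized depolymerization sink; the mass
    # removed by the sink, dt * s_P * P_new, is exactly the oligomer source
    s_P <- dp$k_cat * E / (dp$K_P + P)
    if (any(s_P > 0))
      clip_dep <- max(clip_dep, mean(s_P[s_P > 0] * dt > 1))
    P <- coupled_solve(st, "P", P, s_P, zero, spec$boundary[["P"]])
    depol_site <- dt * s_P * P
    depol_ts[s] <- sum(depol_site)
    # oligomer: diffusion + Monod uptake sink at occupied sites + source
    s_O <- zero
    if (length(cell_pos)) {
      s_O[cell_pos] <- (kin$mu_max / kin$Y) * kin$b_conv * pop$B /
        (kin$K_m + O[cell_pos])
      clip_upt <- max(clip_upt, mean(s_O[cell_pos] * dt > 1))
    }
    O <- coupled_solve(st, "O", O, s_O, dp$conv * depol_site / dt,
                       spec$boundary[["O"]])
    if (any(!is.finite(O)))
      stop(sprintf("run_chamber: instability (non-finite field) at step %d, dt = %g",
                   s, dt))
    if (length(cell_pos)) {
      u_raw <- dt * s_O[cell_pos] * O[cell_pos]
      U <- pmin(u_raw, u_cap * pop$B)
      # return any Monod-ceiling excess to the field so mass stays exact
      O[cell_pos] <- O[cell_pos] + (u_raw - U)
      dB <- kin$Y * U / kin$b_conv
      mu <- dB / (pop$B * dt)
      pop$B <- pop$B + dB
      pop$uptake <- pop$uptake + U
    }
    mu_mean_ts[s] <- if (length(mu)) mean(mu) else 0
    if (s %in% snap_steps)
      snapshots[[sprintf("t%0.4g", s * dt)]] <- pack()
  }
  if (!quiet && (clip_dep > 0.1 || clip_upt > 0.1))
    message(sprintf(
      "run_chamber: linearized reaction rates exceeded 1/dt on up to %.0f%% (depolymerization) / %.0f%% (uptake) of active sites",
      100 * clip_dep, 100 * clip_upt))
  fields <- pack()
  mask <- interior_mask(spec)
  structure(list(
    config = cfg, fields = fields, snapshots = snapshots, pop = pop,
    mu_final = mu,
    mu_timeavg = if (length(pop$B)) log(pop$B / 1) / cfg$duration else numeric(0),
    mu_mean_ts = mu_mean_ts, depol_ts = depol_ts,
    mean_O = mean(fields$O[mask]),
    depol_rate = sum(depol_ts) / cfg$duration,
    max_clipped = c(depoly = clip_dep, uptake = clip_upt)),
    class = "chamber_run")
}

#' Population-mean growth rate of a finished run
#'
#' @param run a [run_chamber()] result.
#' @param type `"instantaneous"` (mean of per-cell rates at the final step,
#'   the reported observable) or `"timeavg"` (mean of per-cell
#'   `log(B_T/B_0)/T`).
#' @return Mean specific growth rate (1/h); 0 for an empty chamber.
#' @export
mean_growth_rate <- function(run, type = c("instantaneous", "timeavg")) {
  stopifnot(inherits(run, "chamber_run"))
  type <- match.arg(type)
  v <- if (type == "instantaneous") run$mu_final else run$mu_timeavg
  if (!length(v)) 0 else mean(v)
}

condition_seed <- function(base_seed, i, j = 0L) {
  (as.integer(base_seed) + 1009L * as.integer(i) + 13L * as.integer(j)) %% 2147483647L
}

#' Sweep cell density and enzymatic activity
#'
#' Runs one chamber per (rho, K_enz) grid point and records the population-mean
#' growth rate at the end of the run, the cumulative depolymerization rate, and
#' the chamber-mean oligomer concentration. Growth rates are additionally
#' normalized by the maximum over the full grid. Per-condition seeds are
#' derived deterministically from the base seed and the grid indices, so
#' reordering grid points does not change any value.
#'
#' @param base a [sim_config()] providing everything but `rho` and `K_enz`.
#' @param rho_grid strictly increasing densities (cells/um^2).
#' @param kenz_grid strictly increasing enzymatic activities (1/h).
#' @return An object of class `sweep_result`; its `results` data frame has one
#'   row per condition.
#' @export
sweep_density_activity <- function(base,
                                   rho_grid = c(0.05, 0.1, 0.2, 0.3, 0.45, 0.6),
                                   kenz_grid = seq(0.1, 0.7, by = 0.1)) {
  stopifnot(inherits(base, "sim_config"))
  if (!length(rho_grid) || !length(kenz_grid))
    stop("sweep_density_activity: grids must be non-empty")
  if (anyDuplicated(rho_grid) || anyDuplicated(kenz_grid))
    stop("sweep_density_activity: grids must not contain duplicates")
  # grids are sorted so that per-condition seeds depend on the condition, not
  # on the order the caller listed it in (reorder invariance)
  rho_grid <- sort(rho_grid); kenz_grid <- sort(kenz_grid)
  rows <- expand.grid(rho = rho_grid, K_enz = kenz_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(r) {
    i <- match(rows$rho[r], rho_grid); j <- match(rows$K_enz[r], kenz_grid)
    cfg <- base
    cfg$rho <- rows$rho[r]
    cfg$kinetics$K_enz <- rows$K_enz[r]
    cfg$seed <- condition_seed(base$seed, i, j)
    run <- tryCatch(run_chamber(cfg), error = function(e)
      stop(sprintf("sweep_density_activity: run failed at rho = %g, K_enz = %g: %s",
                   rows$rho[r], rows$K_enz[r], conditionMessage(e))))
    c(mean_mu = mean_growth_rate(run), depol_rate = run$depol_rate,
      mean_O = run$mean_O)
  })
  res <- do.call(rbind, res)
  out <- cbind(rows, as.data.frame(res))
  out$norm_mu <- normalize_to_max(out$mean_mu)
  out$norm_depol <- normalize_to_max(out$depol_rate)
  structure(list(kind = "density_activity", rho_grid = rho_grid,
                 kenz_grid = kenz_grid, results = out, base = base),
            class = "sweep_result")
}

#' Sweep the relative diffusivity
#'
#' Scales all three diffusion coefficients by each `D_rel` value (diffusivity
#' normalized to free water) and records the total depolymerization rate and
#' the population-mean growth rate per condition, plus max-normalized variants.
#'
#' @param base a [sim_config()].
#' @param drel_grid strictly increasing values in (0, 1].
#' @return A `sweep_result` with one row per `D_rel`.
#' @export
sweep_diffusivity <- function(base, drel_grid = c(1e-3, 1e-2, 1e-1, 1)) {
  stopifnot(inherits(base, "sim_config"))
  if (!length(drel_grid)) stop("sweep_diffusivity: grid must be non-empty")
  if (any(drel_grid <= 0) || any(drel_grid > 1))
    stop("sweep_diffusivity: D_rel values must lie in (0, 1]")
  if (anyDuplicated(drel_grid))
    stop("sweep_diffusivity: grid must not contain duplicates")
  drel_grid <- sort(drel_grid)
  res <- lapply(seq_along(drel_grid), function(i) {
    cfg <- base
    cfg$transport$D_rel <- drel_grid[i]
    cfg$seed <- condition_seed(base$seed, i)
    run <- tryCatch(run_chamber(cfg), error = function(e)
      stop(sprintf("sweep_diffusivity: run failed at D_rel = %g: %s",
                   drel_grid[i], conditionMessage(e))))
    c(mean_mu = mean_growth_rate(run), depol_rate = run$depol_rate,
      mean_O = run$mean_O)
  })
  res <- do.call(rbind, res)
  out <- cbind(data.frame(D_rel = drel_grid), as.data.frame(res))
  out$norm_mu <- normalize_to_max(out$mean_mu)
  out$norm_depol <- normalize_to_max(out$depol_rate)
  structure(list(kind = "diffusivity", drel_grid = drel_grid, results = out,
                 base = base),
            class = "sweep_result")
}

# Divide by the grid maximum; all-zero input stays zero (nothing to normalize).
normalize_to_max <- function(x) {
  m <- max(x)
  if (m <= 0) return(x)
  x / m
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %s, %d conditions>\n", x$kind, nrow(x$results)))
  print(x$results, row.names = FALSE)
  invisible(x)
}
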