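#' Cell kinetic parameters
#'
#' Physiological constants shared by all cells: the enzymatic activity `K_enz`
#' (enzyme secreted per unit biomass per hour, the low- vs high-secretor axis),
#' Monod growth parameters, and the biomass-to-concentration conversion
#' `b_conv` (mg/L of site concentration equivalent to one biomass unit; a cell
#' occupies a single ~1 um site of a ~0.5 um-high chamber, so unit biomass
#' corresponds to a large local concentration; see the methods vignette).
#'
#' @param K_enz enzymatic activity (1/h, >= 0).
#' @param mu_max maximum specific growth rate (1/h, > 0).
#' @param K_m oligomer half-saturation constant (mg/L, > 0).
#' @param Y yield of biomass per oligomer mass consumed (dimensionless, > 0).
#' @param b_conv biomass-to-concentration conversion (mg/L per biomass unit).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(K_enz = 0.1, mu_max = 0.5, K_m = 0.2, Y = 0.5,
                           b_conv = 10) {
  if (!is.finite(K_enz) || K_enz < 0) stop("kinetic_params: K_enz must be >= 0")
  for (nm in c("mu_max", "K_m", "Y", "b_conv")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0)
      stop(sprintf("kinetic_params: %s must be > 0", nm))
  }
  structure(list(K_enz = K_enz, mu_max = mu_max, K_m = K_m, Y = Y,
                 b_conv = b_conv), class = "kinetic_params")
}

# Evaluate expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Place cells uniformly at random on interior lattice sites
#'
#' Chooses `round(rho * interior_area)` distinct interior sites uniformly at
#' random (one cell per site). Placement is deterministic for a fixed seed and
#' does not disturb the caller's RNG state.
#'
#' @param spec a [lattice_spec()].
#' @param rho intended cell density in cells/um^2, in `[0, 1/spacing^2]`.
#' @param seed integer seed.
#' @return An object of class `cell_population`: linear site indices `sites`,
#'   per-cell biomass `B` (initially 1), per-cell cumulative oligomer uptake,
#'   plus `rho` and `seed`.
#' @export
place_cells <- function(spec, rho, seed = 1L) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (!is.finite(rho) || rho < 0 || rho > 1 / spec$spacing^2)
    stop("place_cells: rho must lie in [0, 1/spacing^2] (at most one cell per site)")
  mask <- interior_mask(spec)
  interior_sites <- which(mask)
  area <- length(interior_sites) * spec$spacing^2
  n_cells <- round(rho * area)
  sites <- if (n_cells == 0) integer(0) else
    with_seed(seed, sort(sample(interior_sites, n_cells)))
  structure(list(sites = sites, B = rep(1, n_cells),
                 uptake = rep(0, n_cells), rho = rho, seed = as.integer(seed)),
            class = "cell_population")
}

#' Secrete enzyme at occupied sites for one time step
#'
#' First-order secretion in biomass: the enzyme field at each occupied site
#' increases by `K_enz * B * dt` (enzyme measured in secreted-biomass units;
#' the site-volume normalisation is folded into the depolymerization `k_cat`).
#'
#' @param fields a `field_set`.
#' @param pop a [place_cells()] population.
#' @param kp a [kinetic_params()] object.
#' @param dt time step (h, > 0).
#' @return The updated `field_set`.
#' @export
secrete_step <- function(fields, pop, kp, dt) {
  stopifnot(inherits(fields, "field_set"), inherits(pop, "cell_population"),
            inherits(kp, "kinetic_params"))
  if (!is.finite(dt) || dt <= 0) stop("secrete_step: dt must be > 0")
  if (length(pop$sites) == 0 || kp$K_enz == 0) return(fields)
  fields$E[pop$sites] <- fields$E[pop$sites] + kp$K_enz * pop$B * dt
  fields
}

#' Monod uptake and biomass growth for one time step
#'
#' Per occupied site the cell takes up oligomer at the Monod rate
#' `(mu_max / Y) * b_conv * B * O / (K_m + O)` (concentration units per hour).
#' The rate law is integrated exactly over the step with `B` frozen, so the
#' local oligomer can never be driven negative; the explicit
#' `U = (mu_max/Y) * b_conv * B * O/(K_m+O) * dt` increment is recovered as
#' `dt -> 0`. The site loses the uptaken mass `U`, the cell gains
#' `Y * U / b_conv` biomass, and the instantaneous specific growth rate
#' `mu = Y * U / (b_conv * B * dt)` is recorded (so `mu -> mu_max / 2` at
#' `O = K_m` for small `dt`, and `mu <= mu_max` always). A warning is raised
#' when the explicit predictor would have overshot the available oligomer at
#' more than 10% of cells (step-size diagnostic).
#'
#' @inheritParams secrete_step
#' @param warn warn when the step is too coarse (see above).
#' @return list with `fields`, `pop` (biomass and cumulative uptake updated),
#'   `mu` (per-cell instantaneous rates, 1/h), and `clipped_frac` (fraction of
#'   cells where the Euler predictor overshoots).
#' @export
uptake_grow_step <- function(fields, pop, kp, dt, warn = TRUE) {
  stopifnot(inherits(fields, "field_set"), inherits(pop, "cell_population"),
            inherits(kp, "kinetic_params"))
  if (!is.finite(dt) || dt <= 0) stop("uptake_grow_step: dt must be > 0")
  if (length(pop$sites) == 0)
    return(list(fields = fields, pop = pop, mu = numeric(0), clipped_frac = 0))
  O <- fields$O[pop$sites]
  if (any(O < 0)) stop("uptake_grow_step: oligomer field must be non-negative")
  r <- (kp$mu_max / kp$Y) * kp$b_conv * pop$B * dt
  euler <- r * O / (kp$K_m + O)
  clipped_frac <- if (any(O > 0)) mean(euler > O & O > 0) else 0
  if (warn && clipped_frac > 0.1)
    warning(sprintf(
      "uptake_grow_step: explicit predictor overshoots at %.0f%% of cells; local oligomer exhausted within dt",
      100 * clipped_frac))
  O1 <- mm_decay(O, kp$K_m, r)
  U <- O - O1
  dB <- kp$Y * U / kp$b_conv
  mu <- dB / (pop$B * dt)
  fields$O[pop$sites] <- O1
  pop$B <- pop$B + dB
  pop$uptake <- pop$uptake + U
  list(fields = fields, pop = pop, mu = mu, clipped_frac = clipped_frac)
}
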