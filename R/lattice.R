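#' Lattice specification for a quasi-2D growth chamber
#'
#' Defines the discretisation of a flow-flushed microfluidic growth chamber as
#' a rectangular lattice. The outermost ring of sites is the chamber periphery,
#' where concentrations are pinned to fixed (Dirichlet) values representing the
#' flushing flow: the polymer is resupplied there while secreted enzyme and
#' oligomer are washed out. A `closed = TRUE` lattice replaces the Dirichlet
#' ring by reflecting (zero-flux) edges; this mode exists for mass-balance
#' testing, not as a physical scenario.
#'
#' @param n_rows,n_cols integer number of lattice sites per side (>= 3).
#' @param spacing site edge length in micrometres (> 0).
#' @param boundary named numeric vector of fixed peripheral concentrations in
#'   mg/L for the three fields `P` (polymer), `E` (enzyme), `O` (oligomer).
#'   Defaults: polymer 0.1 mg/L, enzyme and oligomer 0 (washed out by flow).
#' @param closed logical; if `TRUE` the lattice has reflecting edges and no
#'   Dirichlet ring (every site is an interior site).
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(n_rows = 50L, n_cols = 50L, spacing = 1,
                         boundary = c(P = 0.1, E = 0, O = 0),
                         closed = FALSE) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 3L || n_cols < 3L)
    stop("lattice_spec: n_rows and n_cols must be >= 3")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("lattice_spec: spacing must be a single positive number")
  b <- c(P = 0.1, E = 0, O = 0)
  if (!is.null(boundary)) {
    if (is.null(names(boundary)) || !all(names(boundary) %in% c("P", "E", "O")))
      stop("lattice_spec: boundary must be named with a subset of P, E, O")
    b[names(boundary)] <- boundary
  }
  if (any(!is.finite(b)) || any(b < 0))
    stop("lattice_spec: boundary values must be finite and >= 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 boundary = b, closed = isTRUE(closed)),
            class = "lattice_spec")
}

#' Transport parameters for the three diffusible fields
#'
#' Diffusion coefficients in free water for polymer, enzyme, and oligomer, plus
#' a dimensionless relative diffusivity `D_rel` applied multiplicatively to all
#' three (the sweep axis emulating hindered transport inside aggregates or
#' biofilm relative to free water).
#'
#' Defaults are effective in-chamber values for a ~0.5 um-high quasi-2D slit:
#' Stokes-Einstein free-water estimates at 25 C (a high molecular weight
#' polysaccharide ~1e-11 m^2/s, a ~40 kDa enzyme ~5e-11 m^2/s, a short
#' oligosaccharide ~1e-10 m^2/s) reduced ~10x by near-wall hydrodynamic drag.
#' `D_rel = 1` anchors these in-chamber values; the sweep lowers them further,
#' emulating aggregate/biofilm hindrance.
#'
#' @param D_P,D_E,D_O diffusion coefficients (um^2/h), all >= 0.
#' @param D_rel relative diffusivity multiplier in (0, 1].
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(D_P = 3.6e3, D_E = 1.8e4, D_O = 3.6e4,
                             D_rel = 1) {
  v <- c(D_P = D_P, D_E = D_E, D_O = D_O)
  if (any(!is.finite(v)) || any(v < 0))
    stop("transport_params: diffusion coefficients must be finite and >= 0")
  if (!is.finite(D_rel) || D_rel <= 0 || D_rel > 1)
    stop("transport_params: D_rel must lie in (0, 1]")
  structure(list(D_P = D_P, D_E = D_E, D_O = D_O, D_rel = D_rel),
            class = "transport_params")
}

#' Depolymerization rate-law parameters
#'
#' The depolymerization rate per site is Michaelis-Menten in polymer and
#' first-order in enzyme: `k_cat * E * P / (K_P + P)`. `K_P >> P` recovers
#' mass action. The default `k_cat` absorbs the conversion between
#' secreted-biomass enzyme units and catalytic concentration; see the methods
#' vignette for the calibration. A fraction `conv` of degraded polymer mass
#' reappears as oligomer.
#'
#' @param k_cat maximal depolymerization rate, 1/h per unit enzyme (>= 0).
#' @param K_P polymer half-saturation (mg/L, > 0).
#' @param conv mass fraction of degraded polymer converted to oligomer, (0,1].
#' @return An object of class `depoly_params`.
#' @export
depoly_params <- function(k_cat = 1e5, K_P = 0.05, conv = 1) {
  if (!is.finite(k_cat) || k_cat < 0) stop("depoly_params: k_cat must be >= 0")
  if (!is.finite(K_P) || K_P <= 0) stop("depoly_params: K_P must be > 0")
  if (!is.finite(conv) || conv <= 0 || conv > 1)
    stop("depoly_params: conv must lie in (0, 1]")
  structure(list(k_cat = k_cat, K_P = K_P, conv = conv),
            class = "depoly_params")
}

interior_mask <- function(spec) {
  m <- matrix(TRUE, spec$n_rows, spec$n_cols)
  if (!spec$closed) {
    m[c(1L, spec$n_rows), ] <- FALSE
    m[, c(1L, spec$n_cols)] <- FALSE
  }
  m
}

n_interior <- function(spec) sum(interior_mask(spec))

apply_boundary <- function(mat, spec, value) {
  if (spec$closed) return(mat)
  mat[c(1L, spec$n_rows), ] <- value
  mat[, c(1L, spec$n_cols)] <- value
  mat
}

#' Initialise the concentration fields on a lattice
#'
#' Creates the three scalar concentration fields (polymer `P`, enzyme `E`,
#' oligomer `O`, all mg/L). Interior sites take `interior_init`; peripheral
#' sites take the Dirichlet values of the spec.
#'
#' @param spec a [lattice_spec()].
#' @param interior_init named numeric vector of interior concentrations for
#'   `P`, `E`, `O` (all >= 0). Default: polymer at its boundary value, enzyme
#'   and oligomer at 0.
#' @return An object of class `field_set`: list with matrices `P`, `E`, `O`
#'   and the `spec`.
#' @export
make_fields <- function(spec, interior_init = NULL) {
  stopifnot(inherits(spec, "lattice_spec"))
  init <- c(P = unname(spec$boundary["P"]), E = 0, O = 0)
  if (!is.null(interior_init)) {
    if (is.null(names(interior_init)) ||
        !all(names(interior_init) %in% c("P", "E", "O")))
      stop("make_fields: interior_init must be named with a subset of P, E, O")
    init[names(interior_init)] <- interior_init
  }
  for (f in c("P", "E", "O")) {
    if (!is.finite(init[[f]]) || init[[f]] < 0)
      stop(sprintf("make_fields: negative or non-finite initial value for field %s", f))
  }
  out <- list(spec = spec)
  for (f in c("P", "E", "O")) {
    m <- matrix(init[[f]], spec$n_rows, spec$n_cols)
    m <- apply_boundary(m, spec, spec$boundary[[f]])
    out[[f]] <- m
  }
  structure(out[c("P", "E", "O", "spec")], class = "field_set")
}

# Sparse 5-point Laplacian scaffold for one lattice. Returns the unknown-site
# index matrix, the (Deg - Adj) operator L, and the per-site count of Dirichlet
# neighbours (zero everywhere in closed mode).
laplacian_parts <- function(spec) {
  nr <- spec$n_rows; nc <- spec$n_cols
  unknown <- interior_mask(spec)
  idx <- matrix(0L, nr, nc)
  idx[unknown] <- seq_len(sum(unknown))
  n <- sum(unknown)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  deg <- numeric(n)
  nb_dirichlet <- numeric(n)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  pos <- which(unknown, arr.ind = TRUE)
  for (s in shifts) {
    ri <- pos[, 1] + s[1]; ci <- pos[, 2] + s[2]
    inside <- ri >= 1L & ri <= nr & ci >= 1L & ci <= nc
    if (spec$closed) {
      # reflecting edge: neighbour outside the grid contributes nothing
      k <- which(inside)
      nb <- idx[cbind(ri[k], ci[k])]
      ii <- c(ii, idx[unknown][k]); jj <- c(jj, nb); xx <- c(xx, rep(-1, length(k)))
      deg[idx[unknown][k]] <- deg[idx[unknown][k]] + 1
    } else {
      # all neighbours exist in the full grid; boundary ones are Dirichlet
      me <- idx[unknown]
      nb <- idx[cbind(ri, ci)]
      inter <- nb > 0L
      ii <- c(ii, me[inter]); jj <- c(jj, nb[inter])
      xx <- c(xx, rep(-1, sum(inter)))
      deg <- deg + 1
      nb_dirichlet[me[!inter]] <- nb_dirichlet[me[!inter]] + 1
    }
  }
  L <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, deg), dims = c(n, n))
  list(idx = idx, unknown = unknown, L = L, nb_dirichlet = nb_dirichlet)
}

# Eigendecomposition of the 1D five-point Laplacian factor: tridiag(-1, 2, -1)
# for a Dirichlet interior segment, with end degrees 1 for reflecting edges.
spectral_1d <- function(n, closed) {
  T <- diag(2, n)
  if (n >= 2) {
    idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    T[idx] <- -1; T[idx[, 2:1, drop = FALSE]] <- -1
  }
  if (closed) { T[1, 1] <- 1; T[n, n] <- 1 }
  if (n == 1 && closed) T[1, 1] <- 0
  e <- eigen(T, symmetric = TRUE)
  list(Q = e$vectors, lambda = e$values)
}

#' Pre-build the implicit diffusion solvers for a fixed step size
#'
#' One backward-Euler solver per field for a fixed (spec, transport, dt). The
#' 2D five-point Laplacian on a rectangle is the Kronecker sum of two 1D
#' operators, so the implicit solve is carried out spectrally (1D
#' eigendecompositions): exact, unconditionally stable, and fast enough for
#' the ~1e4 steps of a default run. Pass the result to [diffuse_step()] to
#' avoid rebuilding each step.
#'
#' @param spec a [lattice_spec()].
#' @param transport a [transport_params()].
#' @param dt time step (h, > 0).
#' @return An object of class `diffusion_solvers`.
#' @export
make_diffusion_solvers <- function(spec, transport, dt) {
  stopifnot(inherits(spec, "lattice_spec"), inherits(transport, "transport_params"))
  if (!is.finite(dt) || dt <= 0) stop("make_diffusion_solvers: dt must be > 0")
  h2 <- spec$spacing^2
  if (spec$closed) {
    nr <- spec$n_rows; nc <- spec$n_cols
  } else {
    nr <- spec$n_rows - 2L; nc <- spec$n_cols - 2L
  }
  er <- spectral_1d(nr, spec$closed)
  ec <- spectral_1d(nc, spec$closed)
  lam <- outer(er$lambda, ec$lambda, "+")
  nbD <- matrix(0, nr, nc)
  if (!spec$closed) {
    nbD[1, ] <- nbD[1, ] + 1; nbD[nr, ] <- nbD[nr, ] + 1
    nbD[, 1] <- nbD[, 1] + 1; nbD[, nc] <- nbD[, nc] + 1
  }
  solvers <- list()
  for (f in c("P", "E", "O")) {
    D <- transport[[paste0("D_", f)]] * transport$D_rel
    alpha <- D * dt / h2
    if (alpha == 0) { solvers[f] <- list(NULL); next }
    solvers[[f]] <- list(alpha = alpha, Qr = er$Q, tQc = t(ec$Q), Qc = ec$Q,
                         inv_denom = 1 / (1 + alpha * lam),
                         rhs_add = alpha * nbD * spec$boundary[[f]])
  }
  structure(list(spec = spec, dt = dt, solvers = solvers),
            class = "diffusion_solvers")
}

#' Advance all fields one diffusion time step
#'
#' One backward-Euler (linear-implicit) step of the 2D diffusion equation with
#' the five-point Laplacian. The scheme is unconditionally stable in `dt`,
#' preserves non-negativity (the system matrix is an M-matrix), and re-imposes
#' the Dirichlet boundary after the step. With `D = 0` the field is returned
#' unchanged. In closed (reflecting) mode total mass is conserved to round-off.
#'
#' @param fields a [make_fields()] object.
#' @param transport a [transport_params()] object.
#' @param dt time step in hours (> 0).
#' @param solvers optional pre-built solver set from
#'   `make_diffusion_solvers()`; rebuilding each call is supported but slow.
#' @return The advanced `field_set`.
#' @export
diffuse_step <- function(fields, transport, dt, solvers = NULL) {
  stopifnot(inherits(fields, "field_set"))
  spec <- fields$spec
  if (is.null(solvers)) solvers <- make_diffusion_solvers(spec, transport, dt)
  if (!isTRUE(all.equal(solvers$dt, dt)))
    stop("diffuse_step: solver cache was built for a different dt")
  ri <- if (spec$closed) seq_len(spec$n_rows) else 2:(spec$n_rows - 1L)
  ci <- if (spec$closed) seq_len(spec$n_cols) else 2:(spec$n_cols - 1L)
  for (f in c("P", "E", "O")) {
    u <- fields[[f]]
    if (any(!is.finite(u)))
      stop(sprintf("diffuse_step: non-finite values in field %s before step", f))
    sv <- solvers$solvers[[f]]
    if (is.null(sv)) next # D == 0: identity
    b <- u[ri, ci, drop = FALSE] + sv$rhs_add
    x <- sv$Qr %*% ((crossprod(sv$Qr, b) %*% sv$Qc) * sv$inv_denom) %*% sv$tQc
    if (any(!is.finite(x)))
      stop(sprintf("diffuse_step: diffusion solve produced non-finite values in field %s", f))
    # the system matrix is an M-matrix, so the solution is non-negative up to
    # spectral round-off; clamp the round-off
    u[ri, ci] <- pmax(x, 0)
    u <- apply_boundary(u, spec, spec$boundary[[f]])
    fields[[f]] <- u
  }
  fields
}

# Integrate dX/dt = -k X / (K + X) over one step with k frozen: the implicit
# solution satisfies K log(X0/X1) + (X0 - X1) = k dt. Solved by monotone
# Newton iteration from the linearised-exponential guess (which bounds the
# root from above). Exact, unconditionally positive, and reduces to the
# explicit k X/(K+X) dt increment as dt -> 0.
mm_decay <- function(x0, K, r) {
  out <- x0
  # reactions so far beyond depletion that the root underflows double
  # precision: all substrate is consumed
  gone <- x0 > 0 & r > x0 + 500 * K
  out[gone] <- 0
  # far below half-saturation the dynamics are exactly linear; the closed form
  # avoids underflow in the Newton iteration for denormal substrate levels
  lin <- x0 > 0 & r > 0 & !gone & x0 < 1e-12 * K
  out[lin] <- x0[lin] * exp(-pmin(r[lin] / K, 700))
  act <- which(x0 > 0 & r > 0 & !gone & !lin)
  if (!length(act)) return(out)
  x0a <- x0[act]; ra <- r[act]
  x <- x0a * exp(-ra / (K + x0a))
  for (it in 1:50) {
    f <- K * log(x0a / x) + (x0a - x) - ra
    step <- f * x / (K + x)
    x <- pmax(x + step, x0a * 1e-300)
    if (max(abs(f)) < 1e-13 * (K + max(x0a))) break
  }
  out[act] <- x
  out
}

#' Depolymerize polymer into oligomer for one time step
#'
#' Per site the polymer is degraded at rate `k_cat * E * P / (K_P + P)`
#' (Michaelis-Menten in polymer, first-order in enzyme); the oligomer field
#' gains `conv` times the degraded mass. The rate law is integrated exactly
#' over the step with `E` frozen, so the polymer can never be driven negative;
#' the explicit `k_cat * E * P/(K_P+P) * dt` increment is recovered as
#' `dt -> 0`. Reactions act on interior sites only; Dirichlet sites are held
#' fixed. A warning is raised when the explicit-Euler predictor would have
#' overshot the available polymer on more than 10% of active sites (the spec
#' step-size diagnostic).
#'
#' @param fields a [make_fields()] object.
#' @param dp a [depoly_params()] object.
#' @param dt time step in hours.
#' @param warn if `TRUE`, warn when the step is too coarse for the reaction
#'   (see above).
#' @return list with elements `fields` (updated), `depolymerized` (total
#'   degraded polymer mass summed over sites, mg/L-sites) and `clipped_frac`
#'   (fraction of active sites where the Euler predictor overshoots).
#' @export
depolymerize_step <- function(fields, dp, dt, warn = TRUE) {
  stopifnot(inherits(fields, "field_set"), inherits(dp, "depoly_params"))
  spec <- fields$spec
  unknown <- interior_mask(spec)
  P <- fields$P[unknown]; E <- fields$E[unknown]; O <- fields$O[unknown]
  if (any(P < 0) || any(E < 0) || any(O < 0))
    stop("depolymerize_step: fields must be non-negative")
  euler <- dp$k_cat * E * P / (dp$K_P + P) * dt
  active <- euler > 0
  clipped_frac <- if (any(active)) mean(euler[active] > P[active]) else 0
  if (warn && clipped_frac > 0.1)
    warning(sprintf(
      "depolymerize_step: explicit predictor overshoots on %.0f%% of active sites; dt too coarse for the reaction",
      100 * clipped_frac))
  P1 <- mm_decay(P, dp$K_P, dp$k_cat * E * dt)
  dP <- P - P1
  fields$P[unknown] <- P1
  fields$O[unknown] <- O + dp$conv * dP
  list(fields = fields, depolymerized = sum(dP), clipped_frac = clipped_frac)
}

#' Direct steady-state solution of the Dirichlet diffusion problem
#'
#' Solves `-D lap(u) = source` with the lattice's Dirichlet boundary by dense
#' linear algebra. This is the independent oracle used to verify fixed points
#' of [diffuse_step()]; it is restricted to small grids (<= 20 x 20).
#'
#' @param spec a [lattice_spec()] (open mode; a closed lattice with a source
#'   has no steady state).
#' @param transport a [transport_params()] object.
#' @param source per-site production rate (mg/L/h): a single matrix applied to
#'   every field, or a named list with entries `P`, `E`, `O`.
#' @return A `field_set` holding the steady-state fields.
#' @export
steady_state_oracle <- function(spec, transport, source = NULL) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (spec$n_rows > 20L || spec$n_cols > 20L)
    stop("steady_state_oracle: restricted to grids of at most 20 x 20")
  if (spec$closed)
    stop("steady_state_oracle: requires Dirichlet (open) boundaries")
  parts <- laplacian_parts(spec)
  n <- nrow(parts$L)
  Ld <- as.matrix(parts$L)
  out <- list(spec = spec)
  for (f in c("P", "E", "O")) {
    D <- transport[[paste0("D_", f)]] * transport$D_rel
    src <- matrix(0, spec$n_rows, spec$n_cols)
    if (is.matrix(source)) src <- source
    else if (is.list(source) && !is.null(source[[f]])) src <- source[[f]]
    bval <- spec$boundary[[f]]
    m <- matrix(bval, spec$n_rows, spec$n_cols)
    if (D == 0) {
      if (any(src[parts$unknown] != 0))
        stop(sprintf("steady_state_oracle: field %s has a source but zero diffusivity (singular system)", f))
      # no transport: any interior value is stationary; report boundary value
      u <- rep(bval, n)
    } else {
      scale <- D / spec$spacing^2
      rhs <- src[parts$unknown] + scale * parts$nb_dirichlet * bval
      u <- solve(scale * Ld, rhs)
    }
    m[parts$unknown] <- u
    out[[f]] <- m
  }
  structure(out[c("P", "E", "O", "spec")], class = "field_set")
}

#' Total mass of each field (concentration summed over sites)
#' @param fields a `field_set`.
#' @param interior_only sum over interior sites only (default all sites).
#' @return named numeric vector with components `P`, `E`, `O`.
#' @export
field_mass <- function(fields, interior_only = FALSE) {
  stopifnot(inherits(fields, "field_set"))
  m <- if (interior_only) interior_mask(fields$spec) else
    matrix(TRUE, fields$spec$n_rows, fields$spec$n_cols)
  vapply(c("P", "E", "O"), function(f) sum(fields[[f]][m]), numeric(1))
}
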