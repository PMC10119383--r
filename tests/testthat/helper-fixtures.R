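# Small shared fixtures, built in code.

tiny_spec <- function(n = 8, boundary = c(P = 0.1, E = 0, O = 0), ...)
  lattice_spec(n, n, boundary = boundary, ...)

slow_transport <- function(D = 100, D_rel = 1)
  transport_params(D_P = D, D_E = D, D_O = D, D_rel = D_rel)

# A hand-rolled dense 5-point Dirichlet Laplacian (degree - adjacency) on the
# interior of an nr x nc lattice, by explicit loops: the independent oracle
# for the spectral solver.
dense_dirichlet_laplacian <- function(nr, nc) {
  ni <- (nr - 2) * (nc - 2)
  idx <- matrix(0L, nr, nc)
  idx[2:(nr - 1), 2:(nc - 1)] <- seq_len(ni)
  L <- matrix(0, ni, ni)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    me <- idx[i, j]
    L[me, me] <- 4
    for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nb <- idx[i + s[1], j + s[2]]
      if (nb > 0) L[me, nb] <- L[me, nb] - 1
    }
  }
  L
}

# Track table builder for statistics tests.
make_tracks <- function(strain = "s", chamber = 1, birth, rate,
                        founder = seq_along(birth), depart = NA_real_)
  data.frame(strain = strain, chamber = chamber, cell = seq_along(birth),
             founder = founder, birth = birth, rate = rate, depart = depart)
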