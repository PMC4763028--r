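# shared fixtures, built once per test run

the_beams <- default_beams()

# water slab with centered 4 cm spherical target, planning resolution
slab_phantom <- function(spacing = 0.5)
  make_selector_phantom(EP = 6, TS = 4, thickness = 12, spacing = spacing)

# two-layer phantom: 5 cm water over 5 cm lung-density material, beam along +y
two_slab_phantom <- function(spacing = 0.25) {
  shape <- c(16, as.integer(10 / spacing), 16)
  sp <- c(0.5, spacing, 0.5)
  density <- array(1, shape)
  co <- seq_len(shape[2]) * spacing - spacing / 2
  density[, co > 5, ] <- 0.25
  body <- array(TRUE, shape)
  ptv <- array(FALSE, shape)
  ptv[7:9, 8:10, 7:9] <- TRUE
  voxel_phantom(density, sp, c(-4, 0, -4), list(BODY = body, PTV = ptv),
                isocenter = c(0, 5, 0))
}

# tiny synthetic DDC container for algebra-level tests
fake_ddc <- function(A, voxel_index = seq_len(nrow(A))) {
  structure(list(A = Matrix::Matrix(A, sparse = TRUE),
                 voxel_index = voxel_index, grid = NULL, meta = list()),
            class = "ddc_matrix")
}

# single-structure phantom stub matching a fake DDC row space
fake_phantom <- function(n_target, n_oar = 0, n_total = n_target + n_oar) {
  shape <- c(n_total, 1, 1)
  density <- array(1, shape)
  body <- array(TRUE, shape)
  ptv <- array(FALSE, shape); ptv[seq_len(n_target), 1, 1] <- TRUE
  st <- list(BODY = body, PTV = ptv)
  if (n_oar > 0) {
    oar <- array(FALSE, shape)
    oar[n_target + seq_len(n_oar), 1, 1] <- TRUE
    st$OAR <- oar
  }
  voxel_phantom(density, c(1, 1, 1), c(0, 0, 0), st)
}

# finite-difference gradient oracle
fd_gradient <- function(fun, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (fun(xp) - fun(xm)) / (2 * h)
  }, numeric(1))
}
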