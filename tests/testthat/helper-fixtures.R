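# shared fixtures: everything is generated in code at test time

# small, fast cohort spec for structural tests
small_spec <- function(arms = c(placebo = 2L), seed = 1L, ...) {
  cohort_spec(dim = c(8L, 8L, 8L), n_volumes = 60L, arms = arms,
              seed = seed, ...)
}

# neighbour structure of a full nx x ny x nz grid
grid_neighbors <- function(nx, ny = nx, nz = nx, connectivity = 26L) {
  co <- as.matrix(expand.grid(x = 1:nx, y = 1:ny, z = 1:nz))
  node_neighbors(co, connectivity)
}

# amplitude of the Fourier component of x at frequency f (arbitrary f)
amp_at <- function(x, f, tr) {
  t <- (seq_along(x) - 0.5) * tr
  2 * abs(sum(x * exp(-2i * pi * f * t))) / length(x)
}

# single-voxel-series volume
sine_volume <- function(x, tr = 2.5) {
  ts_volume(array(x, c(1, 1, 1, length(x))), tr = tr)
}

# independent naive TFCE oracle: per-threshold BFS component labelling,
# same height rule as the implementation (h = s*dh, membership stat >= h)
tfce_naive <- function(stat, coords, E = 0.5, H = 2, nsteps = 50,
                       connectivity = 26) {
  n <- length(stat)
  hmax <- max(stat, 0)
  out <- numeric(n)
  if (hmax <= 0) return(out)
  dh <- hmax / nsteps
  dmax <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  adj <- lapply(seq_len(n), function(i) {
    d <- abs(sweep(coords, 2, coords[i, ]))
    which(apply(d, 1, max) == 1 & rowSums(d) <= dmax)
  })
  for (s in seq_len(nsteps)) {
    h <- s * dh
    act <- stat >= h
    lab <- integer(n)
    nxt <- 0
    for (i in which(act)) {
      if (lab[i] > 0) next
      nxt <- nxt + 1
      queue <- i
      lab[i] <- nxt
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- adj[[v]]
        nb <- nb[act[nb] & lab[nb] == 0]
        lab[nb] <- nxt
        queue <- c(queue, nb)
      }
    }
    sizes <- tabulate(lab)
    ia <- which(act)
    out[ia] <- out[ia] + sizes[lab[ia]]^E * h^H * dh
  }
  out
}
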