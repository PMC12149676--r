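# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixtures)) assign(name, expr, .fixtures)
  get(name, .fixtures)
}

# small static cohort: no inter-timepoint change randomness switched off
small_cohort <- function() {
  cached("small_cohort", generate_cohort(phantom_config(n_patients = 4, seed = 101)))
}

# random blob mask for metric tests
random_blob <- function(dim, n_spheres = 2, rmin = 2, rmax = 5) {
  m <- array(FALSE, dim)
  co <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  for (i in seq_len(n_spheres)) {
    c0 <- runif(3, rmax, dim - rmax)
    r <- runif(1, rmin, rmax)
    m <- m | array((co$x - c0[1])^2 + (co$y - c0[2])^2 + (co$z - c0[3])^2 <= r^2, dim)
  }
  m
}

# independent brute-force surface-distance oracle (all pairs)
brute_msd <- function(a, b, spacing) {
  surf_pts <- function(m) {
    d <- dim(m)
    idx <- which(adaptseg:::surface_voxels_cpp(as.logical(m), d)) - 1L
    cbind(idx %% d[1], (idx %/% d[1]) %% d[2], idx %/% (d[1] * d[2])) *
      rep(spacing, each = length(idx))
  }
  A <- surf_pts(a); B <- surf_pts(b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

# brute-force voxel-counting DSC oracle
brute_dsc <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
    if (a[i] && b[i]) inter <- inter + 1
  }
  if (na + nb == 0) 1 else 2 * inter / (na + nb)
}

tiny_net_setup <- function(C = 2, S = 2, w = 2, d = c(16, 16, 16), seed = 42) {
  lay <- adaptseg:::unet_layout(C, S, w)
  par <- numeric(sum(lay$n))
  set.seed(seed)
  for (i in seq_len(nrow(lay))) {
    idx <- lay$offset[i] + seq_len(lay$n[i])
    par[idx] <- switch(lay$type[i],
      conv = rnorm(lay$n[i], sd = sqrt(2 / (27 * lay$Cin[i]))),
      tconv = rnorm(lay$n[i], sd = sqrt(2 / (8 * lay$Cin[i]))),
      gamma = 1, beta = 0,
      final = rnorm(lay$n[i], sd = sqrt(1 / lay$Cin[i])),
      bias = -0.5)
  }
  V <- prod(d)
  list(par = par, C = C, S = S, w = w, d = d, V = V,
       input = matrix(rnorm(C * V), C, V),
       target = matrix(as.numeric(matrix(runif(S * V), S, V) > 0.9), S, V))
}
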