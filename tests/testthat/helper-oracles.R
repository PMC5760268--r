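# Independent oracles used across the test files.

## minimum radius of curvature of A*cos(2*pi*x/lambda) by brute-force
## sampling of (1 + g'^2)^(3/2) / |g''| with finite differences
brute_curvature_min <- function(A, lambda, n = 1e4) {
  x <- seq(0, 2 * lambda, length.out = n)
  h <- x[2] - x[1]
  g <- A * cos(2 * pi * x / lambda)
  g1 <- (g[c(2:n, 1)] - g[c(n, 1:(n - 1))]) / (2 * h)
  g2 <- (g[c(2:n, 1)] - 2 * g + g[c(n, 1:(n - 1))]) / h^2
  r <- (1 + g1^2)^1.5 / abs(g2)
  min(r[is.finite(r)])
}

## exhaustive depth-first connected components of an undirected edge list
dfs_components <- function(vertices, edges) {
  adj <- lapply(stats::setNames(vector("list", length(vertices)),
                                as.character(vertices)), identity)
  for (k in seq_len(nrow(edges))) {
    a <- as.character(edges[k, 1]); b <- as.character(edges[k, 2])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- stats::setNames(rep(FALSE, length(vertices)),
                          as.character(vertices))
  comp <- stats::setNames(rep(NA_integer_, length(vertices)),
                          as.character(vertices))
  cid <- 0L
  for (v in as.character(vertices)) {
    if (seen[[v]]) next
    cid <- cid + 1L
    stack <- v
    while (length(stack) > 0) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[[u]]) next
      seen[[u]] <- TRUE
      comp[[u]] <- cid
      stack <- c(stack, adj[[u]])
    }
  }
  comp
}

## D2Q9 moments computed directly from the direction table
d2q9_dirs <- function() {
  list(cx = c(0, 1, 1, 0, -1, -1, -1, 0, 1),
       cy = c(0, 0, 1, 1, 1, 0, -1, -1, -1))
}

## plasma-like fluid used throughout
plasma <- list(rho = 1030, nu = 1.2e-6, mu = 1030 * 1.2e-6)

## small straight-channel coupled configuration for property runs
tiny_coupled_config <- function(duration = 0.002, seed = 1L, dp = 16,
                                n_init = 20L, inject = FALSE,
                                tau_crit = 0.65, diameter = 2.4e-6,
                                concentration = 3e14, force_relax = 1,
                                dt = 4e-7, snapshot_every = 0L,
                                diag_every = 250L) {
  geom <- straight_channel(D = 25e-6, nx = 64, ny = 16, L = 314e-6,
                           dt = dt, nu = plasma$nu)
  sim_config(
    geometry = geom,
    drive = list(dp = dp),
    platelets = list(diameter = diameter, n_init = n_init,
                     inject = inject, concentration = concentration,
                     contact = contact_params(tau_crit = tau_crit)),
    numerics = list(dt = dt, duration = duration, seed = seed,
                    force_relax = force_relax),
    output = list(diag_every = diag_every,
                  snapshot_every = snapshot_every))
}
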