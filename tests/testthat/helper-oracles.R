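# Independent oracles and shared fixtures, built in code at test time.

# Brute-force single-linkage partition via union-find over the all-pairs
# distance matrix: spots i, j are linked when d(i, j) <= radius.
uf_single_linkage <- function(pos, radius) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
        if (d <= radius) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Two partitions of the same points are equal up to label permutation.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(as.integer(factor(a, levels = unique(a))),
              as.integer(factor(b, levels = unique(b))))
}

# Quadrature oracle: mass fraction of a linear-density arc model within a
# Euclidean disc about the ori tip. Integrates over a fine arc grid.
arc_fraction_oracle <- function(arc_radius_um, span_deg, radius_nm,
                                density_fun = function(s) rep(1, length(s)),
                                blob_fraction = 0, n = 20001) {
  L <- arc_radius_um * span_deg * pi / 180
  s <- seq(0, L, length.out = n)
  theta <- s / arc_radius_um
  # chord distance from the s = 0 tip, in nm
  chord_nm <- 2 * arc_radius_um * 1000 * abs(sin(theta / 2))
  rho <- density_fun(s)
  rho <- rho / sum(rho) * (1 - blob_fraction)
  blob_fraction + sum(rho[chord_nm <= radius_nm])
}

# One default-geometry simulated crescent analyzed through segmentation,
# ParB detection and backbone fitting.
analyze_cell <- function(cc, min_prominence = 5) {
  rois <- screen_round(detect_cells(cc$stack))
  stopifnot(nrow(rois) == 1)
  mask <- rois$mask[[1]]
  parb <- detect_foci(max_project(cc$stack, "ParB"), mask,
                      min_prominence = min_prominence)[1, ]
  list(mask = mask, parb = parb,
       dna = max_project(cc$stack, "DNA"))
}
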