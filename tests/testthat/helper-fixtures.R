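# shared fixtures: small centred grids and analytic fields

centred_grid <- function(n = 10, h = 2) {
  volume_grid(rep(n, 3), spacing = rep(h, 3), origin = rep(-(n - 1) * h / 2, 3))
}

# expand a 3-D logical mask along a trailing component axis of length k
mask_k <- function(mask, k) array(rep(as.vector(mask), k), c(dim(mask), k))

# strain field of an analytic deformation on a centred grid
strain_of <- function(def, n = 10, h = 2, scheme = "central") {
  s <- sample_field(def, centred_grid(n, h))
  list(oracle = s, sf = compute_strain_field(s$field, scheme = scheme))
}

# constant-valued scalar map
const_map <- function(value, grid, mask = NULL) {
  scalar_map(array(value, grid$shape), grid, mask)
}

# brute-force Benjamini-Hochberg: search all rejection thresholds
bh_bruteforce_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * q / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}
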