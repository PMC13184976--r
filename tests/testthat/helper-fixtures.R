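# Shared fixtures, all built in code.

# minimal conformer from a coordinate matrix; one residue, atoms A1..An
toy_conformer <- function(xyz, elements = NULL, id = "toy") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (is.null(elements)) elements <- rep("C", n)
  conformer(
    id = id,
    atoms = data.frame(name = paste0("A", seq_len(n)),
                       element = elements,
                       res_index = rep(1L, n),
                       res_name = rep("TOY", n),
                       stringsAsFactors = FALSE),
    xyz = xyz)
}

# pool of single-"bond-pair" conformers at prescribed A1-A2 distances
toy_distance_pool <- function(distances) {
  conformer_pool(lapply(seq_along(distances), function(k) {
    toy_conformer(rbind(c(0, 0, 0), c(distances[[k]], 0, 0)),
                  elements = c("H", "H"), id = paste0("d", k))
  }))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_conformer <- function(cf, rot = diag(3), shift = c(0, 0, 0)) {
  cf$xyz <- sweep(cf$xyz %*% t(rot), 2, -shift)
  cf
}

# small cached default-config pool shared across tests
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sample_pool(generator_config(seed = 42, n_folded = 4,
                                             n_unfolded = 4))
    }
    cache
  }
})

# an RDC table for a pool from explicit pairs / observations
rdc_table <- function(pairs, d_obs, error = 0.5) {
  data.frame(
    res_i = vapply(pairs, function(p) as.integer(p[[1]][1]), integer(1)),
    atom_i = vapply(pairs, function(p) p[[1]][2], character(1)),
    res_j = vapply(pairs, function(p) as.integer(p[[2]][1]), integer(1)),
    atom_j = vapply(pairs, function(p) p[[2]][2], character(1)),
    d_obs = d_obs, error = rep(error, length(d_obs)),
    stringsAsFactors = FALSE)
}

# distinct-conformer pool: folded, xb-enriched and unfolded members whose
# per-conformer RDC predictions have full column rank
distinct_pool <- function(seed = 9) {
  cfg <- generator_config(seed = seed, n_folded = 2, n_unfolded = 2,
                          dihedral_jitter = 10)
  sim <- sample_pool(cfg)
  pool <- enrich_with_xb_conformers(sim$pool, cfg, n = 2, seed = seed + 1)
  list(pool = pool, cfg = cfg, tensor = sim$truth$tensor)
}
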