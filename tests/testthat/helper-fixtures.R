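# Shared fixture builders (all generated in code, deterministic).

# small simulated dataset used by several suites
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_sst(sim_config(
        image_height = 128, image_width = 128, n_cells = 8,
        mean_transcripts_per_cell = 150, rng_seed = 3))
    }
    cache
  }
})

# a 3-type profile with disjoint high-expression blocks
block_profile <- function(n_types = 3, n_genes = 12, fold = 10) {
  m <- matrix(1, n_types, n_genes,
              dimnames = list(paste0("type", seq_len(n_types)),
                              sprintf("g%02d", seq_len(n_genes))))
  block <- ceiling(n_genes / n_types)
  for (t in seq_len(n_types)) {
    lo <- (t - 1) * block + 1
    m[t, lo:min(t * block, n_genes)] <- fold
  }
  reference_profile(m)
}

# regular polygon approximating a circle
circle_polygon <- function(r = 10, n = 1024, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = centre[1] + r * cos(th), y = centre[2] + r * sin(th))
}

# rasterised disc mask
disc_mask <- function(r, pad = 3) {
  d <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  i <- matrix(seq_len(d), d, d); j <- t(i)
  (i - ctr)^2 + (j - ctr)^2 <= r^2
}

# random per-cell loss instance on an h x w patch
random_loss_instance <- function(seed, h = 8, w = 8, M = NULL) {
  set.seed(seed)
  if (is.null(M)) M <- sample(1:3, 1)
  mk <- function(p) matrix(stats::rbinom(h * w, 1, p), h, w)
  q <- lapply(seq_len(M), function(i)
    matrix(stats::runif(h * w, 0.02, 0.98), h, w))
  x_nuc <- lapply(seq_len(M), function(i) mk(0.15))
  list(M = M, h = h, w = w, q = q, x_nuc = x_nuc,
       e_c = lapply(seq_len(M), function(i) mk(0.4)),
       m_pos = lapply(seq_len(M), function(i) mk(0.2)),
       m_neg = lapply(seq_len(M), function(i) mk(0.2)),
       nuc_union = (Reduce(`+`, x_nuc) > 0) * 1)
}
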