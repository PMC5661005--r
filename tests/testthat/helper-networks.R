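# Shared builders for small fixtures and brute-force oracles.

# A small single-column network geometry that keeps tests fast while
# preserving all the structural ratios of the full model.
small_net <- function(num_columns = 1L, seed = 1L, ...) {
  cortical_network(num_columns = num_columns,
                   n_in = 40L, m = 8L, s_in = 5L,
                   n_ext = 400L,
                   n_out = 256L, s_out = 10L,
                   theta_basal = 3L, theta_basal_apical = 2L,
                   theta_apical = 3L, theta_proximal = 4L,
                   theta_lateral = 5L,
                   classify_threshold = 8L,
                   seed = seed, ...)
}

small_library <- function(num_objects = 8L, feature_pool_size = 6L,
                          seed = 1L, features_per_object = 6L) {
  generate_library(num_objects,
                   features_per_object = features_per_object,
                   feature_pool_size = feature_pool_size,
                   num_locations = features_per_object,
                   rng = rng_stream(seed),
                   n_in = 40L, n_ext = 400L, bits_active = 5L)
}

# Brute-force re-scan of every segment in a store: connected-synapse counts
# against an active-bit set, computed directly from the synapse lists.
brute_active_cells <- function(store, active_bits, theta) {
  if (store$n_seg == 0L) return(integer(0))
  hit <- vapply(seq_len(store$n_seg), function(i) {
    conn <- store$syn[[i]][store$perm[[i]] >= store$connected_perm]
    sum(conn %in% active_bits) >= theta
  }, logical(1))
  unique(store$cell[which(hit)])
}

# Brute-force version of the output-layer activation rule: score every
# cell's proximal synapses and every lateral segment from scratch.
brute_select_active <- function(ol, a_in, prev_abar) {
  o <- vapply(seq_len(ol$n_out), function(k) {
    p <- ol_proximal(ol, k)
    if (is.null(p)) return(0L)
    conn <- p$rows[p$perms >= ol$connected_perm]
    sum(conn %in% a_in)
  }, 0L)
  cand <- which(o >= ol$theta_proximal)
  if (length(cand) == 0L) return(integer(0))
  st <- ol$lateral
  rho <- integer(ol$n_out)
  for (i in seq_len(st$n_seg)) {
    conn <- st$syn[[i]][st$perm[[i]] >= st$connected_perm]
    if (sum(conn %in% prev_abar) >= ol$theta_lateral) {
      rho[st$cell[i]] <- rho[st$cell[i]] + 1L
    }
  }
  rho_cand <- rho[cand]
  xi <- if (sum(rho_cand > 0L) < ol$s_out) 0L else
    sort(rho_cand, decreasing = TRUE)[ol$s_out]
  sort(cand[rho_cand >= xi])
}

# First sensation index at which the network classifies the object
# correctly, or NA.
first_recognition <- function(net, library, object_id, K, rng) {
  st <- sensation_stream(library, object_id, K, net$num_columns, rng)
  res <- net_infer(net, st)
  which(res$classification == object_id)[1L]
}
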