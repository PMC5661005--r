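#' Object-pooling output layer of one cortical column
#'
#' `n_out` cells (4,096 by default, not arranged in minicolumns) represent
#' objects by sparse codes of at least `s_out` active cells. Each cell's
#' proximal dendrite holds permanence-weighted synapses onto the column's
#' input-layer cells (stored sparsely per cell); a cell is a feedforward
#' candidate when at least `theta_proximal` connected proximal synapses lie
#' on currently active input cells. Basal (lateral) segments listen to the
#' previous time step's output activity of all columns — each segment
#' samples exactly one source column — and act as a vote: among feedforward
#' candidates, the cells with the most active lateral segments win. With no
#' lateral support at all (e.g. right after a reset) every feedforward
#' candidate becomes active, which realizes the union-of-candidate-objects
#' state that later sensations narrow down.
#'
#' @param n_out Cells in this layer (default 4,096).
#' @param s_out Minimum active cells / object code size (default 40).
#' @param n_in_cells Input-layer cell count of the same column.
#' @param n_columns Number of columns in the network (lateral input space is
#'   `n_out * n_columns`).
#' @param col This column's index (used for global lateral cell ids).
#' @param theta_proximal Connected-synapse count for a feedforward
#'   candidate (default 8). With `s_in` active minicolumns a learned pair
#'   drives its object's cells at overlap `s_in`; the candidate threshold
#'   must sit close below that so that accumulated synapses from hundreds
#'   of stored objects cannot produce chance candidates, while still
#'   tolerating a couple of corrupted input bits.
#' @param theta_lateral Connected-synapse count for an active lateral
#'   segment (default 18).
#' @param connected_perm Permanence threshold for a conducting synapse
#'   (proximal and lateral; default 0.5).
#' @param p_ff_plus,p_ff_minus Proximal permanence increment / decrement.
#'   The decrement is small so that pooling over all of an object's
#'   feature/location pairs survives training: every sensation of one pair
#'   decrements the synapses of the object's other pairs.
#' @param p_lat_plus,p_lat_minus Lateral permanence increment / decrement.
#' @param init_perm Permanence of newly grown synapses (0.6).
#' @param init_frac Fraction of input cells each output cell samples as
#'   random initial potential synapses (default 0.005); roughly half are
#'   born connected.
#' @param rng An [rng_stream()] for the random initial connectivity.
#' @return Mutable object of class `output_layer`.
#' @export
output_layer <- function(n_out = 4096L, s_out = 40L,
                         n_in_cells = 2400L, n_columns = 1L, col = 1L,
                         theta_proximal = 8L, theta_lateral = 18L,
                         connected_perm = 0.5,
                         p_ff_plus = 0.1, p_ff_minus = 0.001,
                         p_lat_plus = 0.1, p_lat_minus = 0.02,
                         init_perm = 0.6, init_frac = 0.005,
                         rng = rng_stream(1)) {
  stopifnot(s_out <= n_out, theta_proximal >= 1L, theta_lateral >= 1L)
  ol <- new.env(parent = emptyenv())
  ol$n_out <- as.integer(n_out); ol$s_out <- as.integer(s_out)
  ol$n_in_cells <- as.integer(n_in_cells)
  ol$n_columns <- as.integer(n_columns); ol$col <- as.integer(col)
  ol$theta_proximal <- as.integer(theta_proximal)
  ol$theta_lateral <- as.integer(theta_lateral)
  ol$connected_perm <- connected_perm
  ol$p_ff_plus <- p_ff_plus; ol$p_ff_minus <- p_ff_minus
  ol$p_lat_plus <- p_lat_plus; ol$p_lat_minus <- p_lat_minus
  ol$init_perm <- init_perm

  # Proximal permanences are stored per output cell (sparse): prox is an
  # environment keyed by cell id holding parallel vectors of potential
  # input rows and their permanences. prox_conn is the inverted index from
  # input cell to output cells with a connected synapse on it.
  ol$chr_in <- as.character(seq_len(ol$n_in_cells))
  ol$chr_out <- as.character(seq_len(ol$n_out))
  n_init <- if (init_frac <= 0) 0L else
    max(2L, as.integer(round(init_frac * ol$n_in_cells)))
  ol$prox <- new.env(parent = emptyenv())
  ol$init_conn <- rep(list(integer(0)), ol$n_out) # frozen initial connected
  ol$prox_conn <- new.env(parent = emptyenv()) # input row -> connected cells
  for (k in seq_len(ol$n_out)) {
    if (n_init == 0L) {
      ol$prox[[as.character(k)]] <- list(rows = integer(0),
                                         perms = numeric(0))
      next
    }
    rows <- with_rng(rng, sample.int(ol$n_in_cells, n_init))
    perms <- with_rng(rng, stats::runif(n_init))
    ol$prox[[as.character(k)]] <- list(rows = rows, perms = perms)
    conn <- rows[perms >= connected_perm]
    ol$init_conn[[k]] <- conn
    for (r in conn) {
      key <- as.character(r)
      ol$prox_conn[[key]] <- c(ol$prox_conn[[key]], k)
    }
  }

  ol$lateral <- segment_store(ol$n_out, ol$n_out * ol$n_columns,
                              connected_perm)
  # per-object training cache: lat_cache[cell, src] = segment id (0 none,
  # negative = saturated, skip)
  ol$lat_cache <- matrix(0L, ol$n_out, ol$n_columns)
  ol$active <- integer(0)
  class(ol) <- "output_layer"
  ol
}

#' @export
print.output_layer <- function(x, ...) {
  cat(sprintf(
    "<output_layer> %d cells (column %d of %d); %d lateral segments\n",
    x$n_out, x$col, x$n_columns, x$lateral$n_seg))
  invisible(x)
}

#' Feedforward overlap of the output layer
#'
#' For each output cell, the number of currently active input cells on
#' which it has a connected proximal synapse.
#'
#' @param ol An [output_layer()].
#' @param a_in Integer vector of active input-layer cell ids.
#' @return Integer vector of length `n_out`.
#' @export
ol_feedforward <- function(ol, a_in) {
  if (length(a_in) == 0L) return(integer(ol$n_out))
  if (max(a_in) > ol$n_in_cells) {
    stop("active input cell id exceeds the input layer size", call. = FALSE)
  }
  hits <- unlist(
    mget(ol$chr_in[a_in], envir = ol$prox_conn,
         ifnotfound = list(integer(0))),
    use.names = FALSE)
  tabulate(hits, nbins = ol$n_out)
}

#' Select the active output cells
#'
#' Feedforward candidates are cells with overlap `>= theta_proximal`. Each
#' candidate's lateral support is its number of active basal segments
#' against the previous time step's concatenated output activity; the
#' `s_out`-th highest support sets the activation cutoff. If fewer than
#' `s_out` candidates have any support (e.g. after a reset) the cutoff is
#' zero and all candidates become active. Cells tied at the cutoff all
#' become active, so `s_out` is a minimum, not an exact count.
#'
#' @param ol An [output_layer()].
#' @param overlap Feedforward overlaps from [ol_feedforward()].
#' @param prev_abar Integer vector of globally indexed output cells active
#'   anywhere in the network at the previous time step.
#' @return Integer vector of active cell ids (also stored in `ol$active`).
#' @export
ol_select_active <- function(ol, overlap, prev_abar = integer(0)) {
  cand <- which(overlap >= ol$theta_proximal)
  if (length(cand) == 0L) {
    ol$active <- integer(0)
    return(ol$active)
  }
  segs <- seg_active_segments(ol$lateral, prev_abar, ol$theta_lateral)
  rho <- tabulate(ol$lateral$cell[segs], nbins = ol$n_out)
  rho_cand <- rho[cand]
  xi <- if (sum(rho_cand > 0L) < ol$s_out) 0L else
    sort(rho_cand, decreasing = TRUE)[ol$s_out]
  ol$active <- cand[rho_cand >= xi]
  ol$active
}

#' Select a fresh object code
#'
#' When training switches to a new object (after a reset), `s_out` cells
#' are drawn uniformly at random to represent it. Under genuinely random
#' initial connectivity, selecting the cells whose initial synapses best
#' match the first sensation is statistically exchangeable with a uniform
#' draw; drawing directly keeps codes independent of each other — scoring
#' through a sparse greedy initialization instead concentrates selection
#' in small input-dependent pools, and two objects first touched at the
#' same feature can then draw near-identical codes.
#'
#' @param ol An [output_layer()].
#' @param a_in Active input cells of the object's first sensation
#'   (unused by the uniform draw; kept for the calling convention).
#' @param rng An [rng_stream()].
#' @return Integer vector of `s_out` cell ids.
#' @export
ol_select_new_code <- function(ol, a_in, rng) {
  sort(with_rng(rng, sample.int(ol$n_out, ol$s_out)))
}

#' Proximal learning step
#'
#' Active (clamped) output cells reinforce proximal synapses onto active
#' input cells (+`p_ff_plus`), decay their other potential synapses
#' (-`p_ff_minus`), and grow connected synapses (at `init_perm`) onto
#' active input cells they did not yet sample. Inactive output cells are
#' untouched.
#'
#' @param ol An [output_layer()].
#' @param a_in Active input cells (during training, the winner cells).
#' @param clamped Active output cells (the object's clamped code).
#' @return Invisibly `ol`.
#' @export
ol_learn_proximal <- function(ol, a_in, clamped) {
  if (length(a_in) == 0L || length(clamped) == 0L) return(invisible(ol))
  thr <- ol$connected_perm
  span <- ol$p_ff_plus + ol$p_ff_minus
  keys <- ol$chr_out[clamped]
  plist <- mget(keys, envir = ol$prox)
  lens <- vapply(plist, function(p) length(p$rows), 0L)
  # one pass over the concatenated synapse vectors of all clamped cells
  rows_all <- unlist(lapply(plist, `[[`, "rows"), use.names = FALSE)
  perms_all <- unlist(lapply(plist, `[[`, "perms"), use.names = FALSE)
  act <- rows_all %in% a_in
  new_all <- perms_all + span * act - ol$p_ff_minus
  new_all[new_all > 1] <- 1
  new_all[new_all < 0] <- 0
  was_conn <- perms_all >= thr
  is_conn <- new_all >= thr
  crossed <- which(was_conn != is_conn)
  cell_of <- rep.int(clamped, lens)
  for (i in crossed) {
    key <- ol$chr_in[rows_all[i]]
    if (is_conn[i]) {
      ol$prox_conn[[key]] <- c(ol$prox_conn[[key]], cell_of[i])
    } else {
      v <- ol$prox_conn[[key]]
      ol$prox_conn[[key]] <- v[v != cell_of[i]]
    }
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  for (j in seq_along(clamped)) {
    idx <- if (lens[j] > 0L) starts[j]:ends[j] else integer(0)
    rows <- rows_all[idx]
    perms <- new_all[idx]
    missing <- a_in[!(a_in %in% rows)]
    if (length(missing)) {
      rows <- c(rows, missing)
      perms <- c(perms, rep(ol$init_perm, length(missing)))
      if (ol$init_perm >= thr) {
        for (key in ol$chr_in[missing]) {
          ol$prox_conn[[key]] <- c(ol$prox_conn[[key]], clamped[j])
        }
      }
    }
    ol$prox[[keys[j]]] <- list(rows = rows, perms = perms)
  }
  invisible(ol)
}

#' Inspect a cell's proximal synapses
#'
#' @param ol An [output_layer()].
#' @param cell Output cell id.
#' @return List with `rows` (potential input cells) and `perms`
#'   (permanences).
#' @export
ol_proximal <- function(ol, cell) {
  ol$prox[[as.character(cell)]]
}

#' Lateral learning step
#'
#' Each active output cell maintains one basal segment per source column
#' (its own column included), grown on first exposure by sampling that
#' column's active cells and reinforced thereafter. A segment never
#' synapses onto its own cell, and never mixes source columns. Reuse
#' requires the existing segment to overlap the source code by at least
#' half of `theta_lateral`; distinct objects therefore get distinct
#' segments on a shared cell.
#'
#' @param ol An [output_layer()].
#' @param abar_codes List of length `n_columns`: each column's active
#'   (clamped) output cells as *local* ids.
#' @return Invisibly `ol`.
#' @export
ol_learn_lateral <- function(ol, abar_codes) {
  stopifnot(length(abar_codes) == ol$n_columns)
  own <- abar_codes[[ol$col]]
  if (length(own) == 0L) return(invisible(ol))
  reuse_thr <- ceiling(ol$theta_lateral / 2)
  cache <- ol$lat_cache
  for (cell in own) {
    gcell <- (ol$col - 1L) * ol$n_out + cell
    for (src in seq_len(ol$n_columns)) {
      seg <- cache[cell, src]
      if (seg < 0L) next              # saturated for this object
      bits <- (src - 1L) * ol$n_out + abar_codes[[src]]
      bits <- bits[bits != gcell]
      if (length(bits) == 0L) next
      if (seg == 0L) {
        segs <- ol$lateral$cell_segs[[cell]]
        segs <- segs[ol$lateral$src[segs] == src]
        found <- 0L
        if (length(segs)) {
          ov <- vapply(segs, function(s)
            sum(ol$lateral$syn[[s]] %in% bits), 0L)
          best <- which.max(ov)
          if (ov[best] >= reuse_thr) {
            found <- segs[best]
            seg_clear_sat(ol$lateral, found)
          }
        }
        if (found == 0L) {
          # first exposure: grow the segment, reinforce from the next one
          cache[cell, src] <- seg_create(ol$lateral, cell, bits,
                                         ol$init_perm, src = src)
          next
        }
        seg <- found
        cache[cell, src] <- seg
      }
      saturated <- seg_reinforce(ol$lateral, seg, bits, ol$p_lat_plus,
                                 ol$p_lat_minus, init_perm = ol$init_perm,
                                 grow = TRUE)
      if (saturated) cache[cell, src] <- -seg
    }
  }
  ol$lat_cache <- cache
  invisible(ol)
}

# Clear per-object training caches (called when a new code is clamped).
ol_new_object <- function(ol) {
  ol$lat_cache <- matrix(0L, ol$n_out, ol$n_columns)
  invisible(ol)
}
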