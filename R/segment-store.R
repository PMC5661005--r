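#' Dendritic segment store
#'
#' A mutable pool of dendritic segments for one population of cells over one
#' named presynaptic space (the location input for basal segments of the
#' input layer, a column's output cells for apical and lateral segments).
#' Each segment belongs to one cell and holds a set of potential synapses
#' (presynaptic index + permanence in \[0, 1\]). A synapse conducts only when
#' its permanence reaches `connected_perm`. The store keeps an inverted
#' index from presynaptic bit to segments with a connected synapse on that
#' bit, so computing which segments are active for a sparse input costs
#' time proportional to the input's active synapse count, not to the number
#' of segments.
#'
#' This is an internal engine type with reference semantics (an
#' environment): learning functions modify it in place.
#'
#' @param n_cells Number of postsynaptic cells.
#' @param presyn_size Size of the presynaptic space in bits.
#' @param connected_perm Permanence threshold for a conducting synapse.
#' @return An object of class `segment_store`.
#' @keywords internal
segment_store <- function(n_cells, presyn_size, connected_perm = 0.5) {
  st <- new.env(parent = emptyenv())
  st$n_cells <- as.integer(n_cells)
  st$presyn_size <- as.integer(presyn_size)
  st$connected_perm <- connected_perm
  st$n_seg <- 0L
  cap <- 256L
  st$cell <- integer(cap)          # segment id -> owning cell
  st$src <- integer(cap)           # segment id -> source column (0 if n/a)
  st$syn <- vector("list", cap)    # segment id -> presynaptic indices
  st$perm <- vector("list", cap)   # segment id -> permanences
  st$cell_segs <- vector("list", n_cells)  # cell -> its segment ids
  st$index <- new.env(parent = emptyenv()) # bit (char) -> connected seg ids
  st$chr <- as.character(seq_len(presyn_size))  # precomputed index keys
  st$sat <- logical(cap)                   # segment id -> saturated memo
  class(st) <- "segment_store"
  st
}

#' @export
print.segment_store <- function(x, ...) {
  cat(sprintf("<segment_store> %d segments over %d cells (%d-bit input)\n",
              x$n_seg, x$n_cells, x$presyn_size))
  invisible(x)
}

seg_index_add <- function(st, bits, id) {
  idx <- st$index
  for (k in st$chr[bits]) {
    idx[[k]] <- c(idx[[k]], id)
  }
}

seg_index_remove <- function(st, bits, id) {
  idx <- st$index
  for (k in st$chr[bits]) {
    v <- idx[[k]]
    idx[[k]] <- v[v != id]
  }
}

# Create a segment on `cell` sampling `bits` at permanence `perm0`.
seg_create <- function(st, cell, bits, perm0, src = 0L) {
  id <- st$n_seg + 1L
  if (id > length(st$cell)) {       # amortized doubling
    new_cap <- length(st$cell) * 2L
    st$cell <- c(st$cell, integer(new_cap - length(st$cell)))
    st$src <- c(st$src, integer(new_cap - length(st$src)))
    st$sat <- c(st$sat, logical(new_cap - length(st$sat)))
    length(st$syn) <- new_cap
    length(st$perm) <- new_cap
  }
  st$n_seg <- id
  st$cell[id] <- as.integer(cell)
  st$src[id] <- as.integer(src)
  st$syn[[id]] <- as.integer(bits)
  st$perm[[id]] <- rep(perm0, length(bits))
  st$cell_segs[[cell]] <- c(st$cell_segs[[cell]], id)
  if (perm0 >= st$connected_perm) seg_index_add(st, bits, id)
  id
}

# Per-segment counts of connected synapses onto `active_bits`
# (integer vector of length n_seg).
seg_hit_counts <- function(st, active_bits) {
  if (st$n_seg == 0L) return(integer(0))
  if (length(active_bits) == 0L) return(integer(st$n_seg))
  hits <- unlist(
    mget(st$chr[active_bits], envir = st$index,
         ifnotfound = list(integer(0))),
    use.names = FALSE)
  tabulate(hits, nbins = st$n_seg)
}

# Ids of segments with >= theta connected synapses among `active_bits`.
seg_active_segments <- function(st, active_bits, theta) {
  counts <- seg_hit_counts(st, active_bits)
  which(counts >= theta)
}

# Cells owning at least one active segment.
seg_active_cells <- function(st, active_bits, theta) {
  unique(st$cell[seg_active_segments(st, active_bits, theta)])
}

# Best potential-overlap segment on `cell` against `bits`.
# Returns list(id, overlap); id = NA if the cell has no segments.
seg_best_match <- function(st, cell, bits) {
  segs <- st$cell_segs[[cell]]
  if (is.null(segs) || length(segs) == 0L) {
    return(list(id = NA_integer_, overlap = 0L))
  }
  ov <- vapply(segs, function(s) sum(st$syn[[s]] %in% bits), 0L)
  best <- which.max(ov)
  list(id = segs[best], overlap = ov[best])
}

# Hebbian segment update: potential synapses onto active bits gain p_plus,
# others lose p_minus (both clamped to [0,1]); missing active bits are grown
# as new potential synapses at init_perm when grow = TRUE. The connected
# index is maintained across threshold crossings. Returns TRUE when the
# segment is saturated for this input (all synapses active at permanence 1,
# nothing left to grow), so callers repeating the same context can skip.
seg_reinforce <- function(st, id, active_bits, p_plus, p_minus,
                          init_perm = NULL, grow = FALSE) {
  # a segment whose every synapse sits at permanence 1 under its own
  # context cannot change when that context recurs
  if (st$sat[id]) return(TRUE)
  syn <- st$syn[[id]]
  pm <- st$perm[[id]]
  act <- syn %in% active_bits
  new_pm <- pm + (p_plus + p_minus) * act - p_minus
  new_pm[new_pm > 1] <- 1
  new_pm[new_pm < 0] <- 0
  thr <- st$connected_perm
  crossed <- (pm >= thr) != (new_pm >= thr)
  if (any(crossed)) {
    newly_conn <- syn[crossed & new_pm >= thr]
    newly_disc <- syn[crossed & new_pm < thr]
    if (length(newly_conn)) seg_index_add(st, newly_conn, id)
    if (length(newly_disc)) seg_index_remove(st, newly_disc, id)
  }
  st$perm[[id]] <- new_pm
  n_missing <- 0L
  if (grow && !is.null(init_perm)) {
    missing <- active_bits[!(active_bits %in% syn)]
    n_missing <- length(missing)
    if (n_missing) {
      st$syn[[id]] <- c(syn, as.integer(missing))
      st$perm[[id]] <- c(new_pm, rep(init_perm, n_missing))
      if (init_perm >= thr) seg_index_add(st, missing, id)
    }
  }
  saturated <- n_missing == 0L && all(act) && all(new_pm == 1)
  if (saturated) st$sat[id] <- TRUE
  saturated
}

# Forget a segment's saturation memo (required whenever the segment is
# about to be trained on a context other than the one that saturated it,
# e.g. segment reuse by a different object).
seg_clear_sat <- function(st, id) {
  st$sat[id] <- FALSE
  invisible(id)
}

# Mild negative reinforcement of a mispredicting segment: synapses onto the
# currently active bits are decremented by p_punish.
seg_punish <- function(st, id, active_bits, p_punish) {
  seg_clear_sat(st, id)
  syn <- st$syn[[id]]
  pm <- st$perm[[id]]
  act <- syn %in% active_bits
  if (!any(act)) return(invisible(id))
  new_pm <- pm
  new_pm[act] <- pmax(new_pm[act] - p_punish, 0)
  thr <- st$connected_perm
  newly_disc <- syn[pm >= thr & new_pm < thr]
  st$perm[[id]] <- new_pm
  if (length(newly_disc)) seg_index_remove(st, newly_disc, id)
  invisible(id)
}

# Plain-list snapshot (for checkpoints/tests).
seg_store_to_list <- function(st) {
  ids <- seq_len(st$n_seg)
  list(
    n_cells = st$n_cells,
    presyn_size = st$presyn_size,
    connected_perm = st$connected_perm,
    segments = lapply(ids, function(i)
      list(cell = st$cell[i], src = st$src[i],
           syn = st$syn[[i]], perm = st$perm[[i]]))
  )
}

seg_store_from_list <- function(x) {
  st <- segment_store(x$n_cells, x$presyn_size, x$connected_perm)
  for (s in x$segments) {
    seg_create(st, s$cell, s$syn, 0, src = s$src)
    st$perm[[st$n_seg]] <- as.numeric(s$perm)
    conn <- s$syn[s$perm >= x$connected_perm]
    if (length(conn)) seg_index_add(st, conn, st$n_seg)
  }
  st
}

# All permanences as one numeric vector (invariant checks in tests).
seg_all_perms <- function(st) {
  if (st$n_seg == 0L) return(numeric(0))
  unlist(st$perm[seq_len(st$n_seg)], use.names = FALSE)
}
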