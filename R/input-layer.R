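#' Minicolumn-structured input layer of one cortical column
#'
#' Cells are arranged in `n_in` minicolumns of `m` cells; all cells of a
#' minicolumn share the same feedforward (sensory) receptive field, so a
#' sensory feature maps directly to a sparse set of winner minicolumns.
#' Basal distal segments listen to the external location signal and put
#' cells into the predictive state; a predicted cell in a winner minicolumn
#' fires first and suppresses its neighbors, yielding a sparse code that is
#' specific to a feature *at a location*. If no cell in a winner minicolumn
#' is predicted, the whole minicolumn bursts. Apical segments carry feedback
#' from the column's output layer: apical support lowers the basal
#' activation threshold and breaks ties among several predicted cells.
#'
#' Cell numbering: cell `i` of minicolumn `j` has id `(j-1)*m + i`.
#'
#' @param n_in Number of minicolumns (default 150).
#' @param m Cells per minicolumn (default 16).
#' @param s_in Active minicolumns per sensation (default 10).
#' @param n_ext Location input width in bits (default 2,400).
#' @param n_out Output-layer size (apical presynaptic space; default 4,096).
#' @param theta_basal Basal activation threshold (connected synapses on
#'   active location bits needed for a prediction; default 6).
#' @param theta_basal_apical Reduced basal threshold used when a cell also
#'   has apical support (default: two below `theta_basal`, at least 1 —
#'   feedback biases predictions but cannot create them on its own).
#' @param theta_apical Connected-synapse threshold for an active apical
#'   segment (default 6).
#' @param theta_match Minimum potential-synapse overlap for an existing
#'   basal segment to be reused (and its owner favored as burst winner)
#'   instead of growing a fresh segment on an unused cell (default 4).
#'   Chance overlaps between sparse location codes sit at 0-1 bits, so a
#'   low-but-real threshold separates genuine re-encounters of a location
#'   from noise; accepting chance matches would gradually merge different
#'   locations' context cells and destroy the feature-at-location code.
#' @param connected_perm Permanence at which a synapse conducts (0.5).
#' @param p_plus,p_minus Basal/apical permanence increment and decrement.
#' @param p_punish Decrement applied to segments that predicted a cell which
#'   then lost the within-minicolumn competition.
#' @param init_perm Permanence of newly grown synapses (0.6: connected at
#'   birth, giving one-shot learning of a location context).
#' @return Mutable object of class `input_layer`.
#' @export
input_layer <- function(n_in = 150L, m = 16L, s_in = 10L,
                        n_ext = 2400L, n_out = 4096L,
                        theta_basal = 6L, theta_basal_apical = NULL,
                        theta_apical = 6L,
                        theta_match = 4L,
                        connected_perm = 0.5,
                        p_plus = 0.1, p_minus = 0.02, p_punish = 0.002,
                        init_perm = 0.6) {
  if (is.null(theta_basal_apical)) {
    theta_basal_apical <- max(1L, as.integer(theta_basal) - 2L)
  }
  stopifnot(theta_basal_apical > 0L, theta_basal_apical <= theta_basal,
            s_in <= n_in,
            connected_perm >= 0, connected_perm <= 1,
            init_perm >= 0, init_perm <= 1)
  il <- new.env(parent = emptyenv())
  il$n_in <- as.integer(n_in); il$m <- as.integer(m)
  il$s_in <- as.integer(s_in)
  il$n_ext <- as.integer(n_ext); il$n_out <- as.integer(n_out)
  il$n_cells <- il$m * il$n_in
  il$theta_basal <- as.integer(theta_basal)
  il$theta_basal_apical <- as.integer(theta_basal_apical)
  il$theta_apical <- as.integer(theta_apical)
  il$theta_match <- as.integer(theta_match)
  il$p_plus <- p_plus; il$p_minus <- p_minus; il$p_punish <- p_punish
  il$init_perm <- init_perm
  il$basal <- segment_store(il$n_cells, il$n_ext, connected_perm)
  il$apical <- segment_store(il$n_cells, il$n_out, connected_perm)
  il$apical_cache <- new.env(parent = emptyenv()) # cell -> segment (object)
  il_clear_state(il)
  class(il) <- "input_layer"
  il
}

#' @export
print.input_layer <- function(x, ...) {
  cat(sprintf(
    "<input_layer> %d minicolumns x %d cells; %d basal / %d apical segments\n",
    x$n_in, x$m, x$basal$n_seg, x$apical$n_seg))
  invisible(x)
}

il_clear_state <- function(il) {
  il$active <- integer(0)      # active cell ids
  il$predicted <- integer(0)   # predictive cell ids
  il$apical_cells <- integer(0)
  il$winners <- integer(0)     # learning cells (one per active minicolumn)
  il$burst_cols <- integer(0)
  il$losers <- integer(0)      # predicted cells beaten in their minicolumn
  il$basal_counts <- NULL      # per-segment active-synapse counts
  invisible(il)
}

il_cells_of_col <- function(il, j) ((j - 1L) * il$m + 1L):(j * il$m)

il_col_of_cell <- function(il, cell) ((cell - 1L) %/% il$m) + 1L

#' Compute the predictive state of the input layer
#'
#' A cell is predictive if one of its basal segments has at least
#' `theta_basal` connected synapses onto the active location bits — or at
#' least `theta_basal_apical` when the cell also has an active apical
#' segment (feedback support from the output layer). Feedback can therefore
#' sharpen or rescue predictions but never create one without basal
#' evidence.
#'
#' @param il An [input_layer()].
#' @param location Location signal, an [sdr()] of size `n_ext`.
#' @param feedback Integer vector of active output cells of the same column
#'   (previous time step); empty for no feedback.
#' @return Invisibly `il`, with `il$predicted` and `il$apical_cells` set.
#' @export
il_predict <- function(il, location, feedback = integer(0)) {
  stopifnot(inherits(location, "sdr"))
  if (location$size != il$n_ext) {
    stop("location SDR size does not match `n_ext`", call. = FALSE)
  }
  il$apical_cells <- seg_active_cells(il$apical, feedback, il$theta_apical)
  counts <- seg_hit_counts(il$basal, location$active)
  il$basal_counts <- counts
  segs_lo <- which(counts >= il$theta_basal_apical)
  cells_lo <- il$basal$cell[segs_lo]
  hi <- counts[segs_lo] >= il$theta_basal
  predicted <- unique(c(
    cells_lo[hi],
    intersect(cells_lo, il$apical_cells)
  ))
  il$predicted <- predicted
  invisible(il)
}

#' Activate cells in the winner minicolumns
#'
#' Within each winner minicolumn, the predicted cells become active; if
#' several are predicted and at least one has apical support, only the
#' supported ones fire (feedback tie-break). A winner minicolumn with no
#' predicted cell bursts: all `m` cells fire, signalling an unanticipated
#' feature/location pair.
#'
#' @param il An [input_layer()] on which [il_predict()] has run.
#' @param winner_cols Integer vector of winner minicolumn indices (for the
#'   simulator this is the active-bit set of the sensory feature SDR).
#' @return Invisibly `il`, with `il$active`, `il$burst_cols`, `il$losers`.
#' @export
il_activate <- function(il, winner_cols) {
  winner_cols <- as.integer(winner_cols)
  if (length(winner_cols) == 0L) {
    stop("`winner_cols` must not be empty", call. = FALSE)
  }
  active <- integer(0)
  burst <- integer(0)
  losers <- integer(0)
  for (j in winner_cols) {
    cells <- il_cells_of_col(il, j)
    pc <- cells[cells %in% il$predicted]
    if (length(pc) == 0L) {
      active <- c(active, cells)
      burst <- c(burst, j)
    } else {
      ap <- pc[pc %in% il$apical_cells]
      win <- if (length(pc) > 1L && length(ap) > 0L) ap else pc
      active <- c(active, win)
      losers <- c(losers, setdiff(pc, win))
    }
  }
  il$active <- active
  il$burst_cols <- burst
  il$losers <- losers
  invisible(il)
}

#' Basal learning step for the input layer
#'
#' For each active minicolumn: predicted cells that fired reinforce the
#' basal segments that predicted them (+`p_plus` on synapses onto active
#' location bits, -`p_minus` on the segment's other potential synapses,
#' missing active bits grown at `init_perm`). In a bursting minicolumn one
#' winner cell is chosen — the cell whose best segment has the largest
#' potential overlap with the location, ties broken by fewest segments then
#' at random — and it grows a segment sampling all active location bits
#' (or extends its best-matching segment when one already overlaps the
#' location). Predicted cells that lost the within-minicolumn competition
#' have the offending segments decremented by `p_punish`.
#'
#' @param il An [input_layer()] after [il_activate()].
#' @param location The location [sdr()] of this sensation.
#' @param rng An [rng_stream()] (burst-winner tie-break).
#' @return Invisibly `il`, with `il$winners` set to the learning cells.
#' @export
il_learn_basal <- function(il, location, rng) {
  bits <- location$active
  if (length(bits) == 0L) {
    il$winners <- integer(0)
    return(invisible(il))
  }
  counts <- il$basal_counts
  winners <- integer(0)
  active_cols <- unique(il_col_of_cell(il, il$active))
  for (j in active_cols) {
    cells <- il_cells_of_col(il, j)
    if (j %in% il$burst_cols) {
      # winner = best potential match; sub-threshold overlaps are chance
      # collisions and count as no match
      matches <- lapply(cells, function(cc) seg_best_match(il$basal, cc, bits))
      ov <- vapply(matches, `[[`, 0L, "overlap")
      ov[ov < il$theta_match] <- 0L
      nseg <- vapply(cells, function(cc)
        length(il$basal$cell_segs[[cc]]), 0L)
      cand <- which(ov == max(ov))
      cand <- cand[nseg[cand] == min(nseg[cand])]
      pick <- if (length(cand) == 1L) cand else
        with_rng(rng, sample(cand, 1L))
      wcell <- cells[pick]
      best <- matches[[pick]]
      if (!is.na(best$id) && best$overlap >= il$theta_match) {
        seg_clear_sat(il$basal, best$id)  # context may differ from memo
        seg_reinforce(il$basal, best$id, bits, il$p_plus, il$p_minus,
                      init_perm = il$init_perm, grow = TRUE)
      } else {
        seg_create(il$basal, wcell, bits, il$init_perm)
      }
      winners <- c(winners, wcell)
    } else {
      fired <- cells[cells %in% il$active]
      for (cc in fired) {
        thr <- if (cc %in% il$apical_cells) il$theta_basal_apical else
          il$theta_basal
        segs <- il$basal$cell_segs[[cc]]
        segs <- segs[counts[segs] >= thr]
        for (s in segs) {
          seg_reinforce(il$basal, s, bits, il$p_plus, il$p_minus,
                        init_perm = il$init_perm, grow = TRUE)
        }
      }
      winners <- c(winners, fired)
    }
  }
  # punish segments whose prediction lost the in-minicolumn competition
  for (cc in il$losers) {
    segs <- il$basal$cell_segs[[cc]]
    segs <- segs[counts[segs] >= il$theta_basal_apical]
    for (s in segs) seg_punish(il$basal, s, bits, il$p_punish)
  }
  il$winners <- winners
  invisible(il)
}

#' Apical learning step for the input layer
#'
#' Winner cells grow or reinforce apical segments sampling the active
#' output cells of their column, with the same Hebbian rule as basal
#' segments. A segment is reused when its potential synapses already
#' overlap the output code by at least `theta_apical`; otherwise a new
#' segment samples the full code.
#'
#' @param il An [input_layer()] after [il_learn_basal()].
#' @param output_active Integer vector of active output cells (during
#'   training, the object's clamped code).
#' @return Invisibly `il`.
#' @export
il_learn_apical <- function(il, output_active) {
  if (length(output_active) == 0L) return(invisible(il))
  for (cc in il$winners) {
    key <- as.character(cc)
    seg <- il$apical_cache[[key]]   # resolved once per object training
    if (is.null(seg)) {
      best <- seg_best_match(il$apical, cc, output_active)
      if (!is.na(best$id) && best$overlap >= il$theta_apical) {
        seg <- best$id
        seg_clear_sat(il$apical, seg)  # reused under a new output code
      } else {
        # first exposure: grow the segment, reinforce from the next one
        il$apical_cache[[key]] <- seg_create(il$apical, cc, output_active,
                                             il$init_perm)
        next
      }
      il$apical_cache[[key]] <- seg
    }
    seg_reinforce(il$apical, seg, output_active, il$p_plus,
                  il$p_minus, init_perm = il$init_perm, grow = TRUE)
  }
  invisible(il)
}

# Clear per-object training caches (called when training switches object).
il_new_object <- function(il) {
  il$apical_cache <- new.env(parent = emptyenv())
  invisible(il)
}
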