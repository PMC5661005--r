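#' A network of laterally connected cortical columns
#'
#' Wires `num_columns` columns — each an [input_layer()] plus an
#' [output_layer()] — into one model. Columns interact in two ways: lateral
#' basal input in the output layer (every column sees every other column's
#' previous-step output activity, the voting pathway) and intra-column
#' feedback from the output layer onto apical dendrites of the input layer.
#' The network owns the trained-object catalog: the clamped output code
#' stored per column when each object was learned.
#'
#' @param num_columns Number of cortical columns (default 1).
#' @param n_in,m,s_in Input-layer geometry; see [input_layer()].
#' @param n_ext Location input width.
#' @param n_out,s_out Output-layer geometry; see [output_layer()].
#' @param theta_basal,theta_basal_apical,theta_apical Input-layer segment
#'   thresholds.
#' @param theta_proximal,theta_lateral Output-layer thresholds.
#' @param connected_perm Synapse connection threshold (all zones).
#' @param training_passes Passes over an object's slots during learning
#'   (default 3: the network senses each feature three times).
#' @param classify_threshold Overlap with a stored code required (and
#'   forbidden for all other codes) to call an object recognized
#'   (default 30).
#' @param seed Integer seed for the network's random initial connectivity.
#' @return Mutable object of class `cortical_network`.
#' @export
cortical_network <- function(num_columns = 1L,
                             n_in = 150L, m = 16L, s_in = 10L,
                             n_ext = 2400L,
                             n_out = 4096L, s_out = 40L,
                             theta_basal = 6L, theta_basal_apical = NULL,
                             theta_apical = 6L,
                             theta_proximal = 8L, theta_lateral = 18L,
                             connected_perm = 0.5,
                             training_passes = 3L,
                             classify_threshold = 30L,
                             seed = 1L) {
  stopifnot(num_columns >= 1L)
  net <- new.env(parent = emptyenv())
  net$num_columns <- as.integer(num_columns)
  net$n_out <- as.integer(n_out)
  net$training_passes <- as.integer(training_passes)
  net$classify_threshold <- as.integer(classify_threshold)
  net$seed <- as.integer(seed)
  init_rng <- rng_stream(derive_seed(seed, "network-init"))
  net$columns <- lapply(seq_len(num_columns), function(c) {
    il <- input_layer(n_in = n_in, m = m, s_in = s_in, n_ext = n_ext,
                      n_out = n_out, theta_basal = theta_basal,
                      theta_basal_apical = theta_basal_apical,
                      theta_apical = theta_apical,
                      connected_perm = connected_perm)
    ol <- output_layer(n_out = n_out, s_out = s_out,
                       n_in_cells = il$n_cells, n_columns = num_columns,
                       col = c, theta_proximal = theta_proximal,
                       theta_lateral = theta_lateral,
                       connected_perm = connected_perm,
                       rng = init_rng)
    list(il = il, ol = ol)
  })
  net$prev_abar <- integer(0)
  net$catalog <- list()     # object id (character) -> per-column codes
  class(net) <- "cortical_network"
  net
}

#' @export
print.cortical_network <- function(x, ...) {
  cat(sprintf(
    "<cortical_network> %d column(s), %d output cells each; %d objects stored\n",
    x$num_columns, x$n_out, length(x$catalog)))
  invisible(x)
}

#' Reset network activity
#'
#' Clears all activation and predictive state and the previous-step lateral
#' activity, as happens between objects during training and testing.
#' Learned synapses and the object catalog are untouched; resetting twice
#' is the same as resetting once.
#'
#' @param net A [cortical_network()].
#' @return Invisibly `net`.
#' @export
net_reset <- function(net) {
  for (colm in net$columns) {
    il_clear_state(colm$il)
    colm$ol$active <- integer(0)
  }
  net$prev_abar <- integer(0)
  invisible(net)
}

#' Train the network on one object
#'
#' Resets the network, clamps a fresh output code per column (chosen by
#' best feedforward match through the frozen random initial connectivity,
#' remaining ties at random), then runs `training_passes` passes over the
#' object's slots. At each sensation the input layer predicts, activates
#' and learns its basal (location) and apical (feedback) segments, and the
#' clamped output cells learn proximal and lateral synapses. The clamped
#' codes are stored in the object catalog. A new code overlapping an
#' already stored code by at least `classify_threshold` triggers a warning
#' (a genuine representational collision) but is kept.
#'
#' @param net A [cortical_network()].
#' @param library An `object_library`.
#' @param object_id Object to learn.
#' @param rng An [rng_stream()] (sensation order, code tie-breaks,
#'   burst-winner tie-breaks).
#' @return Invisibly the per-column clamped codes.
#' @export
net_train_object <- function(net, library, object_id, rng) {
  obj_key <- as.character(object_pairs(library, object_id)$object_id)
  net_reset(net)
  stream <- training_stream(library, object_id,
                            passes = net$training_passes,
                            num_columns = net$num_columns, rng = rng)
  clamped <- vector("list", net$num_columns)
  for (c in seq_len(net$num_columns)) {
    il <- net$columns[[c]]$il; ol <- net$columns[[c]]$ol
    s <- stream[[1L]][[c]]
    il_predict(il, s$location, feedback = integer(0))
    il_activate(il, s$feature$active)
    code <- ol_select_new_code(ol, il$active, rng)
    for (key in names(net$catalog)) {
      if (length(intersect(net$catalog[[key]][[c]], code)) >=
          net$classify_threshold) {
        warning(sprintf(
          "object %s: new code collides with stored object %s in column %d",
          obj_key, key, c), call. = FALSE)
      }
    }
    clamped[[c]] <- code
    ol_new_object(ol)
    il_new_object(il)
  }
  for (t in seq_along(stream)) {
    for (c in seq_len(net$num_columns)) {
      il <- net$columns[[c]]$il; ol <- net$columns[[c]]$ol
      s <- stream[[t]][[c]]
      il_predict(il, s$location, feedback = clamped[[c]])
      il_activate(il, s$feature$active)
      il_learn_basal(il, s$location, rng)
      il_learn_apical(il, clamped[[c]])
      ol_learn_proximal(ol, il$winners, clamped[[c]])
    }
    for (c in seq_len(net$num_columns)) {
      ol_learn_lateral(net$columns[[c]]$ol, clamped)
    }
  }
  net$catalog[[obj_key]] <- clamped
  net_reset(net)
  invisible(clamped)
}

#' Train the network on a whole library
#'
#' Objects are learned one after another in random order, with a reset in
#' between.
#'
#' @param net A [cortical_network()].
#' @param library An `object_library`.
#' @param rng An [rng_stream()].
#' @param object_ids Objects to train (default: all).
#' @return Invisibly `net`.
#' @export
net_train_library <- function(net, library, rng,
                              object_ids = seq_along(library$objects)) {
  order_ids <- with_rng(rng, sample(object_ids))
  for (oid in order_ids) net_train_object(net, library, oid, rng)
  invisible(net)
}

#' Run inference over a sensation stream
#'
#' Resets the network, then processes the sensations with plasticity off.
#' Per sensation and column: the input layer predicts (apical feedback from
#' the column's own previous output activity) and activates; the output
#' layer scores feedforward candidates and applies the lateral vote against
#' the previous step's activity of all columns. After each sensation the
#' output activity is classified against the catalog.
#'
#' @param net A trained [cortical_network()].
#' @param sensations A stream from [sensation_stream()] (optionally
#'   corrupted), with `num_columns` entries per sensation.
#' @return List with `active` (per sensation, per column active output
#'   cells), `n_active` (matrix: sensations x columns),
#'   `classification` (integer vector, `NA` = ambiguous).
#' @export
net_infer <- function(net, sensations) {
  n_c <- net$num_columns
  if (length(sensations) && length(sensations[[1L]]) != n_c) {
    stop("sensation column count does not match the network", call. = FALSE)
  }
  net_reset(net)
  K <- length(sensations)
  active_rec <- vector("list", K)
  n_active <- matrix(0L, nrow = K, ncol = n_c)
  classification <- rep(NA_integer_, K)
  for (t in seq_len(K)) {
    prev <- net$prev_abar
    overlaps <- vector("list", n_c)
    for (c in seq_len(n_c)) {
      il <- net$columns[[c]]$il; ol <- net$columns[[c]]$ol
      s <- sensations[[t]][[c]]
      il_predict(il, s$location, feedback = ol$active)
      il_activate(il, s$feature$active)
      overlaps[[c]] <- ol_feedforward(ol, il$active)
    }
    step_active <- vector("list", n_c)
    for (c in seq_len(n_c)) {
      ol <- net$columns[[c]]$ol
      step_active[[c]] <- ol_select_active(ol, overlaps[[c]], prev)
      n_active[t, c] <- length(step_active[[c]])
    }
    net$prev_abar <- unlist(lapply(seq_len(n_c), function(c)
      (c - 1L) * net$n_out + step_active[[c]]), use.names = FALSE)
    active_rec[[t]] <- step_active
    classification[t] <- net_classify(net, step_active)
  }
  list(active = active_rec, n_active = n_active,
       classification = classification)
}

#' Classify output activity against the stored object catalog
#'
#' An object is recognized when, in *every* column, the output activity
#' overlaps its stored code by at least `classify_threshold` while every
#' other stored code stays below that threshold.
#'
#' @param net A [cortical_network()].
#' @param active Per-column list of active output cell ids.
#' @return The recognized object id, or `NA` (ambiguous / no object).
#' @export
net_classify <- function(net, active) {
  ids <- names(net$catalog)
  n_obj <- length(ids)
  if (n_obj == 0L) stop("the object catalog is empty", call. = FALSE)
  thr <- net$classify_threshold
  ovl <- matrix(0L, nrow = n_obj, ncol = net$num_columns)
  for (c in seq_len(net$num_columns)) {
    member <- logical(net$n_out)
    member[active[[c]]] <- TRUE
    ovl[, c] <- vapply(ids, function(key)
      sum(member[net$catalog[[key]][[c]]]), 0L)
  }
  qualified <- which(apply(ovl >= thr, 1L, all))
  if (length(qualified) != 1L) return(NA_integer_)
  if (any(ovl[-qualified, , drop = FALSE] >= thr)) return(NA_integer_)
  as.integer(ids[qualified])
}

#' Retrieve the stored code for an object
#'
#' @param net A [cortical_network()].
#' @param object_id Trained object id.
#' @return Per-column list of stored output cell ids.
#' @export
net_stored_code <- function(net, object_id) {
  code <- net$catalog[[as.character(object_id)]]
  if (is.null(code)) stop("object not in catalog", call. = FALSE)
  code
}

#' Checkpoint a trained network to JSON
#'
#' Serializes everything needed to resume the network: parameters (seed
#' included), the object catalog, and every column's basal, apical,
#' lateral, and proximal synapses with their permanences. The format is a
#' single JSON document; it is intended for the modest networks used in
#' examples and tests — full-size trained networks are better regenerated
#' from their seeds.
#'
#' @param net A [cortical_network()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
net_checkpoint <- function(net, path) {
  il1 <- net$columns[[1]]$il; ol1 <- net$columns[[1]]$ol
  payload <- list(
    params = list(
      num_columns = net$num_columns, n_in = il1$n_in, m = il1$m,
      s_in = il1$s_in, n_ext = il1$n_ext, n_out = ol1$n_out,
      s_out = ol1$s_out, theta_basal = il1$theta_basal,
      theta_basal_apical = il1$theta_basal_apical,
      theta_apical = il1$theta_apical, theta_match = il1$theta_match,
      theta_proximal = ol1$theta_proximal,
      theta_lateral = ol1$theta_lateral,
      connected_perm = ol1$connected_perm,
      training_passes = net$training_passes,
      classify_threshold = net$classify_threshold,
      seed = net$seed),
    catalog = net$catalog,
    columns = lapply(net$columns, function(cc) {
      cells <- ls(cc$ol$prox)
      prox <- lapply(cells, function(k) cc$ol$prox[[k]])
      names(prox) <- cells
      list(basal = seg_store_to_list(cc$il$basal),
           apical = seg_store_to_list(cc$il$apical),
           lateral = seg_store_to_list(cc$ol$lateral),
           prox = prox)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a network from a checkpoint
#'
#' @param path File written by [net_checkpoint()].
#' @return A [cortical_network()] equivalent to the checkpointed one.
#' @export
net_restore <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  p <- obj$params
  net <- cortical_network(
    num_columns = p$num_columns, n_in = p$n_in, m = p$m, s_in = p$s_in,
    n_ext = p$n_ext, n_out = p$n_out, s_out = p$s_out,
    theta_basal = p$theta_basal,
    theta_basal_apical = p$theta_basal_apical,
    theta_apical = p$theta_apical,
    theta_proximal = p$theta_proximal, theta_lateral = p$theta_lateral,
    connected_perm = p$connected_perm,
    training_passes = p$training_passes,
    classify_threshold = p$classify_threshold, seed = p$seed)
  for (c in seq_len(net$num_columns)) {
    saved <- obj$columns[[c]]
    il <- net$columns[[c]]$il; ol <- net$columns[[c]]$ol
    il$theta_match <- as.integer(p$theta_match)
    restore_store <- function(x) {
      seg_store_from_list(list(
        n_cells = x$n_cells, presyn_size = x$presyn_size,
        connected_perm = x$connected_perm,
        segments = lapply(x$segments, function(s)
          list(cell = as.integer(s$cell), src = as.integer(s$src),
               syn = as.integer(unlist(s$syn)),
               perm = as.numeric(unlist(s$perm))))))
    }
    il$basal <- restore_store(saved$basal)
    il$apical <- restore_store(saved$apical)
    ol$lateral <- restore_store(saved$lateral)
    ol$prox <- new.env(parent = emptyenv())
    ol$prox_conn <- new.env(parent = emptyenv())
    for (k in names(saved$prox)) {
      rows <- as.integer(unlist(saved$prox[[k]]$rows))
      perms <- as.numeric(unlist(saved$prox[[k]]$perms))
      ol$prox[[k]] <- list(rows = rows, perms = perms)
      cell <- as.integer(k)
      for (r in rows[perms >= ol$connected_perm]) {
        key <- as.character(r)
        ol$prox_conn[[key]] <- c(ol$prox_conn[[key]], cell)
      }
    }
  }
  net$catalog <- lapply(obj$catalog, function(codes)
    lapply(codes, function(v) as.integer(unlist(v))))
  net
}
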