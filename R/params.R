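# Parameter trees.
#
# Learned parameters are nested named lists whose leaves are numeric
# arrays.  Leaves named run_mean / run_var are batch-norm buffers: they are
# excluded from parameter counts, gradient updates and weight decay.

.fg_buffer_names <- c("run_mean", "run_var")

fg_is_leaf <- function(x) is.numeric(x)

# apply f(leaf, name) to every numeric leaf, preserving structure and
# attributes (init scheme tags live in attributes)
fg_node_names <- function(p) {
  nms <- names(p)
  if (is.null(nms)) nms <- rep("", length(p))
  nms
}

fg_tree_map <- function(p, f, name = "") {
  if (fg_is_leaf(p)) return(f(p, name))
  if (is.list(p)) {
    nms <- fg_node_names(p)
    for (k in seq_along(p)) {
      if (!is.null(p[[k]])) p[[k]] <- fg_tree_map(p[[k]], f, nms[k])
    }
  }
  p
}

# binary version: walks p and g in lockstep (g may have NULL leaves where no
# gradient exists, e.g. buffers)
fg_tree_map2 <- function(p, g, f, name = "") {
  if (fg_is_leaf(p)) {
    if (is.null(g) || name %in% .fg_buffer_names) return(p)
    return(f(p, g, name))
  }
  if (is.list(p)) {
    nms <- fg_node_names(p)
    for (k in seq_along(p)) {
      if (!is.null(p[[k]]))
        p[[k]] <- fg_tree_map2(p[[k]], g[[k]], f, nms[k])
    }
  }
  p
}

# sum of two congruent gradient trees (used to accumulate skip gradients)
fg_tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (fg_is_leaf(a)) return(a + b)
  for (k in seq_along(a)) a[[k]] <- fg_tree_add(a[[k]], b[[k]])
  a
}

fg_count_params <- function(p) {
  total <- 0
  walk <- function(x, name) {
    if (fg_is_leaf(x)) {
      if (!(name %in% .fg_buffer_names)) total <<- total + length(x)
      return(invisible(NULL))
    }
    if (is.list(x)) {
      nms <- fg_node_names(x)
      for (k in seq_along(x)) if (!is.null(x[[k]])) walk(x[[k]], nms[k])
    }
  }
  walk(p, "")
  total
}

# re-draw every learned leaf according to its recorded initialisation
# scheme; batch norm resets to the identity (gamma 1, beta 0, zeroed
# running mean, unit running variance)
fg_reinit <- function(p) {
  if (inherits(p, "fg_conv_params")) return(draw_conv(p))
  if (inherits(p, "fg_bn_params")) {
    p$gamma[] <- 1; p$beta[] <- 0
    p$run_mean[] <- 0; p$run_var[] <- 1
    return(p)
  }
  if (is.list(p)) {
    for (k in seq_along(p)) if (!is.null(p[[k]])) p[[k]] <- fg_reinit(p[[k]])
  }
  p
}
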