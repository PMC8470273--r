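#' Event-count cost model over a diploid-number state grid
#'
#' The state space is the even diploid numbers in `state_range` (Sankoff
#' parsimony needs a finite grid; the default 40--64 brackets every diploid
#' number reported for Helicoidea). Moving from parent state `a` to child
#' state `b` costs `w_T * (a - b) / 2` translocations when the number drops
#' and `w_F * (b - a) / 2` fissions when it rises; the defaults `w_T = w_F
#' = 1` charge one event per step of two chromosomes.
#'
#' @param state_range Inclusive diploid-number range, default `c(40, 64)`.
#' @param w_T,w_F Per-event weights for translocations and fissions.
#' @return An object of class `karyo_cost_model` with elements `states`,
#'   `w_T`, `w_F` and a precomputed `cost` matrix (`cost[a, b]` = cost of the
#'   branch parent `a` to child `b`).
#' @export
cost_model <- function(state_range = c(40, 64), w_T = 1, w_F = 1) {
  stopifnot(length(state_range) == 2, state_range[1] < state_range[2],
            w_T >= 0, w_F >= 0)
  lo <- 2 * ceiling(state_range[1] / 2)
  hi <- 2 * floor(state_range[2] / 2)
  states <- seq(lo, hi, by = 2)
  d <- outer(states, states, "-") / 2   # parent minus child, in events
  cost <- ifelse(d > 0, w_T * d, -w_F * d)
  dimnames(cost) <- list(states, states)
  structure(list(states = states, w_T = w_T, w_F = w_F, cost = cost),
            class = "karyo_cost_model")
}

#' @export
print.karyo_cost_model <- function(x, ...) {
  cat("<cost model> states ", min(x$states), "-", max(x$states),
      " (even), w_T = ", x$w_T, ", w_F = ", x$w_F, "\n", sep = "")
  invisible(x)
}

resolve_tip_states <- function(tree, tip_states) {
  if (is.data.frame(tip_states)) {
    lab_col <- intersect(c("label", "species", "tip"), names(tip_states))[1]
    if (is.na(lab_col) || !"diploid_number" %in% names(tip_states)) {
      stop("tip_states data frame needs a label/species column and ",
           "`diploid_number`", call. = FALSE)
    }
    v <- setNames(tip_states$diploid_number,
                  gsub(" ", "_", tip_states[[lab_col]]))
    v <- v[!is.na(v)]
    dup <- duplicated(names(v))
    if (any(dup)) {
      agree <- vapply(unique(names(v)[dup]), function(nm)
        length(unique(v[names(v) == nm])) == 1L, TRUE)
      if (!all(agree)) {
        stop("conflicting diploid numbers for: ",
             paste(unique(names(v)[dup])[!agree], collapse = ", "),
             call. = FALSE)
      }
      v <- v[!dup]
    }
    tip_states <- v
  }
  if (is.null(names(tip_states))) {
    stop("tip_states must be named by tip label", call. = FALSE)
  }
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing) == length(tree$tip.label)) {
    stop("no tree tip has a diploid-number state", call. = FALSE)
  }
  if (length(missing)) {
    warning("pruning ", length(missing), " tip(s) without data: ",
            paste(missing, collapse = ", "), call. = FALSE)
    tree <- ape::drop.tip(tree, missing)
  }
  list(tree = tree, states = tip_states[tree$tip.label])
}

new_reconstruction <- function(tree, states, node_total, total_cost,
                               tip_states, model, method,
                               subtree_cost = NULL, opt_labelings = NULL) {
  min_sets <- apply(node_total, 1,
                    function(r) states[r <= total_cost + 1e-9],
                    simplify = FALSE)
  res <- structure(
    list(tree = tree, states = states, node_total_cost = node_total,
         subtree_cost = subtree_cost, node_min_sets = min_sets,
         total_cost = total_cost, tip_states = tip_states,
         cost_model = model, method = method, opt_labelings = opt_labelings),
    class = "karyo_reconstruction"
  )
  res$branch_events <- annotate_branch_events(res)
  res
}

#' Sankoff parsimony reconstruction of ancestral diploid numbers
#'
#' Dynamic program over a rooted tree (polytomies allowed): an upward pass
#' computes, for every node and every state, the minimal event cost of its
#' subtree; a downward pass adds the minimal cost of the rest of the tree, so
#' that per-node sets of states attaining the global minimum can be reported.
#' Ties are reported as sets, never broken silently.
#'
#' @param tree A rooted `phylo`; tips lacking a state are pruned with a
#'   warning.
#' @param tip_states A named vector (names = tip labels) of observed diploid
#'   numbers, or a data frame with `species`/`label` and `diploid_number`
#'   columns (species names may use spaces; they are matched with
#'   underscores).
#' @param model A [cost_model()].
#' @return An object of class `karyo_reconstruction`: per-node minimal-cost
#'   state sets (`node_min_sets`, indexed by ape node number), `total_cost`
#'   in event units, and `branch_events`, the per-branch translocation /
#'   fission annotation under the default `"prefer-ancestral-max"` labeling
#'   (see [annotate_branch_events()]). `tidy()`, `glance()` and `autoplot()`
#'   methods are available.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' sankoff_reconstruct(tr, c(A = 48, B = 46, C = 52))
#' @export
sankoff_reconstruct <- function(tree, tip_states, model = cost_model()) {
  if (is.null(tree) || ape::Ntip(tree) < 1L) {
    stop("empty tree", call. = FALSE)
  }
  rs <- resolve_tip_states(tree, tip_states)
  tree <- rs$tree
  obs <- rs$states
  states <- model$states
  bad <- !obs %in% states
  if (any(bad)) {
    stop("tip state outside the model state set (",
         min(states), "-", max(states), " even): ",
         paste(names(obs)[bad], "=", obs[bad], collapse = ", "),
         call. = FALSE)
  }
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  ns <- length(states)
  S <- matrix(Inf, nnode, ns)
  S[cbind(seq_len(ntip), match(obs, states))] <- 0
  touched <- rep(FALSE, nnode)

  post <- ape::reorder.phylo(tree, "postorder")$edge
  # child contribution to its parent: contrib[child, parent_state] =
  #   min over child state u of cost[parent_state, u] + S[child, u]
  contrib <- matrix(0, nnode, ns)
  for (i in seq_len(nrow(post))) {
    parent <- post[i, 1]
    child <- post[i, 2]
    contrib[child, ] <- apply(
      model$cost + matrix(S[child, ], ns, ns, byrow = TRUE), 1, min)
    if (!touched[parent]) {
      S[parent, ] <- 0
      touched[parent] <- TRUE
    }
    S[parent, ] <- S[parent, ] + contrib[child, ]
  }
  root <- ntip + 1L
  total_cost <- min(S[root, ])

  # downward pass: D[v, s] = min cost of everything outside v's subtree
  D <- matrix(Inf, nnode, ns)
  D[root, ] <- 0
  pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    parent <- pre[i, 1]
    child <- pre[i, 2]
    rest <- D[parent, ] + S[parent, ] - contrib[child, ]
    D[child, ] <- apply(model$cost + matrix(rest, ns, ns), 2, min)
  }
  new_reconstruction(tree, states, S + D, total_cost, obs, model,
                     "sankoff", subtree_cost = S)
}

#' Exhaustive-parsimony oracle
#'
#' Enumerates every assignment of states to internal nodes and minimises the
#' summed branch costs directly. Exponential in the number of internal nodes;
#' refuses more than 8. Used as an independent check of
#' [sankoff_reconstruct()].
#'
#' @inheritParams sankoff_reconstruct
#' @return A `karyo_reconstruction`, as for [sankoff_reconstruct()].
#' @export
brute_force_reconstruct <- function(tree, tip_states, model = cost_model()) {
  if (is.null(tree) || ape::Ntip(tree) < 1L) stop("empty tree", call. = FALSE)
  rs <- resolve_tip_states(tree, tip_states)
  tree <- rs$tree
  obs <- rs$states
  states <- model$states
  if (any(!obs %in% states)) {
    stop("tip state outside the model state set", call. = FALSE)
  }
  ntip <- ape::Ntip(tree)
  k <- tree$Nnode
  if (k > 8L) {
    stop("brute force refused: ", k, " internal nodes x ", length(states),
         " states = ", format(length(states)^k, big.mark = ","),
         " labelings", call. = FALSE)
  }
  ns <- length(states)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), k)))
  tip_idx <- match(obs, states)
  costs <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - ntip
    ch <- tree$edge[e, 2]
    ci <- if (ch <= ntip) rep.int(tip_idx[ch], nrow(grid)) else
      grid[, ch - ntip]
    costs <- costs + model$cost[cbind(grid[, p], ci)]
  }
  total_cost <- min(costs)
  opt <- grid[costs <= total_cost + 1e-9, , drop = FALSE]

  nnode <- ntip + k
  best <- matrix(Inf, nnode, ns)
  best[cbind(seq_len(ntip), tip_idx)] <- total_cost
  for (j in seq_len(k)) {
    for (s in seq_len(ns)) {
      sel <- costs[grid[, j] == s]
      if (length(sel)) best[ntip + j, s] <- min(sel)
    }
  }
  opt_states <- matrix(states[opt], nrow = nrow(opt))
  new_reconstruction(tree, states, best, total_cost, obs, model,
                     "brute-force", opt_labelings = opt_states)
}

#' Per-branch translocation/fission annotation of a reconstruction
#'
#' Picks one optimal labeling of the internal nodes (root-to-tip backtrace)
#' and annotates every branch with [count_translocations_fissions()] between
#' the parent and child states. Summed over branches this reproduces
#' `total_cost` when `w_T = w_F = 1`.
#'
#' @param result A `karyo_reconstruction`.
#' @param policy Tie-break for choosing one optimal labeling:
#'   `"prefer-ancestral-max"` (default; the largest optimal state at each
#'   node, biasing ancestors toward higher chromosome numbers),
#'   `"prefer-ancestral-min"`, or `"all-optimal"`, which keeps counts only on
#'   branches whose assignment is unambiguous across choices and sets the
#'   rest to `NA` (conservative: any upstream tie marks the branch).
#' @return A tibble with one row per branch: `parent`, `child` (ape node
#'   numbers), `parent_label`, `child_label`, `parent_state`, `child_state`,
#'   `translocations`, `fissions`.
#' @export
annotate_branch_events <- function(result,
                                   policy = c("prefer-ancestral-max",
                                              "prefer-ancestral-min",
                                              "all-optimal")) {
  policy <- match.arg(policy)
  tree <- result$tree
  states <- result$states
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  pick <- function(cands) if (policy == "prefer-ancestral-min") min(cands)
    else max(cands)
  chosen <- numeric(nnode)
  chosen[seq_len(ntip)] <- result$tip_states[tree$tip.label]
  ambiguous <- rep(FALSE, nnode)
  root <- ntip + 1L

  if (identical(result$method, "brute-force")) {
    rows <- result$opt_labelings
    for (j in seq_len(ncol(rows))) {
      cands <- unique(rows[, j])
      ambiguous[ntip + j] <- length(cands) > 1L
      keep <- rows[, j] == pick(cands)
      chosen[ntip + j] <- pick(cands)
      rows <- rows[keep, , drop = FALSE]
    }
  } else {
    chosen[root] <- pick(result$node_min_sets[[root]])
    ambiguous[root] <- length(result$node_min_sets[[root]]) > 1L
    post <- ape::reorder.phylo(tree, "postorder")$edge
    pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
    for (i in seq_len(nrow(pre))) {
      p <- pre[i, 1]; ch <- pre[i, 2]
      if (ch <= ntip) next
      v <- result$cost_model$cost[match(chosen[p], states), ] +
        result$subtree_cost[ch, ]
      cands <- states[v <= min(v) + 1e-9]
      chosen[ch] <- pick(cands)
      ambiguous[ch] <- ambiguous[p] || length(cands) > 1L
    }
  }

  out <- tibble::tibble(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    parent_label = node_label(tree, tree$edge[, 1]),
    child_label = node_label(tree, tree$edge[, 2]),
    parent_state = chosen[tree$edge[, 1]],
    child_state = chosen[tree$edge[, 2]]
  )
  ev <- count_translocations_fissions(out$parent_state, out$child_state,
                                      range = range(states))
  out$translocations <- ev$translocations
  out$fissions <- ev$fissions
  if (policy == "all-optimal") {
    amb_edge <- ambiguous[tree$edge[, 1]] | ambiguous[tree$edge[, 2]]
    out$translocations[amb_edge] <- NA_integer_
    out$fissions[amb_edge] <- NA_integer_
  }
  out
}

#' @export
print.karyo_reconstruction <- function(x, ...) {
  root <- ape::Ntip(x$tree) + 1L
  cat("<ancestral diploid-number reconstruction> (", x$method, ")\n",
      "  tips: ", ape::Ntip(x$tree),
      "   total cost: ", x$total_cost, " events\n",
      "  root minimal-cost states: {",
      paste(x$node_min_sets[[root]], collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @rdname sankoff_reconstruct
#' @param x,object A `karyo_reconstruction`.
#' @param ... Ignored.
#' @method tidy karyo_reconstruction
#' @export
tidy.karyo_reconstruction <- function(x, ...) {
  tree <- x$tree
  ntip <- ape::Ntip(tree)
  nodes <- seq_len(ntip + tree$Nnode)
  tibble::tibble(
    node = nodes,
    label = node_label(tree, nodes),
    is_tip = nodes <= ntip,
    min_states = unname(x$node_min_sets),
    states_label = vapply(x$node_min_sets,
                          function(s) paste(s, collapse = "|"), "")
  )
}

#' @rdname sankoff_reconstruct
#' @method glance karyo_reconstruction
#' @export
glance.karyo_reconstruction <- function(x, ...) {
  root <- ape::Ntip(x$tree) + 1L
  tibble::tibble(
    total_cost = x$total_cost,
    root_states = paste(x$node_min_sets[[root]], collapse = "|"),
    root_unique = length(x$node_min_sets[[root]]) == 1L,
    n_tips = ape::Ntip(x$tree),
    n_states = length(x$states),
    method = x$method
  )
}

#' Plot a reconstruction as an annotated tree
#'
#' Simple segment-based tree drawing with each node labelled by its
#' minimal-cost diploid-number set and each branch by its event annotation
#' (`nT` translocations / `nF` fissions).
#'
#' @param object A `karyo_reconstruction`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot karyo_reconstruction
#' @export
autoplot.karyo_reconstruction <- function(object, ...) {
  tree <- object$tree
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  depth <- numeric(nnode)
  kids <- node_children(tree)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in rev(seq_len(nrow(post)))) {
    depth[post[i, 2]] <- depth[post[i, 1]] + 1
  }
  y <- numeric(nnode)
  y[seq_len(ntip)] <- seq_len(ntip)
  for (i in seq_len(nrow(post))) {
    p <- post[i, 1]
    y[p] <- mean(y[kids[[as.character(p)]]])
  }
  node_y <- y
  seg <- tibble::tibble(
    x = depth[tree$edge[, 1]], xend = depth[tree$edge[, 2]],
    y = node_y[tree$edge[, 1]], yend = node_y[tree$edge[, 2]]
  )
  lab <- tidy.karyo_reconstruction(object)
  lab$x <- depth[lab$node]
  lab$y <- y[lab$node]
  ev <- object$branch_events
  ev_lab <- paste0(ifelse(ev$translocations > 0,
                          paste0(ev$translocations, "T"), ""),
                   ifelse(ev$fissions > 0, paste0(ev$fissions, "F"), ""))
  seg$event <- ev_lab[match(paste(tree$edge[, 1], tree$edge[, 2]),
                            paste(ev$parent, ev$child))]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(
      data = seg[nzchar(seg$event), ],
      ggplot2::aes(x = (.data$x + .data$xend) / 2,
                   y = (.data$y + .data$yend) / 2, label = .data$event),
      vjust = -0.4, size = 3) +
    ggplot2::geom_label(
      data = lab,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$states_label),
      size = 3) +
    ggplot2::geom_text(
      data = lab[lab$is_tip, ],
      ggplot2::aes(x = .data$x + 0.1, y = .data$y, label = .data$label),
      hjust = 0, size = 3) +
    ggplot2::scale_x_continuous(
      expand = ggplot2::expansion(mult = c(0.02, 0.25))) +
    ggplot2::theme_void()
}
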