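#' Configuration for the karyotype evolution simulator
#'
#' Describes the conditions under which karyotype formulae evolve along a
#' phylogeny: a tree (or parameters for a random pure-birth tree with edge
#' lengths rescaled to unit mean), a root formula, per-type event rates in
#' expected events per unit branch length, and diploid-number bounds.
#' Defaults emulate the inferred ancestral helicoid condition: a root of 30
#' all-metacentric pairs (2n = 60), diploid numbers confined to 40--64,
#' translocations the dominant event, fissions rare, inversions in between.
#'
#' @param tree A rooted `phylo` with branch lengths, or `NULL` to simulate a
#'   Yule tree with `n_tips` tips.
#' @param n_tips Tip count for the random tree (ignored when `tree` given).
#' @param root_formula Root karyotype (anything [as_karyotype_formula()]
#'   accepts); default `"30m"`.
#' @param rate_T,rate_F,rate_I Expected translocations, fissions and
#'   inversions per unit branch length.
#' @param bounds Diploid-number floor/ceiling, default `c(40, 64)`.
#' @param max_retries Cap on redraws of an event before it is dropped and
#'   counted, default 10. With the built-in event set a uniform draw is
#'   always valid whenever the event type is feasible at all, so in practice
#'   infeasible events (bound reached, no biarmed pair) are dropped directly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree = NULL, n_tips = 8,
                       root_formula = "30m",
                       rate_T = 0.25, rate_F = 0.05, rate_I = 0.15,
                       bounds = c(40, 64), max_retries = 10) {
  root <- as_karyotype_formula(root_formula)
  stopifnot(rate_T >= 0, rate_F >= 0, rate_I >= 0,
            length(bounds) == 2, bounds[1] < bounds[2])
  if (root$diploid_number < bounds[1] || root$diploid_number > bounds[2]) {
    stop("root diploid number ", root$diploid_number,
         " violates bounds [", bounds[1], ", ", bounds[2], "]",
         call. = FALSE)
  }
  structure(
    list(tree = tree, n_tips = n_tips, root_formula = root,
         rate_T = rate_T, rate_F = rate_F, rate_I = rate_I,
         bounds = bounds, max_retries = max_retries),
    class = "sim_config"
  )
}

sample_class_from_counts <- function(counts, size = 1L) {
  pool <- rep(morph_classes, counts)
  pool[sample.int(length(pool), size)]
}

draw_event <- function(type, counts, bounds, max_retries) {
  # returns list(from, to), or NULL when the event is infeasible at this
  # state (diploid bound reached, or no pair of a required class): such an
  # event cannot become feasible by redrawing, so it is dropped directly
  n_pairs <- sum(counts)
  biarmed <- c("m", "sm", "st")
  if (type == "T") {
    if (n_pairs < 2L || 2L * (n_pairs - 1L) < bounds[1]) return(NULL)
    cls <- sample_class_from_counts(counts, 2L)
    return(list(from = paste(cls[1], cls[2], sep = "+"), to = "m"))
  }
  if (type == "F") {
    if (2L * (n_pairs + 1L) > bounds[2]) return(NULL)
    if (sum(counts[biarmed]) == 0L) return(NULL)
    cls <- sample_class_from_counts(
      setNames(c(counts[biarmed], 0L), morph_classes))
    return(list(from = cls, to = "t+t"))
  }
  if (n_pairs < 1L) return(NULL)
  from <- sample_class_from_counts(counts)
  to <- sample(setdiff(morph_classes, from), 1L)
  list(from = from, to = to)
}

#' Evolve karyotype formulae along a phylogeny
#'
#' Per branch, the number of events of each type is drawn as
#' Poisson(rate x branch length); events are applied in random order. A
#' translocation merges two uniformly chosen pairs into one metacentric
#' pair, a fission splits a uniformly chosen biarmed pair into two
#' telocentric pairs, an inversion moves one uniformly chosen pair to a
#' uniformly chosen different class. Events that would leave the diploid
#' number outside the configured bounds, or that need a pair class that is
#' unavailable, are dropped (with a counter in the result); the realised
#' event log replays exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the full result is reproducible from it.
#' @return An object of class `karyo_sim`: `tree`, `tip_formulae` (named
#'   list), `tip_states` (named 2n vector), `true_node_states` (2n per ape
#'   node number), `event_log` (tibble with `branch_child`, `step`, `type`,
#'   `from`, `to`), `n_dropped`, `config`, `seed`.
#' @export
evolve_karyotypes <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rphylo(config$n_tips, birth = 1, death = 0)
    tree$edge.length <- tree$edge.length / mean(tree$edge.length)
  }
  if (is.null(tree$edge.length)) {
    stop("simulation tree needs branch lengths", call. = FALSE)
  }
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  counts_at <- vector("list", nnode)
  counts_at[[root]] <- config$root_formula$counts
  log_rows <- list()
  n_dropped <- 0L

  po <- ape::reorder.phylo(tree, "postorder")
  post <- po$edge
  edge_len <- po$edge.length  # aligned with the postorder edge matrix
  pre_order <- rev(seq_len(nrow(post)))

  for (i in pre_order) {
    parent <- post[i, 1]
    child <- post[i, 2]
    len <- edge_len[i]
    counts <- counts_at[[parent]]
    n_ev <- c(T = stats::rpois(1, config$rate_T * len),
              F = stats::rpois(1, config$rate_F * len),
              I = stats::rpois(1, config$rate_I * len))
    types <- rep(names(n_ev), n_ev)
    if (length(types) > 1L) types <- sample(types)
    step <- 0L
    for (type in types) {
      ev <- draw_event(type, counts, config$bounds, config$max_retries)
      if (is.null(ev)) {
        n_dropped <- n_dropped + 1L
        next
      }
      counts <- apply_one_event(counts, type, ev$from, ev$to)
      step <- step + 1L
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        branch_child = child, step = step, type = type,
        from = ev$from, to = ev$to)
    }
    counts_at[[child]] <- counts
  }

  event_log <- if (length(log_rows)) dplyr::bind_rows(log_rows) else
    tibble::tibble(branch_child = integer(), step = integer(),
                   type = character(), from = character(), to = character())
  formulae <- lapply(counts_at, function(cc)
    validate_karyotype_formula(new_karyotype_formula(cc)))
  tip_formulae <- setNames(formulae[seq_len(ntip)], tree$tip.label)
  structure(
    list(
      tree = tree,
      tip_formulae = tip_formulae,
      tip_states = vapply(tip_formulae, function(f) f$diploid_number, 0),
      true_node_states = vapply(formulae, function(f) f$diploid_number, 0),
      event_log = event_log,
      n_dropped = n_dropped,
      config = config,
      seed = seed
    ),
    class = "karyo_sim"
  )
}

#' Replay a simulation event log
#'
#' Re-applies the logged events branch by branch from the root formula and
#' returns the implied tip formulae; used to verify that the log is an exact
#' record of the simulation.
#'
#' @param sim A `karyo_sim` from [evolve_karyotypes()].
#' @return A named list of [karyotype_formula()] objects, one per tip.
#' @export
replay_event_log <- function(sim) {
  tree <- sim$tree
  ntip <- ape::Ntip(tree)
  counts_at <- vector("list", ntip + tree$Nnode)
  counts_at[[ntip + 1L]] <- sim$config$root_formula$counts
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in rev(seq_len(nrow(post)))) {
    parent <- post[i, 1]; child <- post[i, 2]
    counts <- counts_at[[parent]]
    ev <- sim$event_log[sim$event_log$branch_child == child, , drop = FALSE]
    ev <- ev[order(ev$step), , drop = FALSE]
    for (j in seq_len(nrow(ev))) {
      counts <- apply_one_event(counts, ev$type[j], ev$from[j], ev$to[j])
    }
    counts_at[[child]] <- counts
  }
  out <- lapply(counts_at[seq_len(ntip)], function(cc)
    validate_karyotype_formula(new_karyotype_formula(cc)))
  setNames(out, tree$tip.label)
}

#' @export
print.karyo_sim <- function(x, ...) {
  cat("<karyotype simulation> ", ape::Ntip(x$tree), " tips, ",
      nrow(x$event_log), " events (", x$n_dropped, " dropped), seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' @rdname evolve_karyotypes
#' @param x,object A `karyo_sim`.
#' @param ... Ignored.
#' @method tidy karyo_sim
#' @export
tidy.karyo_sim <- function(x, ...) {
  tibble::tibble(
    tip = names(x$tip_formulae),
    diploid_number = unname(x$tip_states),
    formula = vapply(x$tip_formulae, format_formula, "")
  )
}

#' @rdname evolve_karyotypes
#' @method glance karyo_sim
#' @export
glance.karyo_sim <- function(x, ...) {
  counts <- table(factor(x$event_log$type, levels = c("T", "F", "I")))
  tibble::tibble(
    n_tips = ape::Ntip(x$tree),
    n_translocations = as.integer(counts["T"]),
    n_fissions = as.integer(counts["F"]),
    n_inversions = as.integer(counts["I"]),
    n_dropped = x$n_dropped,
    root_diploid = x$config$root_formula$diploid_number,
    seed = x$seed
  )
}

#' Write a simulation as a karyotype table and Newick tree
#'
#' Simulated data leave through the same formats real data enter by: a
#' record TSV (see [read_karyotype_table()]) and a Newick file.
#'
#' @param sim A `karyo_sim`.
#' @param table_path,tree_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_simulation <- function(sim, table_path, tree_path) {
  records <- tibble::tibble(
    species = names(sim$tip_formulae),
    family = NA_character_, subfamily = NA_character_, tribe = NA_character_,
    diploid_number = as.integer(sim$tip_states),
    formula = vapply(sim$tip_formulae, format_formula, ""),
    nor_pairs = NA_integer_,
    source = "simulated", locality = NA_character_,
    notes = paste0("simulated from ",
                   format_formula(sim$config$root_formula),
                   " with seed ", sim$seed)
  )
  write_karyotype_table(records, table_path)
  ape::write.tree(sim$tree, tree_path)
  invisible(list(table = table_path, tree = tree_path))
}

#' Recovery experiment: can parsimony recover the simulated root?
#'
#' Runs [evolve_karyotypes()] `n_replicates` times, reconstructs ancestral
#' diploid numbers from the simulated tips with [sankoff_reconstruct()], and
#' summarises how often the true root state lies in the root minimal-cost
#' set, the absolute error between inferred total cost and the true number
#' of diploid-number-changing events (translocations + fissions; inversions
#' are invisible to this character), how often the root set is a tie, and
#' how often parsimony respects its lower-bound property.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of simulated datasets.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return A one-row tibble: `recovery_rate`, `mean_abs_error`, `tie_rate`,
#'   `lower_bound_rate`, `n_replicates`.
#' @export
recovery_experiment <- function(config = sim_config(), n_replicates = 100,
                                seed = 1L) {
  if (n_replicates < 1L) stop("need at least one replicate", call. = FALSE)
  model <- cost_model(state_range = config$bounds)
  res <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    sim <- evolve_karyotypes(config, seed = seed + r)
    rec <- sankoff_reconstruct(sim$tree, sim$tip_states, model)
    root_set <- rec$node_min_sets[[ape::Ntip(sim$tree) + 1L]]
    true_root <- sim$true_node_states[ape::Ntip(sim$tree) + 1L]
    true_tf <- sum(sim$event_log$type %in% c("T", "F"))
    tibble::tibble(
      recovered = true_root %in% root_set,
      abs_error = abs(rec$total_cost - true_tf),
      tie = length(root_set) > 1L,
      lower_bound_ok = rec$total_cost <= true_tf
    )
  })
  tibble::tibble(
    recovery_rate = mean(res$recovered),
    mean_abs_error = mean(res$abs_error),
    tie_rate = mean(res$tie),
    lower_bound_rate = mean(res$lower_bound_ok),
    n_replicates = n_replicates
  )
}
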