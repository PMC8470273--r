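#' Minimal translocation/fission count between two diploid numbers
#'
#' Under the event model used for helicoid karyotype evolution, a (tandem or
#' Robertsonian) translocation merges two chromosomes and lowers the diploid
#' number by 2, while a fission splits one chromosome and raises it by 2. The
#' minimal event count separating two diploid numbers is therefore
#' `|2n_a - 2n_b| / 2`, all translocations when the number decreases and all
#' fissions when it increases. Direction is `a -> b`.
#'
#' @param diploid_a,diploid_b Even diploid chromosome numbers (vectors are
#'   recycled to a common length).
#' @param range Admissible diploid-number range, default `c(30, 80)`.
#' @return A tibble with one row per comparison and integer columns
#'   `translocations`, `fissions`, `inversions` (always 0 here); at most one
#'   of the first two is nonzero per row.
#' @examples
#' count_translocations_fissions(60, 52)  # 4 translocations
#' count_translocations_fissions(58, 60)  # 1 fission
#' @export
count_translocations_fissions <- function(diploid_a, diploid_b,
                                          range = c(30, 80)) {
  n <- max(length(diploid_a), length(diploid_b))
  a <- rep_len(as.numeric(diploid_a), n)
  b <- rep_len(as.numeric(diploid_b), n)
  check_diploid <- function(x, label) {
    if (any(is.na(x)) || any(x %% 2 != 0)) {
      stop("odd or missing diploid number in ", label, ": ",
           paste(x[is.na(x) | x %% 2 != 0], collapse = ", "), call. = FALSE)
    }
    if (any(x < range[1] | x > range[2])) {
      stop("diploid number outside [", range[1], ", ", range[2], "] in ",
           label, ": ", paste(x[x < range[1] | x > range[2]], collapse = ", "),
           call. = FALSE)
    }
  }
  check_diploid(a, "diploid_a")
  check_diploid(b, "diploid_b")
  tibble::tibble(
    translocations = as.integer(pmax(0, (a - b) / 2)),
    fissions = as.integer(pmax(0, (b - a) / 2)),
    inversions = 0L
  )
}

#' Minimal inversion count between two karyotype formulae
#'
#' A pericentric inversion moves the centromere and can re-classify exactly
#' one chromosome pair per event, between any two morphology classes. The
#' minimal number of inversions turning one formula into another with the
#' same number of pairs is therefore the number of pairs that change class:
#' half the L1 distance between the class-count vectors.
#'
#' @param formula_a,formula_b Karyotype formulae (anything accepted by
#'   [as_karyotype_formula()]) with equal `n_pairs`.
#' @return A non-negative integer; zero iff the counts are equal. Symmetric
#'   in its arguments and a metric on formulae with a fixed pair number.
#' @examples
#' inversion_distance("24m+2sm+1st", "18m+8sm+1st")  # 6
#' inversion_distance("20m+4sm", "16m+6sm+2t")       # 4
#' @export
inversion_distance <- function(formula_a, formula_b) {
  a <- as_karyotype_formula(formula_a)
  b <- as_karyotype_formula(formula_b)
  if (a$n_pairs != b$n_pairs) {
    stop("formulae have different pair numbers (", a$n_pairs, " vs ",
         b$n_pairs, "); use combined_event_path() for unequal complements",
         call. = FALSE)
  }
  as.integer(sum(abs(a$counts - b$counts)) / 2)
}

# Apply one event to a class-count vector; errors on infeasible counts.
apply_one_event <- function(counts, type, from, to) {
  take <- function(cls) {
    for (cl in cls) {
      if (counts[cl] < 1L) {
        stop("infeasible event: no ", cl, " pair available", call. = FALSE)
      }
      counts[cl] <<- counts[cl] - 1L
    }
  }
  give <- function(cls) for (cl in cls) counts[cl] <<- counts[cl] + 1L
  from <- strsplit(from, "+", fixed = TRUE)[[1]]
  to <- strsplit(to, "+", fixed = TRUE)[[1]]
  switch(type,
    T = { take(from); give(to) },   # two pairs merge into one biarmed
    F = { take(from); give(to) },   # one biarmed splits into two pairs
    I = { take(from); give(to) },   # one pair changes class
    stop("unknown event type: ", type, call. = FALSE)
  )
  counts
}

#' Replay a sequence of rearrangement events on a formula
#'
#' @inheritParams format_formula
#' @param events A tibble with columns `type` (`"T"`, `"F"` or `"I"`), `from`
#'   and `to` (class labels, `+`-separated when an event involves two pairs),
#'   as produced by [combined_event_path()] or the simulator event log.
#' @return The resulting [karyotype_formula()].
#' @export
apply_events <- function(formula, events) {
  f <- as_karyotype_formula(formula)
  counts <- f$counts
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      counts <- apply_one_event(counts, events$type[i],
                                events$from[i], events$to[i])
    }
  }
  validate_karyotype_formula(new_karyotype_formula(counts))
}

# choose the two classes a translocation should consume so that the
# resulting counts stay as close (L1) to the target as possible; ties prefer
# consuming telocentrics (the classical Robertsonian merge)
pick_merge_pair <- function(counts, target, merge_class) {
  best <- NULL
  best_score <- Inf
  for (i in seq_along(morph_classes)) {
    for (j in i:length(morph_classes)) {
      c1 <- morph_classes[i]; c2 <- morph_classes[j]
      need <- if (c1 == c2) 2L else 1L
      if (counts[c1] < need || counts[c2] < 1L) next
      cand <- counts
      cand[c1] <- cand[c1] - 1L
      cand[c2] <- cand[c2] - 1L
      cand[merge_class] <- cand[merge_class] + 1L
      score <- sum(abs(cand - target))
      # tie-break: prefer pairs consuming more telocentric-side classes
      score <- score - 1e-3 * (i + j)
      if (score < best_score) {
        best_score <- score
        best <- c(c1, c2)
      }
    }
  }
  best
}

pick_fission_class <- function(counts, target, fission_class) {
  biarmed <- c("m", "sm", "st")
  best <- NA_character_
  best_score <- Inf
  for (c1 in biarmed) {
    if (counts[c1] < 1L) next
    cand <- counts
    cand[c1] <- cand[c1] - 1L
    cand[fission_class] <- cand[fission_class] + 2L
    score <- sum(abs(cand - target))
    if (score < best_score) {
      best_score <- score
      best <- c1
    }
  }
  best
}

#' Explicit event path between two karyotype formulae
#'
#' Connects two formulae that may differ in pair number: first the
#' `|2n_a - 2n_b| / 2` translocations (each merging two pairs into one pair
#' of class `merge_class`) or fissions (each splitting one biarmed pair into
#' two pairs of class `fission_class`), then the minimal inversions turning
#' the intermediate into the target. Replaying the returned events on
#' `formula_a` reproduces `formula_b` exactly.
#'
#' @inheritParams inversion_distance
#' @param merge_class Class of the pair created by a translocation
#'   (default `"m"`, the standard Robertsonian expectation).
#' @param fission_class Class of the two pairs created by a fission
#'   (default `"t"`).
#' @return A tibble with columns `step`, `type`, `from`, `to`, `description`
#'   and `formula_after`; `nrow()` is the total event count.
#' @examples
#' combined_event_path("30m", "26m")  # 4 translocations
#' @export
combined_event_path <- function(formula_a, formula_b,
                                merge_class = "m", fission_class = "t") {
  a <- as_karyotype_formula(formula_a)
  b <- as_karyotype_formula(formula_b)
  stopifnot(merge_class %in% morph_classes, fission_class %in% morph_classes)
  counts <- a$counts
  target <- b$counts
  steps <- list()
  add_step <- function(type, from, to, description) {
    steps[[length(steps) + 1L]] <<-
      tibble::tibble(type = type, from = from, to = to,
                     description = description)
  }

  n_merge <- max(0L, a$n_pairs - b$n_pairs)
  n_split <- max(0L, b$n_pairs - a$n_pairs)
  for (i in seq_len(n_merge)) {
    pair <- pick_merge_pair(counts, target, merge_class)
    counts[pair[1]] <- counts[pair[1]] - 1L
    counts[pair[2]] <- counts[pair[2]] - 1L
    counts[merge_class] <- counts[merge_class] + 1L
    add_step("T", paste(pair[1], pair[2], sep = "+"), merge_class,
             paste0("translocation: ", pair[1], " + ", pair[2], " -> ",
                    merge_class))
  }
  for (i in seq_len(n_split)) {
    c1 <- pick_fission_class(counts, target, fission_class)
    if (is.na(c1)) {
      stop("infeasible fission: no biarmed pair left (blocking classes: ",
           "m, sm, st all zero)", call. = FALSE)
    }
    counts[c1] <- counts[c1] - 1L
    counts[fission_class] <- counts[fission_class] + 2L
    add_step("F", c1, paste(fission_class, fission_class, sep = "+"),
             paste0("fission: ", c1, " -> 2 ", fission_class))
  }

  # inversions: move pairs from surplus to deficit classes
  repeat {
    diff <- counts - target
    if (all(diff == 0L)) break
    from <- morph_classes[which.max(diff)]
    to <- morph_classes[which.min(diff)]
    counts[from] <- counts[from] - 1L
    counts[to] <- counts[to] + 1L
    add_step("I", from, to,
             paste0("pericentric inversion: ", from, " -> ", to))
  }

  path <- if (length(steps)) dplyr::bind_rows(steps) else
    tibble::tibble(type = character(), from = character(), to = character(),
                   description = character())
  path <- dplyr::mutate(path, step = dplyr::row_number(), .before = 1)
  # formula after each step, by replay from the start
  running <- a$counts
  after <- character(nrow(path))
  for (i in seq_len(nrow(path))) {
    running <- apply_one_event(running, path$type[i], path$from[i], path$to[i])
    after[i] <- format_formula(as_karyotype_formula(
      setNames(as.numeric(running), morph_classes)))
  }
  path$formula_after <- after
  stopifnot(identical(apply_events(a, path)$counts, b$counts))
  path
}
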