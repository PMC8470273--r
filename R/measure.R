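#' Classify a chromosome pair by centromeric index
#'
#' Levan-style classification of chromosome morphology from the centromeric
#' index (CI = 100 * short arm / total length, so CI is in \[0, 50\]).
#' Boundaries used: metacentric `m` for CI in \[37.5, 50\], submetacentric
#' `sm` in \[25, 37.5), subtelocentric `st` in \[12.5, 25), telocentric `t`
#' in \[0, 12.5). A boundary value is assigned to the more metacentric side
#' at 37.5 and to the stated interval otherwise.
#'
#' @param centromeric_index Numeric vector of centromeric indices (percent).
#' @return A character vector of morphology classes (`"m"`, `"sm"`, `"st"`,
#'   `"t"`), one per input value.
#' @examples
#' classify_pair(c(50, 30, 20, 0))  # "m" "sm" "st" "t"
#' @export
classify_pair <- function(centromeric_index) {
  ci <- centromeric_index
  if (!is.numeric(ci) || length(ci) == 0L) {
    stop("centromeric_index must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- is.na(ci) | ci < 0 | ci > 50
  if (any(bad)) {
    stop("centromeric index out of [0, 50]: ",
         paste(ci[bad], collapse = ", "), call. = FALSE)
  }
  dplyr::case_when(
    ci >= 37.5 ~ "m",
    ci >= 25   ~ "sm",
    ci >= 12.5 ~ "st",
    TRUE       ~ "t"
  )
}

#' Compute relative lengths, centromeric indices and morphology classes
#'
#' Takes per-pair short/long arm measurements (arbitrary units) and derives
#' the quantities a karyotype table reports: relative length
#' (RL_i = 100 * (short_i + long_i) / sum of all pair lengths, so RL sums to
#' 100 over the haploid complement), centromeric index
#' (CI_i = 100 * short_i / (short_i + long_i)) and the morphology class from
#' [classify_pair()]. Pairs are re-indexed by decreasing relative length,
#' ties kept in input order.
#'
#' @param arms A data frame with numeric columns `short` and `long` (one row
#'   per chromosome pair), or a two-column numeric matrix, or a list of
#'   `c(short, long)` pairs. Rows with `short > long` are swapped with a
#'   warning: measurement tables list arms in either order.
#' @return A tibble of class `karyotype` with columns `pair`, `short_arm`,
#'   `long_arm`, `relative_length`, `centromeric_index`, `morph_class`. RL
#'   and CI are stored at full precision; round only for presentation.
#' @examples
#' compute_measurements(data.frame(short = c(2, 1), long = c(6, 7)))
#' @export
compute_measurements <- function(arms) {
  if (is.matrix(arms)) arms <- as.data.frame(arms)
  if (is.list(arms) && !is.data.frame(arms)) {
    arms <- as.data.frame(do.call(rbind, arms))
  }
  if (is.data.frame(arms) && ncol(arms) >= 2 &&
      !all(c("short", "long") %in% names(arms))) {
    names(arms)[1:2] <- c("short", "long")
  }
  if (!is.data.frame(arms) || !all(c("short", "long") %in% names(arms))) {
    stop("arms must be a data frame with columns `short` and `long`",
         call. = FALSE)
  }
  if (nrow(arms) == 0L) {
    stop("at least one chromosome pair is required", call. = FALSE)
  }
  short <- as.numeric(arms$short)
  long <- as.numeric(arms$long)
  if (any(is.na(short)) || any(is.na(long)) || any(short < 0) || any(long < 0)) {
    stop("arm lengths must be non-negative numbers", call. = FALSE)
  }
  swap <- short > long
  if (any(swap)) {
    warning(sum(swap), " pair(s) listed short arm first; arms swapped",
            call. = FALSE)
    tmp <- short[swap]
    short[swap] <- long[swap]
    long[swap] <- tmp
  }
  if (any(long <= 0)) {
    stop("long arm must be positive for every pair", call. = FALSE)
  }
  total <- short + long
  rl <- 100 * total / sum(total)
  ci <- 100 * short / total
  ord <- order(-rl)  # stable: ties keep input order
  out <- tibble::tibble(
    pair = seq_along(ord),
    short_arm = short[ord],
    long_arm = long[ord],
    relative_length = rl[ord],
    centromeric_index = ci[ord],
    morph_class = classify_pair(ci[ord])
  )
  class(out) <- c("karyotype", class(out))
  out
}

#' @export
print.karyotype <- function(x, ...) {
  f <- as_karyotype_formula(x)
  cat("<karyotype> ", format_formula(f), "  (2n = ", f$diploid_number, ")\n",
      sep = "")
  NextMethod()
}

#' Plot a karyotype as an idiogram-style bar chart
#'
#' One bar per chromosome pair, split at the centromere into short and long
#' arm, coloured by morphology class.
#'
#' @param object A `karyotype` from [compute_measurements()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot karyotype
#' @export
autoplot.karyotype <- function(object, ...) {
  arms <- tidyr::pivot_longer(
    dplyr::mutate(
      object,
      short = .data$relative_length * .data$centromeric_index / 100,
      long = .data$relative_length * (100 - .data$centromeric_index) / 100
    ),
    cols = c("short", "long"), names_to = "arm", values_to = "length"
  )
  ggplot2::ggplot(
    arms,
    ggplot2::aes(x = factor(.data$pair),
                 y = ifelse(.data$arm == "short", .data$length, -.data$length),
                 fill = .data$morph_class)
  ) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "chromosome pair (by decreasing relative length)",
                  y = "relative length (short arm up, long arm down)",
                  fill = "class") +
    ggplot2::theme_minimal()
}
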