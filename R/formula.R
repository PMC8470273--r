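#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

#' Chromosome morphology classes
#'
#' The four Levan-style morphology classes used throughout the package, in
#' decreasing order of centromeric index: metacentric (`m`), submetacentric
#' (`sm`), subtelocentric (`st`) and telocentric (`t`).
#'
#' @format A character vector of length 4.
#' @export
morph_classes <- c("m", "sm", "st", "t")

new_karyotype_formula <- function(counts) {
  counts <- as.integer(counts)
  names(counts) <- morph_classes
  structure(
    list(
      counts = counts,
      n_pairs = sum(counts),
      diploid_number = 2L * sum(counts)
    ),
    class = "karyotype_formula"
  )
}

validate_karyotype_formula <- function(x) {
  if (any(is.na(x$counts)) || any(x$counts < 0)) {
    stop("karyotype formula counts must be non-negative integers", call. = FALSE)
  }
  if (x$n_pairs < 1L) {
    stop("karyotype formula must contain at least one chromosome pair", call. = FALSE)
  }
  stopifnot(x$diploid_number == 2L * x$n_pairs)
  x
}

#' Build a karyotype formula from class counts
#'
#' A karyotype formula is the multiset of chromosome-pair morphology classes
#' that cytogenetics papers print as e.g. `"10m+1sm+16t"`: so many metacentric
#' pairs, so many submetacentric pairs, and so on. It is the unit on which
#' rearrangement arithmetic ([inversion_distance()], [combined_event_path()])
#' operates.
#'
#' @param m,sm,st,t Number of chromosome *pairs* in each morphology class.
#' @param counts_are Either `"pairs"` (default) or `"chromosomes"`. Haploid
#'   complements are naturally given as pair counts; a diploid chromosome list
#'   must contain an even count per class and is divided by two.
#' @return An object of class `karyotype_formula` with elements `counts`
#'   (named integer vector over `m`, `sm`, `st`, `t`), `n_pairs` and
#'   `diploid_number`.
#' @examples
#' karyotype_formula(m = 10, sm = 1, t = 16)   # Helix lucorum, 2n = 54
#' @seealso [parse_formula()], [format_formula()], [fundamental_number()]
#' @export
karyotype_formula <- function(m = 0, sm = 0, st = 0, t = 0,
                              counts_are = c("pairs", "chromosomes")) {
  counts_are <- match.arg(counts_are)
  counts <- c(m = m, sm = sm, st = st, t = t)
  if (any(counts != round(counts))) {
    stop("class counts must be whole numbers", call. = FALSE)
  }
  if (counts_are == "chromosomes") {
    odd <- counts %% 2 != 0
    if (any(odd)) {
      stop(
        "diploid chromosome counts must be even per class; odd count for: ",
        paste(morph_classes[odd], collapse = ", "),
        call. = FALSE
      )
    }
    counts <- counts / 2
  }
  validate_karyotype_formula(new_karyotype_formula(counts))
}

#' Coerce to a karyotype formula
#'
#' @param x A `karyotype_formula`, a formula string such as `"24m+2sm+1st"`,
#'   a named numeric vector of pair counts, or a [compute_measurements()]
#'   karyotype table.
#' @param ... Passed on to methods.
#' @return A `karyotype_formula`.
#' @export
as_karyotype_formula <- function(x, ...) UseMethod("as_karyotype_formula")

#' @export
as_karyotype_formula.karyotype_formula <- function(x, ...) x

#' @export
as_karyotype_formula.character <- function(x, ...) parse_formula(x)

#' @export
as_karyotype_formula.numeric <- function(x, ...) {
  if (is.null(names(x)) || !all(names(x) %in% morph_classes)) {
    stop("numeric input must be named with morphology classes (m, sm, st, t)",
         call. = FALSE)
  }
  full <- setNames(rep(0, 4), morph_classes)
  full[names(x)] <- x
  validate_karyotype_formula(new_karyotype_formula(full))
}

#' @export
as_karyotype_formula.karyotype <- function(x, ...) {
  counts <- table(factor(x$morph_class, levels = morph_classes))
  validate_karyotype_formula(new_karyotype_formula(as.integer(counts)))
}

#' @export
print.karyotype_formula <- function(x, ...) {
  cat("<karyotype formula> ", format_formula(x),
      "  (n = ", x$n_pairs, ", 2n = ", x$diploid_number, ")\n", sep = "")
  invisible(x)
}

#' @export
format.karyotype_formula <- function(x, ...) format_formula(x)

#' Parse a karyotype formula string
#'
#' Accepts the notation used in the cytogenetics literature: counts followed
#' by a class symbol, separated by `+`, commas or whitespace, with optional
#' space before the symbol. `"24m+2sm+1st"`, `"24 m, 2 sm, 1st"` and
#' `"24m 2sm 1st"` are all equivalent.
#'
#' @param text A single formula string.
#' @return A [karyotype_formula()].
#' @examples
#' parse_formula("10m+1sm+16t")    # 2n = 54
#' parse_formula("20 m, 4 sm")     # 2n = 48
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string", call. = FALSE)
  }
  if (!nzchar(trimws(text))) {
    stop("empty formula string at position 1", call. = FALSE)
  }
  token_re <- "(\\d+)\\s*(sm|st|m|t)"
  mm <- gregexpr(token_re, text, perl = TRUE)
  m <- mm[[1]]
  residual <- text
  if (m[1] != -1L) {
    # blank out matched tokens, then only separators may remain
    for (i in seq_along(m)) {
      substr(residual, m[i], m[i] + attr(m, "match.length")[i] - 1L) <-
        strrep(" ", attr(m, "match.length")[i])
    }
  }
  bad <- regexpr("[^ +,\\t]", residual)
  if (bad != -1L || m[1] == -1L) {
    pos <- if (bad == -1L) 1L else as.integer(bad)
    stop("cannot parse karyotype formula at position ", pos, ": ",
         sQuote(text), call. = FALSE)
  }
  tokens <- regmatches(text, mm)[[1]]
  counts <- setNames(rep(0L, 4L), morph_classes)
  for (tok in tokens) {
    n <- as.integer(sub(token_re, "\\1", tok, perl = TRUE))
    cls <- sub(token_re, "\\2", tok, perl = TRUE)
    counts[cls] <- counts[cls] + n
  }
  validate_karyotype_formula(new_karyotype_formula(counts))
}

#' Format a karyotype formula canonically
#'
#' The canonical form is `"<k>m+<k>sm+<k>st+<k>t"` with zero classes omitted,
#' e.g. `"10m+1sm+16t"`. [parse_formula()] and `format_formula()` round-trip.
#'
#' @param formula Anything accepted by [as_karyotype_formula()].
#' @return A single string.
#' @export
format_formula <- function(formula) {
  f <- as_karyotype_formula(formula)
  keep <- f$counts > 0L
  paste0(f$counts[keep], morph_classes[keep], collapse = "+")
}

#' Fundamental number (NF) of a karyotype
#'
#' The fundamental number is the total count of chromosome arms in the diploid
#' complement: biarmed pairs (m, sm, st) contribute four arms, telocentric
#' pairs two. NF is conserved under Robertsonian translocations that merge two
#' telocentrics into one biarmed chromosome.
#'
#' @inheritParams format_formula
#' @return An integer arm count.
#' @examples
#' fundamental_number("30m")          # 120
#' fundamental_number("10m+1sm+16t")  # 76
#' @export
fundamental_number <- function(formula) {
  f <- as_karyotype_formula(formula)
  biarmed <- sum(f$counts[c("m", "sm", "st")])
  2L * (2L * biarmed + f$counts[["t"]])
}
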