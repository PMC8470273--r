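karyotype_table_columns <- c(
  "species", "family", "subfamily", "tribe", "diploid_number", "formula",
  "nor_pairs", "source", "locality", "notes"
)

validate_records <- function(records, file = "<records>") {
  problems <- list()
  flag <- function(row, msg) {
    problems[[length(problems) + 1L]] <<-
      tibble::tibble(row = row, species = records$species[row], problem = msg)
  }
  for (i in seq_len(nrow(records))) {
    dn <- records$diploid_number[i]
    if (!is.na(dn) && dn %% 2 != 0) {
      flag(i, paste0("odd diploid number ", dn))
    }
    f <- records$formula[i]
    if (!is.na(f) && nzchar(f)) {
      parsed <- tryCatch(parse_formula(f), error = function(e) e)
      if (inherits(parsed, "error")) {
        flag(i, paste0("unparseable formula: ", conditionMessage(parsed)))
      } else if (!is.na(dn) && parsed$diploid_number != dn) {
        flag(i, paste0("formula 2n = ", parsed$diploid_number,
                       " disagrees with diploid_number = ", dn))
      }
    }
    np <- records$nor_pairs[i]
    if (!is.na(np) && np < 1) flag(i, "nor_pairs must be >= 1 when present")
  }
  if (length(problems)) {
    problems <- dplyr::bind_rows(problems)
    warning("dropping ", nrow(problems), " malformed row(s) from ", file,
            ": rows ", paste(problems$row, collapse = ", "), call. = FALSE)
    records <- records[-problems$row, , drop = FALSE]
  } else {
    problems <- tibble::tibble(row = integer(), species = character(),
                               problem = character())
  }
  attr(records, "problems") <- problems
  records
}

#' Read or write a karyotype record table
#'
#' The table format is tab-separated UTF-8 with a header; required columns
#' are `species` and `diploid_number`, the full schema adds `family`,
#' `subfamily`, `tribe`, `formula` (a [parse_formula()] string), `nor_pairs`
#' (count of NOR-bearing chromosome pairs), `source`, `locality` and `notes`.
#' Empty cells mean "not reported", never zero. Malformed rows (odd diploid
#' number, inconsistent formula, invalid NOR count) are dropped with a
#' warning and collected in the `"problems"` attribute of the result; valid
#' rows are still returned.
#'
#' @param path Path to a TSV file.
#' @return `read_karyotype_table()` returns a tibble of taxon records with a
#'   `"problems"` attribute (a tibble of rejected rows with row numbers).
#' @export
read_karyotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  records <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("species", "diploid_number")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(karyotype_table_columns, names(records))) {
    records[[col]] <- NA_character_
  }
  for (col in c("diploid_number", "nor_pairs")) {
    records[[col]] <- suppressWarnings(as.integer(records[[col]]))
  }
  records <- records[, union(karyotype_table_columns,
                             names(records)), drop = FALSE]
  validate_records(records, file = path)
}

#' @rdname read_karyotype_table
#' @param records A tibble of taxon records.
#' @return `write_karyotype_table()` returns `path` invisibly.
#' @export
write_karyotype_table <- function(records, path) {
  readr::write_tsv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Curated Helicoidea karyotype records and phylogeny
#'
#' Returns the package's built-in comparative-cytogenetics dataset for the
#' land-snail superfamily Helicoidea: (i) the sixteen newly karyotyped
#' records (fifteen species; *Theba pisana* sampled from two localities)
#' with diploid numbers, karyotype formulae and NOR-pair annotations;
#' (ii) supplementary literature and clade-level records (e.g. *Helix
#' straminea*, *Helix pomatia*, Bradybaeninae, Polygyridae genera, and
#' tribe/subfamily records such as Hygromiini 2n = 42) that the family-level
#' reconstruction maps onto the tree; and (iii) a rooted family-level
#' phylogeny with named internal nodes, polytomies where relationships are
#' unresolved, and `[&uncertain]` flags on tentatively placed branches.
#' Conflicting published values (e.g. *Cochlicella acuta* 2n = 52 here vs
#' 2n = 46 in earlier literature; two *Monacha* counts) are carried in the
#' `notes` column rather than resolved.
#'
#' @return A list with elements `records` (tibble; the `source` column
#'   separates `this_study` from literature and clade-level rows) and `tree`
#'   (a `phylo` from [read_karyo_tree()]).
#' @examples
#' fx <- paper_fixtures()
#' dplyr::filter(fx$records, species == "Theba pisana")
#' @export
paper_fixtures <- function() {
  study <- read_karyotype_table(
    system.file("extdata", "helicoidea_karyotypes.tsv", package = "karyevol",
                mustWork = TRUE))
  lit <- read_karyotype_table(
    system.file("extdata", "helicoidea_literature.tsv", package = "karyevol",
                mustWork = TRUE))
  tree <- read_karyo_tree(
    system.file("extdata", "helicoidea_tree.nwk", package = "karyevol",
                mustWork = TRUE))
  list(records = dplyr::bind_rows(study, lit), tree = tree)
}

#' Tip states for a reconstruction from a record table
#'
#' Matches tree tip labels (underscored) against record species/taxon names
#' and returns the named diploid-number vector [sankoff_reconstruct()]
#' expects. Records not in the tree are ignored; tips without a record are
#' left unmatched (and will be pruned downstream with a warning).
#'
#' @param records A record tibble (see [read_karyotype_table()]).
#' @param tree A `phylo`.
#' @return A named numeric vector of diploid numbers.
#' @export
fixture_tip_states <- function(records, tree) {
  lab <- gsub(" ", "_", records$species)
  keep <- lab %in% tree$tip.label & !is.na(records$diploid_number)
  v <- tapply(records$diploid_number[keep], lab[keep], function(x) {
    u <- unique(x)
    if (length(u) > 1L) {
      stop("conflicting diploid numbers among records for one tip",
           call. = FALSE)
    }
    u
  })
  setNames(as.numeric(v), names(v))
}

#' Uncorrected p-distance between aligned sequences
#'
#' Counts differences over alignment columns where both sequences carry an
#' unambiguous base (A, C, G or T, case-insensitive); columns with a gap
#' (`-`) or `N` in either sequence are excluded from both numerator and
#' denominator. No substitution-model correction is applied.
#'
#' @param seq_a,seq_b Aligned sequences of equal length, as single strings
#'   or character vectors of residues.
#' @return `p_distance()`: the fraction of differing comparable columns, in
#'   `[0, 1]`. `identity_percent()`: `100 * (1 - p)`.
#' @examples
#' p_distance("ACGT", "ACGA")     # 0.25
#' p_distance("AC-GT", "ACAGA")   # gap column excluded: 0.25
#' @export
p_distance <- function(seq_a, seq_b) {
  split1 <- function(x) {
    if (length(x) == 1L) strsplit(x, "")[[1]] else as.character(x)
  }
  a <- toupper(split1(seq_a))
  b <- toupper(split1(seq_b))
  if (length(a) != length(b)) {
    stop("aligned sequences differ in length (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  ok <- c("A", "C", "G", "T")
  comparable <- a %in% ok & b %in% ok
  if (!any(comparable)) {
    stop("no comparable columns (all gapped or ambiguous)", call. = FALSE)
  }
  sum(a[comparable] != b[comparable]) / sum(comparable)
}

#' @rdname p_distance
#' @export
identity_percent <- function(seq_a, seq_b) {
  100 * (1 - p_distance(seq_a, seq_b))
}

#' Read an aligned FASTA file as character sequences
#'
#' Thin wrapper over [ape::read.FASTA()] returning a named list of
#' per-residue character vectors ready for [p_distance()].
#'
#' @param path Path to a FASTA file.
#' @return A named list of character vectors.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- ape::read.FASTA(path)
  lapply(as.character(dna), toupper)
}
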