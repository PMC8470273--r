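# Shared generators for property-style tests. Everything is built in code;
# no stored fixtures beyond the package's own extdata.

# all karyotype formulae with exactly n pairs (compositions of n into 4 classes)
all_formulae_with_n <- function(n) {
  grid <- expand.grid(m = 0:n, sm = 0:n, st = 0:n)
  grid <- grid[grid$m + grid$sm + grid$st <= n, , drop = FALSE]
  grid$t <- n - grid$m - grid$sm - grid$st
  lapply(seq_len(nrow(grid)), function(i)
    karyotype_formula(grid$m[i], grid$sm[i], grid$st[i], grid$t[i]))
}

random_formula <- function(n_pairs) {
  cls <- sample(morph_classes, n_pairs, replace = TRUE)
  counts <- table(factor(cls, levels = morph_classes))
  karyotype_formula(counts[["m"]], counts[["sm"]], counts[["st"]],
                    counts[["t"]])
}

# random rooted tree with n tips; occasionally collapses short edges into
# polytomies so that both shapes are exercised
random_test_tree <- function(n_tips, polytomy = FALSE) {
  tr <- ape::rtree(n_tips, rooted = TRUE)
  if (polytomy && n_tips >= 3) {
    tr$edge.length[tr$edge.length < 0.3] <- 0
    tr <- ape::di2multi(tr, tol = 1e-9)
  }
  tr
}

random_even_states <- function(labels, lo = 40, hi = 64) {
  setNames(sample(seq(lo, hi, by = 2), length(labels), replace = TRUE),
           labels)
}

# the curated dataset, loaded once per test file
fixture_env <- new.env()
get_fixtures <- function() {
  if (is.null(fixture_env$fx)) fixture_env$fx <- paper_fixtures()
  fixture_env$fx
}
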