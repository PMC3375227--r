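# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force double loops and direct formula
# transcriptions only.

# all-pairs O(n^2) Pareto front membership (maximise all columns,
# strict dominance)
oracle_front <- function(coords) {
  n <- nrow(coords)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j != i && all(coords[j, ] > coords[i, ])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  keep
}

# direct evaluation of the pairwise-coupling activity model for a single
# genotype: background + sum_i d_i p_i + sum_{i<j} d_i d_j p_ij
oracle_activity <- function(delta, p_main, p_pairs, background) {
  M <- length(delta)
  a <- background + sum(delta * p_main)
  if (!is.null(p_pairs)) {
    idx <- 0
    for (i in seq_len(M - 1)) {
      for (j in (i + 1):M) {
        idx <- idx + 1
        a <- a + delta[i] * delta[j] * p_pairs[idx]
      }
    }
  }
  a
}

# post-hoc mutational-path checker, independent of the walk code: verifies
# Hamming-1 steps, monotone improvement, the constraint floor at every
# node, and that the terminal is a local optimum under the rule
oracle_check_path <- function(path_genotypes, activities, rule) {
  act <- function(g, obj) activities[g, obj]
  sgn <- if (rule$direction == "increase") 1 else -1
  for (s in seq_along(path_genotypes)) {
    g <- path_genotypes[s]
    if (act(g, rule$constraint) < rule$threshold) return("constraint violated")
    if (s > 1) {
      prev <- path_genotypes[s - 1]
      db <- sum(strsplit(g, "")[[1]] != strsplit(prev, "")[[1]])
      if (db != 1) return("not a single-mutation step")
      if (sgn * (act(g, rule$improve) - act(prev, rule$improve)) <= 0)
        return("improve objective not monotone")
    }
  }
  term <- path_genotypes[length(path_genotypes)]
  tv <- as.integer(strsplit(term, "")[[1]])
  for (i in seq_along(tv)) {
    nb <- tv
    nb[i] <- 1L - nb[i]
    nbs <- paste(nb, collapse = "")
    if (sgn * (act(nbs, rule$improve) - act(term, rule$improve)) > 0 &&
        act(nbs, rule$constraint) >= rule$threshold)
      return("terminal is not a local optimum")
  }
  "ok"
}

toy5_path <- function() {
  system.file("extdata", "toy5.fasta", package = "promiscreen")
}

# small in-code alignment with a planted signature-coupled column:
# signature at position 4 (H vs P), coupled column at position 8 (Y in the
# His subalignment, W otherwise)
toy5_alignment <- function() {
  read_alignment(toy5_path(), reference_id = "ref")
}
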