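#' Specify a synthetic MSA with planted signature-coupled columns
#'
#' The generator emulates the statistical structure that function-targeted
#' coupling analysis exploits: a signature position whose residue identity
#' (e.g. His vs Pro) splits the alignment, and a handful of planted
#' columns whose residue distribution shifts in the signature
#' subalignment. All other columns draw residues independently from the
#' background distribution, so they carry only sampling noise.
#'
#' Planted-column model: sequences in the complement draw the baseline
#' residue; sequences in the signature subalignment draw the shifted
#' residue with probability equal to the shift strength and the baseline
#' residue otherwise. Shift 0 plants no signal, shift 1 a maximal
#' distribution shift.
#'
#' @param n_seq Number of sequences.
#' @param length Number of alignment columns (no gaps are generated; the
#'   reference maps column i to position i).
#' @param signature_position Column of the signature residue.
#' @param signature_residues Length-2 character vector: subalignment
#'   residue, complement residue (default `c("H", "P")`).
#' @param signature_fraction Fraction of sequences carrying the
#'   subalignment residue (default 0.25).
#' @param planted Data frame with columns `position`, `baseline`,
#'   `shifted`, `shift` (strength in [0, 1]); positions must differ from
#'   the signature position. An optional `ref` column gives the residue
#'   the reference sequence carries at the column (default the baseline
#'   residue). Setting `ref` to the shifted residue plants a *negatively*
#'   shifted column: the signature subalignment then moves weight toward
#'   the reference residue, so the mutation-direction score Gamma at that
#'   column is negative while the coupling energy stays high.
#' @param background Residue distribution for unplanted columns; default
#'   uniform over the 20 amino acids.
#' @param seed Integer seed.
#' @return An `msa_spec` list.
#' @export
msa_spec <- function(n_seq, length, signature_position,
                     signature_residues = c("H", "P"),
                     signature_fraction = 0.25,
                     planted = NULL,
                     background = NULL, seed = 1) {
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20), AA20)
  background <- background / sum(background)
  if (!is.null(planted)) {
    stopifnot(all(c("position", "baseline", "shifted", "shift") %in%
                    names(planted)))
    if (any(planted$position == signature_position))
      stop("planted columns must differ from the signature position")
    if (any(planted$shift < 0 | planted$shift > 1))
      stop("shift strength must lie in [0, 1]")
    if (any(planted$position > length))
      stop("planted position beyond alignment length")
  }
  structure(list(n_seq = n_seq, length = length,
                 signature_position = signature_position,
                 signature_residues = signature_residues,
                 signature_fraction = signature_fraction,
                 planted = planted, background = background, seed = seed),
            class = "msa_spec")
}

#' Generate a synthetic MSA from a spec
#'
#' The reference sequence (id `"ref"`) is generated alongside and carries
#' the complement signature residue and the planted baseline residues, so
#' reference numbering is the identity map. Fixed seeds give identical
#' alignments.
#'
#' @param spec An [msa_spec()].
#' @return An `msa_alignment`; attribute `planted_positions` records the
#'   planted column positions.
#' @export
generate_msa <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_seq
  L <- spec$length
  m <- matrix(sample(AA20, n * L, replace = TRUE, prob = spec$background),
              nrow = n, ncol = L)
  n_sub <- round(n * spec$signature_fraction)
  is_sub <- c(rep(TRUE, n_sub), rep(FALSE, n - n_sub))
  m[, spec$signature_position] <- ifelse(is_sub,
                                         spec$signature_residues[1],
                                         spec$signature_residues[2])
  if (!is.null(spec$planted)) {
    for (r in seq_len(nrow(spec$planted))) {
      p <- spec$planted[r, ]
      col <- rep(p$baseline, n)
      shift_hit <- is_sub & (runif(n) < p$shift)
      col[shift_hit] <- p$shifted
      m[, p$position] <- col
    }
  }
  ref <- sample(AA20, L, replace = TRUE, prob = spec$background)
  ref[spec$signature_position] <- spec$signature_residues[2]
  if (!is.null(spec$planted)) {
    ref_res <- if ("ref" %in% names(spec$planted)) spec$planted$ref
               else spec$planted$baseline
    ref[spec$planted$position] <- ref_res
  }
  records <- c(setNames(paste(ref, collapse = ""), "ref"),
               setNames(apply(m, 1, paste, collapse = ""),
                        paste0("seq", seq_len(n))))
  aln <- new_alignment(records, "ref")
  attr(aln, "planted_positions") <-
    if (is.null(spec$planted)) integer(0) else spec$planted$position
  aln
}

#' Specify a ground-truth pairwise-coupling activity landscape
#'
#' The generative counterpart of the fitted activity model: per objective
#' k, `A^k(g) = background^k + sum_i delta_i p_i^k +
#' sum_{i<j} delta_ij p_ij^k`, with optional homoscedastic Gaussian noise
#' on the log activities.
#'
#' @param M Number of mutations.
#' @param p_main M x K matrix of main-effect coefficients.
#' @param p_pairs M(M-1)/2 x K matrix of pairwise couplings (lexicographic
#'   (i, j) order), or NULL for an additive landscape.
#' @param background Length-K vector of background (no-mutation) log
#'   activities.
#' @param noise_sd Gaussian noise sd on log activities (>= 0).
#' @param objectives Objective names.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(M, p_main, p_pairs = NULL,
                           background = NULL, noise_sd = 0,
                           objectives = NULL) {
  p_main <- as.matrix(p_main)
  if (nrow(p_main) != M) stop("p_main must have M rows")
  K <- ncol(p_main)
  n_pairs <- M * (M - 1) / 2
  if (!is.null(p_pairs)) {
    p_pairs <- as.matrix(p_pairs)
    if (nrow(p_pairs) != n_pairs || ncol(p_pairs) != K)
      stop("p_pairs must be ", n_pairs, " x ", K)
  }
  if (is.null(background)) background <- rep(0, K)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(objectives))
    objectives <- if (K == 2) c("primary", "promiscuous")
                  else paste0("objective", seq_len(K))
  structure(list(M = M, K = K, p_main = p_main, p_pairs = p_pairs,
                 background = background, noise_sd = noise_sd,
                 objectives = objectives),
            class = "landscape_spec")
}

# noiseless model evaluation; the independent brute-force oracle for this
# is a per-genotype double loop in the tests
evaluate_landscape <- function(spec, g) {
  X <- design_matrix(g, include_pairs = !is.null(spec$p_pairs))
  B <- rbind(spec$p_main,
             if (!is.null(spec$p_pairs)) spec$p_pairs)
  A <- sweep(X %*% B, 2, spec$background, "+")
  colnames(A) <- spec$objectives
  A
}

#' Generate an activity table (and its noiseless truth) from a spec
#'
#' @param spec A [landscape_spec()].
#' @param genotypes Genotypes to assay; alternatively give `n_random`.
#' @param n_random Number of distinct genotypes drawn uniformly at random
#'   from the 2^M library.
#' @param seed Integer seed (training-set draw and noise).
#' @return List with `table` (noisy [activity_table()] for fitting) and
#'   `truth` (the complete noiseless [landscape()], the oracle for all
#'   downstream modules).
#' @export
generate_activity_table <- function(spec, genotypes = NULL, n_random = NULL,
                                    seed = 1) {
  set.seed(seed)
  lib <- enumerate_library(spec$M)
  if (is.null(genotypes)) {
    if (is.null(n_random))
      stop("give either genotypes or n_random")
    idx <- sample.int(nrow(lib), n_random, replace = FALSE)
    genotypes <- lib[sort(idx), , drop = FALSE]
  }
  g <- genotype_matrix(genotypes)
  truth_all <- evaluate_landscape(spec, lib)
  A <- evaluate_landscape(spec, g)
  if (spec$noise_sd > 0)
    A <- A + matrix(rnorm(length(A), sd = spec$noise_sd),
                    nrow = nrow(A), ncol = ncol(A))
  list(table = activity_table(g, A, objectives = spec$objectives),
       truth = landscape(lib, truth_all, objectives = spec$objectives))
}

#' Bundle reproducing the study-scale computational geometry
#'
#' One call sets up the canonical problem size of the protocol: M = 10
#' mutations (2^10 = 1024 variants), two objectives, a 29-variant random
#' training subset (58 dependent values) and B = 20 bootstrap replicas.
#' Ground-truth coefficients are drawn once per seed: main effects
#' ~ U(-0.5, 0.5), five non-zero pairwise couplings ~ U(-0.3, 0.3), and
#' Gaussian noise of sd 0.1 on the log activities.
#'
#' @param seed Integer seed.
#' @param n_train Training-set size (default 29).
#' @param noise_sd Log-activity noise sd (default 0.1).
#' @param n_couplings Number of non-zero pairwise couplings (default 5).
#' @return List with `spec` (the [landscape_spec()]), `table` (noisy
#'   training [activity_table()]), `truth` (noiseless full
#'   [landscape()]), `B` (recommended replica count, 20) and `seed`.
#' @export
paper_scale_scenario <- function(seed = 1, n_train = 29, noise_sd = 0.1,
                                 n_couplings = 5) {
  M <- 10
  set.seed(seed)
  p_main <- matrix(runif(M * 2, -0.5, 0.5), ncol = 2)
  n_pairs <- M * (M - 1) / 2
  p_pairs <- matrix(0, n_pairs, 2)
  which_pairs <- sample.int(n_pairs, n_couplings)
  p_pairs[which_pairs, ] <- runif(n_couplings * 2, -0.3, 0.3)
  spec <- landscape_spec(M, p_main, p_pairs, background = c(0, 0),
                         noise_sd = noise_sd)
  gen <- generate_activity_table(spec, n_random = n_train, seed = seed + 1)
  list(spec = spec, table = gen$table, truth = gen$truth, B = 20,
       seed = seed)
}
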