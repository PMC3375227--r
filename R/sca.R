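#' Statistical coupling analysis of a signature perturbation
#'
#' Compares the per-position residue statistics of the signature
#' subalignment (e.g. sequences with His at position 34) with those of the
#' full alignment, yielding a statistical free energy (in arbitrary kT*
#' units) for the coupling of every mapped position with the signature
#' position. Large values mark positions whose residue distribution shifts
#' when the signature residue changes, i.e. candidate co-evolving sites.
#'
#' Two energy forms are available. `"binomial"` (default) follows the
#' binomial-weighting scheme of classical SCA: for position i,
#' `ddG_i = kT* sqrt( sum_x (ln P_sub(x) - ln P_full(x))^2 )` where
#' `P_sub(x) = dbinom(n_sub_x, N_sub, g_x)` is the binomial probability of
#' the observed subalignment count of residue x under the background
#' frequency `g_x` (mean residue frequency over all alignment columns), and
#' the full-alignment counts are rescaled to the subalignment depth before
#' weighting. `"logratio"` is the simpler variant
#' `ddG_i = kT* sqrt( sum_x (ln f_sub - ln f_full)^2 )` on pseudocounted
#' frequencies. A per-position covariance statistic `sigma` (see
#' [covariance_sigma()]) is computed alongside as a robustness cross-check.
#'
#' @param aln Full `msa_alignment`.
#' @param crit A [signature_criterion()].
#' @param pseudocount Frequency pseudocount (default 0.5).
#' @param min_sub_size Minimum signature-subalignment size (default 20);
#'   below it the analysis refuses unless `force = TRUE`.
#' @param method `"binomial"` or `"logratio"`.
#' @param kT Energy scale factor kT* (arbitrary units, default 1).
#' @param force Proceed despite a small subalignment.
#' @return An `sca_result`: data.frame with columns `position`, `ddG`,
#'   `sigma`, `gap_flagged`, sorted by position; attributes `sub_size`,
#'   `full_size`, `criterion`, `method`.
#' @export
sca_statistical_energy <- function(aln, crit, pseudocount = 0.5,
                                   min_sub_size = 20,
                                   method = c("binomial", "logratio"),
                                   kT = 1, force = FALSE) {
  method <- match.arg(method)
  parts <- select_subalignment(aln, crit)
  if (parts$n_sub < min_sub_size) {
    if (!force)
      stop("signature subalignment has only ", parts$n_sub,
           " sequences (< ", min_sub_size,
           "); statistics would be unreliable. Use force = TRUE to override.")
    warning("signature subalignment below min_sub_size (", parts$n_sub,
            " < ", min_sub_size, "); proceeding because force = TRUE")
  }
  f_full <- positional_frequencies(aln, pseudocount)
  f_sub <- positional_frequencies(parts$sub, pseudocount)
  f_comp <- if (!is.null(parts$complement))
    positional_frequencies(parts$complement, pseudocount) else NULL

  positions <- f_full$positions
  ddG <- rep(NA_real_, length(positions))
  g <- colMeans(f_full$freq[f_full$n_eff > 0, , drop = FALSE])
  g <- g / sum(g)
  for (k in seq_along(positions)) {
    if (f_sub$n_eff[k] == 0 || f_full$n_eff[k] == 0) next
    if (method == "binomial") {
      n_sub_x <- f_sub$counts[k, ]
      N_sub <- f_sub$n_eff[k]
      # full counts rescaled to the subalignment depth; raw (unpseudocounted)
      # frequencies so that sub == full gives exactly zero
      n_full_scaled <- round(f_full$counts[k, ] / f_full$n_eff[k] * N_sub)
      lp_sub <- dbinom(n_sub_x, N_sub, g, log = TRUE)
      lp_full <- dbinom(n_full_scaled, N_sub, g, log = TRUE)
      ddG[k] <- kT * sqrt(sum((lp_sub - lp_full)^2))
    } else {
      ddG[k] <- kT * sqrt(sum((log(f_sub$freq[k, ]) -
                                 log(f_full$freq[k, ]))^2))
    }
  }
  sigma <- sigma_from_tables(f_sub, f_comp)
  out <- data.frame(position = positions, ddG = ddG, sigma = sigma,
                    gap_flagged = f_full$flagged)
  out <- out[out$position != crit$position, ]
  rownames(out) <- NULL
  structure(out, class = c("sca_result", "data.frame"),
            sub_size = parts$n_sub, full_size = aln$n_seq,
            complement_size = parts$n_complement,
            criterion = crit, method = method, pseudocount = pseudocount)
}

sigma_from_tables <- function(f_sub, f_comp) {
  if (is.null(f_comp)) return(rep(NA_real_, length(f_sub$positions)))
  sig <- sqrt(rowSums((f_sub$freq - f_comp$freq)^2))
  sig[f_sub$n_eff == 0 | f_comp$n_eff == 0] <- NA_real_
  sig
}

#' Simple covariance analysis of a signature perturbation
#'
#' Per-position association between the signature residue identity and the
#' residue distribution: the Euclidean distance between the pseudocounted
#' frequency vectors of the signature subalignment and its complement,
#' `sigma_i = sqrt( sum_x (f_sub[i,x] - f_comp[i,x])^2 )`. Used as an
#' independent robustness check on the SCA energy ranking; the two rank
#' positions very similarly on alignments with genuine coupling signal.
#'
#' @inheritParams sca_statistical_energy
#' @return Data frame with columns `position` and `sigma`.
#' @export
covariance_sigma <- function(aln, crit, pseudocount = 0.5,
                             min_sub_size = 20, force = FALSE) {
  parts <- select_subalignment(aln, crit)
  if (is.null(parts$complement))
    stop("empty complement: covariance analysis needs both subalignments")
  if (parts$n_sub < min_sub_size && !force)
    stop("signature subalignment has only ", parts$n_sub,
         " sequences (< ", min_sub_size, "); use force = TRUE to override.")
  f_sub <- positional_frequencies(parts$sub, pseudocount)
  f_comp <- positional_frequencies(parts$complement, pseudocount)
  out <- data.frame(position = f_sub$positions,
                    sigma = sigma_from_tables(f_sub, f_comp))
  out[out$position != crit$position, , drop = FALSE]
}

#' Mutation-direction score Gamma
#'
#' Quantifies how strongly the signature substitution shifts the residue
#' statistics at a position from the wild-type residue `Ec` towards a
#' target residue `X`: the log odds ratio
#' `Gamma = ln( f_sub(X) / f_sub(Ec) ) - ln( f_comp(X) / f_comp(Ec) )`,
#' where `f_sub` are the frequencies conditional on the signature residue
#' (e.g. His at 34) and `f_comp` those conditional on the complement
#' residue (e.g. Pro). Gamma is zero when the two conditional
#' distributions coincide, positive when the signature subalignment shifts
#' weight from Ec towards X, and changes sign when the roles of the two
#' subalignments are swapped.
#'
#' @param freq_sub,freq_comp `freq_table`s of the signature subalignment
#'   and its complement (same positions, pseudocount > 0).
#' @param position Reference position.
#' @param ec Wild-type (reference) residue, one-letter code.
#' @param x Target residue, one-letter code, different from `ec`.
#' @return Numeric Gamma score.
#' @export
gamma_score <- function(freq_sub, freq_comp, position, ec, x) {
  if (ec == x) stop("target residue X must differ from the wild-type residue")
  k_sub <- match(position, freq_sub$positions)
  k_comp <- match(position, freq_comp$positions)
  if (is.na(k_sub) || is.na(k_comp))
    stop("position ", position, " not covered by both frequency tables")
  if (freq_sub$n_eff[k_sub] == 0 || freq_comp$n_eff[k_comp] == 0)
    stop("position ", position, " is all-gap in one subalignment; ",
         "frequencies undefined")
  fs <- freq_sub$freq[k_sub, ]
  fc <- freq_comp$freq[k_comp, ]
  log(fs[[x]] / fs[[ec]]) - log(fc[[x]] / fc[[ec]])
}

#' Nominate candidate mutations from the SCA ranking
#'
#' Takes the `n_top` positions with the highest SCA coupling energies,
#' determines for each the target residue X (the most frequent residue
#' other than the reference residue in the signature subalignment; ties
#' broken alphabetically), scores the Ec->X substitution with
#' [gamma_score()], and returns the candidates with positive Gamma ranked
#' by coupling energy. This mirrors the two-layer selection that yields a
#' small set of mutations for combinatorial library construction.
#'
#' @inheritParams sca_statistical_energy
#' @param n_top Number of top-energy positions to examine (default 13).
#' @param sca Optionally, a precomputed [sca_statistical_energy()] result.
#' @return A `mutation_candidates` data.frame with columns `position`,
#'   `ec`, `x`, `sca_energy`, `gamma`, `rank` and a `mutation` label like
#'   `"I4V"`.
#' @export
top_candidate_mutations <- function(aln, crit, n_top = 13,
                                    pseudocount = 0.5, min_sub_size = 20,
                                    method = c("binomial", "logratio"),
                                    force = FALSE, sca = NULL) {
  method <- match.arg(method)
  if (is.null(sca))
    sca <- sca_statistical_energy(aln, crit, pseudocount = pseudocount,
                                  min_sub_size = min_sub_size,
                                  method = method, force = force)
  if (n_top <= 0)
    return(structure(data.frame(position = integer(), ec = character(),
                                x = character(), sca_energy = numeric(),
                                gamma = numeric(), rank = integer(),
                                mutation = character()),
                     class = c("mutation_candidates", "data.frame")))
  parts <- select_subalignment(aln, crit)
  f_sub <- positional_frequencies(parts$sub, pseudocount)
  f_comp <- if (!is.null(parts$complement))
    positional_frequencies(parts$complement, pseudocount)
  else stop("empty complement: Gamma scores need both subalignments")

  ok <- !is.na(sca$ddG)
  ord <- order(-sca$ddG[ok])
  top <- sca[ok, ][ord, ][seq_len(min(n_top, sum(ok))), ]

  ref_seq <- strsplit(aln$records[[aln$reference_id]], "")[[1]]
  mapped_cols <- which(!is.na(aln$column_map))
  ref_residue <- setNames(ref_seq[mapped_cols], aln$column_map[mapped_cols])

  rows <- lapply(seq_len(nrow(top)), function(r) {
    pos <- top$position[r]
    ec <- ref_residue[[as.character(pos)]]
    k <- match(pos, f_sub$positions)
    counts <- f_sub$counts[k, ]
    counts <- counts[names(counts) != ec]
    # ties broken alphabetically: AA20 order is alphabetical and
    # which.max returns the first maximum
    x <- names(counts)[which.max(counts)]
    g <- gamma_score(f_sub, f_comp, pos, ec, x)
    data.frame(position = pos, ec = ec, x = x,
               sca_energy = top$ddG[r], gamma = g)
  })
  out <- do.call(rbind, rows)
  out <- out[out$gamma > 0, , drop = FALSE]
  out <- out[order(-out$sca_energy), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$mutation <- paste0(out$ec, out$position, out$x)
  rownames(out) <- NULL
  structure(out, class = c("mutation_candidates", "data.frame"))
}

#' Write SCA results and candidate mutations as TSV
#'
#' @param x An `sca_result` or `mutation_candidates` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sca_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
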