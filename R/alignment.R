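#' @importFrom stats dbinom coef cor lm median quantile runif rnorm sd setNames
#' @importFrom utils combn read.delim write.table head
NULL

#' The 20 standard amino acids (one-letter codes, alphabetical)
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP <- "-"

#' Read an aligned FASTA file into an alignment object
#'
#' Parses a gapped amino-acid multiple sequence alignment and builds the
#' map between alignment columns and reference positions by walking the
#' non-gap columns of the named reference sequence (1-based numbering).
#'
#' @param path Path to an aligned FASTA file.
#' @param reference_id Identifier of the sequence that defines position
#'   numbering. Must be present in the file.
#' @param format Input format; only `"fasta"` is supported.
#' @return An object of class `msa_alignment` with components `records`
#'   (named character vector of gapped sequences), `reference_id`,
#'   `column_map` (integer vector, one entry per alignment column, `NA`
#'   where the reference has a gap) and `n_seq`/`width`.
#' @export
read_alignment <- function(path, reference_id, format = "fasta") {
  format <- match.arg(format, "fasta")
  aa <- Biostrings::readAAStringSet(path, format = "fasta")
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  new_alignment(seqs, reference_id)
}

#' Construct an alignment object from gapped sequences
#'
#' @param records Named character vector of equal-length gapped sequences.
#' @param reference_id Name of the reference record.
#' @return An `msa_alignment` object.
#' @export
new_alignment <- function(records, reference_id) {
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all sequences must be named")
  widths <- nchar(records)
  if (length(unique(widths)) != 1L)
    stop("malformed alignment: sequences have unequal lengths (",
         paste(unique(widths), collapse = ", "), ")")
  if (!reference_id %in% names(records))
    stop("reference sequence '", reference_id, "' not found in alignment")
  ref <- strsplit(records[[reference_id]], "")[[1]]
  column_map <- rep(NA_integer_, length(ref))
  nongap <- ref != GAP
  column_map[nongap] <- seq_len(sum(nongap))
  bad <- nongap & !(ref %in% AA20)
  if (any(bad))
    stop("reference sequence contains non-standard residues at mapped columns: ",
         paste(unique(ref[bad]), collapse = ","))
  structure(
    list(records = records, reference_id = reference_id,
         column_map = column_map, n_seq = length(records),
         width = unique(widths)),
    class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("Aligned MSA: ", x$n_seq, " sequences x ", x$width, " columns\n",
      "reference: ", x$reference_id, " (",
      sum(!is.na(x$column_map)), " mapped positions)\n", sep = "")
  invisible(x)
}

#' Write an alignment to aligned FASTA
#'
#' @param aln An `msa_alignment` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln$records), path)
  invisible(path)
}

# character matrix view (sequences x columns); cached computation is cheap
# at the alignment sizes used here so no memoisation
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$records), ""))
  rownames(m) <- names(aln$records)
  m
}

# alignment column holding a given reference position
position_column <- function(aln, position) {
  col <- match(position, aln$column_map)
  if (is.na(col))
    stop("reference position ", position, " is not mapped in this alignment")
  col
}

#' Define a signature criterion for subalignment selection
#'
#' A perturbation of the alignment: sequences carrying a residue from
#' `residue_set` at `position` form the signature subalignment, those
#' carrying a residue from `complement_residue_set` form the complement.
#' The canonical use is His vs Pro at the CXXC-adjacent position 34.
#'
#' @param position Reference position (1-based reference numbering).
#' @param residue_set Character vector of one-letter codes selecting the
#'   subalignment (e.g. `"H"`).
#' @param complement_residue_set Residues selecting the complement
#'   (e.g. `"P"`). Must be disjoint from `residue_set`.
#' @return A `signature_criterion` object.
#' @export
signature_criterion <- function(position, residue_set, complement_residue_set) {
  residue_set <- toupper(residue_set)
  complement_residue_set <- toupper(complement_residue_set)
  if (length(residue_set) == 0L || length(complement_residue_set) == 0L)
    stop("residue sets must be non-empty")
  if (length(intersect(residue_set, complement_residue_set)) > 0L)
    stop("residue sets must be disjoint")
  structure(list(position = position, residue_set = residue_set,
                 complement_residue_set = complement_residue_set),
            class = "signature_criterion")
}

#' Split an alignment by a signature criterion
#'
#' @param aln An `msa_alignment`.
#' @param crit A [signature_criterion()]. Sequences whose residue at the
#'   signature position is in neither residue set (or is a gap) belong to
#'   neither output.
#' @return List with components `sub` and `complement`, both
#'   `msa_alignment` objects sharing the reference and column map. The
#'   reference sequence is carried into both for numbering purposes even
#'   when it does not satisfy the criterion.
#' @export
select_subalignment <- function(aln, crit) {
  col <- position_column(aln, crit$position)
  res <- substr(aln$records, col, col)
  in_sub <- res %in% crit$residue_set
  in_comp <- res %in% crit$complement_residue_set
  if (!any(in_sub))
    stop("empty perturbation: no sequence carries ",
         paste(crit$residue_set, collapse = "/"), " at position ",
         crit$position, " (SCA undefined)")
  split_one <- function(keep) {
    recs <- aln$records[keep]
    if (!aln$reference_id %in% names(recs))
      recs <- c(aln$records[aln$reference_id], recs)
    out <- new_alignment(recs, aln$reference_id)
    out$n_members <- sum(keep)
    out$members <- names(aln$records)[keep]
    out
  }
  sub <- split_one(in_sub)
  complement <- if (any(in_comp)) split_one(in_comp) else NULL
  list(sub = sub, complement = complement,
       n_sub = sum(in_sub), n_complement = sum(in_comp))
}

#' Per-position amino-acid frequencies with pseudocount regularisation
#'
#' Gaps are excluded from the 20-residue normalisation:
#' `f[i,x] = (n[i,x] + pc) / (N[i] + 20 pc)` where `n[i,x]` counts residue
#' `x` among non-gap entries at mapped position `i` and `N[i]` is the
#' non-gap count. Positions with more than half gaps are flagged; all-gap
#' positions get `NA` frequencies.
#'
#' @param aln An `msa_alignment`.
#' @param pseudocount Non-negative pseudocount (default 0.5, Jeffreys-like,
#'   so that log-frequencies are finite).
#' @param members_only If the alignment came from [select_subalignment()],
#'   count only member sequences (the carried reference is excluded).
#' @return A `freq_table`: list with `freq` (positions x 20 matrix),
#'   `counts`, `n_eff` (non-gap depth per position), `gap_fraction`,
#'   `flagged` (gap fraction > 0.5) and `pseudocount`.
#' @export
positional_frequencies <- function(aln, pseudocount = 0.5,
                                   members_only = TRUE) {
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  m <- alignment_matrix(aln)
  if (members_only && !is.null(aln$members))
    m <- m[aln$members, , drop = FALSE]
  mapped <- which(!is.na(aln$column_map))
  positions <- aln$column_map[mapped]
  counts <- matrix(0L, nrow = length(mapped), ncol = 20,
                   dimnames = list(positions, AA20))
  for (k in seq_along(mapped)) {
    tab <- table(factor(m[, mapped[k]], levels = AA20))
    counts[k, ] <- as.integer(tab)
  }
  n_eff <- rowSums(counts)
  freq <- (counts + pseudocount) / (n_eff + 20 * pseudocount)
  freq[n_eff == 0, ] <- NA_real_
  gap_fraction <- 1 - n_eff / nrow(m)
  structure(list(freq = freq, counts = counts, n_eff = n_eff,
                 gap_fraction = gap_fraction, flagged = gap_fraction > 0.5,
                 positions = positions, n_seq = nrow(m),
                 pseudocount = pseudocount),
            class = "freq_table")
}

#' Optional sequence-identity prefilter
#'
#' Keeps sequences whose identity to the reference, computed over the
#' reference's non-gap columns, is at least `min_identity`. Off by default
#' in the analysis entry points since the alignment is an input.
#'
#' @param aln An `msa_alignment`.
#' @param min_identity Minimum fractional identity (default 0.3).
#' @return Filtered `msa_alignment` (reference always retained).
#' @export
filter_by_identity <- function(aln, min_identity = 0.3) {
  m <- alignment_matrix(aln)
  cols <- which(!is.na(aln$column_map))
  ref <- m[aln$reference_id, cols]
  ident <- apply(m[, cols, drop = FALSE], 1, function(s) mean(s == ref))
  keep <- ident >= min_identity | names(aln$records) == aln$reference_id
  new_alignment(aln$records[keep], aln$reference_id)
}
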