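#' Enumerate a combinatorial mutant library
#'
#' All 2^M binary genotypes over M candidate mutations, ordered by the
#' integer value of the bit vector with bit 1 (the first mutation) as the
#' least significant bit. The first row is the background (no mutations),
#' the last the all-mutations variant.
#'
#' @param M Number of candidate mutations (0..20; larger libraries must be
#'   sampled, not enumerated).
#' @return Integer matrix of 0/1 with 2^M rows and M columns, rownames the
#'   genotype bitstrings.
#' @export
enumerate_library <- function(M) {
  if (M < 0) stop("M must be non-negative")
  if (M > 20)
    stop("M = ", M, " would enumerate 2^", M, " genotypes; ",
         "enumerate_library() is capped at M = 20 - sample the space instead")
  if (M == 0) {
    g <- matrix(integer(0), nrow = 1, ncol = 0)
    rownames(g) <- ""
    return(g)
  }
  v <- 0:(2^M - 1)
  g <- vapply(seq_len(M), function(i) bitwAnd(v %/% 2^(i - 1), 1L),
              integer(length(v)))
  g <- matrix(as.integer(g), nrow = length(v), ncol = M)
  rownames(g) <- apply(g, 1, paste, collapse = "")
  colnames(g) <- paste0("m", seq_len(M))
  g
}

#' Convert genotypes between bitstring and matrix form
#'
#' Bit order: character i of the string is mutation i (bit 1 first).
#'
#' @param x Character vector of bitstrings, or a 0/1 matrix/vector.
#' @return `genotype_matrix()` returns an integer matrix with bitstring
#'   rownames; `genotype_string()` returns a character vector.
#' @export
genotype_matrix <- function(x) {
  if (is.character(x)) {
    M <- unique(nchar(x))
    if (length(M) != 1L) stop("genotype bitstrings have unequal lengths")
    g <- do.call(rbind, lapply(strsplit(x, ""), as.integer))
    if (any(is.na(g)) || any(!g %in% c(0L, 1L)))
      stop("genotype strings must be binary")
    rownames(g) <- x
    colnames(g) <- paste0("m", seq_len(ncol(g)))
    return(g)
  }
  g <- as.matrix(x)
  storage.mode(g) <- "integer"
  if (any(!g %in% c(0L, 1L))) stop("genotypes must be 0/1")
  rownames(g) <- apply(g, 1, paste, collapse = "")
  if (is.null(colnames(g)) && ncol(g) > 0)
    colnames(g) <- paste0("m", seq_len(ncol(g)))
  g
}

#' @rdname genotype_matrix
#' @export
genotype_string <- function(x) {
  if (is.character(x)) return(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  apply(x, 1, paste, collapse = "")
}

#' Pairwise-coupling design matrix for the activity model
#'
#' Expands binary genotypes into the predictor block of the pairwise
#' epistasis model: M main-effect indicators delta_i followed by the
#' M(M-1)/2 pair indicators delta_ij = delta_i * delta_j in lexicographic
#' (i, j) order with i < j. With `include_pairs = FALSE` only the main
#' effects are used (the additive model).
#'
#' @param genotypes Genotype matrix or character vector of bitstrings.
#' @param include_pairs Include pairwise interaction columns (default TRUE).
#' @return Numeric matrix; column names `m<i>` and `m<i>:m<j>`.
#' @export
design_matrix <- function(genotypes, include_pairs = TRUE) {
  g <- genotype_matrix(genotypes)
  M <- ncol(g)
  X <- matrix(as.numeric(g), nrow = nrow(g), ncol = M,
              dimnames = list(rownames(g), colnames(g)))
  if (include_pairs && M >= 2) {
    pairs <- combn(M, 2)
    P <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
    colnames(P) <- paste0("m", pairs[1, ], ":m", pairs[2, ])
    X <- cbind(X, P)
  }
  X
}

#' Construct a variant-activity table
#'
#' The data model of a combinatorial screen: one row per assayed variant,
#' identified by its genotype bitstring, with one column of log10 specific
#' activity per objective (and optional per-objective standard errors in
#' columns named `<objective>_se`).
#'
#' @param genotypes Genotype matrix or bitstring vector (no duplicates).
#' @param activities Numeric matrix or data.frame, one column per objective.
#' @param objectives Objective names; defaults to the activity column names
#'   or `c("primary", "promiscuous")`.
#' @param se Optional matrix of standard errors, same shape as `activities`.
#' @return An `activity_table` data.frame with a `genotype` column and one
#'   column per objective; attribute `objectives`.
#' @export
activity_table <- function(genotypes, activities, objectives = NULL,
                           se = NULL) {
  ids <- genotype_string(if (is.character(genotypes)) genotypes
                         else genotype_matrix(genotypes))
  activities <- as.matrix(activities)
  if (length(ids) != nrow(activities))
    stop("genotypes and activities disagree on the number of variants")
  if (anyDuplicated(ids))
    stop("duplicate genotypes in activity table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!is.finite(activities)))
    stop("activities must be finite")
  if (is.null(objectives)) {
    objectives <- colnames(activities)
    if (is.null(objectives))
      objectives <- if (ncol(activities) == 2) c("primary", "promiscuous")
                    else paste0("objective", seq_len(ncol(activities)))
  }
  colnames(activities) <- objectives
  out <- data.frame(genotype = ids, activities, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(se)) {
    se <- as.matrix(se)
    colnames(se) <- paste0(objectives, "_se")
    out <- cbind(out, se)
  }
  rownames(out) <- NULL
  structure(out, class = c("activity_table", "data.frame"),
            objectives = objectives)
}

#' Objectives recorded in an activity table
#' @param table An `activity_table`.
#' @return Character vector of objective names.
#' @export
table_objectives <- function(table) {
  obj <- attr(table, "objectives")
  if (is.null(obj))
    obj <- setdiff(names(table)[!grepl("_se$", names(table))], "genotype")
  obj
}

#' Read / write the activity-table TSV dialect
#'
#' Columns: `genotype` (bitstring, bit order = candidate rank order), one
#' column per objective (log10 activity), optional `<objective>_se`.
#'
#' @param path File path.
#' @param table An `activity_table` (for writing).
#' @return `read_activity_table()` returns an `activity_table`;
#'   `write_activity_table()` returns `path` invisibly.
#' @export
read_activity_table <- function(path) {
  df <- read.delim(path, colClasses = c(genotype = "character"),
                   check.names = FALSE)
  obj <- setdiff(names(df)[!grepl("_se$", names(df))], "genotype")
  se_cols <- paste0(obj, "_se")
  se <- if (all(se_cols %in% names(df))) df[se_cols] else NULL
  activity_table(df$genotype, df[obj], objectives = obj, se = se)
}

#' @rdname read_activity_table
#' @export
write_activity_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
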