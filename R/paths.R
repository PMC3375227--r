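#' Activity landscape over a complete genotype space
#'
#' Holds the activities of all 2^M genotypes (from a bootstrap
#' reconstruction replica, or a ground-truth generator) for path
#' exploration.
#'
#' @param genotypes Genotype matrix or bitstring vector covering the
#'   complete 2^M space.
#' @param activities Matrix of activities, rows matching `genotypes`.
#' @param objectives Objective names.
#' @return A `landscape` object with O(1) genotype lookup.
#' @export
landscape <- function(genotypes, activities, objectives = NULL) {
  g <- genotype_matrix(genotypes)
  activities <- as.matrix(activities)
  if (nrow(g) != nrow(activities))
    stop("genotypes and activities disagree on the number of variants")
  M <- ncol(g)
  if (nrow(g) != 2^M || anyDuplicated(rownames(g)))
    stop("landscape must cover all 2^", M, " genotypes exactly once")
  if (is.null(objectives)) {
    objectives <- colnames(activities)
    if (is.null(objectives))
      objectives <- if (ncol(activities) == 2) c("primary", "promiscuous")
                    else paste0("objective", seq_len(ncol(activities)))
  }
  colnames(activities) <- objectives
  rownames(activities) <- rownames(g)
  index <- setNames(seq_len(nrow(g)), rownames(g))
  structure(list(genotypes = g, activities = activities,
                 objectives = objectives, M = M, index = index),
            class = "landscape")
}

#' Landscape from one reconstruction replica
#'
#' @param ensemble A [bootstrap_reconstruct()] result covering the full
#'   library.
#' @param replica Replica index (default 1).
#' @return A [landscape()].
#' @export
landscape_from_ensemble <- function(ensemble, replica = 1) {
  landscape(ensemble$genotypes, ensemble$predictions[[replica]],
            objectives = ensemble$objectives)
}

landscape_activity <- function(ls, genotype, objective) {
  ls$activities[ls$index[[genotype]], objective]
}

#' Single-mutation neighbours of a genotype
#'
#' @param g Genotype bitstring or 0/1 vector.
#' @return Character vector of the M genotypes at Hamming distance 1.
#' @export
neighbors <- function(g) {
  v <- if (is.character(g)) as.integer(strsplit(g, "")[[1]]) else as.integer(g)
  vapply(seq_along(v), function(i) {
    w <- v
    w[i] <- 1L - w[i]
    paste(w, collapse = "")
  }, character(1))
}

#' Define a mutational-path rule
#'
#' A step from one variant to a single-mutation neighbour is allowed when
#' the improve objective changes strictly in the stated direction and the
#' constraint objective stays at or above the threshold.
#'
#' @param improve Objective that must change at every step.
#' @param direction `"increase"` or `"decrease"`.
#' @param constraint Objective that must stay above the floor; must differ
#'   from `improve`.
#' @param threshold Activity floor for the constraint objective
#'   (log-activity units, same scale as the landscape).
#' @return A `path_rule`.
#' @export
path_rule <- function(improve, direction = c("increase", "decrease"),
                      constraint, threshold) {
  direction <- match.arg(direction)
  if (improve == constraint)
    stop("improve and constraint objectives must differ")
  structure(list(improve = improve, direction = direction,
                 constraint = constraint, threshold = threshold),
            class = "path_rule")
}

step_allowed <- function(ls, rule, from, to) {
  a_from <- landscape_activity(ls, from, rule$improve)
  a_to <- landscape_activity(ls, to, rule$improve)
  improve_ok <- if (rule$direction == "increase") a_to > a_from
                else a_to < a_from
  improve_ok &&
    landscape_activity(ls, to, rule$constraint) >= rule$threshold
}

#' Constrained single-mutation random walks over a landscape
#'
#' The path-construction loop: from the current variant, test all
#' single-mutation neighbours against the rule; choose one of the passing
#' neighbours uniformly at random; repeat until no neighbour passes.
#' Strict improvement of the improve objective guarantees termination.
#'
#' @param ls A [landscape()].
#' @param start Starting genotype bitstring; must satisfy the constraint.
#' @param rule A [path_rule()].
#' @param seed Integer seed; path j uses seed `seed + j`.
#' @param n_paths Number of independent paths (default 10).
#' @return A `mutational_paths` list of paths; each path is a list with
#'   `genotypes` (visited, including start), `activities` (matrix), `seed`.
#' @export
random_walk <- function(ls, start, rule, seed = 1, n_paths = 10) {
  if (!start %in% names(ls$index))
    stop("start genotype not present in the landscape")
  if (landscape_activity(ls, start, rule$constraint) < rule$threshold)
    stop("start genotype violates the constraint: ",
         rule$constraint, " = ",
         landscape_activity(ls, start, rule$constraint), " < ",
         rule$threshold)
  paths <- lapply(seq_len(n_paths), function(j) {
    set.seed(seed + j)
    cur <- start
    visited <- cur
    repeat {
      nb <- neighbors(cur)
      pass <- nb[vapply(nb, function(x) step_allowed(ls, rule, cur, x),
                        logical(1))]
      if (length(pass) == 0) break
      cur <- if (length(pass) == 1) pass else sample(pass, 1)
      visited <- c(visited, cur)
    }
    acts <- ls$activities[ls$index[visited], , drop = FALSE]
    rownames(acts) <- visited
    list(genotypes = visited, activities = acts, seed = seed + j)
  })
  structure(list(paths = paths, rule = rule, start = start,
                 landscape = ls),
            class = "mutational_paths")
}

#' Summarise a set of mutational paths
#'
#' @param walks A [random_walk()] result.
#' @return List with `summary` (data.frame: one row per path with terminal
#'   genotype, terminal activities, path length, and whether any
#'   intermediate exceeds the start in both objectives) and
#'   `fraction_dual_enhanced` (fraction of paths with such an
#'   intermediate).
#' @export
path_report <- function(walks) {
  if (length(walks$paths) == 0) stop("need at least one path")
  ls <- walks$landscape
  start_act <- ls$activities[ls$index[[walks$start]], ]
  rows <- lapply(seq_along(walks$paths), function(j) {
    p <- walks$paths[[j]]
    n_steps <- length(p$genotypes) - 1L
    terminal <- p$genotypes[length(p$genotypes)]
    term_act <- p$activities[nrow(p$activities), ]
    inter <- p$activities[-1, , drop = FALSE]
    dual <- nrow(inter) > 0 &&
      any(apply(inter, 1, function(a) all(a > start_act)))
    out <- data.frame(path = j, terminal = terminal, length = n_steps,
                      dual_enhanced = dual, stringsAsFactors = FALSE)
    for (k in seq_along(ls$objectives))
      out[[paste0("terminal_", ls$objectives[k])]] <- term_act[k]
    out
  })
  summary <- do.call(rbind, rows)
  list(summary = summary,
       fraction_dual_enhanced = mean(summary$dual_enhanced))
}

#' Write paths and a landscape as TSV
#'
#' @param walks A [random_walk()] result.
#' @param ls A [landscape()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paths_tsv <- function(walks, path) {
  rows <- do.call(rbind, lapply(seq_along(walks$paths), function(j) {
    p <- walks$paths[[j]]
    data.frame(path = j, step = seq_along(p$genotypes) - 1L,
               genotype = p$genotypes, p$activities,
               check.names = FALSE, row.names = NULL)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_paths_tsv
#' @export
write_landscape_tsv <- function(ls, path) {
  df <- data.frame(genotype = rownames(ls$genotypes), ls$activities,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
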