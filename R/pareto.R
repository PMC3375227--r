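#' Construct a set of objective points
#'
#' A set of variants placed in objective space. The activity scale is an
#' explicit tag: Pareto extraction and screening operate on log
#' activities, while the trade-off-line and triangle analyses are defined
#' on linear activities; operations check the tag and refuse mismatches.
#'
#' @param coords Numeric matrix (rows = variants, columns = objectives).
#' @param ids Identifiers (genotype strings or labels); default rownames.
#' @param scale `"log"` or `"linear"`.
#' @return An `objective_points` object.
#' @export
objective_points <- function(coords, ids = NULL, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (is.null(ids)) ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
  rownames(coords) <- NULL
  structure(list(ids = ids, coords = coords, scale = scale),
            class = "objective_points")
}

#' @export
print.objective_points <- function(x, ...) {
  cat("objective_points:", nrow(x$coords), "points x", ncol(x$coords),
      "objectives (", x$scale, "scale )\n")
  invisible(x)
}

check_scale <- function(points, expected) {
  if (points$scale != expected)
    stop("this operation is defined on the ", expected,
         " activity scale but the points are tagged '", points$scale, "'")
}

#' Pareto dominance between two variants
#'
#' Variant `a` dominates variant `b` when it is strictly greater in every
#' objective simultaneously (all objectives are maximised). With
#' `strict = FALSE` the weak form is used: `a >= b` in all objectives and
#' `a > b` in at least one.
#'
#' @param a,b Numeric vectors of equal length (one value per objective).
#' @param strict Require strict improvement in every objective (default).
#' @return Logical.
#' @export
dominates <- function(a, b, strict = TRUE) {
  if (length(a) != length(b))
    stop("dimension mismatch: ", length(a), " vs ", length(b), " objectives")
  if (strict) all(a > b) else all(a >= b) && any(a > b)
}

# all-pairs O(n^2) reference used by tests as an independent oracle; also
# the fallback the sweep is checked against
pareto_front_bruteforce <- function(coords, strict = TRUE) {
  n <- nrow(coords)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(coords[j, ], coords[i, ], strict)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

#' Extract the Pareto front (non-dominated set)
#'
#' Sort-based sweep: points are ordered lexicographically by decreasing
#' objectives, so any dominator of a point precedes it; each point is then
#' tested only against the current front. Under strict dominance,
#' duplicated coordinates are all retained (no copy strictly dominates
#' another).
#'
#' @param points An [objective_points()] set, or a numeric matrix.
#' @param strict Dominance mode (see [dominates()]).
#' @return An `objective_points` subset of the non-dominated points, with
#'   attribute `index` giving their row indices in the input.
#' @export
pareto_front <- function(points, strict = TRUE) {
  mat_in <- !inherits(points, "objective_points")
  coords <- if (mat_in) as.matrix(points) else points$coords
  n <- nrow(coords)
  if (n == 0) stop("need at least one point")
  ord <- do.call(order, c(lapply(seq_len(ncol(coords)),
                                 function(j) -coords[, j])))
  front_idx <- integer(0)
  for (i in ord) {
    dominated <- FALSE
    for (j in front_idx) {
      if (dominates(coords[j, ], coords[i, ], strict)) {
        dominated <- TRUE
        break
      }
    }
    if (!dominated) front_idx <- c(front_idx, i)
  }
  front_idx <- sort(front_idx)
  if (mat_in) {
    out <- coords[front_idx, , drop = FALSE]
    attr(out, "index") <- front_idx
    return(out)
  }
  out <- objective_points(coords[front_idx, , drop = FALSE],
                          ids = points$ids[front_idx], scale = points$scale)
  attr(out, "index") <- front_idx
  out
}

#' Optimistic Pareto-set prediction from a reconstruction ensemble
#'
#' Pools the predicted activities of every genotype from every bootstrap
#' replica into one cloud and extracts its non-dominated set: a genotype
#' belongs to the optimistic prediction if any replica places it on the
#' pooled front. The optimism is deliberate - reconstruction uncertainty
#' widens the candidate set, and the experiment then arbitrates. With
#' `pool = FALSE` the per-replica fronts are extracted first and their
#' genotypes unioned instead.
#'
#' @param ensemble A [bootstrap_reconstruct()] result.
#' @param pool Pool replicas before front extraction (default TRUE).
#' @return Character vector of distinct candidate genotype bitstrings, in
#'   genotype order; attribute `front_points` holds the pooled-front
#'   `objective_points`.
#' @export
optimistic_pareto <- function(ensemble, pool = TRUE) {
  gs <- rownames(ensemble$genotypes)
  if (pool) {
    cloud <- do.call(rbind, ensemble$predictions)
    ids <- rep(gs, times = length(ensemble$predictions))
    pts <- objective_points(cloud, ids = ids, scale = "log")
    front <- pareto_front(pts)
    cand <- unique(front$ids)
  } else {
    fronts <- lapply(ensemble$predictions, function(P)
      pareto_front(objective_points(P, ids = gs, scale = "log")))
    cand <- unique(unlist(lapply(fronts, `[[`, "ids")))
    front <- NULL
  }
  cand <- unname(gs[gs %in% cand])
  attr(cand, "front_points") <- front
  cand
}

#' Emit the next screening-round request
#'
#' Given the measured variant set and the optimistic Pareto candidates,
#' returns the candidates that still lack measurements, as a request sheet
#' in the activity-table TSV dialect (activity columns `NA`). Merging the
#' measured results back and re-running reconstruction + prediction closes
#' the iterative screening loop.
#'
#' @param measured An [activity_table()] of measured variants.
#' @param candidates Character vector of candidate genotypes (from
#'   [optimistic_pareto()]).
#' @return Data frame with a `genotype` column and `NA` activity columns
#'   for the unmeasured candidates (zero rows when all are measured).
#' @export
screening_round <- function(measured, candidates) {
  objectives <- table_objectives(measured)
  todo <- setdiff(candidates, measured$genotype)
  req <- data.frame(genotype = todo, stringsAsFactors = FALSE)
  for (obj in objectives) req[[obj]] <- rep(NA_real_, length(todo))
  req
}

#' Merge measured screening results into the variant set
#'
#' @param measured Existing [activity_table()].
#' @param new_results An `activity_table` of newly measured variants;
#'   genotypes already present are ignored.
#' @return The expanded `activity_table`.
#' @export
merge_screening_results <- function(measured, new_results) {
  objectives <- table_objectives(measured)
  add <- new_results[!new_results$genotype %in% measured$genotype, ,
                     drop = FALSE]
  activity_table(c(measured$genotype, add$genotype),
                 rbind(as.matrix(as.data.frame(measured)[objectives]),
                       as.matrix(as.data.frame(add)[objectives])),
                 objectives = objectives)
}

#' Least-squares trade-off line through a two-objective Pareto front
#'
#' Fits promiscuous (objective 2) versus primary (objective 1) by ordinary
#' least squares through the front points, on the linear activity scale.
#'
#' @param front An `objective_points` set (typically a [pareto_front()])
#'   with 2 objectives, tagged `"linear"`.
#' @return A `tradeoff_line`: list with `slope`, `intercept`, `rss`,
#'   `n_points`, `degenerate` (TRUE when the primary coordinate is
#'   constant, in which case the fit is flagged and slope is `NA`).
#' @export
fit_tradeoff_line <- function(front) {
  check_scale(front, "linear")
  coords <- front$coords
  if (ncol(coords) != 2) stop("trade-off line is defined for 2 objectives")
  if (nrow(coords) < 2) stop("need at least 2 front points")
  x <- coords[, 1]; y <- coords[, 2]
  if (sd(x) < 1e-12) {
    warning("vertical degeneracy: primary activity constant across front")
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          rss = NA_real_, n_points = nrow(coords),
                          degenerate = TRUE), class = "tradeoff_line"))
  }
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 rss = sum(fit$residuals^2), n_points = nrow(coords),
                 degenerate = FALSE),
            class = "tradeoff_line")
}

#' Line connecting the maximum observed activities
#'
#' The reference line of the triangular-occupancy argument: it connects
#' the maximum primary activity (on the primary axis) with the maximum
#' promiscuous activity (on the promiscuous axis), i.e.
#' `x / max_x + y / max_y = 1`.
#'
#' @param points An `objective_points` set, 2 objectives, linear scale.
#' @return A `tradeoff_line` with the implied slope and intercept.
#' @export
max_connecting_line <- function(points) {
  check_scale(points, "linear")
  coords <- points$coords
  if (ncol(coords) != 2) stop("defined for 2 objectives")
  mx <- max(coords[, 1]); my <- max(coords[, 2])
  if (mx <= 0) stop("maximum primary activity must be positive")
  structure(list(slope = -my / mx, intercept = my, rss = NA_real_,
                 n_points = nrow(coords), degenerate = FALSE),
            class = "tradeoff_line")
}

#' Triangular-occupancy statistic
#'
#' Counts the points lying at or below a reference line in the linear
#' primary/promiscuous activity plane and reports the order-of-magnitude
#' probability `(1/2)^count` that this many of the points would fall on
#' one side of the line by chance if the two activities were uncorrelated.
#' The default reference is the [max_connecting_line()] of the point set.
#'
#' @param points An `objective_points` set, 2 objectives, linear scale.
#' @param line A `tradeoff_line`; default the max-connecting line.
#' @param tolerance Slack added to the line (default 0: "at or below").
#' @return A `triangle_statistic`: list with `ndp` (number of points),
#'   `count_below`, `null_probability`.
#' @export
triangle_statistic <- function(points, line = NULL, tolerance = 0) {
  check_scale(points, "linear")
  coords <- points$coords
  if (ncol(coords) != 2) stop("defined for 2 objectives")
  if (nrow(coords) == 0)
    return(structure(list(ndp = 0L, count_below = 0L, null_probability = 1),
                     class = "triangle_statistic"))
  if (is.null(line)) line <- max_connecting_line(points)
  below <- coords[, 2] <= line$intercept + line$slope * coords[, 1] +
    tolerance
  count <- sum(below)
  structure(list(ndp = nrow(coords), count_below = count,
                 null_probability = 0.5^count),
            class = "triangle_statistic")
}

#' @export
print.triangle_statistic <- function(x, ...) {
  cat("triangle statistic: ", x$count_below, "/", x$ndp,
      " points at or below the reference line; null probability ~ ",
      format(x$null_probability, digits = 3), "\n", sep = "")
  invisible(x)
}
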