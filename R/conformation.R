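#' Define a conformational-diversity model
#'
#' A protein is modelled as an equilibrium ensemble of conformations, each
#' carrying a pair of activity coefficients (primary, promiscuous) >= 0.
#' For a variant, per-conformation statistical weights w_i are drawn from
#' a flat distribution, mol fractions are X(a_i) = w_i / sum(w), and the
#' observable activities are the mol-fraction-weighted sums of the
#' coefficients (proportionality constants 1, which only rescales axes).
#'
#' @param coefficients Numeric matrix with one row per conformation and
#'   two columns (`primary`, `promiscuous`), all entries >= 0.
#' @param labels Conformation labels; default `a0, a1, ...`.
#' @return A `conformation_model`.
#' @export
conformation_model <- function(coefficients, labels = NULL) {
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) < 2) stop("need at least 2 conformations")
  if (ncol(coefficients) != 2)
    stop("coefficients must have two columns (primary, promiscuous)")
  if (any(!is.finite(coefficients)) || any(coefficients < 0))
    stop("activity coefficients must be finite and >= 0")
  if (is.null(labels)) labels <- paste0("a", seq_len(nrow(coefficients)) - 1)
  dimnames(coefficients) <- list(labels, c("primary", "promiscuous"))
  structure(list(coefficients = coefficients, labels = labels),
            class = "conformation_model")
}

#' Built-in conformational-diversity models
#'
#' The model variants used to contrast trade-off and no-trade-off
#' scenarios:
#' \describe{
#'   \item{fig8C}{3 conformations: a0 inactive (0,0); a1 carries only the
#'     promiscuous activity (0,1); a2 carries only the primary (1,0). The
#'     idealised trade-off model whose optimal situations (zero mol
#'     fraction of a0) lie on the trade-off line x + y = 1.}
#'   \item{fig9A}{as fig8C but the suboptimal conformation has a low,
#'     non-zero level of both activities.}
#'   \item{fig9B}{4 conformations, two suboptimal (0,0), plus one pure
#'     primary and one pure promiscuous conformation.}
#'   \item{fig9C}{as fig9B, but each optimal conformation also has a low
#'     level of the alternative activity.}
#'   \item{fig9D}{as fig9C, but the two optimal conformations carry a high
#'     level of both activities - the no-trade-off control, producing a
#'     positive inter-activity correlation and a very small Pareto set.}
#' }
#' "low" defaults to 0.1 and "high" to 1.0; the captions' contrasts are
#' qualitative and robust to these values.
#'
#' @param name One of `"fig8C"`, `"fig9A"`, `"fig9B"`, `"fig9C"`, `"fig9D"`.
#' @param low,high Coefficient values for "low" and "high" activity levels.
#' @return A [conformation_model()].
#' @export
builtin_model <- function(name = c("fig8C", "fig9A", "fig9B", "fig9C",
                                   "fig9D"),
                          low = 0.1, high = 1.0) {
  name <- match.arg(name)
  m <- switch(name,
    fig8C = rbind(a0 = c(0, 0), a1 = c(0, high), a2 = c(high, 0)),
    fig9A = rbind(a0 = c(low, low), a1 = c(0, high), a2 = c(high, 0)),
    fig9B = rbind(a0 = c(0, 0), a1 = c(0, 0),
                  a2 = c(high, 0), a3 = c(0, high)),
    fig9C = rbind(a0 = c(0, 0), a1 = c(0, 0),
                  a2 = c(high, low), a3 = c(low, high)),
    fig9D = rbind(a0 = c(0, 0), a1 = c(0, 0),
                  a2 = c(high, high), a3 = c(high, high)))
  conformation_model(m, labels = rownames(m))
}

#' Stochastic simulation of a variant set under conformational diversity
#'
#' For each variant, independent statistical weights w_i ~ U[0,1] are
#' drawn per conformation; mol fractions X(a_i) = w_i / sum(w) then sum to
#' one exactly, and the linear-scale activities are X %*% coefficients.
#' The all-weights-zero event (measure zero, but possible at floating
#' point) is guarded by a redraw.
#'
#' @param model A [conformation_model()].
#' @param n_variants Number of simulated variants.
#' @param seed Integer seed; identical seeds give identical point sets.
#' @return A `simulated_points` list: `mol_fractions` (n x conformations),
#'   `activities` (an [objective_points()] set, linear scale), `model`,
#'   `seed`.
#' @export
simulate_variants <- function(model, n_variants, seed = 1) {
  if (n_variants < 1) stop("n_variants must be >= 1")
  set.seed(seed)
  nc <- nrow(model$coefficients)
  w <- matrix(runif(n_variants * nc), nrow = n_variants, ncol = nc)
  zero <- rowSums(w) == 0
  while (any(zero)) {
    w[zero, ] <- runif(sum(zero) * nc)
    zero <- rowSums(w) == 0
  }
  X <- w / rowSums(w)
  colnames(X) <- model$labels
  act <- X %*% model$coefficients
  structure(list(mol_fractions = X,
                 activities = objective_points(act, scale = "linear"),
                 model = model, seed = seed),
            class = "simulated_points")
}

#' Summary statistics contrasting trade-off and no-trade-off patterns
#'
#' Pearson correlation between the two activities, Pareto-front size, and
#' the fraction of points at or below the max-connecting reference line.
#' Trade-off models produce negative correlations, sizeable linear-like
#' fronts and near-total sub-line occupancy; no-trade-off models produce
#' positive correlations and very small fronts.
#'
#' @param points An `objective_points` set (linear scale) or a
#'   `simulated_points` result.
#' @return List with `correlation`, `front_size`, `fraction_below`,
#'   `degenerate` (TRUE when an activity has zero variance, in which case
#'   the correlation is `NA`).
#' @export
pattern_summary <- function(points) {
  if (inherits(points, "simulated_points")) points <- points$activities
  coords <- points$coords
  if (nrow(coords) < 3) stop("need at least 3 points")
  degenerate <- any(apply(coords, 2, sd) < 1e-12)
  rho <- if (degenerate) NA_real_ else cor(coords[, 1], coords[, 2])
  front <- pareto_front(points)
  tri <- triangle_statistic(points)
  list(correlation = rho, front_size = nrow(front$coords),
       fraction_below = tri$count_below / tri$ndp, degenerate = degenerate)
}

#' Write simulated points as TSV
#' @param sim A `simulated_points` result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulated_points <- function(sim, path) {
  df <- data.frame(sim$mol_fractions, sim$activities$coords,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
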