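# NIPALS partial least squares (PLS2) on centered X / autoscaled Y.
# Returns weights W, X-loadings P, Y-loadings C and scores T for up to
# ncomp latent vectors; extraction stops early if X is exhausted.
nipals <- function(X, Y, ncomp, tol = 1e-12, maxit = 500) {
  n <- nrow(X); p <- ncol(X); K <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, K, ncomp); Tm <- matrix(0, n, ncomp)
  Xr <- X; Yr <- Y
  a <- 0
  for (comp in seq_len(ncomp)) {
    if (sum(Xr^2) < 1e-14 || sum(Yr^2) < 1e-14) break
    u <- Yr[, which.max(colSums(Yr^2)), drop = FALSE]
    t_old <- rep(Inf, n)
    w <- NULL; tt <- NULL; cc <- NULL
    for (it in seq_len(maxit)) {
      w_new <- crossprod(Xr, u)
      wn <- sqrt(sum(w_new^2))
      if (wn < 1e-14) break
      w <- w_new / wn
      tt <- Xr %*% w
      cc <- crossprod(Yr, tt) / sum(tt^2)
      if (sum(cc^2) < 1e-14) break
      u <- Yr %*% cc / sum(cc^2)
      if (sum((tt - t_old)^2) / max(sum(tt^2), 1e-300) < tol) break
      t_old <- tt
    }
    if (is.null(tt) || is.null(cc) || sum(tt^2) < 1e-14) break
    pp <- crossprod(Xr, tt) / sum(tt^2)
    Xr <- Xr - tt %*% t(pp)
    Yr <- Yr - tt %*% t(cc)
    a <- comp
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Tm[, a] <- tt
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       C = C[, seq_len(a), drop = FALSE], T = Tm[, seq_len(a), drop = FALSE],
       ncomp = a)
}

# regression coefficients (on the scaled/centered data) using the first l
# latent vectors: B_l = W_l (P_l' W_l)^{-1} C_l'
nipals_coef <- function(fit, l) {
  W <- fit$W[, seq_len(l), drop = FALSE]
  P <- fit$P[, seq_len(l), drop = FALSE]
  C <- fit$C[, seq_len(l), drop = FALSE]
  W %*% solve(crossprod(P, W), t(C))
}

#' Fit the pairwise-coupling activity model by partial least squares
#'
#' Fits `A^k = background^k + sum_i delta_i p_i^k + sum_{i<j} delta_ij
#' p_ij^k` jointly for all objectives using PLS with the NIPALS algorithm.
#' Responses (log activities) are auto-scaled (mean-subtracted, divided by
#' the standard deviation); predictors are mean-centered but not
#' variance-scaled, since they are binary indicators. The number of latent
#' variables is chosen to minimise the mean leave-one-out cross-validation
#' squared error (averaged over objectives, on the auto-scaled response
#' scale); rows carrying the same genotype (as arise from bootstrap
#' resampling) are always left out together. Coefficients are
#' back-transformed to the original log-activity scale, with the implicit
#' intercept of the centered model reported explicitly.
#'
#' @param table An [activity_table()] (duplicated genotypes allowed when
#'   `allow_duplicates = TRUE`, as for bootstrap replicas).
#' @param max_lv Maximum latent variables to consider; default
#'   `min(n - 2, 15)` where n is the number of distinct genotypes.
#' @param cv Cross-validation scheme; only `"loo"` (leave-one-genotype-out).
#' @param include_pairs Use the pairwise design (default) or the additive
#'   main-effects design.
#' @param joint Fit all objectives jointly in one PLS2 model (default) or
#'   one PLS1 model per objective.
#' @param n_lv Fix the number of latent variables, skipping CV.
#' @param allow_duplicates Accept duplicated genotype rows.
#' @return A `pls_model`: list with `coefficients` (predictors x
#'   objectives, original scale), `intercept`, `n_lv`, `cv_error` (mean
#'   scaled PRESS/n per candidate L), scaling parameters, and the design
#'   settings needed by [pls_predict()].
#' @export
pls_fit <- function(table, max_lv = NULL, cv = "loo", include_pairs = TRUE,
                    joint = TRUE, n_lv = NULL, allow_duplicates = FALSE) {
  cv <- match.arg(cv, "loo")
  objectives <- table_objectives(table)
  g <- genotype_matrix(table$genotype)
  Y <- as.matrix(as.data.frame(table)[objectives])
  if (anyDuplicated(rownames(g)) && !allow_duplicates)
    stop("duplicate genotypes; pass allow_duplicates = TRUE for replicas")
  n_distinct <- length(unique(rownames(g)))
  if (n_distinct < 4)
    stop("insufficient data: need at least 4 distinct genotypes, got ",
         n_distinct)
  y_sd <- apply(Y, 2, sd)
  if (any(y_sd < 1e-12))
    stop("degenerate scaling: objective(s) ",
         paste(objectives[y_sd < 1e-12], collapse = ", "),
         " have zero variance")
  X <- design_matrix(g, include_pairs = include_pairs)
  if (is.null(max_lv)) max_lv <- min(n_distinct - 2L, 15L)
  max_lv <- min(max_lv, ncol(X), nrow(X) - 1L)

  y_mean <- colMeans(Y)
  Ys <- sweep(sweep(Y, 2, y_mean), 2, y_sd, "/")
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)

  fit_block <- function(Xc, Ys, ncomp) {
    if (joint || ncol(Ys) == 1L) {
      nipals(Xc, Ys, ncomp)
    } else {
      lapply(seq_len(ncol(Ys)), function(k)
        nipals(Xc, Ys[, k, drop = FALSE], ncomp))
    }
  }
  coef_block <- function(fit, l, K) {
    if (joint || K == 1L) {
      nipals_coef(fit, min(l, fit$ncomp))
    } else {
      do.call(cbind, lapply(fit, function(f)
        nipals_coef(f, min(l, f$ncomp))))
    }
  }

  cv_error <- NULL
  if (is.null(n_lv)) {
    groups <- rownames(g)
    press <- matrix(0, nrow = max_lv, ncol = ncol(Ys))
    for (gid in unique(groups)) {
      hold <- groups == gid
      Xt <- X[!hold, , drop = FALSE]; Yt <- Y[!hold, , drop = FALSE]
      ym <- colMeans(Yt); ysd <- apply(Yt, 2, sd)
      if (any(ysd < 1e-12)) next
      xm <- colMeans(Xt)
      Yts <- sweep(sweep(Yt, 2, ym), 2, ysd, "/")
      Xts <- sweep(Xt, 2, xm)
      lmax <- min(max_lv, nrow(Xts) - 1L)
      f <- fit_block(Xts, Yts, lmax)
      Xh <- sweep(X[hold, , drop = FALSE], 2, xm)
      Yhs <- sweep(sweep(Y[hold, , drop = FALSE], 2, ym), 2, ysd, "/")
      for (l in seq_len(max_lv)) {
        B <- coef_block(f, l, ncol(Ys))
        press[l, ] <- press[l, ] + colSums((Yhs - Xh %*% B)^2)
      }
    }
    cv_error <- rowMeans(press) / nrow(X)
    n_lv <- which.min(cv_error)
  }

  final <- fit_block(Xc, Ys, n_lv)
  Bs <- coef_block(final, n_lv, ncol(Ys))
  # back to the original log-activity scale
  B <- sweep(Bs, 2, y_sd, "*")
  intercept <- y_mean - as.numeric(crossprod(B, x_mean))
  dimnames(B) <- list(colnames(X), objectives)
  names(intercept) <- objectives
  fitted <- sweep(X %*% B, 2, intercept, "+")
  structure(list(coefficients = B, intercept = intercept,
                 n_lv = n_lv, cv_error = cv_error,
                 M = ncol(g), objectives = objectives,
                 include_pairs = include_pairs, joint = joint,
                 x_mean = x_mean, y_mean = y_mean, y_sd = y_sd,
                 fitted = fitted, n_obs = nrow(X),
                 genotypes = rownames(g)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS activity model: M =", x$M, "mutations,",
      length(x$objectives), "objectives (",
      paste(x$objectives, collapse = ", "), ")\n")
  cat("  design:", nrow(x$coefficients), "predictors",
      if (x$include_pairs) "(main + pairwise)" else "(main effects only)",
      "\n  latent variables:", x$n_lv,
      "| training rows:", x$n_obs, "\n")
  invisible(x)
}

#' Extract main-effect and coupling coefficients
#'
#' @param model A `pls_model`.
#' @return List with `main` (M x K matrix of p_i^k) and `pairs`
#'   (M(M-1)/2 x K matrix of p_ij^k, NULL for additive fits).
#' @export
pls_coefficients <- function(model) {
  B <- model$coefficients
  main <- B[seq_len(model$M), , drop = FALSE]
  pairs <- if (model$include_pairs && model$M >= 2)
    B[-seq_len(model$M), , drop = FALSE] else NULL
  list(main = main, pairs = pairs, intercept = model$intercept)
}

#' Predict activities for arbitrary genotypes
#'
#' Predictions on the original log-activity scale; training genotypes
#' reproduce their fitted values.
#'
#' @param model A `pls_model`.
#' @param genotypes Genotype matrix or bitstring vector of width `model$M`.
#' @return Numeric matrix, one row per genotype, one column per objective.
#' @export
pls_predict <- function(model, genotypes) {
  g <- genotype_matrix(genotypes)
  if (ncol(g) != model$M)
    stop("genotype length ", ncol(g), " does not match model M = ", model$M)
  X <- design_matrix(g, include_pairs = model$include_pairs)
  out <- sweep(X %*% model$coefficients, 2, model$intercept, "+")
  rownames(out) <- rownames(g)
  out
}

#' Bootstrap reconstruction of the full combinatorial library
#'
#' Draws `B` bootstrap replicas of the measured variant set (rows resampled
#' with replacement), fits the PLS model to each replica (the number of
#' latent variables is re-selected per replica by leave-one-genotype-out
#' CV) and predicts the complete library per replica. The resulting
#' ensemble carries the reconstruction uncertainty used by the optimistic
#' Pareto prediction.
#'
#' @param table An [activity_table()] of measured variants.
#' @param B Number of bootstrap replicas (default 20).
#' @param seed Integer seed; replica r uses seed `seed + r`.
#' @param genotypes Genotypes to predict; default the full 2^M enumeration.
#' @param max_retries Redraws allowed when a replica is degenerate for
#'   fitting (too few distinct genotypes or a zero-variance objective).
#' @param ... Passed to [pls_fit()].
#' @return A `reconstruction_ensemble`: list with `predictions` (list of B
#'   genotype x objective matrices), `genotypes`, `objectives`, `n_lv`
#'   (per replica), `seeds`, and the training table.
#' @export
bootstrap_reconstruct <- function(table, B = 20, seed = 1, genotypes = NULL,
                                  max_retries = 20, ...) {
  if (B < 1) stop("B must be >= 1")
  objectives <- table_objectives(table)
  M <- nchar(table$genotype[1])
  if (is.null(genotypes)) genotypes <- enumerate_library(M)
  g_all <- genotype_matrix(genotypes)
  n <- nrow(table)
  preds <- vector("list", B)
  n_lv <- integer(B)
  seeds <- seed + seq_len(B)
  for (r in seq_len(B)) {
    set.seed(seeds[r])
    fit <- NULL
    for (try in seq_len(max_retries)) {
      idx <- sample.int(n, n, replace = TRUE)
      rep_tab <- structure(as.data.frame(table)[idx, , drop = FALSE],
                           class = c("activity_table", "data.frame"),
                           objectives = objectives)
      fit <- tryCatch(pls_fit(rep_tab, allow_duplicates = TRUE, ...),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop("replica ", r, " remained degenerate after ", max_retries,
           " redraws")
    preds[[r]] <- pls_predict(fit, g_all)
    n_lv[r] <- fit$n_lv
  }
  structure(list(predictions = preds, genotypes = g_all,
                 objectives = objectives, n_lv = n_lv, seeds = seeds,
                 table = table, B = B),
            class = "reconstruction_ensemble")
}

#' @export
print.reconstruction_ensemble <- function(x, ...) {
  cat("Bootstrap reconstruction ensemble: B =", x$B, "replicas x",
      nrow(x$genotypes), "genotypes x", length(x$objectives),
      "objectives\n  latent variables per replica:",
      paste(x$n_lv, collapse = " "), "\n")
  invisible(x)
}

#' Serialize a PLS model to JSON
#'
#' @param model A `pls_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path) {
  obj <- list(M = model$M, objectives = model$objectives,
              include_pairs = model$include_pairs, joint = model$joint,
              n_lv = model$n_lv, cv_error = model$cv_error,
              intercept = as.list(model$intercept),
              coefficients = as.data.frame(model$coefficients),
              predictor = rownames(model$coefficients),
              y_mean = as.list(model$y_mean), y_sd = as.list(model$y_sd))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
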