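# Principal-components factor analysis of the 12 weekly category counts,
# with varimax rotation and Kaiser retention. Used to compare the factor
# structure induced by different coding methods (automated vs manual).

#' Varimax rotation (Kaiser's pairwise algorithm)
#'
#' Orthogonally rotates a loading matrix to maximise the varimax criterion
#' (the summed variance of squared loadings per factor), using Kaiser's
#' classical planar-rotation sweeps with row (communality) normalisation.
#' Row communalities are preserved by construction.
#'
#' @param L loadings matrix (variables x factors), at least one column.
#' @param tol convergence tolerance on the rotation angle (radians);
#'   default 1e-6.
#' @param max_iter maximum number of full sweeps over factor pairs.
#' @param normalize apply Kaiser row normalisation before rotating.
#' @return a list with `loadings` (rotated matrix), `rotmat` (orthogonal
#'   rotation matrix, `loadings = L %*% rotmat`), `converged` (logical) and
#'   `iterations` (sweeps used).
#' @export
varimax_rotate <- function(L, tol = 1e-6, max_iter = 100, normalize = TRUE) {
  L <- as.matrix(L)
  p <- nrow(L)
  k <- ncol(L)
  if (k < 2) {
    return(list(loadings = L, rotmat = diag(k), converged = TRUE,
                iterations = 0L))
  }
  h <- if (normalize) sqrt(rowSums(L^2)) else rep(1, p)
  h[h == 0] <- 1
  A <- L / h
  R <- diag(k)
  converged <- FALSE
  it <- 0L
  for (sweep in seq_len(max_iter)) {
    it <- sweep
    max_angle <- 0
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        x <- A[, i]
        y <- A[, j]
        u <- x^2 - y^2
        v <- 2 * x * y
        Au <- sum(u)
        Bv <- sum(v)
        Cc <- sum(u^2 - v^2)
        Dd <- sum(2 * u * v)
        num <- Dd - 2 * Au * Bv / p
        den <- Cc - (Au^2 - Bv^2) / p
        theta <- atan2(num, den) / 4
        if (abs(theta) > .Machine$double.eps) {
          co <- cos(theta)
          si <- sin(theta)
          A[, i] <- co * x + si * y
          A[, j] <- -si * x + co * y
          G <- diag(k)
          G[i, i] <- co; G[j, j] <- co
          G[j, i] <- si; G[i, j] <- -si
          R <- R %*% G
        }
        max_angle <- max(max_angle, abs(theta))
      }
    }
    if (max_angle < tol) {
      converged <- TRUE
      break
    }
  }
  loadings <- (A * h)
  dimnames(loadings) <- dimnames(L)
  list(loadings = loadings, rotmat = R, converged = converged,
       iterations = it)
}

#' Varimax criterion value
#'
#' The raw varimax objective: sum over factors of the variance of squared
#' loadings. Useful for checking that rotation did not decrease it.
#'
#' @param L loadings matrix.
#' @return numeric scalar.
#' @export
varimax_criterion <- function(L) {
  L <- as.matrix(L)
  sum(apply(L^2, 2, function(s) mean(s^2) - mean(s)^2))
}

flip_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    m <- which.max(abs(L[, j]))
    if (L[m, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Principal-components factor analysis with varimax rotation
#'
#' Fits the factor model used to summarise the 12 weekly interaction counts:
#' Pearson correlation matrix of the columns, eigendecomposition, Kaiser
#' retention (eigenvalue strictly greater than 1), unrotated loadings
#' `eigenvector * sqrt(eigenvalue)`, then varimax rotation of the retained
#' block. Eigenvalues and variance proportions are reported pre-rotation;
#' each rotated column's sign is flipped so its largest-magnitude loading is
#' positive.
#'
#' @param X numeric matrix or data.frame of non-negative counts; rows are
#'   observation units (participant-weeks by default elsewhere), columns the
#'   12 categories in code order. At least 3 rows; no constant column.
#' @param tol,max_iter passed to [varimax_rotate()].
#' @return an object of class `sva_factors`: list with `eigenvalues` (all,
#'   descending), `n_retained`, `loadings` (variables x retained, rotated),
#'   `proportion_per_factor` (percent, eigenvalue/p*100 for retained
#'   factors), `total_proportion`, `total_eigenvalue`, `converged`,
#'   `iterations`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rpois(600, 3), ncol = 12,
#'             dimnames = list(NULL, category_names()))
#' fit_factor_solution(X)
fit_factor_solution <- function(X, tol = 1e-6, max_iter = 100) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 observations to fit")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- as.character(seq_len(ncol(X)))
    stop("constant column(s): ", paste(nm[sds == 0], collapse = ", "))
  }
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  ev <- e$values
  p <- ncol(X)
  retained <- which(ev > 1)
  n_retained <- length(retained)
  if (n_retained > 0) {
    L <- e$vectors[, retained, drop = FALSE] %*%
      diag(sqrt(ev[retained]), n_retained)
    rownames(L) <- colnames(X)
    colnames(L) <- paste0("F", seq_len(n_retained))
    rot <- varimax_rotate(L, tol = tol, max_iter = max_iter)
    loadings <- flip_signs(rot$loadings)
    converged <- rot$converged
    iterations <- rot$iterations
  } else {
    loadings <- matrix(numeric(0), nrow = p, ncol = 0,
                       dimnames = list(colnames(X), NULL))
    converged <- TRUE
    iterations <- 0L
  }
  structure(
    list(
      eigenvalues = ev,
      n_retained = n_retained,
      loadings = loadings,
      proportion_per_factor = 100 * ev[retained] / p,
      total_proportion = 100 * sum(ev[retained]) / p,
      total_eigenvalue = sum(ev[retained]),
      converged = converged,
      iterations = iterations
    ),
    class = "sva_factors"
  )
}

#' @export
print.sva_factors <- function(x, digits = 3, ...) {
  cat("Principal-components factor solution\n")
  cat("  retained factors (eigenvalue > 1):", x$n_retained, "\n")
  cat("  eigenvalues:", paste(round(x$eigenvalues, 2), collapse = ", "),
      "\n")
  if (x$n_retained > 0) {
    cat("  variance per factor (%):",
        paste(round(x$proportion_per_factor, 2), collapse = ", "), "\n")
    cat(sprintf("  total: eigenvalue %.2f, variance %.2f%%\n",
                x$total_eigenvalue, x$total_proportion))
    cat("  rotated loadings:\n")
    print(round(x$loadings, digits))
  }
  invisible(x)
}

#' Tucker congruence coefficient
#'
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))` between two loading columns.
#'
#' @param x,y numeric vectors of equal length.
#' @return numeric in [-1, 1].
#' @export
tucker_congruence <- function(x, y) {
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Compare two factor solutions
#'
#' Reports whether the retained-factor counts differ; when they are equal,
#' greedily matches factor pairs on absolute Tucker congruence (largest
#' first) and reports the matched coefficients. A solution identical up to
#' column permutation and sign flips matches itself with congruence 1.
#'
#' @param A,B `sva_factors` objects over the same variables.
#' @return list with `structure_differs` (logical), `delta_n_factors`,
#'   and (when counts match) `matching` — a data.frame of
#'   `factor_a`, `factor_b`, `congruence` (signed, for the matched pair).
#' @export
compare_solutions <- function(A, B) {
  stopifnot(inherits(A, "sva_factors"), inherits(B, "sva_factors"))
  if (nrow(A$loadings) != nrow(B$loadings)) {
    stop("solutions cover different variable sets")
  }
  delta <- abs(A$n_retained - B$n_retained)
  if (A$n_retained != B$n_retained) {
    return(list(structure_differs = TRUE, delta_n_factors = delta,
                matching = NULL))
  }
  k <- A$n_retained
  phi <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      phi[i, j] <- tucker_congruence(A$loadings[, i], B$loadings[, j])
    }
  }
  avail_a <- seq_len(k)
  avail_b <- seq_len(k)
  rows <- list()
  while (length(avail_a) > 0) {
    sub <- abs(phi[avail_a, avail_b, drop = FALSE])
    pos <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    ia <- avail_a[pos[1]]
    ib <- avail_b[pos[2]]
    rows[[length(rows) + 1]] <- data.frame(
      factor_a = ia, factor_b = ib, congruence = phi[ia, ib]
    )
    avail_a <- setdiff(avail_a, ia)
    avail_b <- setdiff(avail_b, ib)
  }
  matching <- do.call(rbind, rows)
  list(structure_differs = FALSE, delta_n_factors = 0L,
       matching = matching[order(matching$factor_a), ])
}

#' Read a counts matrix from CSV
#'
#' Rows are observation units (e.g. participant-weeks), columns the 12
#' category names. A leading non-numeric id column, and `week`/`TOTAL`
#' bookkeeping from crosstab exports, are ignored.
#'
#' @param path CSV path.
#' @return numeric matrix with the 12 category columns in code order.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(category_names(), names(df))
  if (length(missing) > 0) {
    stop("counts file is missing category column(s): ",
         paste(missing, collapse = ", "))
  }
  if ("week" %in% names(df)) df <- df[df$week != "TOTAL", , drop = FALSE]
  as.matrix(df[, category_names()])
}

#' Build a participant-week counts matrix from episodes
#'
#' The observation unit of the factor analysis: one row per
#' participant-week, one column per category, cell = episode count. Weeks
#' with no episodes inside a participant's observed span are zero-filled.
#'
#' @param episodes an episode data.frame.
#' @param per_participant if `TRUE`, collapse to one row per participant
#'   (total counts) instead.
#' @return integer matrix with the 12 category columns.
#' @export
episode_counts_matrix <- function(episodes, per_participant = FALSE) {
  ids <- unique(episodes$participant_id)
  rows <- list()
  for (id in ids) {
    ct <- build_crosstab(episodes, scope = id)
    if (per_participant) {
      rows[[length(rows) + 1]] <- matrix(
        ct$totals, nrow = 1, dimnames = list(id, names(ct$totals))
      )
    } else {
      m <- ct$counts
      rownames(m) <- paste0(id, ".w", ct$weeks)
      rows[[length(rows) + 1]] <- m
    }
  }
  out <- do.call(rbind, rows)
  storage.mode(out) <- "integer"
  out
}
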