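# Data-driven dietary patterns: correlation-matrix PCA with sampling-adequacy
# diagnostics (KMO / per-variable MSA / Bartlett sphericity), eigenvalue > 1
# retention, varimax rotation, regression factor scores and loading-based
# food-group attribution.

#' Sampling adequacy of a correlation matrix
#'
#' Kaiser-Meyer-Olkin measure and per-variable measures of sampling adequacy
#' from the anti-image (partial) correlations, plus Bartlett's test of
#' sphericity.
#'
#' @param R Correlation matrix (symmetric, invertible).
#' @param n Number of observations behind `R`.
#' @return List with `kmo`, `msa` (named per variable), and `bartlett`
#'   (`chisq`, `df`, `p_value`).
#' @export
factor_adequacy <- function(R, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (p < 2L) stop("need at least 2 variables")
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix must be symmetric")
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; prune collinear variables ",
         "before assessing adequacy")
  })
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * outer(d, d)       # partial correlations
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0

  r2 <- R0^2
  q2 <- Q^2
  kmo <- sum(r2) / (sum(r2) + sum(q2))
  msa <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(msa) <- colnames(R)

  detR <- det(R)
  chisq <- max(0, -(n - 1 - (2 * p + 5) / 6) * log(detR))
  df <- p * (p - 1) / 2
  list(kmo = kmo, msa = msa,
       bartlett = list(chisq = chisq, df = df,
                       p_value = stats::pchisq(chisq, df, lower.tail = FALSE)))
}

# flip factor signs so each factor's largest-|loading| variable loads
# positively (sign indeterminacy convention)
fix_loading_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Extract dietary patterns by correlation-matrix PCA
#'
#' Standardizes columns, eigendecomposes the correlation matrix, retains
#' components with eigenvalue above `eigen_cut` (scree data are kept for
#' inspection), varimax-rotates the retained loadings, computes regression
#' factor scores and attributes each food group to at most one factor by its
#' maximum absolute rotated loading.
#'
#' Zero-variance columns are dropped with a message; variables with a
#' measure of sampling adequacy below `msa_cut` are removed iteratively
#' (worst first) before extraction.
#'
#' @param data Numeric data frame or matrix, participants x food-group
#'   grams.
#' @param eigen_cut Retention threshold on eigenvalues (default 1.0).
#' @param msa_cut Minimum per-variable MSA; `NULL` disables pruning.
#' @param loading_cut Attribution threshold on absolute rotated loadings
#'   (strict inequality, default 0.2).
#' @param rotate Apply varimax (Kaiser-normalized) when two or more factors
#'   are retained?
#' @return Object of class `pattern_model`: `variables`, `n`, `kmo`, `msa`,
#'   `bartlett`, `eigenvalues`, `retained_k`, `loadings` (rotated),
#'   `pct_variance`, `cumulative_pct_variance`, `scores`, `attribution`,
#'   `dropped` (pruning log), `scree` (eigenvalue table).
#' @export
extract_patterns <- function(data, eigen_cut = 1, msa_cut = 0.5,
                             loading_cut = 0.2, rotate = TRUE) {
  X <- as.matrix(data)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in pattern input")
  n <- nrow(X)

  dropped <- character()
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    zv <- colnames(X)[sds == 0]
    message("dropping zero-variance columns: ", paste(zv, collapse = ", "))
    dropped <- c(dropped, paste0(zv, " (zero variance)"))
    X <- X[, sds > 0, drop = FALSE]
  }

  # iterative MSA pruning, worst variable first
  if (!is.null(msa_cut)) {
    repeat {
      if (ncol(X) <= 2L) break
      adq <- factor_adequacy(stats::cor(X), n)
      if (min(adq$msa) >= msa_cut) break
      worst <- names(which.min(adq$msa))
      message("pruning '", worst, "' (MSA = ",
              format(min(adq$msa), digits = 3), " < ", msa_cut, ")")
      dropped <- c(dropped, paste0(worst, " (MSA below ", msa_cut, ")"))
      X <- X[, colnames(X) != worst, drop = FALSE]
    }
  }
  p <- ncol(X)
  if (p < 2L) stop("fewer than 2 variables remain after pruning")
  if (n <= p) warning("fewer observations than variables; loadings unstable")

  R <- stats::cor(X)
  adq <- factor_adequacy(R, n)
  eig <- eigen(R, symmetric = TRUE)
  eigenvalues <- eig$values
  k <- sum(eigenvalues > eigen_cut)
  k <- max(k, 1L)

  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eigenvalues[seq_len(k)]), k)
  rownames(L) <- colnames(X)
  if (rotate && k >= 2L) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- L %*% rot$rotmat
  }
  # order rotated factors by explained variance, then fix signs
  ss <- colSums(L^2)
  L <- L[, order(ss, decreasing = TRUE), drop = FALSE]
  L <- fix_loading_signs(L)
  colnames(L) <- paste0("F", seq_len(k))
  pct <- colSums(L^2) / p * 100

  Z <- scale(X)
  scores <- Z %*% solve(R) %*% L
  colnames(scores) <- colnames(L)
  rownames(scores) <- rownames(data)

  structure(
    list(variables = colnames(X), n = n,
         kmo = adq$kmo, msa = adq$msa, bartlett = adq$bartlett,
         eigenvalues = eigenvalues, retained_k = k,
         loadings = L, pct_variance = pct,
         cumulative_pct_variance = cumsum(pct),
         scores = scores,
         attribution = attribute_loadings(L, loading_cut = loading_cut),
         dropped = dropped,
         scree = data.frame(component = seq_along(eigenvalues),
                            eigenvalue = eigenvalues)),
    class = "pattern_model")
}

#' Regression (Thomson) factor scores for new data
#'
#' `scores = Z %*% solve(R) %*% L` with `Z` the data standardized to the
#' model's variables.
#'
#' @param model A `pattern_model`.
#' @param data Participants x variables matrix with at least the model's
#'   variables, in any column order.
#' @return Participants x factors score matrix.
#' @export
pattern_scores <- function(model, data) {
  X <- as.matrix(data)
  if (!all(model$variables %in% colnames(X))) {
    stop("data lack model variables: ",
         paste(setdiff(model$variables, colnames(X)), collapse = ", "))
  }
  X <- X[, model$variables, drop = FALSE]
  Z <- scale(X)
  R <- stats::cor(X)
  S <- Z %*% solve(R) %*% model$loadings
  colnames(S) <- colnames(model$loadings)
  S
}

#' Attribute food groups to factors by maximum absolute loading
#'
#' Each food group is assigned to the factor where its absolute rotated
#' loading is largest, provided that loading strictly exceeds `loading_cut`;
#' otherwise it stays unassigned.  Ties go to the lowest factor index (and
#' are messaged).  Signed loadings are reported so inverse contributions
#' stay visible.
#'
#' @param loadings Variables x factors rotated loading matrix.
#' @param loading_cut Threshold on `abs(loading)` (strict).
#' @return Data frame with `variable`, `factor` (NA if unassigned) and
#'   `loading` (signed).
#' @export
attribute_loadings <- function(loadings, loading_cut = 0.2) {
  L <- as.matrix(loadings)
  vars <- rownames(L)
  if (is.null(vars)) vars <- paste0("V", seq_len(nrow(L)))
  rows <- lapply(seq_len(nrow(L)), function(i) {
    a <- abs(L[i, ])
    best <- which(a == max(a))
    if (length(best) > 1L) {
      message("tie in |loading| for '", vars[i],
              "'; assigned to lowest factor index")
    }
    j <- best[1]
    if (a[j] > loading_cut) {
      data.frame(variable = vars[i], factor = j, loading = L[i, j],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variable = vars[i], factor = NA_integer_,
                 loading = L[i, j], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Congruence coefficients between two loading matrices
#'
#' Tucker's congruence (cosine similarity) between each pair of factors,
#' plus the best sign-invariant one-to-one matching of columns of `target`
#' to columns of `candidate` (exhaustive over permutations for k <= 7).
#'
#' @param target,candidate Loading matrices with the same rows.
#' @return List with `matrix` (|congruence|, target x candidate),
#'   `matching` (candidate column matched to each target column) and
#'   `matched` (the matched |congruence| per target factor).
#' @export
factor_congruence <- function(target, candidate) {
  A <- as.matrix(target)
  B <- as.matrix(candidate)
  stopifnot(nrow(A) == nrow(B))
  norm <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")
  C <- abs(t(norm(A)) %*% norm(B))
  ka <- ncol(A); kb <- ncol(B)
  if (ka > kb) stop("candidate has fewer factors than target")
  if (ka <= 7L) {
    perms <- permutations_of(seq_len(kb), ka)
    best <- NULL; best_sum <- -Inf
    for (p in perms) {
      s <- sum(C[cbind(seq_len(ka), p)])
      if (s > best_sum) { best_sum <- s; best <- p }
    }
  } else {
    # greedy fallback for large k
    best <- integer(ka)
    free <- seq_len(kb)
    for (i in seq_len(ka)) {
      j <- free[which.max(C[i, free])]
      best[i] <- j
      free <- setdiff(free, j)
    }
  }
  list(matrix = C, matching = best,
       matched = C[cbind(seq_len(ka), best)])
}

# all ordered selections of length k from v (small k only)
permutations_of <- function(v, k) {
  if (k == 0L) return(list(integer()))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i], k - 1L)) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' @export
print.pattern_model <- function(x, ...) {
  cat("<pattern_model>", length(x$variables), "variables, n =", x$n, "\n")
  cat(" KMO =", format(x$kmo, digits = 3),
      "; Bartlett chi^2 =", format(x$bartlett$chisq, digits = 4),
      "(df", x$bartlett$df, ", p =",
      format(x$bartlett$p_value, digits = 3), ")\n")
  cat(" retained", x$retained_k, "factors;",
      format(sum(x$pct_variance), digits = 4), "% variance explained\n")
  invisible(x)
}
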