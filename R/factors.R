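#' Filter counts by total-count thresholds
#'
#' One pass, gene-first: genes with total count below `min_counts_gene` are
#' removed, then spots whose total (over the surviving genes) falls below
#' `min_counts_spot` are removed. A spot can therefore be dropped because
#' gene removal took its total below threshold; the order dependence is
#' deliberate and documented.
#'
#' @param counts genes x spots count matrix (or an [st_dataset()], in which
#'   case spots and images are filtered consistently).
#' @param min_counts_gene,min_counts_spot non-negative thresholds.
#' @return The filtered matrix (or dataset).
#' @export
filter_counts <- function(counts, min_counts_gene = 0, min_counts_spot = 0) {
  stopifnot(min_counts_gene >= 0, min_counts_spot >= 0)
  if (inherits(counts, "st_dataset")) {
    ds <- counts
    m <- filter_counts(ds$counts, min_counts_gene, min_counts_spot)
    keep_spots <- match(colnames(m), colnames(ds$counts))
    if (is.null(colnames(ds$counts))) {
      keep_spots <- attr(m, "kept_spots")
    }
    return(st_dataset(m, ds$spots[keep_spots, ], ds$images, ds$spacing_um))
  }
  gene_tot <- Matrix::rowSums(counts)
  keep_g <- which(gene_tot >= min_counts_gene)
  out <- counts[keep_g, , drop = FALSE]
  spot_tot <- Matrix::colSums(out)
  keep_s <- unname(which(spot_tot >= min_counts_spot))
  if (length(keep_s) == 0) stop("all spots removed by filtering")
  out <- out[, keep_s, drop = FALSE]
  attr(out, "kept_spots") <- keep_s
  out
}

#' Negative-binomial Pearson residuals
#'
#' Analytic residuals under a multinomial-rate null: the expected count is
#' `mu[g, s] = gene_total * spot_total / grand_total` and the residual is
#' `(x - mu) / sqrt(mu + mu^2 / theta)` for a negative-binomial model with a
#' single global dispersion `theta`. Residuals are clipped to
#' `+/- sqrt(n_spots)` by default, the usual guard against single-spot
#' outliers dominating downstream factorization.
#'
#' @param counts genes x spots count matrix, no all-zero spots.
#' @param theta NB dispersion; variance is `mu + mu^2 / theta`. `Inf` gives
#'   Poisson residuals. Default 100.
#' @param clip clipping bound; `NULL` (default) uses `sqrt(n_spots)`.
#' @return A genes x spots dense matrix of clipped residuals with attributes
#'   `theta` and `clip`, class `residual_matrix`.
#' @export
pearson_residuals <- function(counts, theta = 100, clip = NULL) {
  m <- as.matrix(counts)
  gene_tot <- rowSums(m)
  spot_tot <- colSums(m)
  grand <- sum(gene_tot)
  if (grand <= 0) stop("zero grand total: no counts to normalize")
  if (any(spot_tot == 0)) stop("all-zero spot(s) present; filter first")
  if (is.null(clip)) clip <- sqrt(ncol(m))
  mu <- outer(gene_tot, spot_tot) / grand
  r <- (m - mu) / sqrt(mu + mu^2 / theta)
  r[!is.finite(r)] <- 0  # genes with zero total have mu = 0 everywhere
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  structure(r, theta = theta, clip = clip,
            class = c("residual_matrix", class(r)))
}

#' Non-negative transform of a residual matrix
#'
#' NMF requires non-negative input; negative residuals are clipped at zero
#' (default) or the whole matrix is shifted by its minimum.
#'
#' @param R residual (or any numeric) matrix.
#' @param mode `"clip"` (default): `pmax(R, 0)`; `"shift"`: `R - min(R)`.
#' @return A non-negative matrix of the same shape.
#' @export
nonneg_transform <- function(R, mode = c("clip", "shift")) {
  mode <- match.arg(mode)
  out <- if (mode == "clip") pmax(unclass(R), 0) else unclass(R) - min(R)
  attributes(out)$theta <- NULL
  class(out) <- "matrix"
  dim(out) <- dim(R)
  dimnames(out) <- dimnames(R)
  out
}

#' ICA-based NMF initialization
#'
#' Runs fast ICA with `k` components on the input and builds a non-negative
#' starting point from them. Each (centered, hence bipolar) component
#' `s m'` contributes two non-negative candidate patterns — the positive
#' parts `(s+, m+)` and the sign-flipped parts `(s-, m-)` — and the `k`
#' candidates with the largest norm product are kept, so the sign-aligned
#' positive part of every component always enters first and an
#' anti-correlated partner pattern can claim a slot when it carries real
#' mass (as when two disjoint expression programs form one ICA contrast).
#' Exactly-zero entries are nudged to `1e-6` so the multiplicative updates
#' can move them. If ICA fails, a seeded uniform-random initialization is
#' returned and flagged.
#'
#' @param X non-negative genes x spots matrix.
#' @param k number of components, `1 <= k <= min(dim(X))`.
#' @param seed RNG seed.
#' @return List with `W0` (genes x k), `H0` (k x spots) and `method`
#'   (`"ica"` or `"random"`).
#' @export
nmf_ica_init <- function(X, k, seed = 1) {
  X <- as.matrix(X)
  stopifnot(k >= 1, k <= min(dim(X)))
  set.seed(seed)
  res <- tryCatch({
    fit <- ica::icafast(X, nc = k)
    S <- fit$S                      # genes x k
    M <- fit$M                      # spots x k (transposed when k = 1)
    if (!is.matrix(S)) S <- matrix(S, ncol = k)
    if (!is.matrix(M)) M <- matrix(M, ncol = k)
    if (nrow(M) != ncol(X)) M <- t(M)
    cand_w <- cand_h <- list()
    score <- numeric(0)
    for (j in seq_len(k)) {
      for (sgn in c(1, -1)) {
        w <- pmax(sgn * S[, j], 0)
        h <- pmax(sgn * M[, j], 0)
        cand_w[[length(cand_w) + 1]] <- w
        cand_h[[length(cand_h) + 1]] <- h
        score <- c(score, sqrt(sum(w^2)) * sqrt(sum(h^2)))
      }
    }
    top <- order(-score)[seq_len(k)]
    list(W0 = do.call(cbind, cand_w[top]),
         H0 = t(do.call(cbind, cand_h[top])), method = "ica")
  }, error = function(e) NULL)
  if (is.null(res)) {
    res <- list(W0 = matrix(runif(nrow(X) * k), ncol = k),
                H0 = matrix(runif(k * ncol(X)), nrow = k),
                method = "random")
  }
  res$W0[res$W0 == 0] <- 1e-6
  res$H0[res$H0 == 0] <- 1e-6
  rownames(res$W0) <- rownames(X)
  colnames(res$H0) <- colnames(X)
  res
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Decomposes a non-negative genes x spots matrix `A` as `A ~ W H` with `W`
#' (genes x k) the feature loadings and `H` (k x spots) the low-dimensional
#' representation, minimizing the Frobenius loss `||A - WH||_F^2` by the
#' classic multiplicative updates starting from an ICA initialization
#' ([nmf_ica_init()]). The objective is recorded per iteration and is
#' non-increasing. On output, columns of `W` have unit L2 norm with the
#' compensating scale moved into the rows of `H`.
#'
#' @param X non-negative genes x spots matrix (typically
#'   `nonneg_transform(pearson_residuals(counts))`).
#' @param k number of factors (no automatic selection; choose per tissue).
#' @param init optional list with `W0`, `H0`; default [nmf_ica_init()].
#' @param max_iter maximum update sweeps (default 200).
#' @param tol stop when the relative objective decrease falls below this.
#' @param seed RNG seed (initialization).
#' @return An object of class `factor_model`: `W`, `H`, `k`,
#'   `objective_trace`, `iterations`, `converged`, `init_method`.
#' @export
fit_nmf <- function(X, k, init = NULL, max_iter = 200, tol = 1e-5, seed = 1) {
  X <- as.matrix(X)
  if (min(X) < 0) stop("X must be non-negative; see nonneg_transform()")
  if (is.null(init)) init <- nmf_ica_init(X, k, seed = seed)
  W <- init$W0; H <- init$H0
  stopifnot(nrow(W) == nrow(X), ncol(W) == k,
            nrow(H) == k, ncol(H) == ncol(X))
  eps <- 1e-10
  obj <- function(W, H) sum((X - W %*% H)^2)
  trace <- obj(W, H)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (!all(is.finite(W)) || !all(is.finite(H))) {
      stop("non-finite values in NMF update at iteration ", it)
    }
    o <- obj(W, H)
    trace <- c(trace, o)
    prev <- trace[it]
    if (prev - o < tol * max(prev, eps)) {
      converged <- TRUE
      break
    }
  }
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(W, 2, nrm, "/")
  H <- sweep(H, 1, nrm, "*")
  colnames(W) <- rownames(H) <- paste0("factor_", seq_len(k))
  structure(
    list(W = W, H = H, k = k, objective_trace = trace, iterations = it,
         converged = converged, init_method = init$method %||% "user"),
    class = "factor_model"
  )
}

#' @exportS3Method base::print
print.factor_model <- function(x, ...) {
  cat("factor_model: k =", x$k, "|", nrow(x$W), "genes x", ncol(x$H),
      "spots\n  iterations:", x$iterations,
      "| final objective:", signif(tail(x$objective_trace, 1), 6),
      "| init:", x$init_method, "\n")
  invisible(x)
}

#' Top driver genes of a factor
#'
#' Genes sorted by their loading in the chosen column of `W`, descending,
#' ties broken by gene identifier.
#'
#' @param model a [fit_nmf()] result.
#' @param factor_index which factor, `1..k`.
#' @param n how many genes (default 10; capped at the gene count).
#' @return Character vector of gene identifiers.
#' @export
top_drivers <- function(model, factor_index, n = 10) {
  stopifnot(inherits(model, "factor_model"), n >= 1)
  if (factor_index < 1 || factor_index > model$k) {
    stop("factor_index must be in 1..", model$k)
  }
  w <- model$W[, factor_index]
  genes <- rownames(model$W) %||% as.character(seq_along(w))
  ord <- order(-w, genes)
  genes[head(ord, n)]
}

#' Match recovered factors to reference patterns
#'
#' Finds the one-to-one assignment of recovered factors (rows of `H`) to
#' reference spatial patterns maximizing the mean cosine similarity —
#' useful for comparing a factorization against planted ground truth, where
#' factor order and scale are arbitrary. Exact assignment by enumeration
#' for up to 8 factors, greedy beyond.
#'
#' @param H k x spots matrix of recovered factor activities.
#' @param patterns k x spots matrix of reference patterns (same k).
#' @return List with `assignment` (index into `patterns` rows for each row
#'   of `H`), `cosines` (per-factor similarity under the assignment) and
#'   `mean_cosine`.
#' @export
match_factors <- function(H, patterns) {
  stopifnot(nrow(H) == nrow(patterns), ncol(H) == ncol(patterns))
  k <- nrow(H)
  cs <- function(a, b) {
    n <- sqrt(sum(a^2) * sum(b^2))
    if (n == 0) 0 else sum(a * b) / n
  }
  S <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) cs(H[i, ], patterns[j, ])))
  if (k <= 8) {
    perms <- permutations_of(k)
    scores <- vapply(perms, function(p) mean(S[cbind(seq_len(k), p)]),
                     numeric(1))
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(k)
    avail <- seq_len(k)
    for (i in order(-apply(S, 1, max))) {
      j <- avail[which.max(S[i, avail])]
      best[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  cosines <- S[cbind(seq_len(k), best)]
  list(assignment = best, cosines = cosines, mean_cosine = mean(cosines))
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in permutations_of(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1]] <- append(p, k, after = pos)
    }
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a factor model into a long loading table
#'
#' @param x a [fit_nmf()] result.
#' @param matrix which matrix to tidy: `"W"` (gene loadings, default) or
#'   `"H"` (spot activities).
#' @param ... unused.
#' @return A tibble `(gene, factor, loading)` or `(spot, factor, activity)`.
#' @export
tidy.factor_model <- function(x, matrix = c("W", "H"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    tibble::tibble(
      gene = rep(rownames(x$W) %||% as.character(seq_len(nrow(x$W))),
                 times = x$k),
      factor = rep(colnames(x$W), each = nrow(x$W)),
      loading = as.numeric(x$W)
    )
  } else {
    tibble::tibble(
      spot = rep(colnames(x$H) %||% as.character(seq_len(ncol(x$H))),
                 each = x$k),
      factor = rep(rownames(x$H), times = ncol(x$H)),
      activity = as.numeric(x$H)
    )
  }
}

#' One-row summary of a factor model fit
#' @param x a [fit_nmf()] result.
#' @param ... unused.
#' @return A one-row tibble with `k`, `iterations`, `final_objective`,
#'   `relative_error`, `converged`, `init_method`.
#' @export
glance.factor_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    iterations = x$iterations,
    final_objective = tail(x$objective_trace, 1),
    converged = x$converged,
    init_method = x$init_method
  )
}
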