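# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Restores the caller's `.Random.seed` afterwards so that seeded internals
#' (control-gene sampling, modularity optimization) do not perturb the
#' session RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Open a text connection, transparently handling gzip
#' @noRd
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Column ranks of a sparse matrix, midranks for ties
#'
#' Equivalent to `apply(as.matrix(x), 2, rank)` but only touches nonzero
#' entries per column: zeros share the midrank of the zero block.
#' Returns a dense matrix (cells x genes) of ranks plus, per column, the
#' tie-correction sum `sum(t^3 - t)` over tie groups (needed by the
#' rank-sum normal approximation).
#' @noRd
sparse_col_ranks <- function(x) {
  x <- methods::as(x, "CsparseMatrix")
  n <- nrow(x)
  p <- ncol(x)
  ranks <- matrix(0, n, p)
  ties <- numeric(p)
  xp <- x@p
  xi <- x@i
  xv <- x@x
  for (j in seq_len(p)) {
    idx <- if (xp[j + 1] > xp[j]) (xp[j] + 1L):xp[j + 1] else integer(0)
    vals <- xv[idx]
    rows <- xi[idx] + 1L
    nz <- length(vals)
    n0 <- n - nz
    r <- rep((n0 + 1) / 2, n)      # zeros share the zero-block midrank
    if (nz > 0) {
      r[rows] <- n0 + rank(vals, ties.method = "average")
    }
    ranks[, j] <- r
    # tie correction: zero block plus tie groups among nonzero values
    tt <- if (nz > 0) table(vals) else integer(0)
    tt <- c(n0, as.integer(tt))
    tt <- tt[tt > 1]
    ties[j] <- sum(tt^3 - tt)
  }
  list(ranks = ranks, ties = ties)
}

#' Vectorized two-sided Wilcoxon rank-sum test, one gene per column
#'
#' Group 1 = `in_idx` rows. Uses the exact Mann-Whitney null distribution
#' (`stats::pwilcox`) when a column has no ties and both groups have fewer
#' than 50 observations; otherwise the normal approximation with tie and
#' continuity correction, matching `stats::wilcox.test`.
#' @noRd
ranksum_pvalues <- function(ranks, ties, in_idx) {
  n <- nrow(ranks)
  n1 <- length(in_idx)
  n2 <- n - n1
  rsum <- colSums(ranks[in_idx, , drop = FALSE])
  U <- rsum - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - ties / (n * (n - 1)))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  exact_ok <- (ties == 0) & (n1 < 50) & (n2 < 50)
  for (j in which(exact_ok)) {
    pj <- if (U[j] > mu)
      2 * stats::pwilcox(U[j] - 1, n1, n2, lower.tail = FALSE)
    else
      2 * stats::pwilcox(U[j], n1, n2)
    p[j] <- min(1, pj)
  }
  p
}

#' Normalized Shannon entropy of a label vector
#' @noRd
norm_entropy <- function(labels, levels_all) {
  tab <- tabulate(factor(labels, levels = levels_all),
                  nbins = length(levels_all))
  pr <- tab / sum(tab)
  pr <- pr[pr > 0]
  if (length(levels_all) < 2) return(1)
  -sum(pr * log(pr)) / log(length(levels_all))
}
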