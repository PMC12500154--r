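#' Find clusters in participant-level paired-difference series
#'
#' Computes a pointwise one-sample t statistic across participants (the
#' series are paired differences: condition minus zero or condition A minus
#' B), keeps samples significant at the two-sided `alpha`, and groups
#' maximal runs of adjacent same-signed significant samples into clusters.
#' Cluster mass is the sum of t values inside the cluster. For
#' time-frequency maps (a participants x freq x time array) adjacency is
#' 4-connectivity over the freq x time grid. Time points with zero variance
#' have an undefined t; they are treated as non-significant and counted in
#' the `n_degenerate` attribute.
#'
#' @param series participants x time matrix, or participants x freq x time
#'   array for 2D maps.
#' @param alpha two-sided pointwise significance level (default 0.05).
#' @return a `cluster_scan` tibble: `cluster`, `start`, `end` (indices;
#'   for 2D, bounding-box columns `f1`, `f2`, `t1`, `t2`), `sign`, `mass`,
#'   `n_points`; attributes `tvals`, `crit`, `alpha`, `n_degenerate`.
#' @export
find_clusters <- function(series, alpha = 0.05) {
  dims <- if (length(dim(series)) == 3) dim(series)[2:3] else NULL
  X <- if (is.null(dims)) as.matrix(series)
       else matrix(series, dim(series)[1], prod(dims))
  n <- nrow(X)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tvals <- ifelse(v > 0, m / sqrt(v / n), NA_real_)
  crit <- qt(1 - alpha / 2, df = n - 1)
  cl <- if (is.null(dims)) clusters_1d(tvals, crit)
        else clusters_2d(matrix(tvals, dims[1], dims[2]), crit)
  attr(cl, "tvals") <- tvals
  attr(cl, "crit") <- crit
  attr(cl, "alpha") <- alpha
  attr(cl, "dims") <- dims
  attr(cl, "n_degenerate") <- sum(is.na(tvals))
  class(cl) <- c("cluster_scan", class(cl))
  cl
}

clusters_1d <- function(tvals, crit) {
  code <- integer(length(tvals))
  ok <- !is.na(tvals)
  code[ok & tvals > crit] <- 1L
  code[ok & tvals < -crit] <- -1L
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  if (!length(keep))
    return(tibble(cluster = integer(), start = integer(), end = integer(),
                  sign = integer(), mass = numeric(), n_points = integer()))
  cs <- c(0, cumsum(ifelse(ok, tvals, 0)))
  tibble(cluster = seq_along(keep), start = starts[keep], end = ends[keep],
         sign = r$values[keep],
         mass = cs[ends[keep] + 1] - cs[starts[keep]],
         n_points = r$lengths[keep])
}

clusters_2d <- function(tm, crit) {
  nr <- nrow(tm); nc <- ncol(tm)
  sig <- !is.na(tm) & abs(tm) > crit
  sgn <- sign(tm)
  lab <- matrix(0L, nr, nc)
  rows <- list()
  id <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!sig[i, j] || lab[i, j] != 0L) next
    id <- id + 1L
    s <- sgn[i, j]
    stack <- matrix(c(i, j), 1)
    lab[i, j] <- id
    cells <- stack
    while (nrow(stack) > 0) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        ii <- cur[1] + d[1]; jj <- cur[2] + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            sig[ii, jj] && lab[ii, jj] == 0L && sgn[ii, jj] == s) {
          lab[ii, jj] <- id
          stack <- rbind(stack, c(ii, jj))
          cells <- rbind(cells, c(ii, jj))
        }
      }
    }
    rows[[id]] <- tibble(cluster = id, f1 = min(cells[, 1]),
                         f2 = max(cells[, 1]), t1 = min(cells[, 2]),
                         t2 = max(cells[, 2]), sign = as.integer(s),
                         mass = sum(tm[cells]), n_points = nrow(cells))
  }
  if (!length(rows))
    return(tibble(cluster = integer(), f1 = integer(), f2 = integer(),
                  t1 = integer(), t2 = integer(), sign = integer(),
                  mass = numeric(), n_points = integer()))
  bind_rows(rows)
}

# largest |cluster mass| in a t series given the pointwise threshold
max_cluster_mass_1d <- function(tvals, crit) {
  code <- integer(length(tvals))
  ok <- !is.na(tvals)
  code[ok & tvals > crit] <- 1L
  code[ok & tvals < -crit] <- -1L
  r <- rle(code)
  keep <- r$values != 0L
  if (!any(keep)) return(0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cs <- c(0, cumsum(ifelse(ok, tvals, 0)))
  max(abs(cs[ends[keep] + 1] - cs[starts[keep]]))
}

max_cluster_mass_2d <- function(tm, crit) {
  cl <- clusters_2d(tm, crit)
  if (nrow(cl) == 0) 0 else max(abs(cl$mass))
}

#' Cluster-based sign-flip permutation test
#'
#' Tests participant-level paired-difference series against zero. Each
#' permutation multiplies every participant's series by an independent
#' random sign (a participant-level condition swap) and records the largest
#' absolute cluster mass; a cluster's p value is the proportion of
#' permutations whose largest mass is at least the observed cluster's
#' absolute mass (ties count against the hypothesis). The identity
#' labelling is not forcibly included, so a cluster exceeding every
#' permuted maximum gets the literal p = 0, reported alongside as
#' `"< 1/n_perm"`. With `exhaustive = TRUE` all `2^n` sign patterns are
#' enumerated instead (exact test; `n <= 16`).
#'
#' @inheritParams find_clusters
#' @param n_perm number of random sign-flip permutations (default 10000).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param exhaustive enumerate all sign patterns instead of sampling.
#' @return a `cluster_test` object: the cluster tibble with `p` and
#'   `p_label` columns, plus `null_max` (permutation distribution of the
#'   maximum |mass|), `n_perm`, `alpha`, `seed`, and the scan attributes.
#' @export
permutation_test <- function(series, n_perm = 10000, seed = NULL,
                             alpha = 0.05, exhaustive = FALSE) {
  scan <- find_clusters(series, alpha = alpha)
  dims <- attr(scan, "dims")
  X <- if (is.null(dims)) as.matrix(series)
       else matrix(series, dim(series)[1], prod(dims))
  n <- nrow(X)
  crit <- attr(scan, "crit")
  if (exhaustive) {
    if (n > 16) stop("exhaustive enumeration limited to n <= 16",
                     call. = FALSE)
    Fm <- t(as.matrix(expand.grid(rep(list(c(-1, 1)), n))))
    n_perm <- ncol(Fm)
  } else {
    if (n_perm < 100)
      warning("fewer than 100 permutations gives a very coarse p value")
    Fm <- with_seed(seed,
                    matrix(sample(c(-1, 1), n * n_perm, replace = TRUE),
                           n, n_perm))
  }
  ss <- colSums(X^2)  # invariant under sign flips
  null_max <- numeric(n_perm)
  block <- 1024L
  for (b0 in seq(1, n_perm, by = block)) {
    cols <- b0:min(b0 + block - 1L, n_perm)
    M <- crossprod(Fm[, cols, drop = FALSE], X) / n     # perms x points
    V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
    V[V < 0] <- 0
    Tm <- M / sqrt(V / n)
    Tm[V == 0] <- NA_real_
    for (k in seq_along(cols)) {
      null_max[cols[k]] <-
        if (is.null(dims)) max_cluster_mass_1d(Tm[k, ], crit)
        else max_cluster_mass_2d(matrix(Tm[k, ], dims[1], dims[2]), crit)
    }
  }
  p <- vapply(scan$mass,
              function(m) mean(null_max >= abs(m)), numeric(1))
  scan$p <- p
  scan$p_label <- ifelse(p == 0, paste0("< ", format(1 / n_perm)),
                         format(p))
  out <- list(clusters = scan, null_max = null_max, n_perm = n_perm,
              alpha = alpha, seed = seed,
              tvals = attr(scan, "tvals"), crit = crit, dims = dims,
              exhaustive = exhaustive)
  class(out) <- "cluster_test"
  out
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("<cluster_test> ", nrow(x$clusters), " cluster(s), ",
      x$n_perm, if (x$exhaustive) " exhaustive" else " random",
      " sign-flip permutations, pointwise alpha ", x$alpha, "\n", sep = "")
  if (nrow(x$clusters)) {
    print(as_tibble(x$clusters))
  }
  invisible(x)
}

#' Smallest cluster p value of a test (1 when no cluster was found)
#' @param x a `cluster_test` object.
#' @export
min_cluster_p <- function(x) {
  if (nrow(x$clusters) == 0) 1 else min(x$clusters$p)
}
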