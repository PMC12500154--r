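#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cluster permutation test
#'
#' One row per observed cluster with its extent, mass, sign and
#' permutation p value.
#'
#' @param x a `cluster_test` object.
#' @param ... ignored.
#' @method tidy cluster_test
#' @export
tidy.cluster_test <- function(x, ...) {
  as_tibble(x$clusters)
}

#' @rdname tidy.cluster_test
#' @method glance cluster_test
#' @export
glance.cluster_test <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         min_p = min_cluster_p(x),
         n_perm = x$n_perm, alpha = x$alpha,
         exhaustive = x$exhaustive)
}

#' Tidy a repeated-measures ANOVA fit
#'
#' @param x an `rm_anova` object.
#' @param ... ignored.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble(term = "class", statistic = x$F, df1 = x$df1, df2 = x$df2,
         p.value = x$p, partial.eta.squared = x$pes)
}

#' @rdname tidy.rm_anova
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n = x$n, k = x$k, statistic = x$F, p.value = x$p,
         partial.eta.squared = x$pes)
}
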