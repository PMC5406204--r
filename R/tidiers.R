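#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a free-energy surface into a long tibble
#' @param x a `fes_grid`
#' @param ... unused
#' @return tibble with `cv1`, `cv2`, `free`
#' @export
tidy.fes_grid <- function(x, ...) {
  g <- expand.grid(i = seq_along(x$ax1), j = seq_along(x$ax2))
  tibble::tibble(cv1 = x$ax1[g$i], cv2 = x$ax2[g$j],
                 free = x$values[cbind(g$i, g$j)])
}

#' One-row summary of a free-energy surface
#' @param x a `fes_grid`
#' @param ... unused
#' @return tibble with grid size, free-energy range, number of minima
#' @export
glance.fes_grid <- function(x, ...) {
  m <- find_minima(x)
  tibble::tibble(n_cv1 = length(x$ax1), n_cv2 = length(x$ax2),
                 f_max = max(x$values), n_minima = nrow(m),
                 temperature = x$temperature,
                 bias_factor = x$bias_factor)
}

#' Tidy a metadynamics run: the CV record of the base replica
#' @param x a `metad_run`
#' @param ... unused
#' @return the colvar tibble
#' @export
tidy.metad_run <- function(x, ...) x$colvar

#' One-row summary of a metadynamics run
#' @param x a `metad_run`
#' @param ... unused
#' @return tibble with hill count, final height, mean exchange rate
#' @export
glance.metad_run <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, n_hills = nrow(x$hills),
    w_first = if (nrow(x$hills) > 0) x$hills$height[1] else NA_real_,
    w_last = if (nrow(x$hills) > 0)
      x$hills$height[nrow(x$hills)] else NA_real_,
    mean_exchange_rate = if (!is.null(x$exchange))
      mean(x$exchange$rate, na.rm = TRUE) else NA_real_,
    seed = x$seed)
}

#' Tidy gromos clusters into one row per cluster
#' @param x a `gromos_clusters`
#' @param ... unused
#' @return tibble with `cluster`, `size`, `center`, `members`
#'   (list-column)
#' @export
tidy.gromos_clusters <- function(x, ...) {
  tibble::tibble(
    cluster = seq_along(x),
    size = vapply(x, function(cl) length(cl$members), integer(1)),
    center = vapply(x, function(cl) cl$center, integer(1)),
    members = lapply(x, function(cl) cl$members))
}

#' One-row summary of a clustering
#' @param x a `gromos_clusters`
#' @param ... unused
#' @return tibble with cluster count and top-5 coverage
#' @export
glance.gromos_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = length(x),
                 n_frames = sum(vapply(x, function(cl)
                   length(cl$members), integer(1))),
                 top5_coverage = top_clusters_coverage(x, 5),
                 cutoff = attr(x, "cutoff"))
}

#' Tidy a distance histogram into one row per bin
#' @param x a `dist_histogram`
#' @param ... unused
#' @return tibble with `mid`, `count`
#' @export
tidy.dist_histogram <- function(x, ...) {
  tibble::tibble(mid = x$mids, count = x$counts)
}
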