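#' Subsampling configuration
#'
#' @param k number of subsamples to draw per sample (default 4).
#' @param pct percentage of cells per subsample, in (0, 100] (default 70).
#' @param seed integer master seed for the draws.
#' @return an object of class `SubsampleConfig`.
#' @export
subsample_config <- function(k = 4L, pct = 70, seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (!is.numeric(pct) || pct <= 0 || pct > 100) stop("pct must be in (0, 100]")
  structure(list(k = k, pct = pct, seed = as.integer(seed)),
            class = "SubsampleConfig")
}

#' Draw random cell subsamples from a sample
#'
#' Draws `k` independent subsamples of `floor(M / 100 * pct)` distinct cells
#' each (sampling without replacement within a subsample; different
#' subsamples may overlap). A master seed spawns one child seed per
#' subsample, so increasing `k` extends the set without reshuffling earlier
#' draws.
#'
#' @param sample an [ExpressionSample][expression_sample].
#' @param cfg a [subsample_config()].
#' @return an object of class `SubsampleSet`: list with the parent sample,
#'   `members` (list of `k` integer index vectors) and the config.
#' @export
draw_subsamples <- function(sample, cfg = subsample_config()) {
  stopifnot(inherits(sample, "ExpressionSample"), inherits(cfg, "SubsampleConfig"))
  m <- sample$n_cells
  size <- floor(m / 100 * cfg$pct)
  if (size < 2L)
    stop("subsample size floor(", m, "/100*", cfg$pct, ") = ", size,
         " is too small to fit a network; need at least ",
         ceiling(200 / cfg$pct), " cells")
  set.seed(cfg$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, cfg$k)
  members <- lapply(child_seeds, function(s) {
    set.seed(s)
    sort(sample.int(m, size))
  })
  structure(list(parent = sample, members = members, cfg = cfg),
            class = "SubsampleSet")
}

#' @export
print.SubsampleSet <- function(x, ...) {
  cat(sprintf("SubsampleSet: %d subsamples of %d cells (of %d) from sample %s\n",
              length(x$members), length(x$members[[1]]), x$parent$n_cells,
              x$parent$label))
  invisible(x)
}
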