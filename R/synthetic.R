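#' Normalized 1-D empirical marginal on an opinion grid
#'
#' @param grid An [opinion_grid1d()].
#' @param values Nonnegative cell values; they are renormalized so that
#'   `sum(values) * dw == 1` (an all-zero vector is rejected).
#' @return Object of class `empirical_marginal`.
#' @export
empirical_marginal <- function(grid, values) {
  stopifnot(inherits(grid, "opinion_grid1d"))
  values <- as.numeric(values)
  if (length(values) != grid$n) stop("values length must equal grid$n")
  if (any(values < 0)) stop("marginal values must be nonnegative")
  mass <- sum(values) * grid$dw
  if (mass <= 0) stop("marginal has zero mass")
  structure(list(grid = grid, values = values / mass),
            class = "empirical_marginal")
}

#' @export
print.empirical_marginal <- function(x, ...) {
  cat(sprintf("<empirical_marginal> %d cells, mean = %.4g\n",
              x$grid$n, marginal_mean(x)))
  invisible(x)
}

#' Density-weighted mean of a 1-D marginal
#' @param marginal An `empirical_marginal`.
#' @return Cell-center weighted mean.
#' @export
marginal_mean <- function(marginal) {
  stopifnot(inherits(marginal, "empirical_marginal"))
  sum(marginal$grid$centers * marginal$values) * marginal$grid$dw
}

#' Sentiment dataset: timestamped bivariate score records
#'
#' One row per post: time `t` (days), positive score `w_plus` and negative
#' score `w_minus` in `[0, 1]`, and an optional `group` label.
#'
#' @param t,w_plus,w_minus Numeric vectors of equal length.
#' @param group Optional character/factor vector of group labels.
#' @param t_span Length-2 numeric `(t0, t1)`; defaults to the data range
#'   (or `c(0, 0)` for an empty dataset). All record times must lie inside.
#' @return A `data.frame` of class `sentiment_dataset`, sorted by time,
#'   with attribute `t_span`.
#' @export
sentiment_dataset <- function(t = numeric(), w_plus = numeric(),
                              w_minus = numeric(), group = NULL,
                              t_span = NULL) {
  n <- length(t)
  stopifnot(length(w_plus) == n, length(w_minus) == n)
  if (!is.null(group)) stopifnot(length(group) == n)
  if (n > 0) {
    if (any(!is.finite(t))) stop("record times must be finite")
    if (any(w_plus < 0 | w_plus > 1) || any(w_minus < 0 | w_minus > 1))
      stop("scores must lie in [0, 1]")
  }
  if (is.null(t_span)) {
    t_span <- if (n > 0) range(t) else c(0, 0)
  }
  if (n > 0 && (any(t < t_span[1]) || any(t > t_span[2])))
    stop("record times must lie within t_span")
  d <- data.frame(t = as.numeric(t), w_plus = as.numeric(w_plus),
                  w_minus = as.numeric(w_minus))
  d$group <- if (is.null(group)) rep(NA_character_, n) else as.character(group)
  d <- d[order(d$t), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, t_span = as.numeric(t_span),
            class = c("sentiment_dataset", "data.frame"))
}

#' Ground-truth score densities for the synthetic generator
#'
#' `stationary_truth()` describes a corpus whose score pairs are drawn,
#' independently per axis, from fixed Beta mixtures at every time.
#' `drifting_truth()` interpolates all mixture parameters (weight, means,
#' mu ratios) linearly in time between an initial and a final state,
#' emulating a community that polarizes over the observation window.
#'
#' @param plus,minus [beta_spec()] or [beta_mixture_spec()] for the
#'   positive and negative axis.
#' @param initial,final Lists with elements `plus` and `minus` (each a
#'   `beta_spec` or `beta_mixture_spec`) describing the start and end of
#'   the window.
#' @return Object of class `sentiment_truth`: a list with a function
#'   `at(s)` mapping normalized time `s` in `[0, 1]` to a list
#'   `(plus = , minus = )` of `beta_mixture_spec`s.
#' @export
stationary_truth <- function(plus, minus) {
  plus <- .as_mixture(plus); minus <- .as_mixture(minus)
  structure(list(kind = "stationary",
                 at = function(s) list(plus = plus, minus = minus)),
            class = "sentiment_truth")
}

#' @rdname stationary_truth
#' @export
drifting_truth <- function(initial, final) {
  p0 <- .as_mixture(initial$plus); p1 <- .as_mixture(final$plus)
  m0 <- .as_mixture(initial$minus); m1 <- .as_mixture(final$minus)
  lerp_spec <- function(a, b, s)
    beta_spec((1 - s) * a$m + s * b$m, (1 - s) * a$mu + s * b$mu)
  lerp_mix <- function(a, b, s)
    beta_mixture_spec((1 - s) * a$weight_S + s * b$weight_S,
                      lerp_spec(a$spec_S, b$spec_S, s),
                      lerp_spec(a$spec_R, b$spec_R, s))
  structure(list(kind = "drifting",
                 at = function(s) list(plus = lerp_mix(p0, p1, s),
                                       minus = lerp_mix(m0, m1, s))),
            class = "sentiment_truth")
}

.sample_mixture <- function(mix, n) {
  if (n == 0L) return(numeric())
  comp <- stats::rbinom(n, 1L, mix$weight_S)  # 1 -> S component
  out <- numeric(n)
  nS <- sum(comp == 1L)
  out[comp == 1L] <- stats::rbeta(nS, mix$spec_S$a, mix$spec_S$b)
  out[comp == 0L] <- stats::rbeta(n - nS, mix$spec_R$a, mix$spec_R$b)
  out
}

#' Generate a synthetic sentiment corpus with known ground truth
#'
#' Stand-in for a scraped group-chat corpus: post times are i.i.d. uniform
#' on `t_span` (or taken from `times`), and each post's score pair is drawn
#' independently per axis from the truth density evaluated at that post's
#' time. Fully reproducible under a fixed seed.
#'
#' @param truth A [stationary_truth()] or [drifting_truth()] object.
#' @param n_posts Number of posts (>= 0).
#' @param t_span Observation window in days, default `c(0, 190)` (the
#'   length of a roughly six-month scrape).
#' @param seed Integer seed; required for reproducibility.
#' @param groups Character vector of group labels sampled uniformly per
#'   post; default six anonymized chat labels.
#' @param times Optional explicit post times (overrides uniform sampling).
#' @return A [sentiment_dataset()].
#' @export
generate_synthetic_dataset <- function(truth, n_posts, t_span = c(0, 190),
                                       seed, groups = paste0("chat", 1:6),
                                       times = NULL) {
  stopifnot(inherits(truth, "sentiment_truth"))
  n_posts <- as.integer(n_posts)
  if (is.na(n_posts) || n_posts < 0L) stop("n_posts must be >= 0")
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  if (n_posts == 0L)
    return(sentiment_dataset(t_span = t_span))
  t <- if (is.null(times)) {
    sort(stats::runif(n_posts, t_span[1], t_span[2]))
  } else {
    if (length(times) != n_posts) stop("times must have length n_posts")
    sort(as.numeric(times))
  }
  s <- if (diff(t_span) > 0) (t - t_span[1]) / diff(t_span) else rep(0, n_posts)
  w_plus <- numeric(n_posts); w_minus <- numeric(n_posts)
  if (truth$kind == "stationary") {
    mix <- truth$at(0)
    w_plus <- .sample_mixture(mix$plus, n_posts)
    w_minus <- .sample_mixture(mix$minus, n_posts)
  } else {
    # parameters vary per post; draw one pair at a time in time order
    for (i in seq_len(n_posts)) {
      mix <- truth$at(s[i])
      w_plus[i] <- .sample_mixture(mix$plus, 1L)
      w_minus[i] <- .sample_mixture(mix$minus, 1L)
    }
  }
  grp <- sample(groups, n_posts, replace = TRUE)
  sentiment_dataset(t, w_plus, w_minus, group = grp, t_span = t_span)
}

#' Read and write sentiment datasets as delimited text
#'
#' The expected layout is one header row naming the time, positive-score
#' and negative-score columns (mapping configurable via `columns`), one
#' row per post. In strict mode any score outside `[0, 1]` aborts with the
#' offending row number; otherwise such rows are dropped with a warning.
#'
#' @param path File path.
#' @param columns Named character vector mapping the internal names
#'   `t`, `w_plus`, `w_minus`, `group` to header names in the file.
#' @param strict If `TRUE` (default) invalid rows are an error.
#' @param sep Field delimiter (default comma).
#' @return `read_sentiment_csv()` returns a [sentiment_dataset()] sorted by
#'   time; `write_sentiment_csv()` writes and returns `path` invisibly.
#' @export
read_sentiment_csv <- function(path,
                               columns = c(t = "t", w_plus = "w_plus",
                                           w_minus = "w_minus",
                                           group = "group"),
                               strict = TRUE, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- columns[c("t", "w_plus", "w_minus")]
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0)
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  t <- as.numeric(d[[columns[["t"]]]])
  wp <- as.numeric(d[[columns[["w_plus"]]]])
  wm <- as.numeric(d[[columns[["w_minus"]]]])
  bad <- which(!is.finite(t) | !is.finite(wp) | !is.finite(wm) |
                 wp < 0 | wp > 1 | wm < 0 | wm > 1)
  if (length(bad) > 0) {
    if (strict)
      stop("invalid score or time in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           " of ", path)
    warning(length(bad), " invalid row(s) dropped")
    keep <- setdiff(seq_along(t), bad)
    t <- t[keep]; wp <- wp[keep]; wm <- wm[keep]; d <- d[keep, , drop = FALSE]
  }
  grp <- if (!is.na(columns["group"]) && columns[["group"]] %in% names(d))
    as.character(d[[columns[["group"]]]]) else NULL
  sentiment_dataset(t, wp, wm, group = grp)
}

#' @rdname read_sentiment_csv
#' @param dataset A [sentiment_dataset()].
#' @export
write_sentiment_csv <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "sentiment_dataset"))
  utils::write.table(as.data.frame(dataset), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bin a sentiment dataset to a cell-averaged density on the unit square
#'
#' Records with `t` inside `window` are counted per grid cell and divided
#' by `N_window * dw+ * dw-`, so the result has unit mass whenever the
#' window is nonempty (each snapshot is treated as a probability density).
#' Scores of exactly 1 land in the last cell.
#'
#' @param dataset A [sentiment_dataset()].
#' @param grid An [opinion_grid2d()] (default 20 x 20).
#' @param window Length-2 time interval, closed on both ends; default the
#'   dataset's `t_span`.
#' @return A [density_field2d()] with `n_records` set to the in-window
#'   count; an empty window yields a zero field (mass 0), not `NaN`.
#' @export
bin_to_density <- function(dataset, grid = opinion_grid2d(), window = NULL) {
  stopifnot(inherits(dataset, "sentiment_dataset"),
            inherits(grid, "opinion_grid2d"))
  if (is.null(window)) window <- attr(dataset, "t_span")
  if (length(window) != 2L || window[2] < window[1])
    stop("window must be a nonempty time interval")
  sel <- dataset$t >= window[1] & dataset$t <= window[2]
  n <- sum(sel)
  counts <- matrix(0, grid$plus$n, grid$minus$n)
  if (n > 0) {
    i <- .cell_index(dataset$w_plus[sel], grid$plus)
    j <- .cell_index(dataset$w_minus[sel], grid$minus)
    for (k in seq_len(n)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1
    counts <- counts / (n * grid$cell_area)
  }
  density_field2d(grid, counts, n_records = n)
}

#' Marginal densities and means of a 2-D opinion density field
#'
#' Integrates out one axis: `g(w+) = sum_j f(i, j) dw-` and
#' `h(w-) = sum_i f(i, j) dw+`, both renormalized to unit mass, plus the
#' density-weighted cell-center means of both axes.
#'
#' @param field A [density_field2d()] with positive mass.
#' @return List with `plus` and `minus` (`empirical_marginal`s), and means
#'   `m_plus`, `m_minus`.
#' @export
empirical_marginals <- function(field) {
  stopifnot(inherits(field, "density_field2d"))
  if (field$mass <= 0) stop("field has zero mass")
  g <- rowSums(field$values) * field$grid$minus$dw
  h <- colSums(field$values) * field$grid$plus$dw
  gm <- empirical_marginal(field$grid$plus, g)
  hm <- empirical_marginal(field$grid$minus, h)
  list(plus = gm, minus = hm,
       m_plus = marginal_mean(gm), m_minus = marginal_mean(hm))
}

#' Write a density field as a CSV matrix with a JSON sidecar
#'
#' The matrix is written with positive-score cells as rows; the sidecar
#' (same path with extension `.json`) records the grid spec, record count
#' and total mass.
#'
#' @param field A [density_field2d()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(field, path) {
  stopifnot(inherits(field, "density_field2d"))
  utils::write.table(field$values, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  sidecar <- sub("\\.[^.]*$", "", path)
  jsonlite::write_json(
    list(n_plus = field$grid$plus$n, n_minus = field$grid$minus$n,
         dw_plus = field$grid$plus$dw, dw_minus = field$grid$minus$dw,
         n_records = field$n_records, mass = field$mass),
    paste0(sidecar, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
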