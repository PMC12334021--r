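#' Construct a decision matrix
#'
#' @param values numeric matrix or data frame, alternatives in rows,
#'   criteria in columns.
#' @param weights positive weights, one per criterion; normalized to sum
#'   to 1.
#' @param directions `"min"` or `"max"` per criterion (default all min).
#' @param alternatives row names (default from `values`).
#' @return a `gg_decision_matrix`.
#' @export
decision_matrix <- function(values, weights,
                            directions = rep("min", ncol(values)),
                            alternatives = rownames(values)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 2, length(weights) == ncol(values),
            all(weights > 0), length(directions) == ncol(values),
            all(directions %in% c("min", "max")), !anyNA(values))
  if (is.null(alternatives)) alternatives <- paste0("alt", seq_len(nrow(values)))
  rownames(values) <- alternatives
  structure(list(values = values, weights = weights / sum(weights),
                 directions = directions),
            class = "gg_decision_matrix")
}

#' TOPSIS ranking
#'
#' Vector normalization `r_ij = x_ij / sqrt(sum_i x_ij^2)` (or min-max
#' when `normalization = "minmax"`), weighting, per-criterion ideal and
#' anti-ideal points, Euclidean distances to both, and the closeness
#' coefficient `C_i = d^- / (d^+ + d^-)`, ranked descending. An all-zero
#' criterion column cannot be normalized and is dropped with a warning.
#'
#' @param dm a [decision_matrix()].
#' @param normalization `"vector"` (default) or `"minmax"`.
#' @return a `gg_ranking`: `closeness` (named per alternative), `rank`
#'   (1 = best), `order` (alternative names best to worst).
#' @export
topsis_rank <- function(dm, normalization = c("vector", "minmax")) {
  stopifnot(inherits(dm, "gg_decision_matrix"))
  normalization <- match.arg(normalization)
  x <- dm$values
  w <- dm$weights
  dirs <- dm$directions
  zero <- apply(x, 2, function(col) all(col == 0))
  if (any(zero)) {
    warning("dropping all-zero criterion column(s): ",
            paste(colnames(x)[zero], collapse = ", "))
    x <- x[, !zero, drop = FALSE]
    w <- w[!zero] / sum(w[!zero])
    dirs <- dirs[!zero]
  }
  if (normalization == "vector") {
    r <- sweep(x, 2, sqrt(colSums(x^2)), "/")
  } else {
    r <- apply(x, 2, function(col) {
      rng <- range(col)
      if (diff(rng) == 0) rep(0.5, length(col))
      else (col - rng[1]) / diff(rng)
    })
  }
  v <- sweep(r, 2, w, "*")
  ideal <- ifelse(dirs == "min", apply(v, 2, min), apply(v, 2, max))
  anti <- ifelse(dirs == "min", apply(v, 2, max), apply(v, 2, min))
  dplus <- sqrt(rowSums(sweep(v, 2, ideal)^2))
  dminus <- sqrt(rowSums(sweep(v, 2, anti)^2))
  denom <- dplus + dminus
  C <- ifelse(denom == 0, 0.5, dminus / denom)
  names(C) <- rownames(dm$values)
  rk <- rank(-C, ties.method = "first")
  structure(list(closeness = C, rank = rk,
                 order = names(sort(rk))),
            class = "gg_ranking")
}

#' @export
print.gg_ranking <- function(x, ...) {
  cat("<gg_ranking>\n")
  print(data.frame(alternative = names(x$closeness),
                   closeness = round(x$closeness, 4), rank = x$rank,
                   row.names = NULL))
  invisible(x)
}

#' Weight-perturbation robustness analysis
#'
#' Repeats the ranking under perturbed weights. In the default
#' independent mode each iteration starts from the initial weights and
#' moves `step_frac` of one randomly chosen criterion's weight to
#' another; in walk mode the moves accumulate across iterations. Moves
#' that would push any weight beyond `max_dev` (relative) of its initial
#' value are rejected. Reports the distribution of ranks per alternative
#' and the modal rank.
#'
#' @param dm a [decision_matrix()].
#' @param n_iter iterations (default 20000).
#' @param max_dev maximum relative deviation of any weight from its
#'   initial value (default 0.5).
#' @param step_frac fraction of the source weight moved per step
#'   (default 0.05).
#' @param seed RNG seed.
#' @param mode `"independent"` (default) or `"walk"`.
#' @param normalization passed to [topsis_rank()].
#' @return a `gg_ranking` with extra fields `rank_freq` (alternatives x
#'   ranks count matrix) and `modal_rank`.
#' @export
weight_perturbation <- function(dm, n_iter = 20000, max_dev = 0.5,
                                step_frac = 0.05, seed = 1,
                                mode = c("independent", "walk"),
                                normalization = "vector") {
  stopifnot(inherits(dm, "gg_decision_matrix"), n_iter >= 1,
            max_dev > 0, max_dev <= 1)
  mode <- match.arg(mode)
  set.seed(child_seed(seed, "weight-perturbation"))
  base <- topsis_rank(dm, normalization)
  w0 <- dm$weights
  k <- length(w0)
  n_alt <- nrow(dm$values)
  freq <- matrix(0L, n_alt, n_alt,
                 dimnames = list(rownames(dm$values), seq_len(n_alt)))
  w <- w0
  for (it in seq_len(n_iter)) {
    if (mode == "independent") w <- w0
    if (k >= 2) {       # a single criterion admits no weight shift
      pair <- sample.int(k, 2)
      delta <- step_frac * w[pair[1]]
      cand <- w
      cand[pair[1]] <- cand[pair[1]] - delta
      cand[pair[2]] <- cand[pair[2]] + delta
      if (all(abs(cand - w0) <= max_dev * w0 + 1e-12)) w <- cand
    }
    m2 <- dm
    m2$weights <- w
    rk <- suppressWarnings(topsis_rank(m2, normalization)$rank)
    freq[cbind(seq_len(n_alt), rk)] <- freq[cbind(seq_len(n_alt), rk)] + 1L
  }
  modal <- apply(freq, 1, which.max)
  out <- base
  out$rank_freq <- freq
  out$modal_rank <- modal
  out
}

#' The packaged scenario decision matrix
#'
#' Loads the worked-example decision matrix shipped with the package
#' (eight growth scenarios scored on the seven impact criteria at two
#' demand levels, with the published weights and all-minimize
#' directions).
#'
#' @param demand `"23850"` or `"2385"` (hectares of projected demand).
#' @return a [decision_matrix()].
#' @export
scenario_decision_matrix <- function(demand = c("23850", "2385")) {
  demand <- match.arg(demand)
  path <- system.file("extdata", "scenario_decision_matrix.csv",
                      package = "greengrowth", mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  sub <- tab[tab$demand_ha == as.numeric(demand), ]
  vals <- as.matrix(sub[, !(names(sub) %in% c("scenario", "demand_ha"))])
  rownames(vals) <- sub$scenario
  wpath <- system.file("extdata", "scenario_criteria_weights.csv",
                       package = "greengrowth", mustWork = TRUE)
  wtab <- utils::read.csv(wpath, check.names = FALSE)
  stopifnot(identical(colnames(vals), wtab$criterion))
  decision_matrix(vals, weights = wtab$weight, directions = wtab$direction)
}
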