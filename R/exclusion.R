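#' Build the base exclusion layer (variant 1)
#'
#' Combines binary constraint masks (waterbodies, roads, protected areas,
#' floodplains, ...) cellwise by maximum of their resistance values.
#' Resistance is on a 0-100 scale: 100 means urbanization is impossible,
#' intermediate values reject urbanization attempts probabilistically,
#' and cells in no constraint get 0.
#'
#' @param constraints a list of `list(mask = <binary grid>, resistance =
#'   <value in [0, 100]>)` entries.
#' @param template a [grid()] defining shape and cellsize when
#'   `constraints` is empty.
#' @return a `gg_exclusion`: `grid` (continuous [grid()], 0-100) and
#'   `variant = "exclusion1"`.
#' @export
build_exclusion1 <- function(constraints, template = NULL) {
  if (length(constraints) == 0) {
    if (is.null(template)) stop("need a template grid when no constraints given")
    out <- matrix(0, nrow(template$values), ncol(template$values))
    return(structure(list(grid = grid(out, template$cellsize_m,
                                      kind = "continuous"),
                          variant = "exclusion1"),
                     class = "gg_exclusion"))
  }
  ref <- constraints[[1]]$mask
  out <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (ct in constraints) {
    stopifnot(inherits(ct$mask, "gg_grid"))
    if (ct$resistance < 0 || ct$resistance > 100)
      stop("resistance outside [0, 100]: ", ct$resistance)
    if (!identical(dim(ct$mask$values), dim(out)))
      stop("constraint mask shape mismatch")
    if (!all(ct$mask$values %in% c(0, 1))) stop("constraint mask not binary")
    out <- pmax(out, ct$mask$values * ct$resistance)
  }
  structure(list(grid = grid(out, ref$cellsize_m, kind = "continuous"),
                 variant = "exclusion1"),
            class = "gg_exclusion")
}

#' Build the green-space-informed exclusion layer (variant 2)
#'
#' Maps the core-importance raster and corridor current raster from their
#' 0-255 scale to 0-100 resistance (linear by default, with optional
#' floor/ceiling clamps), then combines them cellwise by maximum with
#' each other and with the base exclusion. The result dominates the base
#' layer everywhere, which is the mechanism that keeps the growth model
#' away from important cores and corridors.
#'
#' @param excl1 a [build_exclusion1()] result.
#' @param importance continuous [grid()] on 0-255 (from
#'   [rasterize_importance()]).
#' @param current continuous [grid()] on 0-255 (the `byte` grid of
#'   [cumulative_current()]).
#' @param floor,ceiling optional clamps applied after the linear 0-255 to
#'   0-100 rescale: values below `floor` drop to 0, values above
#'   `ceiling` saturate at 100.
#' @param combine `"max"` (default, conservative: preserves hard
#'   constraints) or `"sum"` (capped at 100).
#' @return a `gg_exclusion` tagged `"exclusion2"`.
#' @export
build_exclusion2 <- function(excl1, importance, current, floor = 0,
                             ceiling = 100, combine = c("max", "sum")) {
  stopifnot(inherits(excl1, "gg_exclusion"), inherits(importance, "gg_grid"),
            inherits(current, "gg_grid"))
  combine <- match.arg(combine)
  base <- excl1$grid$values
  if (!identical(dim(importance$values), dim(base)) ||
      !identical(dim(current$values), dim(base)))
    stop("misaligned shapes")
  rescale <- function(x) {
    r <- x / 255 * 100
    r[r < floor] <- 0
    r[r > ceiling] <- 100
    r
  }
  imp <- rescale(importance$values)
  cur <- rescale(current$values)
  green <- if (combine == "max") pmax(imp, cur) else pmin(imp + cur, 100)
  out <- if (combine == "max") pmax(base, green) else pmin(base + green, 100)
  structure(list(grid = grid(out, excl1$grid$cellsize_m, kind = "continuous"),
                 variant = "exclusion2"),
            class = "gg_exclusion")
}

#' @export
print.gg_exclusion <- function(x, ...) {
  cat(sprintf("<gg_exclusion %s> mean resistance %.1f, %.1f%% fully excluded\n",
              x$variant, mean(x$grid$values),
              100 * mean(x$grid$values == 100)))
  invisible(x)
}
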