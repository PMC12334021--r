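#' Raster grid objects
#'
#' All layers in the pipeline are carried by a single lightweight raster
#' container: a numeric matrix plus a cell size in metres, a nodata
#' sentinel and a kind tag. Grids are abstract (unprojected); the
#' convention everywhere is row-major with the origin at the top-left and
#' 1-based R indices. Any georeferencing metadata read from a file is
#' carried opaquely in `attr(, "georef")` and never used in computation.
#'
#' @param values numeric matrix (rows x cols).
#' @param cellsize_m positive cell edge length in metres (default 90).
#' @param nodata nodata sentinel (default `NA`).
#' @param kind one of `"categorical"`, `"continuous"`, `"binary"`.
#' @param codes for categorical grids, the set of legal class codes.
#' @return an object of class `gg_grid`.
#' @examples
#' g <- grid(matrix(0, 3, 3), cellsize_m = 90, kind = "binary")
#' area_of_grid(g)
#' @export
grid <- function(values, cellsize_m = 90, nodata = NA, kind = "continuous",
                 codes = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(nrow(values) >= 1, ncol(values) >= 1, cellsize_m > 0)
  kind <- match.arg(kind, c("categorical", "continuous", "binary"))
  g <- structure(
    list(values = values, cellsize_m = cellsize_m, nodata = nodata,
         kind = kind, codes = codes),
    class = "gg_grid")
  validate_grid(g)
  g
}

validate_grid <- function(g) {
  v <- g$values
  ok <- !is.na(v)
  if (!is.na(g$nodata)) ok <- ok & v != g$nodata
  if (g$kind == "binary" && !all(v[ok] %in% c(0, 1)))
    stop("binary grid contains values other than {0, 1, nodata}")
  if (g$kind == "categorical" && !is.null(g$codes) &&
      !all(v[ok] %in% g$codes))
    stop("categorical grid contains undeclared class codes: ",
         paste(setdiff(unique(v[ok]), g$codes), collapse = ", "))
  invisible(g)
}

#' @export
print.gg_grid <- function(x, ...) {
  cat(sprintf("<gg_grid %s> %d x %d cells at %g m (%.2f ha)\n",
              x$kind, nrow(x$values), ncol(x$values), x$cellsize_m,
              area_of_grid(x)))
  invisible(x)
}

#' @export
dim.gg_grid <- function(x) dim(x$values)

#' Total grid area in hectares
#'
#' `rows * cols * cellsize_m^2 / 10000`. A 1000 x 1000 grid at 90 m covers
#' 810,000 ha.
#'
#' @param grid a [grid()] object.
#' @return area in hectares.
#' @export
area_of_grid <- function(grid) {
  d <- dim(grid$values)
  d[1] * d[2] * grid$cellsize_m^2 / 1e4
}

#' Read a raster from an ESRI ASCII grid file
#'
#' The plain-text ESRI ASCII dialect (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header followed by rows from the top) is the
#' raster format used throughout: every fixture and artifact stays
#' human-readable text.
#'
#' @param path file path.
#' @param layer_kind `"categorical"`, `"continuous"` or `"binary"`.
#' @param codes legal codes for categorical layers.
#' @param template optional [grid()] whose shape and cellsize the file
#'   must match.
#' @return a [grid()].
#' @export
read_grid <- function(path, layer_kind = "continuous", codes = NULL,
                      template = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  nhdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1
    } else break
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]])) stop("malformed ASCII grid header: missing ", key)
  vals <- scan(path, what = numeric(), skip = nhdr, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value %||% NA
  if (!is.na(nodata)) m[m == nodata] <- NA
  g <- grid(m, cellsize_m = hdr$cellsize, nodata = NA, kind = layer_kind,
            codes = codes)
  attr(g, "georef") <- list(xllcorner = hdr$xllcorner %||% 0,
                            yllcorner = hdr$yllcorner %||% 0)
  if (!is.null(template)) {
    if (!identical(dim(g$values), dim(template$values)))
      stop("grid shape ", paste(dim(g$values), collapse = "x"),
           " does not match template ",
           paste(dim(template$values), collapse = "x"))
    if (g$cellsize_m != template$cellsize_m)
      stop("cellsize mismatch against template")
  }
  g
}

#' Write a raster as an ESRI ASCII grid file
#'
#' @param grid a [grid()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  geo <- attr(grid, "georef") %||% list(xllcorner = 0, yllcorner = 0)
  v <- grid$values
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", geo$xllcorner),
    paste("yllcorner", geo$yllcorner),
    paste("cellsize", format(grid$cellsize_m, scientific = FALSE)),
    paste("NODATA_value", -9999)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a stack of aligned layers
#'
#' A layer stack bundles every raster the growth model consumes: one slope
#' layer (percent), LULC at >= 2 epochs, urban masks at >= 4 epochs, road
#' masks at >= 2 epochs, and an exclusion layer, all on one shape and
#' cellsize. Layer names follow `<layer>_<epoch>` (e.g. `urban_1990`).
#'
#' @param ... named [grid()] entries, or a single named list.
#' @return an object of class `gg_stack` (a named list of grids).
#' @export
layer_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "gg_grid")) layers <- layers[[1]]
  stopifnot(length(names(layers)) == length(layers))
  structure(layers, class = "gg_stack")
}

#' Validate a layer stack
#'
#' Report-only check: lists missing required layers, shape or cellsize
#' mismatches, and epoch-count shortfalls. Never raises for content
#' problems.
#'
#' @param stack a [layer_stack()].
#' @return a data frame with columns `issue` and `detail` (zero rows when
#'   the stack is complete and consistent).
#' @export
validate_stack <- function(stack) {
  issues <- list()
  add <- function(issue, detail)
    issues[[length(issues) + 1]] <<- data.frame(issue = issue, detail = detail)
  nm <- names(stack)
  counts <- c(slope = 1, lulc = 2, urban = 4, roads = 2, exclusion = 1)
  for (layer in names(counts)) {
    n <- sum(grepl(paste0("^", layer, "($|_)"), nm))
    if (n < counts[[layer]])
      add("missing-layer", sprintf("%s: found %d, need >= %d",
                                   layer, n, counts[[layer]]))
  }
  if (length(stack)) {
    ref <- stack[[1]]
    for (i in seq_along(stack)) {
      g <- stack[[i]]
      if (!identical(dim(g$values), dim(ref$values)))
        add("shape-mismatch", sprintf("%s: %s vs %s", nm[i],
                                      paste(dim(g$values), collapse = "x"),
                                      paste(dim(ref$values), collapse = "x")))
      else if (g$cellsize_m != ref$cellsize_m)
        add("cellsize-mismatch", sprintf("%s: %g vs %g", nm[i],
                                         g$cellsize_m, ref$cellsize_m))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(issue = character(0), detail = character(0))
}

# Epoch-sorted layer names matching a prefix, e.g. "urban" -> urban_1990...
stack_epochs <- function(stack, prefix) {
  nm <- grep(paste0("^", prefix, "_\\d+$"), names(stack), value = TRUE)
  nm[order(as.integer(sub(paste0("^", prefix, "_"), "", nm)))]
}
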