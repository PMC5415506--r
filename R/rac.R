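## Spatial diagnostics and the residual autocovariate (RAC).

#' Residual autocovariate from first-pass model residuals
#'
#' Rasterises residuals of a model fitted WITHOUT spatial terms onto a
#' regular lat/lon grid (cell means), then assigns each specimen the mean
#' residual of the 8 cells surrounding its own (queen neighbourhood,
#' focal cell excluded, empty neighbours ignored). Specimens with no
#' occupied neighbouring cell get 0. Adding this autocovariate to the
#' refitted model absorbs residual spatial autocorrelation.
#'
#' @param residuals numeric, per-specimen residuals.
#' @param latitude,longitude decimal degrees per specimen.
#' @param cell grid cell size in degrees (default 1).
#' @return numeric vector of RAC values, one per specimen.
#' @export
computeRac <- function(residuals, latitude, longitude, cell = 1) {
  stopifnot(length(residuals) == length(latitude),
            length(latitude) == length(longitude))
  cx <- floor(longitude / cell)
  cy <- floor(latitude / cell)
  key <- paste(cx, cy, sep = ":")
  cellMean <- tapply(residuals, key, mean)
  if (length(cellMean) == 1L) {
    warning("all specimens fall in one grid cell; RAC is identically 0")
    return(numeric(length(residuals)))
  }
  offsets <- expand.grid(dx = -1:1, dy = -1:1)
  offsets <- offsets[!(offsets$dx == 0 & offsets$dy == 0), ]
  rac <- numeric(length(residuals))
  ucells <- unique(data.frame(cx = cx, cy = cy, key = key,
                              stringsAsFactors = FALSE))
  racByCell <- setNames(numeric(nrow(ucells)), ucells$key)
  for (r in seq_len(nrow(ucells))) {
    nbKeys <- paste(ucells$cx[r] + offsets$dx, ucells$cy[r] + offsets$dy,
                    sep = ":")
    vals <- cellMean[nbKeys]
    vals <- vals[!is.na(vals)]
    racByCell[r] <- if (length(vals)) mean(vals) else 0
  }
  as.numeric(racByCell[key])
}

#' Moran's I spatial autocorrelation of residuals
#'
#' Standard Moran's I with row-standardised weights. By default weights
#' are inverse great-circle-free planar distances between specimen
#' locations (1/d, zero on the diagonal); a custom weight matrix (e.g.
#' rook contiguity) can be supplied instead.
#'
#' @param residuals numeric values.
#' @param latitude,longitude coordinates (ignored when \code{weights}
#'   given).
#' @param weights optional n x n weight matrix.
#' @return list with \code{observed} Moran's I and \code{expected}
#'   \eqn{-1/(n-1)} under the null.
#' @export
moransI <- function(residuals, latitude = NULL, longitude = NULL,
                    weights = NULL) {
  n <- length(residuals)
  if (is.null(weights)) {
    d <- as.matrix(dist(cbind(longitude, latitude)))
    d[d == 0] <- NA
    weights <- 1 / d
    weights[is.na(weights)] <- 0
  }
  rs <- rowSums(weights)
  rs[rs == 0] <- 1
  W <- weights / rs
  mi <- ape::Moran.I(residuals, W)
  list(observed = mi$observed, expected = mi$expected)
}

#' Lag-1 autocorrelation of year-mean residuals
#'
#' Residuals are averaged within collection year; the lag-1 Pearson
#' autocorrelation of the year-ordered series diagnoses remaining
#' temporal autocorrelation (the reason decade, not year, enters the
#' linear models).
#'
#' @param residuals numeric residuals.
#' @param year collection year per residual.
#' @return lag-1 autocorrelation of the year-mean series.
#' @export
residualAcf <- function(residuals, year) {
  m <- tapply(residuals, year, mean)
  m <- m[order(as.numeric(names(m)))]
  n <- length(m)
  if (n < 3L) stop("need at least 3 distinct years")
  if (sd(m) == 0) stop("zero variance in year-mean residuals")
  cor(m[-1], m[-n])
}
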