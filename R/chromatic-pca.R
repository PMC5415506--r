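## Per-species PCA of xyz chromatic coordinates, sign-anchored to
## carotenoid chroma.

#' Summarise chromatic variation by a species-level PCA
#'
#' Eigendecomposition of the covariance matrix of the centred xyz
#' chromatic coordinates of one species' specimens (covariance, not
#' correlation, so jnd units are preserved). PC1 scores are sign-aligned
#' so that higher PC1 means more intense carotenoid colour: if the
#' correlation of PC1 with carotenoid chroma is negative, the scores (and
#' the first loading vector) are flipped.
#'
#' @param coords numeric matrix (n x 3) of specimen xyz coordinates, or a
#'   data.frame with columns x, y, z.
#' @param chroma numeric(n), carotenoid chroma per specimen, aligned with
#'   the rows of \code{coords}.
#' @return list with \code{loadings} (3x3 orthonormal),
#'   \code{varianceExplained} (proportions, non-increasing),
#'   \code{scores} (PC1 per specimen, jnd), and \code{signAnchor}
#'   (corr(PC1, chroma), non-negative after alignment).
#' @export
fitSpeciesPca <- function(coords, chroma) {
  coords <- as.matrix(coords[, c("x", "y", "z")])
  if (nrow(coords) < 3L)
    stop("PCA needs at least 3 specimens; got ", nrow(coords))
  if (length(chroma) != nrow(coords))
    stop("chroma must align with coords rows")
  cv <- stats::cov(coords)
  if (max(abs(cv)) == 0) stop("zero chromatic variance: PCA undefined")
  eg <- eigen(cv, symmetric = TRUE)
  centred <- sweep(coords, 2, colMeans(coords))
  scores <- as.numeric(centred %*% eg$vectors[, 1])
  anchor <- if (sd(chroma) > 0 && sd(scores) > 0) cor(scores, chroma) else 0
  loadings <- eg$vectors
  if (!is.na(anchor) && anchor < 0) {
    scores <- -scores
    loadings[, 1] <- -loadings[, 1]
    anchor <- -anchor
  }
  list(
    loadings = loadings,
    varianceExplained = eg$values / sum(eg$values),
    scores = scores,
    signAnchor = anchor
  )
}

#' Score specimens of every species on chromatic PC1
#'
#' Applies [fitSpeciesPca()] species by species and returns the records
#' with a \code{pc1} column appended (and the per-species variance
#' explained as an attribute).
#'
#' @param records specimen data.frame with a \code{species} column.
#' @param coords n x 3 matrix of xyz coordinates aligned with records.
#' @param chroma numeric(n) carotenoid chroma aligned with records.
#' @return records with a \code{pc1} column; attribute
#'   \code{"pca_summary"} holds one [fitSpeciesPca()] result per species.
#' @export
scoreChromaticPc1 <- function(records, coords, chroma) {
  stopifnot(nrow(records) == nrow(coords), nrow(records) == length(chroma))
  records$pc1 <- NA_real_
  summaries <- list()
  for (sp in unique(records$species)) {
    idx <- which(records$species == sp)
    fit <- fitSpeciesPca(coords[idx, , drop = FALSE], chroma[idx])
    records$pc1[idx] <- fit$scores
    summaries[[sp]] <- fit
  }
  attr(records, "pca_summary") <- summaries
  records
}
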