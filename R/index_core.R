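#' Fit the index model (first principal component)
#'
#' Columns are z-score standardized, so the principal components are the
#' eigenvectors of the indicator correlation matrix; this follows the
#' asset-index tradition of pooling mixed-scale indicators (counts, ratios,
#' binaries) on a common scale. The first component's loading vector is the
#' index: because every indicator is deprivation-oriented, the sign is fixed
#' so the loadings sum to a positive value and a higher score means more
#' deprived. The fit is pooled over all rows supplied (all countries or
#' regions together), which keeps scores comparable across regions; sample
#' weights do not enter the PCA — they are applied at aggregation.
#'
#' @param x numeric matrix of indicators, columns in canonical order (see
#'   [indicator_matrix()]).
#' @return object of class `pdi_model`: list with `means`, `sds`,
#'   `loadings` (unit Euclidean norm), `explained_variance_share` and
#'   `columns`.
#' @export
fit_pdi_model <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to fit the index model")
  means <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero) > 0) {
    nm <- if (!is.null(colnames(x))) colnames(x)[zero] else as.character(zero)
    stop("zero-variance indicator column(s): ", paste(nm, collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  loadings <- pc$rotation[, 1]
  if (sum(loadings) <= 0) loadings <- -loadings
  loadings <- loadings / sqrt(sum(loadings^2))
  structure(
    list(
      means = means,
      sds = sds,
      loadings = loadings,
      explained_variance_share = pc$sdev[1]^2 / ncol(x),
      columns = colnames(x)
    ),
    class = "pdi_model"
  )
}

#' Score households with a fitted index model
#'
#' The score is the projection of the z-scored indicator row onto the first
#' component: `score_i = sum_j loadings_j (x_ij - mean_j) / sd_j`. Scores on
#' the training matrix have mean zero.
#'
#' @param model a `pdi_model`.
#' @param x indicator matrix with columns matching the training order.
#' @return numeric score vector, one element per row of `x`.
#' @export
score_households <- function(model, x) {
  stopifnot(inherits(model, "pdi_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$loadings)) {
    stop("indicator matrix has ", ncol(x), " columns; model expects ",
         length(model$loadings))
  }
  if (!is.null(colnames(x)) && !is.null(model$columns) &&
      !identical(colnames(x), model$columns)) {
    stop("indicator columns do not match the training order: ",
         paste(colnames(x), collapse = ", "))
  }
  z <- sweep(sweep(x, 2, model$means, "-"), 2, model$sds, "/")
  drop(z %*% model$loadings)
}

#' Serialize / read an index model as JSON text
#'
#' @param model a `pdi_model`.
#' @param path file path.
#' @export
write_pdi_model <- function(model, path) {
  stopifnot(inherits(model, "pdi_model"))
  obj <- list(
    columns = model$columns,
    means = unname(model$means),
    sds = unname(model$sds),
    loadings = unname(model$loadings),
    explained_variance_share = model$explained_variance_share
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pdi_model
#' @export
read_pdi_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      means = stats::setNames(obj$means, obj$columns),
      sds = stats::setNames(obj$sds, obj$columns),
      loadings = stats::setNames(obj$loadings, obj$columns),
      explained_variance_share = obj$explained_variance_share,
      columns = obj$columns
    ),
    class = "pdi_model"
  )
}
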