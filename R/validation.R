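#' Correlate regional index values with epidemic caseloads
#'
#' Matches regions by id, drops (and reports) unmatched ones, and returns
#' the correlation across matched pairs. Both Pearson and Spearman are of
#' interest: Spearman is invariant to the min-max normalization of the
#' index, Pearson is not (it is invariant to affine maps, which min-max
#' is, so in practice both are unaffected).
#'
#' @param aggregates `region_aggregate` data frame (uses `pdi_normalized`,
#'   falling back to `pdi_raw` when normalization is absent).
#' @param caseloads data frame with `region_id`, `cumulative_cases`.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `correlation`, `method`, `n_regions`, `unmatched`.
#' @export
correlate_with_caseload <- function(aggregates, caseloads,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(aggregates), is.data.frame(caseloads))
  pdi <- if ("pdi_normalized" %in% names(aggregates) &&
             !anyNA(aggregates$pdi_normalized)) {
    aggregates$pdi_normalized
  } else {
    aggregates$pdi_raw
  }
  a <- data.frame(region_id = aggregates$region_id, pdi = pdi)
  m <- merge(a, caseloads[, c("region_id", "cumulative_cases")], by = "region_id")
  unmatched <- c(setdiff(a$region_id, m$region_id),
                 setdiff(caseloads$region_id, m$region_id))
  if (nrow(m) < 3) stop("fewer than 3 matched regions; correlation undefined")
  if (length(unmatched) > 0) {
    message("unmatched regions excluded: ", paste(unmatched, collapse = ", "))
  }
  list(
    correlation = stats::cor(m$pdi, m$cumulative_cases, method = method),
    method = method,
    n_regions = nrow(m),
    unmatched = unmatched
  )
}

#' Leave-one-indicator-out robustness of the index
#'
#' Refits the index model on each 4-indicator submatrix, rescores all
#' households, and reports the Pearson correlation of each reduced score
#' vector with the full 5-indicator scores. Values near 1 show that no
#' single indicator drives the index.
#'
#' @param x indicator matrix in canonical column order.
#' @return list with `correlations` (named by the dropped indicator, in
#'   canonical order), `scores` (matrix of reduced score vectors) and
#'   `full_scores`.
#' @export
leave_one_out_index <- function(x) {
  x <- as.matrix(x)
  full_model <- fit_pdi_model(x)
  full <- score_households(full_model, x)
  nm <- if (!is.null(colnames(x))) colnames(x) else paste0("col", seq_len(ncol(x)))
  scores <- matrix(NA_real_, nrow(x), ncol(x), dimnames = list(NULL, nm))
  cors <- stats::setNames(numeric(ncol(x)), nm)
  for (j in seq_len(ncol(x))) {
    sub <- x[, -j, drop = FALSE]
    mod <- fit_pdi_model(sub)
    scores[, j] <- score_households(mod, sub)
    cors[j] <- stats::cor(scores[, j], full)
  }
  list(correlations = cors, scores = scores, full_scores = full)
}

#' Recovery of the latent regional truth
#'
#' Spearman rank correlation between the (normalized) regional index and
#' the true regional mean latent deprivation of the synthetic generator —
#' the acceptance surface for the whole synthetic pipeline.
#'
#' @param aggregates `region_aggregate` data frame.
#' @param truth data frame with `region_id`, `risk`.
#' @return list with `spearman` and `n_regions`.
#' @export
recover_truth <- function(aggregates, truth) {
  stopifnot(is.data.frame(aggregates), is.data.frame(truth))
  pdi <- if ("pdi_normalized" %in% names(aggregates) &&
             !anyNA(aggregates$pdi_normalized)) {
    aggregates$pdi_normalized
  } else {
    aggregates$pdi_raw
  }
  a <- data.frame(region_id = aggregates$region_id, pdi = pdi)
  m <- merge(a, truth[, c("region_id", "risk")], by = "region_id")
  if (nrow(m) < 3) stop("fewer than 3 matched regions; correlation undefined")
  list(
    spearman = stats::cor(m$pdi, m$risk, method = "spearman"),
    n_regions = nrow(m)
  )
}

#' Full validation report
#'
#' @param aggregates `region_aggregate` data frame.
#' @param caseloads regional caseload table.
#' @param x indicator matrix (for the leave-one-out check); optional.
#' @param truth optional regional truth table.
#' @return list of class `pdi_validation`.
#' @export
validation_report <- function(aggregates, caseloads, x = NULL, truth = NULL) {
  rep <- list(
    pearson = correlate_with_caseload(aggregates, caseloads, "pearson"),
    spearman = correlate_with_caseload(aggregates, caseloads, "spearman")
  )
  if (!is.null(x)) rep$loo <- leave_one_out_index(x)$correlations
  if (!is.null(truth)) rep$truth <- recover_truth(aggregates, truth)
  class(rep) <- "pdi_validation"
  rep
}
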