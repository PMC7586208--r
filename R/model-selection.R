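#' Rank candidate structural models by DOPE and RMSD
#'
#' Orders a model-quality table best-first: ascending DOPE statistical
#' potential (lower energy = better model) as the primary key, ascending RMSD
#' to the reference structure as the tie-break, and ascending model id as the
#' final tie-break.  DOPE leads because, when the two criteria disagree, the
#' lowest-energy model is the one taken forward as the docking substrate.
#'
#' @param scores data.frame with columns \code{model_id}, \code{rmsd} (Å),
#'   \code{dope}
#' @return the same data.frame, rows reordered best-first, with a
#'   \code{rank} column prepended
#' @examples
#' rankModels(data.frame(model_id = 1:3, rmsd = c(1.2, 1.0, 1.1),
#'                       dope = c(-100, -100, -200)))
#' @export
rankModels <- function(scores) {
  need <- c("model_id", "rmsd", "dope")
  if (!all(need %in% names(scores)))
    stop("scores must have columns: ", paste(need, collapse = ", "))
  if (nrow(scores) < 1) stop("scores must contain at least one model")
  if (anyDuplicated(scores$model_id))
    stop("duplicate model ids in score table")
  if (any(scores$rmsd < 0)) stop("rmsd must be non-negative")
  o <- order(scores$dope, scores$rmsd, scores$model_id)
  out <- scores[o, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Best model under the DOPE-primary ranking
#'
#' @inheritParams rankModels
#' @return the top-ranked row of [rankModels()] output
#' @export
bestModel <- function(scores) rankModels(scores)[1, , drop = FALSE]
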