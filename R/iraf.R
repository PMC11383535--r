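#' Item-wise RSM-activity fit (IRAF)
#'
#' The core item-wise statistic: the Pearson correlation between one item's
#' row of the (temporally corrected) activity-pattern matrix and the same
#' item's row of a model RSM, both excluding the self-similarity element.
#' It indexes the representational strength of that item, in that region, in
#' that phase, for that feature type. Unlike whole-matrix second-order RSA
#' it retains trial-level variance, so stimuli can enter downstream models
#' as a random effect.
#'
#' @param apm an [apm_matrix()] with `item_ids` set.
#' @param rsm a [model_rsm()] containing (at least) the APM's items.
#' @param item the item (concept id) to score.
#' @param fisher_z if `TRUE`, return the Fisher z-transform
#'   `atanh(r)` instead of raw r.
#' @return numeric scalar in `[-1, 1]` (or its Fisher z), `NA` with a
#'   warning when the item's pattern row is constant.
#' @export
compute_iraf <- function(apm, rsm, item, fisher_z = FALSE) {
  stopifnot(inherits(apm, "apm_matrix"), inherits(rsm, "model_rsm"))
  if (is.null(apm$item_ids)) stop("APM carries no item ids")
  i <- match(item, apm$item_ids)
  if (is.na(i)) stop("item '", item, "' not present in the APM")
  ridx <- match(apm$item_ids, rsm$item_ids)
  if (anyNA(ridx)) stop("APM items missing from the RSM: ",
                        paste(apm$item_ids[is.na(ridx)], collapse = ", "))
  a <- apm$values[i, -i]
  r <- rsm$values[ridx[i], ridx[-i]]
  if (stats::sd(a) == 0 || stats::sd(r) == 0) {
    warning("constant row for item '", item, "'; IRAF undefined")
    return(NA_real_)
  }
  val <- stats::cor(a, r)
  if (fisher_z) atanh(val) else val
}

#' Assemble the long-format IRAF analysis table
#'
#' One row per participant x ROI x phase x feature type x valid old item,
#' the input to the mixed-effects stage. Rows whose IRAF is undefined
#' (constant pattern row) are dropped and their count reported.
#'
#' @param apms list of corrected APM entries, each a list with
#'   `participant`, `roi_id`, `roi_class`, `phase`, and `apm` (an
#'   [apm_matrix()] with `item_ids`).
#' @param rsms named list with elements `visual` and `semantic`, each a
#'   [model_rsm()].
#' @param trials trial table whose `memory` labels have been resolved (see
#'   [adjust_memory_labels()]).
#' @param fisher_z pass-through to [compute_iraf()].
#' @return data frame with columns `participant`, `roi_id`, `roi_class`,
#'   `phase`, `feature_type`, `item`, `iraf`, `memory`.
#' @export
build_iraf_table <- function(apms, rsms, trials, fisher_z = FALSE) {
  if (!all(c("visual", "semantic") %in% names(rsms)))
    stop("`rsms` must contain 'visual' and 'semantic' model RSMs")
  mem_key <- paste(trials$participant, trials$phase, trials$concept_id)
  rows <- list()
  dropped <- 0L
  for (entry in apms) {
    apm <- entry$apm
    if (!isTRUE(apm$corrected))
      stop("all APMs must be temporally corrected before IRAF computation")
    items <- apm$item_ids
    mem <- trials$memory[match(paste(entry$participant, entry$phase, items),
                               mem_key)]
    keep <- which(!is.na(mem) & mem %in% c("remembered", "forgotten"))
    for (ft in c("visual", "semantic")) {
      vals <- suppressWarnings(
        vapply(items[keep], function(it) compute_iraf(apm, rsms[[ft]], it,
                                                      fisher_z = fisher_z),
               numeric(1)))
      ok <- !is.na(vals)
      dropped <- dropped + sum(!ok)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = entry$participant, roi_id = entry$roi_id,
        roi_class = entry$roi_class, phase = entry$phase, feature_type = ft,
        item = items[keep][ok], iraf = unname(vals[ok]),
        memory = mem[keep][ok], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (dropped > 0)
    message(dropped, " IRAF row(s) dropped (undefined correlation)")
  out
}
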