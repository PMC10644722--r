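# Structure-activity similarity (SAS) maps: pairwise Tanimoto similarity
# against absolute pIC50 difference, partitioned into four zones:
#   ZI  low similarity,  low  |dpIC50|  - scaffold hops
#   ZII high similarity, low  |dpIC50|  - smooth / continuous SAR
#   ZIII low similarity, high |dpIC50|  - non-descript
#   ZIV high similarity, high |dpIC50|  - activity cliffs
# "High" includes the threshold value (>=).

ZONES <- c("ZI", "ZII", "ZIII", "ZIV")

#' Zone thresholds for a SAS map
#'
#' @param s_low_high similarity boundary in [0, 1] (default 0.5), or `NA` to
#'   use the median off-diagonal pairwise similarity of the map's own
#'   similarity matrix (data-driven option).
#' @param a_low_high activity-difference boundary in pIC50 units (default 1).
#' @return an object of class `zone_thresholds`.
#' @export
zone_thresholds <- function(s_low_high = 0.5, a_low_high = 1.0) {
  if (!is.na(s_low_high)) stopifnot(s_low_high >= 0, s_low_high <= 1)
  stopifnot(a_low_high > 0)
  structure(list(s_low_high = s_low_high, a_low_high = a_low_high),
            class = "zone_thresholds")
}

#' Classify a compound pair into a SAS zone
#'
#' @param similarity Tanimoto similarity in [0, 1] (vectorized).
#' @param d_activity absolute pIC50 difference, >= 0 (vectorized).
#' @param thresholds a [zone_thresholds()] (with a resolved numeric
#'   similarity boundary).
#' @return character vector of zone labels.
#' @export
#' @examples
#' classify_zone(c(0.2, 0.9, 0.9), c(0.1, 0.1, 2), zone_thresholds())
classify_zone <- function(similarity, d_activity, thresholds = zone_thresholds()) {
  stopifnot(inherits(thresholds, "zone_thresholds"))
  if (is.na(thresholds$s_low_high)) {
    stop("similarity threshold is NA; resolve it (see build_sas_map) first",
         call. = FALSE)
  }
  if (any(similarity < 0 | similarity > 1)) {
    stop("similarity must lie in [0, 1]", call. = FALSE)
  }
  if (any(d_activity < 0)) stop("d_activity must be >= 0", call. = FALSE)
  hs <- similarity >= thresholds$s_low_high
  ha <- d_activity >= thresholds$a_low_high
  ifelse(ha, ifelse(hs, "ZIV", "ZIII"), ifelse(hs, "ZII", "ZI"))
}

#' Build a structure-activity similarity map
#'
#' Combines a similarity matrix with per-compound pIC50 values into the full
#' set of (similarity, |dpIC50|) pairs with zone labels. In `all_pairs` mode
#' every unordered pair is emitted; in `reference` mode only the pairs that
#' contain the reference compound. Activity differences use the unrounded
#' pIC50 values (rounded reporting is a presentation convention only).
#'
#' @param records data.frame with columns `compound_id` and `pic50`.
#' @param sim a [similarity_matrix()] covering all compound ids.
#' @param thresholds a [zone_thresholds()]; an `NA` similarity boundary is
#'   resolved to the median off-diagonal pairwise similarity.
#' @param mode `"all_pairs"` or `"reference"`.
#' @param reference_id compound id anchoring `reference` mode.
#' @return an object of class `sas_map`: `pairs` (data.frame `id_a`, `id_b`,
#'   `similarity`, `d_activity`, `zone`), `zone_counts` (named integer),
#'   `thresholds`, `mode`, `reference_id`.
#' @export
build_sas_map <- function(records, sim, thresholds = zone_thresholds(),
                          mode = c("all_pairs", "reference"),
                          reference_id = NULL) {
  mode <- match.arg(mode)
  check_columns(records, c("compound_id", "pic50"), "compound table")
  stopifnot(inherits(sim, "similarity_matrix"))
  bad <- records$compound_id[!is.finite(records$pic50)]
  if (length(bad) > 0) {
    stop("missing pIC50 for compound(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ids <- records$compound_id
  if (!all(ids %in% rownames(sim))) {
    stop("similarity matrix does not cover all compound ids", call. = FALSE)
  }
  sim_m <- unclass(sim)[ids, ids]
  if (is.na(thresholds$s_low_high)) {
    thresholds$s_low_high <- stats::median(sim_m[upper.tri(sim_m)])
  }
  pic50 <- stats::setNames(records$pic50, ids)

  if (mode == "reference") {
    if (is.null(reference_id) || !reference_id %in% ids) {
      stop("reference mode requires a reference_id present in the records",
           call. = FALSE)
    }
    others <- setdiff(ids, reference_id)
    pairs <- data.frame(id_a = reference_id, id_b = others,
                        similarity = sim_m[reference_id, others],
                        d_activity = abs(pic50[reference_id] - pic50[others]),
                        row.names = NULL)
  } else {
    idx <- which(upper.tri(sim_m), arr.ind = TRUE)
    pairs <- data.frame(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
                        similarity = sim_m[idx],
                        d_activity = abs(pic50[ids[idx[, 1]]] - pic50[ids[idx[, 2]]]),
                        row.names = NULL)
  }
  pairs$zone <- classify_zone(pairs$similarity, pairs$d_activity, thresholds)
  counts <- table(factor(pairs$zone, levels = ZONES))
  structure(list(pairs = pairs,
                 zone_counts = stats::setNames(as.integer(counts), ZONES),
                 thresholds = thresholds, mode = mode,
                 reference_id = reference_id),
            class = "sas_map")
}

#' @export
print.sas_map <- function(x, ...) {
  cat("<sas_map>", x$mode,
      if (!is.null(x$reference_id)) paste0("(reference: ", x$reference_id, ")"),
      "\n  pairs:", nrow(x$pairs),
      sprintf("\n  thresholds: similarity %.3g, |dpIC50| %.3g\n",
              x$thresholds$s_low_high, x$thresholds$a_low_high))
  print(x$zone_counts)
  invisible(x)
}

# pairs from a sas_map that involve a given compound, with the partner id
.pairs_with <- function(result, id) {
  p <- result$pairs
  sel <- p$id_a == id | p$id_b == id
  p <- p[sel, , drop = FALSE]
  p$partner <- ifelse(p$id_a == id, p$id_b, p$id_a)
  p
}

#' Scaffold hops relative to a reference compound
#'
#' Compounds whose pair with the reference falls in ZI (low similarity, low
#' activity difference): structurally novel chemotypes that keep the
#' reference's potency. Sorted by ascending activity difference, then
#' ascending similarity.
#'
#' @param result a [build_sas_map()] result covering `reference_id`.
#' @param reference_id the anchor compound id.
#' @return character vector of compound ids.
#' @export
scaffold_hops <- function(result, reference_id) {
  stopifnot(inherits(result, "sas_map"))
  p <- .pairs_with(result, reference_id)
  p <- p[p$zone == "ZI", , drop = FALSE]
  p$partner[order(p$d_activity, p$similarity)]
}

#' Activity cliffs on a SAS map
#'
#' All pairs in ZIV (high similarity, high activity difference), sorted by
#' descending similarity: small structural changes with large potency
#' consequences.
#'
#' @param result a [build_sas_map()] result.
#' @return data.frame of ZIV pairs.
#' @export
activity_cliffs <- function(result) {
  stopifnot(inherits(result, "sas_map"))
  p <- result$pairs[result$pairs$zone == "ZIV", , drop = FALSE]
  p[order(-p$similarity), , drop = FALSE]
}

#' True analogs of a reference compound
#'
#' Compounds whose pair with the reference falls in ZII (high similarity,
#' low activity difference): same chemotype, same potency class.
#'
#' @inheritParams scaffold_hops
#' @return character vector of compound ids.
#' @export
true_analogs <- function(result, reference_id) {
  stopifnot(inherits(result, "sas_map"))
  p <- .pairs_with(result, reference_id)
  p$partner[p$zone == "ZII"]
}

#' @export
plot.sas_map <- function(x, ...) {
  cols <- c(ZI = "#1b9e77", ZII = "#7570b3", ZIII = "#d95f02", ZIV = "#e7298a")
  graphics::plot(x$pairs$similarity, x$pairs$d_activity,
                 col = cols[x$pairs$zone], pch = 19,
                 xlab = "Tanimoto similarity", ylab = "|dpIC50|",
                 main = "SAS map", xlim = c(0, 1), ...)
  graphics::abline(v = x$thresholds$s_low_high, h = x$thresholds$a_low_high,
                   lty = 2, col = "grey50")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}
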