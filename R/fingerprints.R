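# Molecular fingerprints, Tanimoto similarity, and TSD-based fingerprint
# selection. Fingerprint bit definitions are delegated to ChemmineR /
# ChemmineOB (Open Babel); this module owns the similarity analysis.

.FP_NAMES <- c("fp2_path", "fp3_keys", "fp4_keys", "maccs", "atompair")

#' Supported fingerprint names
#'
#' `fp2_path` (1024-bit linear-path), `fp3_keys` and `fp4_keys` (SMARTS key
#' sets), `maccs` (MACCS-like keys), all via Open Babel; `atompair`
#' (1024-bit folded atom-pair descriptor set) via ChemmineR.
#'
#' @return character vector of fingerprint names.
#' @export
fingerprint_names <- function() .FP_NAMES

# Parse SMILES into an SDFset, stopping with the offending id on failure.
.parse_smiles <- function(records) {
  check_columns(records, c("compound_id", "smiles"), "compound table")
  if (anyDuplicated(records$compound_id)) {
    stop("compound ids must be unique", call. = FALSE)
  }
  smis <- records$smiles
  names(smis) <- records$compound_id
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smis)),
    error = function(e) {
      stop("SMILES parsing failed: ", conditionMessage(e), call. = FALSE)
    })
  # the parser silently drops invalid records: detect and name them
  if (length(sdf) != nrow(records)) {
    dropped <- setdiff(records$compound_id, ChemmineR::sdfid(sdf))
    stop("unparseable SMILES for compound: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  valid <- ChemmineR::validSDF(sdf)
  if (!all(valid)) {
    stop("unparseable SMILES for compound: ",
         paste(records$compound_id[!valid], collapse = ", "), call. = FALSE)
  }
  ChemmineR::cid(sdf) <- records$compound_id
  sdf
}

#' Compute binary molecular fingerprints
#'
#' @param records data.frame with columns `compound_id` and `smiles`.
#' @param fp_name one of [fingerprint_names()].
#' @return an object of class `fingerprint_set`: list with `fp_name`,
#'   `length` (bits), and `bits` (0/1 integer matrix, one row per compound,
#'   rownames = compound ids).
#' @export
compute_fingerprints <- function(records, fp_name = "fp2_path") {
  if (!fp_name %in% .FP_NAMES) {
    stop("unknown fingerprint '", fp_name, "'; supported: ",
         paste(.FP_NAMES, collapse = ", "), call. = FALSE)
  }
  sdf <- .parse_smiles(records)
  bits <- if (fp_name == "atompair") {
    ap <- suppressWarnings(ChemmineR::sdf2ap(sdf))
    # most-frequent atom-pair descriptor basis shipped with ChemmineR
    e <- new.env()
    utils::data("apfp", package = "ChemmineR", envir = e)
    fp <- ChemmineR::desc2fp(ap, descnames = as.character(e$apfp$AP[seq_len(1024)]),
                             type = "FPset")
    fp@fpma
  } else {
    ob_name <- c(fp2_path = "FP2", fp3_keys = "FP3", fp4_keys = "FP4",
                 maccs = "MACCS")[[fp_name]]
    fp <- suppressWarnings(ChemmineR::fingerprintOB(sdf, ob_name))
    fp@fpma
  }
  storage.mode(bits) <- "integer"
  rownames(bits) <- records$compound_id
  structure(list(fp_name = fp_name, length = ncol(bits), bits = bits),
            class = "fingerprint_set")
}

#' Build a fingerprint set from a raw bit matrix
#'
#' Useful for ingesting externally computed fingerprints (e.g. an 881-bit
#' PubChem bit-string table) or constructing test cases.
#'
#' @param bits 0/1 matrix, one row per compound, rownames = compound ids.
#' @param fp_name label for the fingerprint.
#' @return a `fingerprint_set`.
#' @export
fingerprint_set <- function(bits, fp_name = "custom") {
  bits <- as.matrix(bits)
  if (is.null(rownames(bits))) stop("bit matrix needs compound-id rownames",
                                    call. = FALSE)
  if (anyDuplicated(rownames(bits))) stop("compound ids must be unique",
                                          call. = FALSE)
  if (!all(bits %in% c(0L, 1L))) stop("fingerprint bits must be 0/1",
                                      call. = FALSE)
  storage.mode(bits) <- "integer"
  structure(list(fp_name = fp_name, length = ncol(bits), bits = bits),
            class = "fingerprint_set")
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`. Two all-zero vectors are defined to have
#' similarity 0 (featureless molecules are treated as dissimilar rather than
#' leaving 0/0 undefined).
#'
#' @param a,b 0/1 (or logical) vectors of equal length.
#' @return similarity in [0, 1].
#' @export
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)) # 0.5
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' Computes all pairwise coefficients via bit-count cross-products; the
#' result is identical to looping [tanimoto()] over every pair. The diagonal
#' is set to 1 by convention.
#'
#' @param fps a `fingerprint_set` with at least 2 compounds.
#' @return an object of class `similarity_matrix`: symmetric numeric matrix
#'   with compound-id dimnames.
#' @export
similarity_matrix <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  m <- fps$bits
  if (nrow(m) < 2) stop("need at least 2 compounds", call. = FALSE)
  inter <- tcrossprod(m)
  on_bits <- rowSums(m)
  un <- outer(on_bits, on_bits, "+") - inter
  sim <- ifelse(un == 0, 0, inter / un)
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(m), rownames(m))
  structure(sim, class = c("similarity_matrix", "matrix"))
}

# Off-diagonal unordered pair similarities of a similarity matrix.
pair_similarities <- function(sim) {
  sim <- unclass(sim)
  sim[upper.tri(sim)]
}

#' Tanimoto similarity cumulative distribution (TSD) curve
#'
#' For each threshold t, the fraction of the n(n-1)/2 unordered compound
#' pairs whose similarity is <= t. Discriminative fingerprints concentrate
#' pairs at low similarity, pushing the curve up early.
#'
#' @param sim a [similarity_matrix()].
#' @param grid ascending thresholds within [0, 1]; default 101 equal steps.
#' @param fp_name label carried into the result.
#' @return an object of class `tsd_curve`: data.frame with columns
#'   `threshold`, `cumulative_fraction`, plus attribute `fp_name`.
#' @export
tsd_curve <- function(sim, grid = seq(0, 1, by = 0.01), fp_name = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (is.unsorted(grid, strictly = TRUE) || any(grid < 0) || any(grid > 1)) {
    stop("threshold grid must be strictly ascending within [0, 1]", call. = FALSE)
  }
  ps <- pair_similarities(sim)
  frac <- vapply(grid, function(t) mean(ps <= t), numeric(1))
  out <- data.frame(threshold = grid, cumulative_fraction = frac)
  attr(out, "fp_name") <- fp_name %||% "unnamed"
  class(out) <- c("tsd_curve", "data.frame")
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Select the most discriminative fingerprint from TSD curves
#'
#' Ranks fingerprints by area under their TSD curve (trapezoidal rule):
#' a larger area means more pairs sit at low similarity, i.e. the
#' fingerprint spreads the library out more. Ties are broken by name order
#' and flagged.
#'
#' @param curves named list of [tsd_curve()] objects on the same compound
#'   set (names are used if the curves carry no `fp_name`).
#' @return an object of class `fp_selection`: `winner` (name), `ranking`
#'   (data.frame of name and AUC, best first), `tie` (logical).
#' @export
select_fingerprint <- function(curves) {
  if (length(curves) < 2) stop("need at least 2 TSD curves", call. = FALSE)
  nms <- vapply(seq_along(curves), function(k) {
    attr(curves[[k]], "fp_name") %||% names(curves)[k]
  }, character(1))
  if (!is.null(names(curves)) && all(nzchar(names(curves)))) nms <- names(curves)
  auc <- vapply(curves, function(cv) {
    x <- cv$threshold; y <- cv$cumulative_fraction
    n <- length(y)
    sum(diff(x) * (y[-n] + y[-1]) / 2)
  }, numeric(1))
  ord <- order(-auc, nms)
  ranking <- data.frame(fp_name = nms[ord], tsd_auc = auc[ord], row.names = NULL)
  tie <- length(auc) > 1 && isTRUE(all.equal(ranking$tsd_auc[1], ranking$tsd_auc[2]))
  structure(list(winner = ranking$fp_name[1], ranking = ranking, tie = tie),
            class = "fp_selection")
}

#' @export
print.fp_selection <- function(x, ...) {
  cat("<fp_selection> winner:", x$winner, if (x$tie) "(tied)" else "", "\n")
  print(x$ranking, digits = 4)
  invisible(x)
}

#' @export
plot.tsd_curve <- function(x, ...) {
  graphics::plot(x$threshold, x$cumulative_fraction, type = "s",
                 xlab = "Tanimoto similarity threshold",
                 ylab = "cumulative fraction of pairs",
                 main = attr(x, "fp_name"), ...)
  invisible(x)
}
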